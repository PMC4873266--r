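test_that("delta to atom percent matches high-precision evaluation", {
  r <- 0.0036765
  k <- isotope_constants(r_std = r)
  # direct evaluation of 100*R/(1+R), R = r*(1 + delta/1000)
  expect_equal(delta_to_atom_percent(0, k), 100 * r / (1 + r),
               tolerance = 1e-12)
  expect_equal(delta_to_atom_percent(0, k), 0.3663033, tolerance = 1e-6)
  expect_equal(delta_to_atom_percent(1000, k), 100 * 2 * r / (1 + 2 * r),
               tolerance = 1e-12)
  expect_equal(delta_to_atom_percent(1000, k), 0.7299328, tolerance = 1e-6)
  # the strongest tissue enrichment seen in the field data, 284 per mil
  expect_equal(delta_to_atom_percent(284, k), 0.4698446, tolerance = 1e-6)
  # strictly increasing in delta
  d <- seq(-900, 5000, length.out = 200)
  expect_true(all(diff(delta_to_atom_percent(d, k)) > 0))
})

test_that("delta domain is guarded and constants validated", {
  expect_error(delta_to_atom_percent(-1000), "-1000")
  expect_error(delta_to_atom_percent(-1500), "-1000")
  expect_error(isotope_constants(r_std = -1), "positive")
  expect_error(isotope_constants(0.0036765, natural_abundance_atom_pct = 0.5),
               "inconsistent")
  k <- isotope_constants(0.0036765)
  expect_equal(k$natural_abundance_atom_pct,
               100 * k$r_std / (1 + k$r_std), tolerance = 1e-12)
})

test_that("atom percent and delta are exact inverses over a wide range", {
  k <- isotope_constants()
  expect_equal(atom_percent_to_delta(delta_to_atom_percent(0, k), k), 0,
               tolerance = 1e-9)
  expect_equal(atom_percent_to_delta(0.7299328, k), 1000, tolerance = 1e-4)
  set.seed(42)
  d <- c(stats::runif(500, -900, 10000), -899.999, 9999.9)
  expect_equal(atom_percent_to_delta(delta_to_atom_percent(d, k), k), d,
               tolerance = 1e-9)
  expect_error(atom_percent_to_delta(0), "between 0 and 100")
  expect_error(atom_percent_to_delta(100), "between 0 and 100")
})

test_that("percent_ndfa is the linear tracer mixing model", {
  ref <- 0.3663
  expect_equal(percent_ndfa(ref, ref, 6.17), 0)
  expect_equal(percent_ndfa(ref + 6.17, ref, 6.17), 100)
  # fixture derived by inverting the published %Ndfa for the strongest
  # cutting: excess 0.761 * 6.17 / 100 atom%
  expect_equal(percent_ndfa(ref + 0.0469537, ref, 6.17), 0.761,
               tolerance = 1e-6)
  # linearity: scaling the excess scales the result
  for (kk in c(0.5, 2, 10)) {
    expect_equal(percent_ndfa(ref + kk * 0.01, ref, 6.17),
                 kk * percent_ndfa(ref + 0.01, ref, 6.17),
                 tolerance = 1e-12)
  }
  expect_error(percent_ndfa(1, 1, 0), "positive")
  expect_error(percent_ndfa(1, 1, -2), "positive")
})

test_that("mixing-model consistency: %Ndfa recovers the labeled fraction", {
  k <- isotope_constants()
  nat <- k$natural_abundance_atom_pct
  atm <- 6.536  # labeled atmosphere atom%
  for (f in seq(0, 1, by = 0.05)) {
    sample_atom <- (1 - f) * nat + f * atm
    expect_equal(percent_ndfa(sample_atom, nat, atm - nat), 100 * f,
                 tolerance = 1e-9)
  }
})

test_that("fixation rate converts %Ndfa and tissue N to mg/kg/day", {
  expect_equal(fixation_rate(0, 0.04, 14), 0)
  # inverted fixture: the strongest cutting implies ~3.79% tissue N
  expect_equal(fixation_rate(0.761, 0.037894, 14), 20.6, tolerance = 0.005)
  # uniform-fixation assumption: doubling exposure halves the rate
  expect_equal(fixation_rate(0.4, 0.03, 28), fixation_rate(0.4, 0.03, 14) / 2)
  # conservation: rate * days recovers the fixed-N mass per kg
  expect_equal(fixation_rate(0.5, 0.04, 7) * 7, 0.5 / 100 * 0.04 * 1e6)
  expect_true(is.na(fixation_rate(0.5, NA_real_, 14)))
  expect_error(fixation_rate(0.5, 0.04, 0), "positive")
  expect_error(fixation_rate(-1, 0.04, 14), "non-negative")
})

test_that("BDL classification is inclusive at the threshold", {
  expect_true(classify_bdl(0, 0.001))
  expect_true(classify_bdl(0.001, 0.001))
  expect_false(classify_bdl(0.047, 0.001))
  expect_error(classify_bdl(0.1, -1), "non-negative")
  # default threshold: 2 sd of controls, 0 when fewer than 3
  expect_identical(bdl_threshold_from_controls(c(0.366, 0.367)), 0)
  x <- c(0.366, 0.3661, 0.3666, 0.3659)
  expect_equal(bdl_threshold_from_controls(x), 2 * sd(x))
})

test_that("ndfa_table runs the full chain and derives its reference", {
  k <- isotope_constants()
  nat <- k$natural_abundance_atom_pct
  truth_ndfa <- c(0.2, 0.5, 0)
  atoms <- nat + truth_ndfa / 100 * 6.17
  meas <- tibble::tibble(
    sample_id = c("d1", "d2", "d3", "u1", "u2", "u3"),
    tree_id = "t1", tissue = "stem",
    group = c(rep("dosed_wild", 3), rep("undosed_wild", 3)),
    delta15n_permil = c(atom_percent_to_delta(atoms, k), 0, 0, 0),
    n_mass_fraction = 0.04)
  res <- ndfa_table(meas, 6.17, 14)
  expect_equal(attr(res, "reference_atom_pct"), nat, tolerance = 1e-12)
  expect_equal(res$ndfa_pct[1:2], truth_ndfa[1:2], tolerance = 1e-9)
  expect_true(res$bdl[3])            # zero-enrichment dosed cutting
  expect_true(all(res$bdl[4:6]))     # controls sit at the reference
  expect_true(all(is.na(res$ndfa_pct[res$bdl])))
  expect_true(all(is.na(res$rate_mg_per_kg_day[res$bdl])))
  expect_equal(res$rate_mg_per_kg_day[1],
               fixation_rate(0.2, 0.04, 14), tolerance = 1e-9)
  # no controls and no explicit reference is an explicit error
  expect_error(ndfa_table(meas[1:3, ], 6.17, 14), "reference")
  # a sample depleted below the reference is below detection, not negative
  meas2 <- meas
  meas2$delta15n_permil[3] <- -30
  res2 <- ndfa_table(meas2, 6.17, 14, bdl_threshold = 0.001)
  expect_true(res2$bdl[3])
  expect_true(res2$atom_pct_excess[3] < 0)
  expect_true(is.na(res2$ndfa_pct[3]))
})
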