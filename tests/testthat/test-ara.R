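test_that("standard curve matches the normal-equations closed form", {
  two <- tibble::tibble(known_ethylene_amount = c(0, 10),
                        peak_area = c(0, 100))
  cv <- fit_standard_curve(two)
  expect_equal(cv$slope, 0.1)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r_squared, 1)
  set.seed(11)
  pts <- tibble::tibble(peak_area = runif(5, 0, 500))
  pts$known_ethylene_amount <- 0.04 * pts$peak_area + rnorm(5, 1, 0.3)
  cv5 <- suppressWarnings(fit_standard_curve(pts))
  oracle <- ols_closed_form(pts$peak_area, pts$known_ethylene_amount)
  expect_equal(cv5$slope, unname(oracle["slope"]), tolerance = 1e-9)
  expect_equal(cv5$intercept, unname(oracle["intercept"]), tolerance = 1e-9)
  # collinear points give r2 = 1
  lin <- tibble::tibble(peak_area = c(0, 50, 100),
                        known_ethylene_amount = c(0, 5, 10))
  expect_equal(fit_standard_curve(lin)$r_squared, 1)
  expect_error(fit_standard_curve(two[1, ]), "two")
  expect_error(fit_standard_curve(
    tibble::tibble(known_ethylene_amount = c(1, 2),
                   peak_area = c(5, 5))), "variance")
  # large intercept triggers the blank warning
  off <- tibble::tibble(peak_area = c(0, 100),
                        known_ethylene_amount = c(2, 12))
  expect_warning(fit_standard_curve(off), "intercept")
  expect_equal(fit_standard_curve(off, force_origin = TRUE)$intercept, 0)
})

test_that("quantification adjusts for sample mass and floors negatives", {
  cv <- fit_standard_curve(tibble::tibble(
    known_ethylene_amount = c(0, 10), peak_area = c(0, 100)))
  vials <- tibble::tibble(
    vial_id = c("a", "b", "c"), branch_id = "br1",
    dosed = TRUE, sample_mass_g = c(1, 0.5, 1), peak_area = c(0, 200, 200))
  q <- quantify_ethylene(vials, cv)
  expect_equal(q$ethylene_per_g[1], 0)
  # same area, half the mass: twice the per-gram value
  expect_equal(q$ethylene_per_g[2], 2 * q$ethylene_per_g[3])
  # negative predictions floored with a warning
  cvb <- suppressWarnings(fit_standard_curve(tibble::tibble(
    known_ethylene_amount = c(0, 10), peak_area = c(10, 110))))
  expect_warning(qb <- quantify_ethylene(vials, cvb), "floored")
  expect_true(all(qb$ethylene_per_g >= 0))
})

test_that("quantification round-trips vials generated at known ethylene levels", {
  st <- simulate_study(sim_config(seed = 31))
  cv <- fit_standard_curve(st$ara_standards)
  q <- quantify_ethylene(st$ara_vials, cv)
  truth_eth <- ifelse(st$ara_vials$dosed,
                      st$true_ara_baseline *
                        st$truth$true_ara_fold[match(
                          sub("^v_", "", st$ara_vials$vial_id),
                          st$truth$cutting_id)],
                      NA_real_)
  expect_equal(q$ethylene_per_g[q$dosed], truth_eth[q$dosed],
               tolerance = 1e-6)
})

test_that("quantification is invariant to affine rescaling of detector units", {
  set.seed(12)
  std <- tibble::tibble(peak_area = seq(0, 400, by = 100))
  std$known_ethylene_amount <- 0.03 * std$peak_area + 0.5
  vials <- tibble::tibble(vial_id = letters[1:4], branch_id = "b",
                          dosed = TRUE, sample_mass_g = runif(4, 0.9, 1.2),
                          peak_area = runif(4, 50, 350))
  q1 <- quantify_ethylene(vials, suppressWarnings(fit_standard_curve(std)))
  rescale <- function(a) 3.7 * a + 120   # new detector units
  std2 <- dplyr::mutate(std, peak_area = rescale(peak_area))
  vials2 <- dplyr::mutate(vials, peak_area = rescale(peak_area))
  q2 <- quantify_ethylene(vials2, suppressWarnings(fit_standard_curve(std2)))
  expect_equal(q2$ethylene_per_g, q1$ethylene_per_g, tolerance = 1e-9)
})

test_that("undosed baseline and fold calls reproduce the stem-sample survey", {
  ara <- example_dataset("ara_stems")
  base <- undosed_baseline(ara)
  expect_equal(base, 5.11, tolerance = 1e-12)
  expect_equal(round(base), 5)
  res <- fold_and_call(ara)
  folds <- res$fold_over_baseline[res$dosed]
  expect_equal(sort(folds, decreasing = TRUE)[1:2], c(20.92, 12.02),
               tolerance = 0.005)
  # exactly three acetylene-dosed vials exceed twice the baseline
  expect_equal(sum(res$positive), 3L)
  expect_false(any(res$positive[!res$dosed]))
  expect_true(all(is.na(res$fold_over_baseline[!res$dosed])))
  # order invariance of the baseline
  expect_equal(undosed_baseline(ara[sample(nrow(ara)), ]), base)
})

test_that("baseline edge cases and errors", {
  one <- tibble::tibble(dosed = c(FALSE, TRUE), ethylene_per_g = c(4.2, 9))
  expect_equal(undosed_baseline(one), 4.2)
  same <- tibble::tibble(dosed = FALSE, ethylene_per_g = rep(3.3, 5))
  expect_equal(undosed_baseline(same), 3.3)
  expect_error(undosed_baseline(
    tibble::tibble(dosed = TRUE, ethylene_per_g = 1)), "undosed")
  # dosed vial at exactly the baseline: fold 1, not positive
  res <- fold_and_call(tibble::tibble(dosed = c(FALSE, TRUE),
                                      ethylene_per_g = c(5, 5)))
  expect_equal(res$fold_over_baseline[2], 1)
  expect_false(res$positive[2])
  expect_error(fold_and_call(one, baseline = 0), "positive")
})
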