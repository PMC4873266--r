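test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(p_active = 1.5), "p_active")
  expect_error(sim_config(irms_noise_sd_permil = -1), "deviations")
  expect_error(sim_config(ndfa_active_range = c(0.8, 0.03)), "ordered")
  expect_error(sim_config(n_trees = 0), "n_trees")
  expect_error(simulate_study(sim_config(ndfa_log_uniform = TRUE,
                                         ndfa_active_range = c(0, 1))),
               "positive lower bound")
})

test_that("same seed and config give identical studies; seeds differ", {
  s1 <- simulate_study(sim_config(seed = 9))
  s2 <- simulate_study(sim_config(seed = 9))
  expect_identical(s1$irms, s2$irms)
  expect_identical(s1$ara_vials, s2$ara_vials)
  expect_identical(s1$plates, s2$plates)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(sim_config(seed = 10))
  expect_false(identical(s1$irms$delta15n_permil,
                         s3$irms$delta15n_permil))
})

test_that("noise-free fully-active study is recovered exactly", {
  cfg <- sim_config(seed = 4, p_active = 1, irms_noise_sd_permil = 0)
  st <- simulate_study(cfg)
  nd <- ndfa_table(st$irms, 6.17, 14, bdl_threshold = 1e-9)
  m <- match(st$truth$cutting_id[st$truth$group == "dosed_wild"],
             nd$sample_id)
  expect_equal(nd$ndfa_pct[m],
               st$truth$true_ndfa_pct[st$truth$group == "dosed_wild"],
               tolerance = 1e-9)
  expect_true(all(st$truth$active[st$truth$group == "dosed_wild"]))
})

test_that("all-inactive studies stay near zero and BDL behaves like its nominal level", {
  cfg <- sim_config(seed = 8, n_trees = 20, cuttings_per_tree = 10,
                    controls_per_tree = 3, p_active = 0)
  st <- simulate_study(cfg)
  nd <- ndfa_table(st$irms, 6.17, 14)
  dosed <- nd$group == "dosed_wild"
  # error propagation: delta noise sd 0.3 maps to atom% noise of about
  # sd_delta * r_std / (1+r)^2 / 10, i.e. ~1.1e-4 atom%, ~1.8e-3 %Ndfa
  k <- isotope_constants()
  sd_atom <- 0.3 * k$r_std / (1 + k$r_std)^2 / 10
  sd_ndfa <- 100 * sd_atom / 6.17
  est <- 100 * nd$atom_pct_excess[dosed] / 6.17
  expect_lt(abs(mean(est)), 3 * sd_ndfa / sqrt(sum(dosed)) * 2)
  expect_equal(sd(est), sd_ndfa, tolerance = 0.2)
  # the 2-sd rule on a one-sided exceedance keeps most nulls BDL
  expect_gt(mean(nd$bdl[dosed]), 0.9)
})

test_that("inactive dosed cuttings and undosed controls are exchangeable", {
  cfg <- sim_config(seed = 13, n_trees = 40, cuttings_per_tree = 6,
                    controls_per_tree = 6, p_active = 0)
  st <- simulate_study(cfg)
  dosed <- st$irms$delta15n_permil[st$irms$group == "dosed_wild"]
  ctrl <- st$irms$delta15n_permil[st$irms$group == "undosed_wild"]
  expect_gt(suppressWarnings(stats::ks.test(dosed, ctrl)$p.value), 0.01)
})

test_that("%Ndfa RMSE grows with IRMS noise", {
  rmse_at <- function(noise, seed) {
    st <- simulate_study(sim_config(seed = seed, n_trees = 10,
                                    irms_noise_sd_permil = noise))
    nd <- ndfa_table(st$irms, 6.17, 14)
    truth_recovery_report(nd, st$truth)$ndfa_rmse
  }
  r_lo <- mean(vapply(1:5, function(s) rmse_at(0.1, s), numeric(1)))
  r_hi <- mean(vapply(1:5, function(s) rmse_at(1.0, s), numeric(1)))
  expect_gt(r_hi, r_lo)
})

test_that("recovery report: perfect estimates give zero error", {
  st <- simulate_study(sim_config(seed = 21, p_active = 1,
                                  irms_noise_sd_permil = 0))
  nd <- ndfa_table(st$irms, 6.17, 14, bdl_threshold = 1e-9)
  rep <- truth_recovery_report(nd, st$truth)
  expect_equal(rep$ndfa_bias, 0, tolerance = 1e-9)
  expect_equal(rep$ndfa_rmse, 0, tolerance = 1e-9)
  expect_equal(rep$confusion$sensitivity, 1)
  expect_equal(rep$confusion$fp + rep$confusion$fn, 0L)
  bad <- st$truth
  bad$cutting_id <- paste0("x", bad$cutting_id)
  expect_error(truth_recovery_report(nd, bad), "ids must match")
})

test_that("CFU counts are independent of activity by default, shifted on demand", {
  cfg <- sim_config(seed = 17, n_trees = 30, cuttings_per_tree = 8,
                    cfu_activity_shift = 0)
  st <- simulate_study(cfg)
  tr <- st$truth[st$truth$group == "dosed_wild", ]
  ct <- stats::cor.test(log10(tr$true_cfu_per_g), as.numeric(tr$active))
  expect_gt(ct$p.value, 0.001)   # no built-in correlation
  cfg2 <- sim_config(seed = 17, n_trees = 30, cuttings_per_tree = 8,
                     cfu_activity_shift = 2)
  tr2 <- simulate_study(cfg2)$truth
  tr2 <- tr2[tr2$group == "dosed_wild", ]
  expect_gt(mean(log10(tr2$true_cfu_per_g[tr2$active])),
            mean(log10(tr2$true_cfu_per_g[!tr2$active])) + 1)
})

test_that("tree-level random effect induces between-tree activity clustering", {
  base_var <- function(sd_tree, seed) {
    st <- simulate_study(sim_config(seed = seed, n_trees = 25,
                                    cuttings_per_tree = 12,
                                    p_active = 0.5, tree_effect_sd = sd_tree))
    tr <- st$truth[st$truth$group == "dosed_wild", ]
    stats::var(tapply(tr$active, tr$tree_id, mean))
  }
  v0 <- mean(vapply(1:4, function(s) base_var(0, s), numeric(1)))
  v3 <- mean(vapply(1:4, function(s) base_var(3, s), numeric(1)))
  expect_gt(v3, v0)
})
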