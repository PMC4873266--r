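#' Configuration for a synthetic tracer study
#'
#' Describes the study design and noise model of a simulated closed-flask
#' 15N2 experiment on cuttings from wild trees with heterogeneously
#' colonized endophytic diazotrophs. The defaults emulate the two-week
#' hydroponic design: 5 source trees, 4 dosed cuttings and 1 undosed
#' control each, an atmosphere at 6.17 atom percent excess, about half the
#' dosed cuttings hosting an actively fixing consortium with true %Ndfa
#' spanning 0.03--0.8, and EA-IRMS noise of 0.3 per mil.
#'
#' @param seed Integer RNG seed; the same seed and config give
#'   bit-identical output.
#' @param n_trees Number of source trees.
#' @param cuttings_per_tree Dosed cuttings per tree.
#' @param controls_per_tree Undosed control cuttings per tree.
#' @param subsamples_per_cutting IRMS subsamples measured per cutting.
#' @param p_active Probability a dosed cutting hosts an actively fixing
#'   consortium.
#' @param tree_effect_sd SD of a tree-level random shift of the activity
#'   probability on the logit scale (0 = activity purely cutting-level).
#' @param ndfa_active_range True %Ndfa interval for active cuttings.
#' @param ndfa_log_uniform Draw true %Ndfa log-uniformly over the range
#'   instead of uniformly.
#' @param irms_noise_sd_permil Measurement noise SD on the delta-15N scale.
#' @param atmosphere_excess_atom_pct Dosed-atmosphere atom percent excess.
#' @param exposure_days Tracer exposure length.
#' @param tissue_n_fraction_mean,tissue_n_fraction_sd Tissue N content
#'   (g/g) distribution.
#' @param colonization_log10_mean,colonization_log10_sd log10 CFU per gram
#'   of the culturable population.
#' @param cfu_activity_shift Added to the log10 CFU mean of active
#'   cuttings; default 0 (colonization density uninformative about
#'   fixation activity).
#' @param ara_baseline_mean,ara_baseline_sd Background ethylene production
#'   per gram of undosed vials.
#' @param ara_active_fold_range Ethylene fold over baseline for vials from
#'   active cuttings.
#' @param ara_curve_slope Amount of ethylene per GC area unit used to
#'   synthesise peak areas (standards are emitted so the curve can be
#'   re-fitted).
#' @param plate_dilution_factor,plate_volume_ml,extraction_ml_per_g
#'   Dilution-plating settings.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_trees = 5L,
                       cuttings_per_tree = 4L,
                       controls_per_tree = 1L,
                       subsamples_per_cutting = 1L,
                       p_active = 0.5,
                       tree_effect_sd = 0,
                       ndfa_active_range = c(0.03, 0.8),
                       ndfa_log_uniform = FALSE,
                       irms_noise_sd_permil = 0.3,
                       atmosphere_excess_atom_pct = 6.17,
                       exposure_days = 14,
                       tissue_n_fraction_mean = 0.04,
                       tissue_n_fraction_sd = 0.006,
                       colonization_log10_mean = 6.5,
                       colonization_log10_sd = 0.7,
                       cfu_activity_shift = 0,
                       ara_baseline_mean = 5.11,
                       ara_baseline_sd = 1.7,
                       ara_active_fold_range = c(4, 21),
                       ara_curve_slope = 0.05,
                       plate_dilution_factor = 1e-3,
                       plate_volume_ml = 0.1,
                       extraction_ml_per_g = 5) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_trees >= 1, cfg$cuttings_per_tree >= 1,
            cfg$controls_per_tree >= 0, cfg$subsamples_per_cutting >= 1)
  if (cfg$p_active < 0 || cfg$p_active > 1) {
    stop("`p_active` must lie in [0, 1].", call. = FALSE)
  }
  sds <- c(cfg$tree_effect_sd, cfg$irms_noise_sd_permil,
           cfg$tissue_n_fraction_sd, cfg$colonization_log10_sd,
           cfg$ara_baseline_sd)
  if (any(sds < 0)) stop("Standard deviations must be >= 0.", call. = FALSE)
  for (r in list(cfg$ndfa_active_range, cfg$ara_active_fold_range)) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0) {
      stop("Ranges must be ordered non-negative pairs.", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

rtrunc_norm_pos <- function(n, mean, sd, floor = .Machine$double.eps) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= floor)) {
    x[x <= floor] <- stats::rnorm(sum(x <= floor), mean, sd)
  }
  x
}

#' Simulate a complete tracer study with ground truth
#'
#' Generates the three observation tables a real study would produce — an
#' IRMS delta-15N table, an ARA vial/standards pair, and a plate-count
#' table — together with the per-cutting ground truth used to produce
#' them. Each dosed cutting is independently active with `p_active`
#' (optionally shifted per tree); active cuttings draw a true %Ndfa from
#' `ndfa_active_range`, giving a tissue atom percent of
#' `reference + ndfa/100 * excess` whose delta is observed with Gaussian
#' IRMS noise. Undosed controls sit at the reference composition plus the
#' same noise. ARA ethylene is the baseline times a fold drawn from
#' `ara_active_fold_range` for active cuttings and ~1 for inactive ones;
#' peak areas are back-calculated through a linear detector response.
#' Plate counts are Poisson draws from a log10-normal colonization
#' density, independent of fixation activity by default.
#'
#' @param config A [sim_config()].
#' @param constants An [isotope_constants()].
#' @return List of class `sim_study`: `irms`, `ara_vials`, `ara_standards`,
#'   `plates`, `truth` (per-cutting), `config`, and study-level
#'   `reference_atom_pct`.
#' @export
simulate_study <- function(config = sim_config(),
                           constants = isotope_constants()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nat <- constants$natural_abundance_atom_pct

  trees <- sprintf("tree%02d", seq_len(config$n_trees))
  tree_shift <- if (config$tree_effect_sd > 0) {
    stats::rnorm(config$n_trees, 0, config$tree_effect_sd)
  } else rep(0, config$n_trees)

  cut_rows <- list()
  for (ti in seq_along(trees)) {
    p_t <- stats::plogis(stats::qlogis(min(max(config$p_active, 1e-12),
                                           1 - 1e-12)) + tree_shift[ti])
    for (ci in seq_len(config$cuttings_per_tree)) {
      cut_rows[[length(cut_rows) + 1L]] <- tibble::tibble(
        cutting_id = sprintf("%s-c%02d", trees[ti], ci),
        tree_id = trees[ti], group = "dosed_wild",
        active = stats::runif(1) < p_t)
    }
    for (ci in seq_len(config$controls_per_tree)) {
      cut_rows[[length(cut_rows) + 1L]] <- tibble::tibble(
        cutting_id = sprintf("%s-u%02d", trees[ti], ci),
        tree_id = trees[ti], group = "undosed_wild", active = FALSE)
    }
  }
  cuttings <- dplyr::bind_rows(cut_rows)
  n_cut <- nrow(cuttings)
  if (n_cut == 0L) stop("Degenerate config: no cuttings.", call. = FALSE)

  rng <- config$ndfa_active_range
  true_ndfa <- numeric(n_cut)
  n_act <- sum(cuttings$active)
  if (n_act > 0) {
    true_ndfa[cuttings$active] <- if (config$ndfa_log_uniform) {
      if (rng[1] <= 0) stop("Log-uniform %Ndfa needs a positive lower bound.",
                            call. = FALSE)
      exp(stats::runif(n_act, log(rng[1]), log(rng[2])))
    } else {
      stats::runif(n_act, rng[1], rng[2])
    }
  }

  true_cfu <- 10^stats::rnorm(
    n_cut,
    config$colonization_log10_mean +
      config$cfu_activity_shift * cuttings$active,
    config$colonization_log10_sd)
  true_fold <- ifelse(cuttings$active,
                      stats::runif(n_cut, config$ara_active_fold_range[1],
                                   config$ara_active_fold_range[2]),
                      exp(stats::rnorm(n_cut, 0, 0.05)))

  truth <- dplyr::mutate(cuttings,
                         true_ndfa_pct = true_ndfa,
                         true_cfu_per_g = true_cfu,
                         true_ara_fold = true_fold)

  # --- IRMS table: dosed cuttings enriched in proportion to true %Ndfa ---
  dosed <- cuttings$group == "dosed_wild"
  atom_true <- nat + ifelse(dosed, true_ndfa / 100, 0) *
    config$atmosphere_excess_atom_pct
  nsub <- config$subsamples_per_cutting
  irms <- tibble::tibble(
    sample_id = rep(cuttings$cutting_id, each = nsub),
    tree_id = rep(cuttings$tree_id, each = nsub),
    tissue = rep(rep_len(c("stem", "leaf", "root"), nsub), n_cut),
    group = rep(cuttings$group, each = nsub),
    delta15n_permil = atom_percent_to_delta(rep(atom_true, each = nsub),
                                            constants) +
      stats::rnorm(n_cut * nsub, 0, config$irms_noise_sd_permil),
    n_mass_fraction = rtrunc_norm_pos(n_cut * nsub,
                                      config$tissue_n_fraction_mean,
                                      config$tissue_n_fraction_sd)
  )

  # --- ARA: one vial per cutting; dosed flag = received acetylene ---
  baseline_truth <- config$ara_baseline_mean
  vial_base <- rtrunc_norm_pos(n_cut, config$ara_baseline_mean,
                               config$ara_baseline_sd)
  ethylene_per_g <- ifelse(dosed, baseline_truth * true_fold, vial_base)
  mass <- stats::runif(n_cut, 0.9, 1.2)
  ara_vials <- tibble::tibble(
    vial_id = paste0("v_", cuttings$cutting_id),
    branch_id = cuttings$tree_id,
    dosed = dosed,
    sample_mass_g = mass,
    peak_area = ethylene_per_g * mass / config$ara_curve_slope
  )
  top_amount <- max(ethylene_per_g * mass) * 1.2
  std_amount <- seq(0, top_amount, length.out = 5)
  ara_standards <- tibble::tibble(
    known_ethylene_amount = std_amount,
    peak_area = std_amount / config$ara_curve_slope
  )

  # --- plate counts: Poisson sampling of the colonization density ---
  lambda <- true_cfu * config$plate_dilution_factor *
    config$plate_volume_ml / config$extraction_ml_per_g
  plates <- tibble::tibble(
    sample_id = cuttings$cutting_id,
    tissue = "stem",
    medium = "NL-CCM",
    colonies = stats::rpois(n_cut, lambda),
    tntc = FALSE,
    dilution_factor = config$plate_dilution_factor,
    plated_volume_ml = config$plate_volume_ml,
    extraction_ml_per_g = config$extraction_ml_per_g
  )

  structure(
    list(irms = irms, ara_vials = ara_vials, ara_standards = ara_standards,
         plates = plates, truth = truth, config = config,
         reference_atom_pct = nat,
         true_ara_baseline = baseline_truth),
    class = "sim_study"
  )
}

#' Compare pipeline estimates against simulation ground truth
#'
#' Joins an [ndfa_table()] result with the generator's per-cutting truth
#' and reports estimation error and detection performance: bias and RMSE
#' of %Ndfa (below-detection estimates counted as 0), and the confusion of
#' the below-detection call against true activity (sensitivity =
#' proportion of truly active cuttings called above detection; specificity
#' = proportion of truly inactive dosed cuttings called BDL).
#'
#' @param estimates An [ndfa_table()] tibble (dosed cuttings are matched on
#'   `sample_id`; subsample rows are averaged per cutting first).
#' @param truth The `truth` tibble of a [simulate_study()] result.
#' @return List with `ndfa_bias`, `ndfa_rmse`, and `confusion` (tibble with
#'   tp/fp/fn/tn, sensitivity, specificity).
#' @export
truth_recovery_report <- function(estimates, truth) {
  stopifnot(is.data.frame(estimates), is.data.frame(truth))
  est <- dplyr::summarise(
    dplyr::group_by(estimates, .data$sample_id),
    ndfa_est = mean(ifelse(.data$bdl, 0, .data$ndfa_pct)),
    detected = any(!.data$bdl),
    .groups = "drop")
  tr <- truth[truth$group == "dosed_wild", , drop = FALSE]
  m <- match(tr$cutting_id, est$sample_id)
  if (any(is.na(m))) {
    stop("Estimates are missing ", sum(is.na(m)), " dosed cutting(s); ",
         "ids must match the truth table.", call. = FALSE)
  }
  err <- est$ndfa_est[m] - tr$true_ndfa_pct
  detected <- est$detected[m]
  tp <- sum(detected & tr$active); fn <- sum(!detected & tr$active)
  fp <- sum(detected & !tr$active); tn <- sum(!detected & !tr$active)
  list(
    ndfa_bias = mean(err),
    ndfa_rmse = sqrt(mean(err^2)),
    confusion = tibble::tibble(
      tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  )
}

#' Simulate plant-level aggregates for the three-treatment comparison
#'
#' Direct generator for the group-comparison stage: plant-level mean
#' delta-15N values for the three treatments of the pooled hydroponic
#' analysis. Defaults reflect the observed structure: dosed wild plants
#' highly variable around a strongly enriched mean; dosed sterile
#' (endophyte-free clone) plants mildly enriched (mean 13.7 per mil);
#' undosed controls near natural abundance with small spread.
#'
#' @param n_per_group Plants per treatment group (default 5).
#' @param means,sds Named numeric vectors over groups `dosed_wild`,
#'   `dosed_sterile`, `undosed`.
#' @return Tibble with `plant_id`, `group`, `mean_delta15n_permil`,
#'   `n_subsamples` (1), ready for [group_compare()].
#' @export
simulate_group_aggregates <- function(
    n_per_group = 5L,
    means = c(dosed_wild = 80, dosed_sterile = 13.7, undosed = 2),
    sds = c(dosed_wild = 40, dosed_sterile = 10, undosed = 2)) {
  stopifnot(setequal(names(means), names(sds)))
  groups <- names(means)
  dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(
      plant_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
      group = g,
      mean_delta15n_permil = stats::rnorm(n_per_group, means[[g]], sds[[g]]),
      n_subsamples = 1L)
  }))
}
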