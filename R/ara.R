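#' Fit an ethylene standard curve
#'
#' Ordinary least-squares line relating known ethylene amounts to GC peak
#' areas, `amount = slope * area + intercept`, fitted with [stats::lm()].
#' The intercept is free by default (FID baselines are rarely exactly
#' zero); set `force_origin = TRUE` to constrain it. A warning is issued
#' when the fitted intercept exceeds 5% of the largest standard amount.
#'
#' @param standards Data frame with columns `known_ethylene_amount` and
#'   `peak_area` (at least two points with distinct peak areas).
#' @param force_origin Force the line through the origin.
#' @return A `standard_curve` object with `slope`, `intercept`,
#'   `r_squared`, and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(standards, force_origin = FALSE) {
  standards <- validate_table(standards, "ara_standards")
  if (nrow(standards) < 2L) {
    stop("At least two standard points are required.", call. = FALSE)
  }
  if (stats::var(standards$peak_area) == 0) {
    stop("Standard peak areas have zero variance; cannot fit a curve.",
         call. = FALSE)
  }
  fit <- if (force_origin) {
    stats::lm(known_ethylene_amount ~ peak_area + 0, data = standards)
  } else {
    stats::lm(known_ethylene_amount ~ peak_area, data = standards)
  }
  co <- stats::coef(fit)
  slope <- unname(co[["peak_area"]])
  intercept <- if (force_origin) 0 else unname(co[["(Intercept)"]])
  pred <- stats::fitted(fit)
  ss_tot <- sum((standards$known_ethylene_amount -
                   mean(standards$known_ethylene_amount))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  top <- max(standards$known_ethylene_amount)
  if (!force_origin && top > 0 && abs(intercept) > 0.05 * top) {
    warning("Standard-curve intercept (", signif(intercept, 3),
            ") exceeds 5% of the top standard (", signif(top, 3),
            "); check blank vials.", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Ethylene standard curve: amount = %.6g * area + %.6g (r2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Quantify per-gram ethylene from GC peak areas
#'
#' Applies a fitted [fit_standard_curve()] to each vial's peak area and
#' divides by the sample mass, giving ethylene per gram of plant tissue.
#' Negative predictions (areas below the curve's blank) are floored at zero
#' with a warning.
#'
#' @param vials Data frame with columns `vial_id`, `branch_id`, `dosed`
#'   (logical: received acetylene), `sample_mass_g`, `peak_area`.
#' @param curve A `standard_curve`.
#' @return The vials tibble with an `ethylene_per_g` column appended.
#' @export
quantify_ethylene <- function(vials, curve) {
  vials <- validate_table(vials, "ara_vials")
  stopifnot(inherits(curve, "standard_curve"))
  amount <- curve$slope * vials$peak_area + curve$intercept
  if (any(amount < 0)) {
    warning(sum(amount < 0), " vial(s) predicted below zero ethylene; ",
            "floored at 0.", call. = FALSE)
    amount <- pmax(amount, 0)
  }
  dplyr::mutate(tibble::as_tibble(vials),
                ethylene_per_g = amount / .data$sample_mass_g)
}

#' Mean ethylene production of undosed vials
#'
#' The background (baseline) ethylene production of the plant tissue
#' itself: the arithmetic mean of `ethylene_per_g` over vials that did not
#' receive acetylene.
#'
#' @param results Data frame with columns `dosed` and `ethylene_per_g`.
#' @return Baseline ethylene per gram (single number).
#' @export
undosed_baseline <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("dosed", "ethylene_per_g") %in% names(results)))
  undosed <- results$ethylene_per_g[!results$dosed]
  if (length(undosed) == 0L) {
    stop("No undosed vials: baseline unavailable, folds cannot be computed.",
         call. = FALSE)
  }
  mean(undosed)
}

#' Fold enrichment over baseline and positive calls
#'
#' For each acetylene-dosed vial, the ratio of its ethylene production to
#' the undosed baseline; vials at or above `fold_threshold` are called
#' acetylene-reduction positive. Undosed vials get `NA` fold and are never
#' positive.
#'
#' @param results Data frame with columns `dosed` and `ethylene_per_g`
#'   (e.g. from [quantify_ethylene()]).
#' @param baseline Undosed baseline (default computed from `results` via
#'   [undosed_baseline()]); must be positive.
#' @param fold_threshold Positive-call threshold (default 2).
#' @return `results` with `fold_over_baseline` and `positive` columns; the
#'   baseline used is attached as attribute `baseline`.
#' @export
fold_and_call <- function(results, baseline = undosed_baseline(results),
                          fold_threshold = 2) {
  stopifnot(is.data.frame(results),
            all(c("dosed", "ethylene_per_g") %in% names(results)))
  if (!is.finite(baseline) || baseline <= 0) {
    stop("Baseline must be a positive number.", call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(results),
    fold_over_baseline = ifelse(.data$dosed,
                                .data$ethylene_per_g / baseline, NA_real_),
    positive = .data$dosed & !is.na(.data$fold_over_baseline) &
      .data$fold_over_baseline >= fold_threshold
  )
  attr(out, "baseline") <- baseline
  out
}

#' Acetylene reduction assay analysis
#'
#' Convenience wrapper running the full ARA chain: standard-curve fit,
#' per-gram quantification, undosed baseline, and fold/positive calling.
#' When `vials` already carries an `ethylene_per_g` column (values
#' pre-quantified by the GC software), the curve step is skipped.
#'
#' @param vials Vial table; either raw (`peak_area`, `sample_mass_g`) with
#'   `standards` supplied, or pre-quantified (`ethylene_per_g`).
#' @param standards Standard-curve points (required for raw vials).
#' @param fold_threshold Positive-call threshold (default 2).
#' @param force_origin Passed to [fit_standard_curve()].
#' @return Annotated tibble as from [fold_and_call()].
#' @export
ara_analysis <- function(vials, standards = NULL, fold_threshold = 2,
                         force_origin = FALSE) {
  if (!"ethylene_per_g" %in% names(vials)) {
    if (is.null(standards)) {
      stop("Raw vial tables need `standards` to fit the curve.",
           call. = FALSE)
    }
    curve <- fit_standard_curve(standards, force_origin = force_origin)
    vials <- quantify_ethylene(vials, curve)
  }
  fold_and_call(vials, fold_threshold = fold_threshold)
}
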