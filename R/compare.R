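#' Aggregate tissue subsamples to plant-level experimental units
#'
#' Diazotrophic endophytes are unevenly distributed within a plant, so
#' subsamples from one cutting are pseudo-replicates. This collapses each
#' plant to the unweighted mean of its subsample delta-15N values, the
#' experimental unit for group comparison. Undosed wild and undosed sterile
#' plants are merged into a single `undosed` group.
#'
#' @param measurements Data frame with columns `sample_id` (plant id),
#'   `group`, `delta15n_permil`; multiple rows per plant are subsamples.
#' @return Tibble with `plant_id`, `group` (undosed labels collapsed),
#'   `mean_delta15n_permil`, `n_subsamples`.
#' @export
aggregate_subsamples <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("sample_id", "group", "delta15n_permil") %in%
                  names(measurements)))
  grp <- ifelse(grepl("undosed", measurements$group, fixed = TRUE),
                "undosed", as.character(measurements$group))
  n_groups <- tapply(grp, measurements$sample_id,
                     function(g) length(unique(g)))
  if (any(n_groups > 1L)) {
    stop("Plant(s) assigned to more than one group: ",
         paste(names(n_groups)[n_groups > 1L], collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(plant_id = measurements$sample_id, group = grp,
                     delta = measurements$delta15n_permil),
      .data$plant_id, .data$group),
    mean_delta15n_permil = mean(.data$delta),
    n_subsamples = dplyr::n(),
    .groups = "drop"
  )
  out
}

#' One-way group comparison with pairwise least-squares-means contrasts
#'
#' Fits a one-way fixed-effects cell-means model to plant-level values by
#' ordinary least squares ([stats::lm()]) and computes all pairwise
#' contrasts between group means with the pooled residual variance:
#' t-based tests on `diff / SE`, `SE = sigma * sqrt(1/n_i + 1/n_j)`, with
#' the residual degrees of freedom. In a one-factor design with no
#' covariates the least-squares means are exactly the group means, and in
#' the balanced two-group case each contrast reduces to the classical
#' pooled two-sample t-test.
#'
#' @param aggregates Data frame with columns `group` and a value column
#'   (default `mean_delta15n_permil`), e.g. from [aggregate_subsamples()].
#' @param value Name of the value column.
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()];
#'   default `"none"` (plain pairwise comparisons), `"bonferroni"`
#'   available.
#' @return List with `means` (tibble: group, n, lsmean, se) and `contrasts`
#'   (tibble: pair, estimate, se, df, t, p); residual sigma and df as
#'   attributes on `contrasts`.
#' @export
group_compare <- function(aggregates, value = "mean_delta15n_permil",
                          p_adjust = c("none", "bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(aggregates),
            all(c("group", value) %in% names(aggregates)))
  y <- aggregates[[value]]
  g <- factor(aggregates$group)
  if (nlevels(g) < 2L) {
    stop("Need at least two groups to compare.", call. = FALSE)
  }
  if (length(y) - nlevels(droplevels(g)) < 1L) {
    stop("No residual degrees of freedom: need at least one group with ",
         "two or more plants.", call. = FALSE)
  }
  fit <- stats::lm(y ~ g + 0)   # cell-means parameterisation
  sigma2 <- sum(stats::resid(fit)^2) / fit$df.residual
  df <- fit$df.residual
  n_k <- as.integer(table(g))
  means <- tibble::tibble(
    group = levels(g),
    n = n_k,
    lsmean = unname(stats::coef(fit)),
    se = sqrt(sigma2 / n_k)
  )
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  contrasts <- dplyr::bind_rows(lapply(pairs, function(p) {
    i <- match(p[1], means$group); j <- match(p[2], means$group)
    est <- means$lsmean[i] - means$lsmean[j]
    se <- sqrt(sigma2 * (1 / means$n[i] + 1 / means$n[j]))
    tval <- if (se == 0) {
      if (est == 0) 0 else sign(est) * Inf
    } else est / se
    tibble::tibble(pair = paste(p[1], "-", p[2]), estimate = est,
                   se = se, df = df, t = tval,
                   p = 2 * stats::pt(-abs(tval), df))
  }))
  contrasts$p_adj <- stats::p.adjust(contrasts$p, method = p_adjust)
  attr(contrasts, "sigma") <- sqrt(sigma2)
  attr(contrasts, "df") <- df
  list(means = means, contrasts = contrasts)
}
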