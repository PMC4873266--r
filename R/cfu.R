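#' Colony-forming units per gram of tissue from dilution plating
#'
#' The plating arithmetic: an extract prepared at `extraction_ml_per_g` ml
#' of buffer per gram of tissue is diluted by `dilution_factor` and
#' `plated_volume_ml` of the dilution is spread. Each colony then
#' represents `1 / dilution_factor / plated_volume_ml * extraction_ml_per_g`
#' CFU per gram, so
#'
#' `CFU/g = colonies / dilution_factor / plated_volume_ml * extraction_ml_per_g`
#'
#' Plates flagged too-numerous-to-count (TNTC) yield a lower bound computed
#' at the top of the countable range; zero-colony plates yield a
#' below-detection flag with the single-colony detection limit. Counts
#' outside the countable range carry a reliability warning flag.
#'
#' @param plates Data frame with columns `sample_id`, `tissue`, `medium`,
#'   `colonies` (count, `NA` allowed when `tntc` is `TRUE`), `tntc`
#'   (logical, optional; default all `FALSE`), `dilution_factor` (in
#'   (0, 1], e.g. 1e-3 for a 1:1000 dilution), `plated_volume_ml`,
#'   `extraction_ml_per_g`.
#' @param countable_range Counts considered reliable on a single plate
#'   (default 30--300); the upper end defines the TNTC lower bound.
#' @return Tibble with `cfu_per_g` (point estimate, lower bound for TNTC,
#'   detection limit for zero counts), `flag` (`"ok"`, `"tntc_lower_bound"`,
#'   `"below_detection"`, `"outside_countable_range"`).
#' @examples
#' cfu_per_gram(tibble::tibble(
#'   sample_id = "s1", tissue = "root", medium = "NL-CCM",
#'   colonies = 400, tntc = FALSE, dilution_factor = 1e-3,
#'   plated_volume_ml = 0.1, extraction_ml_per_g = 5))  # 2e7 CFU/g
#' @export
cfu_per_gram <- function(plates, countable_range = c(30, 300)) {
  plates <- validate_table(plates, "plates")
  if (!"tntc" %in% names(plates)) plates$tntc <- FALSE
  stopifnot(length(countable_range) == 2L,
            countable_range[1] < countable_range[2])
  per_colony <- plates$extraction_ml_per_g /
    (plates$dilution_factor * plates$plated_volume_ml)
  cfu <- plates$colonies * per_colony
  flag <- rep("ok", nrow(plates))
  low <- !plates$tntc & !is.na(plates$colonies) &
    plates$colonies > 0 & plates$colonies < countable_range[1]
  high <- !plates$tntc & !is.na(plates$colonies) &
    plates$colonies > countable_range[2]
  flag[low | high] <- "outside_countable_range"
  zero <- !plates$tntc & !is.na(plates$colonies) & plates$colonies == 0
  flag[zero] <- "below_detection"
  cfu[zero] <- per_colony[zero]  # single-colony detection limit
  flag[plates$tntc] <- "tntc_lower_bound"
  cfu[plates$tntc] <- countable_range[2] * per_colony[plates$tntc]
  dplyr::mutate(tibble::as_tibble(plates), cfu_per_g = cfu, flag = flag)
}

#' Summarise variability of a culturable population
#'
#' Range-based heterogeneity summary of quantified CFU densities: minimum,
#' maximum, max/min ratio and its log10 (the "orders of magnitude" spread),
#' overall and per tissue. Records flagged TNTC or below detection are
#' excluded and their number reported.
#'
#' @param records Data frame with columns `cfu_per_g`, `flag` (optional;
#'   rows with flags other than `"ok"`/`"outside_countable_range"` are
#'   excluded), and optionally `tissue` for the per-tissue table.
#' @return List with `overall` (tibble: n, min, max, ratio, log10_spread,
#'   n_excluded) and, when a `tissue` column is present, `by_tissue`.
#' @export
variability_summary <- function(records) {
  stopifnot(is.data.frame(records), "cfu_per_g" %in% names(records))
  if (!"flag" %in% names(records)) records$flag <- "ok"
  usable <- records$flag %in% c("ok", "outside_countable_range")
  n_excluded <- sum(!usable)
  rec <- records[usable, , drop = FALSE]
  if (nrow(rec) < 2L) {
    stop("Fewer than two quantified records; variability summary absent ",
         "(", n_excluded, " record(s) excluded as TNTC/below detection).",
         call. = FALSE)
  }
  summarise_one <- function(d) {
    tibble::tibble(
      n = nrow(d),
      min_cfu_per_g = min(d$cfu_per_g),
      max_cfu_per_g = max(d$cfu_per_g),
      ratio = max(d$cfu_per_g) / min(d$cfu_per_g),
      log10_spread = log10(max(d$cfu_per_g) / min(d$cfu_per_g))
    )
  }
  out <- list(overall = dplyr::mutate(summarise_one(rec),
                                      n_excluded = n_excluded))
  if ("tissue" %in% names(rec)) {
    out$by_tissue <- dplyr::bind_rows(
      lapply(split(rec, rec$tissue), summarise_one),
      .id = "tissue"
    )
  }
  out
}
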