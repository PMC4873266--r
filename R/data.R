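#' Bundled example datasets from a wild-poplar endophyte fixation survey
#'
#' Three small tables from a field survey of endophytic nitrogen fixation
#' in wild black cottonwood, shipped as plain CSV under `extdata` and used
#' in examples, tests, and the analysis scripts:
#'
#' * `"ara_stems"`: acetylene reduction assay results for 18 stem-sample
#'   vials from one wild genotype (9 acetylene-dosed, 9 undosed), as
#'   ethylene per gram of tissue already quantified against a GC standard
#'   curve and adjusted for sample mass.
#' * `"ndfa_hydroponic"`: per-cutting %Ndfa and N2-fixation rate
#'   (mg N/kg/day) for five wild trees after a two-week closed-flask 15N2
#'   exposure at 6.17 atom percent excess; undosed controls are below
#'   detection (`NA`).
#' * `"cfu_sections"`: culturable endophyte densities (CFU per gram) of
#'   ten sections of a single wild tree plated on three media, with
#'   too-numerous-to-count entries flagged.
#'
#' @param name Dataset name (see above).
#' @return A tibble.
#' @examples
#' example_dataset("ara_stems")
#' @export
example_dataset <- function(name = c("ara_stems", "ndfa_hydroponic",
                                     "cfu_sections")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "diazoquant", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
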