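#' Isotope reference constants for at-air nitrogen
#'
#' Bundle of the two equivalent descriptions of the atmospheric N2 isotope
#' reference: the 15N/14N isotope ratio `r_std` and the natural abundance in
#' atom percent 15N. The two are linked by
#' `atom% = 100 * r_std / (1 + r_std)`; supply either one and the other is
#' derived, or supply both and they are checked for mutual consistency.
#'
#' @param r_std 15N/14N ratio of the at-air reference. Default 0.0036765,
#'   the international standard for atmospheric N2 (0.36630 atom percent
#'   15N; the value is often quoted rounded as 0.364--0.366 atom %).
#' @param natural_abundance_atom_pct Atom percent 15N of air N2. If missing,
#'   derived from `r_std`.
#' @return An object of class `isotope_constants` with fields `r_std` and
#'   `natural_abundance_atom_pct`.
#' @examples
#' isotope_constants()
#' isotope_constants(r_std = 0.00364 / (1 - 0.00364))
#' @export
isotope_constants <- function(r_std = 0.0036765,
                              natural_abundance_atom_pct = NULL) {
  stopifnot(is.numeric(r_std), length(r_std) == 1L, is.finite(r_std))
  if (r_std <= 0) {
    stop("`r_std` must be positive.", call. = FALSE)
  }
  derived <- 100 * r_std / (1 + r_std)
  if (is.null(natural_abundance_atom_pct)) {
    natural_abundance_atom_pct <- derived
  } else if (abs(natural_abundance_atom_pct - derived) > 1e-9) {
    stop("`natural_abundance_atom_pct` (", natural_abundance_atom_pct,
         ") is inconsistent with `r_std` (implies ", derived, " atom %).",
         call. = FALSE)
  }
  structure(
    list(r_std = r_std,
         natural_abundance_atom_pct = natural_abundance_atom_pct),
    class = "isotope_constants"
  )
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("Isotope reference (at-air N2)\n")
  cat("  15N/14N ratio:     ", format(x$r_std, digits = 8), "\n")
  cat("  natural abundance: ",
      format(x$natural_abundance_atom_pct, digits = 8), " atom % 15N\n")
  invisible(x)
}

#' Convert delta-15N (per mil, at-air) to atom percent 15N
#'
#' The IRMS delta value is the per-mil deviation of the sample 15N/14N ratio
#' from the at-air reference, `delta = (R_sam / R_std - 1) * 1000`.
#' Rearranged, the sample ratio is `R = r_std * (1 + delta / 1000)` and the
#' fraction of nitrogen atoms that are 15N is `100 * R / (1 + R)`.
#'
#' @param delta_permil Numeric vector of delta-15N values in per mil vs
#'   at-air. Must exceed -1000 (a delta of -1000 would imply zero 15N).
#' @param constants An [isotope_constants()] object.
#' @return Atom percent 15N, same length as `delta_permil`. Strictly
#'   increasing in delta.
#' @examples
#' delta_to_atom_percent(0)     # natural abundance, 0.36630
#' delta_to_atom_percent(284)   # strongly enriched tissue
#' @export
delta_to_atom_percent <- function(delta_permil,
                                  constants = isotope_constants()) {
  stopifnot(is.numeric(delta_permil), inherits(constants, "isotope_constants"))
  if (any(delta_permil <= -1000, na.rm = TRUE)) {
    stop("delta-15N must be > -1000 per mil (isotope ratio must be positive).",
         call. = FALSE)
  }
  r <- constants$r_std * (1 + delta_permil / 1000)
  100 * r / (1 + r)
}

#' Convert atom percent 15N to delta-15N (per mil, at-air)
#'
#' Exact inverse of [delta_to_atom_percent()]: recovers the isotope ratio
#' `R = atom% / (100 - atom%)` and expresses it as a per-mil deviation from
#' the reference ratio. Needed to synthesise IRMS observations from
#' simulated atom-percent compositions and for round-trip checks.
#'
#' @param atom_pct Numeric vector of atom percent 15N, strictly within
#'   (0, 100).
#' @inheritParams delta_to_atom_percent
#' @return delta-15N in per mil vs at-air.
#' @export
atom_percent_to_delta <- function(atom_pct,
                                  constants = isotope_constants()) {
  stopifnot(is.numeric(atom_pct), inherits(constants, "isotope_constants"))
  if (any(atom_pct <= 0 | atom_pct >= 100, na.rm = TRUE)) {
    stop("`atom_pct` must lie strictly between 0 and 100.", call. = FALSE)
  }
  r <- atom_pct / (100 - atom_pct)
  1000 * (r / constants$r_std - 1)
}
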