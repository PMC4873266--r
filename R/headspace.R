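#' Closed-flask specification
#'
#' Geometry of a sealed culture flask: total volume, liquid (medium)
#' volume, and the N2 fraction of the air filling the headspace. Only the
#' headspace N2 pool matters for the tracer atmosphere; O2 and CO2 are not
#' tracked.
#'
#' @param total_volume_ml Total flask volume in ml.
#' @param liquid_volume_ml Volume occupied by liquid or agar medium, ml;
#'   must be strictly between 0 and the total volume.
#' @param air_n2_fraction Volume fraction of N2 in air (default 0.78).
#' @return A `flask_spec` object.
#' @examples
#' flask_spec(125, 25)  # 100 ml headspace, 78 ml N2
#' @export
flask_spec <- function(total_volume_ml, liquid_volume_ml,
                       air_n2_fraction = 0.78) {
  stopifnot(is.numeric(total_volume_ml), is.numeric(liquid_volume_ml),
            is.numeric(air_n2_fraction))
  if (liquid_volume_ml <= 0 || liquid_volume_ml >= total_volume_ml) {
    stop("`liquid_volume_ml` must be strictly between 0 and ",
         "`total_volume_ml` (the flask needs a headspace).", call. = FALSE)
  }
  if (air_n2_fraction <= 0 || air_n2_fraction >= 1) {
    stop("`air_n2_fraction` must lie in (0, 1).", call. = FALSE)
  }
  structure(
    list(total_volume_ml = total_volume_ml,
         liquid_volume_ml = liquid_volume_ml,
         headspace_ml = total_volume_ml - liquid_volume_ml,
         air_n2_fraction = air_n2_fraction),
    class = "flask_spec"
  )
}

#' Label-gas dose event
#'
#' One dosing step: withdraw `removed_ml` of well-mixed headspace, then
#' inject `added_ml` of pure N2 label gas at `label_atom_pct` atom percent
#' 15N. `duration_days` is the time until the next event, used by
#' time-weighted regime summaries.
#'
#' @param removed_ml Headspace volume withdrawn, ml (>= 0).
#' @param added_ml Label gas volume added, ml (>= 0).
#' @param label_atom_pct Atom percent 15N of the label gas (0, 100];
#'   default 98, typical commercial 15N2 purity.
#' @param duration_days Days until the next event (>= 0).
#' @return A `dose_event` object.
#' @export
dose_event <- function(removed_ml, added_ml, label_atom_pct = 98,
                       duration_days = 0) {
  stopifnot(is.numeric(removed_ml), is.numeric(added_ml),
            is.numeric(label_atom_pct), is.numeric(duration_days))
  if (removed_ml < 0 || added_ml < 0) {
    stop("Removed and added volumes must be non-negative.", call. = FALSE)
  }
  if (label_atom_pct <= 0 || label_atom_pct > 100) {
    stop("`label_atom_pct` must lie in (0, 100].", call. = FALSE)
  }
  if (duration_days < 0) stop("`duration_days` must be >= 0.", call. = FALSE)
  structure(
    list(removed_ml = removed_ml, added_ml = added_ml,
         label_atom_pct = label_atom_pct, duration_days = duration_days),
    class = c("dose_event", "regime_event")
  )
}

#' Air-exchange event
#'
#' Opening the flask for a fresh-air exchange; the headspace is assumed
#' completely flushed back to the initial natural-abundance atmosphere
#' (partial exchange via `efficiency` < 1 mixes the current pool with fresh
#' air in that proportion).
#'
#' @param duration_days Days until the next event (>= 0).
#' @param efficiency Fraction of the headspace replaced by fresh air
#'   (default 1, complete flushing).
#' @return An `air_exchange` object.
#' @export
air_exchange <- function(duration_days = 0, efficiency = 1) {
  stopifnot(is.numeric(duration_days), is.numeric(efficiency))
  if (efficiency < 0 || efficiency > 1) {
    stop("`efficiency` must lie in [0, 1].", call. = FALSE)
  }
  if (duration_days < 0) stop("`duration_days` must be >= 0.", call. = FALSE)
  structure(list(duration_days = duration_days, efficiency = efficiency),
            class = c("air_exchange", "regime_event"))
}

#' Initial flask atmosphere
#'
#' The headspace N2 pool before any dosing: `air_n2_fraction` of the
#' headspace volume, at natural-abundance atom percent 15N.
#'
#' @param flask A [flask_spec()].
#' @param constants An [isotope_constants()].
#' @return An `atmosphere_state` with fields `n2_volume_ml` and `atom_pct`.
#' @examples
#' initial_atmosphere(flask_spec(125, 25))  # 78 ml N2 at 0.36630 atom%
#' @export
initial_atmosphere <- function(flask, constants = isotope_constants()) {
  stopifnot(inherits(flask, "flask_spec"))
  new_atmosphere(flask$air_n2_fraction * flask$headspace_ml,
                 constants$natural_abundance_atom_pct)
}

new_atmosphere <- function(n2_volume_ml, atom_pct) {
  if (n2_volume_ml <= 0) {
    stop("Headspace N2 volume must be positive.", call. = FALSE)
  }
  structure(list(n2_volume_ml = n2_volume_ml, atom_pct = atom_pct),
            class = "atmosphere_state")
}

#' @export
print.atmosphere_state <- function(x, ...) {
  cat(sprintf("Headspace N2 pool: %.4g ml at %.5f atom%% 15N\n",
              x$n2_volume_ml, x$atom_pct))
  invisible(x)
}

#' Apply a dose event to the headspace N2 pool
#'
#' Removal withdraws a well-mixed headspace aliquot, so it removes
#' `air_n2_fraction * removed_ml` of N2 at the pool's current atom percent
#' (the non-N2 share of the aliquot does not touch the N2 pool). Addition
#' injects `added_ml` of pure N2 at the label's atom percent. The new pool
#' composition is the amount-weighted mixture; 15N amount is conserved
#' across the step up to the removal loss and addition gain.
#'
#' @param state An `atmosphere_state`.
#' @param dose A [dose_event()].
#' @param flask The [flask_spec()] (supplies the N2 fraction of the
#'   withdrawn aliquot).
#' @return The updated `atmosphere_state`.
#' @examples
#' fl <- flask_spec(125, 25)
#' apply_dose(initial_atmosphere(fl), dose_event(5, 5, 98), fl)
#' @export
apply_dose <- function(state, dose, flask) {
  stopifnot(inherits(state, "atmosphere_state"),
            inherits(dose, "dose_event"), inherits(flask, "flask_spec"))
  if (dose$removed_ml > flask$headspace_ml) {
    stop("Cannot remove ", dose$removed_ml, " ml from a ",
         flask$headspace_ml, " ml headspace.", call. = FALSE)
  }
  n2_removed <- flask$air_n2_fraction * dose$removed_ml
  if (n2_removed >= state$n2_volume_ml) {
    stop("Removal would exhaust the headspace N2 pool.", call. = FALSE)
  }
  v_rest <- state$n2_volume_ml - n2_removed
  v_new <- v_rest + dose$added_ml
  # amount-weighted mixing of 15N across remaining + added N2
  atom_new <- (v_rest * state$atom_pct +
                 dose$added_ml * dose$label_atom_pct) / v_new
  new_atmosphere(v_new, atom_new)
}

#' Apply an air-exchange event
#'
#' With full efficiency the pool resets to [initial_atmosphere()]; a
#' partial exchange replaces that fraction of the headspace with fresh air
#' and mixes.
#'
#' @inheritParams apply_dose
#' @param exchange An [air_exchange()].
#' @param constants An [isotope_constants()].
#' @return The updated `atmosphere_state`.
#' @export
apply_air_exchange <- function(state, exchange, flask,
                               constants = isotope_constants()) {
  stopifnot(inherits(state, "atmosphere_state"),
            inherits(exchange, "air_exchange"),
            inherits(flask, "flask_spec"))
  fresh <- initial_atmosphere(flask, constants)
  e <- exchange$efficiency
  if (e == 1) return(fresh)
  v_new <- (1 - e) * state$n2_volume_ml + e * fresh$n2_volume_ml
  atom_new <- ((1 - e) * state$n2_volume_ml * state$atom_pct +
                 e * fresh$n2_volume_ml * fresh$atom_pct) / v_new
  new_atmosphere(v_new, atom_new)
}

#' Trace a dosing regime and summarise its atom-percent excess
#'
#' Plays an ordered list of [dose_event()] / [air_exchange()] events
#' through the headspace model and reports the 15N atom-percent excess the
#' plants experienced. `final_dose` returns the excess prevailing after the
#' last dose event; `time_weighted` returns the duration-weighted mean
#' excess over all intervals with positive duration.
#'
#' @param flask A [flask_spec()].
#' @param events List of regime events in chronological order; at least one
#'   dose event is required.
#' @param weighting `"final_dose"` (default) or `"time_weighted"`.
#' @param constants An [isotope_constants()].
#' @return Atom percent excess (a single number). The full interval table
#'   is available from [regime_history()].
#' @examples
#' fl <- flask_spec(125, 25)
#' ev <- list(dose_event(1, 1, 98, duration_days = 4),
#'            air_exchange(),
#'            dose_event(5, 5, 98, duration_days = 7),
#'            air_exchange(),
#'            dose_event(5, 5, 98, duration_days = 4))
#' regime_excess(fl, ev)                     # 6.17
#' regime_excess(fl, ev, "time_weighted")    # lower, includes the 1-ml span
#' @export
regime_excess <- function(flask, events,
                          weighting = c("final_dose", "time_weighted"),
                          constants = isotope_constants()) {
  weighting <- match.arg(weighting)
  hist <- regime_history(flask, events, constants)
  doses <- hist[hist$event == "dose", , drop = FALSE]
  if (nrow(doses) == 0L) {
    stop("The regime contains no dose events.", call. = FALSE)
  }
  if (weighting == "final_dose") {
    return(doses$excess[nrow(doses)])
  }
  w <- hist$duration_days
  if (sum(w) <= 0) {
    stop("Time-weighted summary needs intervals with positive duration.",
         call. = FALSE)
  }
  sum(hist$excess * w) / sum(w)
}

#' Per-interval history of a dosing regime
#'
#' @inheritParams regime_excess
#' @return A tibble with one row per event: event type, post-event N2
#'   volume (ml), atom percent, atom percent excess over natural abundance,
#'   and the interval duration in days.
#' @export
regime_history <- function(flask, events, constants = isotope_constants()) {
  stopifnot(inherits(flask, "flask_spec"), is.list(events))
  if (length(events) == 0L) {
    stop("Empty dosing regime.", call. = FALSE)
  }
  nat <- constants$natural_abundance_atom_pct
  state <- initial_atmosphere(flask, constants)
  rows <- vector("list", length(events))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (inherits(ev, "dose_event")) {
      state <- apply_dose(state, ev, flask)
      type <- "dose"
    } else if (inherits(ev, "air_exchange")) {
      state <- apply_air_exchange(state, ev, flask, constants)
      type <- "air_exchange"
    } else {
      stop("Event ", i, " is neither a dose_event nor an air_exchange.",
           call. = FALSE)
    }
    rows[[i]] <- tibble::tibble(
      step = i, event = type,
      n2_volume_ml = state$n2_volume_ml,
      atom_pct = state$atom_pct,
      excess = state$atom_pct - nat,
      duration_days = ev$duration_days
    )
  }
  dplyr::bind_rows(rows)
}

#' The two-week hydroponic dosing regime
#'
#' Convenience constructor for the hydroponic exposure used throughout the
#' package's examples: a 125-ml flask with 25 ml medium, an initial 1-ml
#' label dose held 4 days, a fresh-air exchange, a 5-ml dose held 7 days,
#' another exchange, and a final 5-ml dose held 4 days. The final-dose
#' atom-percent excess is 6.17.
#'
#' @param label_atom_pct Label gas purity in atom percent 15N (default 98).
#' @return List with elements `flask` and `events`, ready for
#'   [regime_excess()].
#' @export
hydroponic_regime <- function(label_atom_pct = 98) {
  list(
    flask = flask_spec(125, 25),
    events = list(
      dose_event(1, 1, label_atom_pct, duration_days = 4),
      air_exchange(),
      dose_event(5, 5, label_atom_pct, duration_days = 7),
      air_exchange(),
      dose_event(5, 5, label_atom_pct, duration_days = 4)
    )
  )
}
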