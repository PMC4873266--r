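# Independent oracles used across tests.

# Two-pool headspace oracle: track 15N and 14N N2 "amounts" (volumes)
# separately through a regime, never computing atom% until the end.
two_pool_trace <- function(flask, events, nat_atom_pct) {
  v15 <- flask$air_n2_fraction * flask$headspace_ml * nat_atom_pct / 100
  v14 <- flask$air_n2_fraction * flask$headspace_ml * (100 - nat_atom_pct) / 100
  reset15 <- v15; reset14 <- v14
  for (ev in events) {
    if (inherits(ev, "air_exchange")) {
      e <- ev$efficiency
      v15 <- (1 - e) * v15 + e * reset15
      v14 <- (1 - e) * v14 + e * reset14
    } else {
      frac_removed <- flask$air_n2_fraction * ev$removed_ml / (v15 + v14)
      v15 <- v15 * (1 - frac_removed)
      v14 <- v14 * (1 - frac_removed)
      v15 <- v15 + ev$added_ml * ev$label_atom_pct / 100
      v14 <- v14 + ev$added_ml * (100 - ev$label_atom_pct) / 100
    }
  }
  list(n2_volume_ml = v15 + v14, atom_pct = 100 * v15 / (v15 + v14))
}

# Closed-form simple-linear-regression coefficients (normal equations).
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Random feasible dosing regime for property tests: removals are kept
# below what the current N2 pool can supply.
random_regime <- function(flask, n_events) {
  pool <- flask$air_n2_fraction * flask$headspace_ml
  events <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    if (stats::runif(1) < 0.25) {
      ex <- air_exchange(duration_days = stats::runif(1, 0, 5),
                         efficiency = sample(c(1, stats::runif(1)), 1))
      events[[i]] <- ex
      pool <- (1 - ex$efficiency) * pool +
        ex$efficiency * flask$air_n2_fraction * flask$headspace_ml
    } else {
      max_removed <- min(flask$headspace_ml,
                         0.9 * pool / flask$air_n2_fraction)
      ev <- dose_event(removed_ml = stats::runif(1, 0, max_removed / 2),
                       added_ml = stats::runif(1, 0, 10),
                       label_atom_pct = stats::runif(1, 50, 100),
                       duration_days = stats::runif(1, 0, 5))
      pool <- pool - flask$air_n2_fraction * ev$removed_ml + ev$added_ml
      events[[i]] <- ev
    }
  }
  events
}
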