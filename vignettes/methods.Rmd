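---
title: "Quantifying endophytic nitrogen fixation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endophytic nitrogen fixation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazoquant)
```

## The measurement problem

A cutting from a wild poplar contains an unknown, patchily distributed
community of endophytic bacteria, some of which may fix atmospheric N₂.
Sealed in a flask whose headspace has been spiked with ¹⁵N₂, any nitrogen
the plant acquires by fixation carries the label, while nitrogen
remobilised from its own tissues does not. The analysis chain that turns
raw instrument readings into "this cutting fixed X mg N per kg per day"
has five links, each implemented by one module of this package:

1. what the atmosphere actually was (headspace dosing model);
2. what the tissue's isotope composition is (δ¹⁵N → atom % conversion);
3. what fraction of tissue N came from that atmosphere (%Ndfa, with a
   detection limit);
4. corroborating assays (acetylene reduction; dilution plating);
5. whether treatments differ (plant-level group comparison).

## Headspace model

The flask is described by total volume, medium volume, and the N₂ volume
fraction of air (default 0.78). Only the N₂ pool is tracked: the %Ndfa
denominator depends solely on the isotopic composition of the N₂ the
plant could fix, so O₂ and CO₂ bookkeeping would add state without
changing any output. A dose withdraws a *well-mixed* aliquot — removing
`air_n2_fraction × removed_ml` of N₂ at the pool's current atom % — and
injects pure label N₂; the new composition is the amount-weighted
mixture. Withdrawing mixed headspace is the only self-consistent reading
of "removing air" from a sealed vessel. An air exchange resets the pool
to fresh air (a partial-efficiency option mixes instead; default 1.0).
Biological N₂ consumption between events is ignored: at the trace
fixation levels measured here (≤0.8% of tissue N over two weeks) the pool
composition is unaffected at the fourth decimal.

For the standard two-week hydroponic regime:

```{r}
reg <- hydroponic_regime()
regime_history(reg$flask, reg$events)
```

Two summary conventions are provided because an "overall exposure" figure
is inherently ambiguous: `final_dose` (6.17 atom % excess here, the state
the flasks were in for 11 of the 15 days) and `time_weighted` (4.86,
which also counts the initial low-dose interval). The headline 6.17
figure is the final-dose value; %Ndfa computed with it is therefore
conservative-to-neutral for nitrogen fixed during the first interval.

Two quantitative loose ends are recorded rather than forced. First, the
month-long agar variant (125-ml flask, 50 ml agar, two 5-ml doses) yields
8.19 atom % excess under any plausible volume accounting, not the 6.61
sometimes quoted for that design; no combination of flask geometry and
dose volumes we tried reproduces 6.61, so the model reports its own
arithmetic. Second, the N₂ fraction of the withdrawn aliquot assumes the
pool is at air composition for the non-N₂ gases; after heavy dosing this
is an approximation, but for ≤5-ml doses into ~100-ml headspaces the
error is below 0.1% of the excess.

## Isotope conversions and %Ndfa

With `r_std` the ¹⁵N/¹⁴N ratio of atmospheric N₂ (default 0.0036765,
i.e. 0.36630 atom %; the constant is configurable and every downstream
number is insensitive to the 0.364 vs 0.3663 rounding at the precision
reported), a δ¹⁵N‰ value maps to atom % via
`R = r_std (1 + δ/1000)`, `atom% = 100 R/(1+R)`, and back. The round trip
is exact to 10⁻⁹ ‰ across δ ∈ (−900, 10000); the domain guard at
δ = −1000 marks the physical boundary of zero ¹⁵N.

%Ndfa is the two-member mixing model: tissue N is a mixture of a fraction
*f* fixed from the labeled atmosphere and 1−*f* at the reference
composition, so *f* = (sample − reference)/(atmosphere excess). The
reference is the unweighted mean atom % of the undosed controls across
tissues (a per-study scalar; per-tree references are possible by passing
`reference_atom_pct` explicitly but are off by default — with one control
cutting per tree they would put all reference noise into single
measurements).

**Detection limit.** The data that motivate this package show many dosed
cuttings statistically indistinguishable from controls, and published
tables in this field print "BDL" without stating the criterion. The
package's rule is explicit: a sample is BDL when its atom % excess is at
most twice the standard deviation of the control atom % values (boundary
inclusive), falling back to 0 when fewer than three controls exist. Under
Gaussian noise this holds the per-sample false-positive rate near 2.3%.
BDL samples report no %Ndfa and no rate; they are never silently zeroed.

**Rates.** `rate = (%Ndfa/100) × tissue-N fraction × 10⁶ / days`
(mg N kg⁻¹ d⁻¹) under the stated assumption that fixation was uniform
over the exposure; rate × days recovers the fixed-N mass exactly
(conservation). Rates require a measured tissue N fraction; a missing
value propagates as missing, not zero. The bundled field %Ndfa/rate table
can be checked only by inversion — its raw δ values were never printed —
and the strongest cutting (0.761 %Ndfa, 20.6 mg kg⁻¹ d⁻¹) implies a
3.79% tissue N content, squarely in the poplar range, which is the
self-consistency the tests assert.

## Acetylene reduction assay

Nitrogenase reduces acetylene to ethylene, so ethylene accumulation above
the plant's own background indicates nitrogenase activity. The module
fits an OLS standard curve (free intercept by default, since FID
baselines are rarely zero; a flag forces the origin and a warning fires
when the intercept exceeds 5% of the top standard), converts peak areas
to per-gram ethylene, and calls a dosed vial positive when it reaches
twice the mean of the undosed vials. The 2-fold default is a deliberate
choice where published work reports folds without a criterion; at that
threshold the bundled 18-vial survey yields exactly three positives (4-,
12-, and 21-fold), matching the qualitative description of that data,
though the weakest printed fold ("6") is not reproduced by any ratio in
the table itself (20.63/5.11 = 4.0) — noted, not reconciled. Ethylene
units are carried as opaque labels from the standards file: the survey's
printed "mmol per gram" is implausibly large for endophytic activity
(nmol is typical), and silently "correcting" units would be worse than
propagating the label.

## CFU quantification

Dilution-plating arithmetic with explicit flags: TNTC plates become lower
bounds at the top of the countable range (30–300 colonies, the
plate-count convention; the bound at the bundled survey's settings is
1.5 × 10⁷ CFU g⁻¹), zero-colony plates become single-colony detection
limits, and counts outside the countable range keep their estimate but
carry a reliability flag. Variability is summarised as min, max, and
log₁₀(max/min) — the "orders of magnitude" figure used to describe
within-tree heterogeneity — with flagged records excluded and counted.

## Group comparison

Because endophytes are unevenly distributed, tissue subsamples within a
cutting are pseudo-replicates; the experimental unit is the plant.
`aggregate_subsamples()` averages δ values per plant and merges undosed
wild and undosed sterile plants into one control group.
`group_compare()` fits the one-way cell-means model by OLS and computes
pairwise contrasts with the pooled residual variance — exactly the
least-squares-means procedure for a one-factor design, where LSMEANs
reduce to group means. In the balanced two-group case each contrast *is*
the pooled two-sample t-test, which the tests verify against the
closed form, and the unbalanced case is verified against emmeans. No
multiplicity adjustment is applied by default (plain pairwise
comparisons at α = 0.05 are the field's convention here); Bonferroni and
Holm are available. No experiment factor enters the default model: when
studies are pooled the package treats group as the only factor, matching
an analysis that collapses to plant means first.

## Synthetic studies: what they emulate and what they do not

`simulate_study()` generates the full observation set of a tracer study
with known truth. Its defaults *are* the study conditions of the two-week
hydroponic design and were fixed from the published structure before any
testing: 5 trees × 4 dosed cuttings + 1 control; activity Bernoulli at
the cutting level with `p_active = 0.5` (about half of dosed cuttings
incorporate label at control-like levels); true %Ndfa uniform on
[0.03, 0.8] (the span of the field table, with a log-uniform option);
atmosphere excess 6.17; exposure 14 d; IRMS noise Normal with sd 0.3‰ on
the δ scale (typical EA-IRMS precision — the instrument itself is not
specified in the motivating work); tissue N 4% ± 0.6% (the range implied
by the field table's rate/%Ndfa ratios); colonization log₁₀-normal
(mean 6.5, sd 0.7, the plating survey's spread) and *independent of
activity* by default, encoding the observed non-correlation between
culturable counts and ARA, with a `cfu_activity_shift` knob for
sensitivity analysis; ARA baseline 5.11 ± 1.7 with active folds uniform
on [4, 21]. An optional tree-level logit shift clusters activity within
trees; it defaults to 0 because within-tree variation exceeded
between-tree variation in the motivating data.

The generator does **not** emulate: nitrogenase kinetics or its oxygen
sensitivity; isotope fractionation during uptake (enzymatic preference
for ¹⁴N would make real estimates conservative); gas dissolution in the
medium; subsample-level biological heterogeneity beyond instrument noise;
or community assembly. Passing tests therefore demonstrate that the
*arithmetic chain* is correct and well-calibrated under realistic noise,
not that the biological assumptions hold in any particular orchard.

For the three-treatment comparison a direct plant-level generator
(`simulate_group_aggregates()`) draws dosed wild plants from N(80, 40) ‰,
the internally sterile clone from N(13.7, 10) ‰, and undosed controls
from N(2, 2) ‰ — means from the published group summaries, spreads chosen
once to reflect the huge dosed-wild heterogeneity and the near-reference
controls visible in the published figure. Under these conditions the
dosed-wild vs undosed contrast at α = 0.01 with 5 plants per group has
~92–97% power (Monte Carlo, 1000 replicates, ~1 s).

## Numerical choices

- Mixing is computed on amounts (volume × atom %), conserving ¹⁵N by
  construction; a brute-force two-pool (¹⁵N/¹⁴N) oracle agrees to 10⁻⁹
  on random regimes.
- Problem sizes in the tests were chosen for statistical resolution:
  200 simulated studies for the estimated-vs-true %Ndfa slope (4000
  paired points give a slope CI far narrower than the asserted
  [0.95, 1.05]), 1000 replicates for power (MC sd ≈ 0.8%).
- CSV output writes doubles with 15 significant digits, making
  write → read → write cycles byte-stable and fixed-seed runs
  byte-identical.
- Degenerate inputs fail loudly and specifically: no undosed controls
  (no reference), removal exceeding the headspace, zero baseline, a
  plant in two groups, fewer than two standards. Zero-variance group
  comparisons return t = 0, p = 1 rather than NaN.

## Known limitations

- %Ndfa assumes the reference composition is shared by controls and
  dosed plants; soil- or medium-derived N with unusual δ¹⁵N would bias
  small %Ndfa values.
- The BDL rule is a per-sample test against control spread; it does not
  control family-wise error over a table of cuttings.
- ARA fold calls inherit whatever units the standards carry; no
  acetylene-to-N₂ conversion (3:1/4:1) is attempted, since the motivating
  analyses do not make that leap either.
- TNTC lower bounds depend on the assumed countable maximum (300); plates
  should be re-diluted rather than trusted at that bound.
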