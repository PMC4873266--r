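# diazoquant

Quantification of biological nitrogen fixation by endophytic diazotrophs in
plant cuttings, built around closed-flask ¹⁵N₂ tracer experiments on wild
black cottonwood (*Populus trichocarpa*). Wild poplar thrives on
nutrient-poor river bars, and part of the explanation is nitrogen-fixing
bacteria living inside its tissues. Measuring that fixation is a chain of
small quantitative steps — headspace gas mixing, isotope-ratio conversion,
detection-limit calling, gas-chromatograph calibration, dilution-plating
arithmetic, and a group comparison on the right experimental unit — and
this package implements that chain as tested, reusable functions for
anyone running ¹⁵N₂ incorporation or acetylene-reduction assays on plant
material.

## What it computes

**Headspace dosing model.** A sealed flask (e.g. 125 ml with 25 ml medium)
holds a headspace N₂ pool. Dosing replaces a well-mixed aliquot with pure
¹⁵N₂ label; the pool's composition follows amount-weighted mixing. For the
standard two-week regime (1 ml dose, air exchange, two 5 ml doses of
98 atom % ¹⁵N₂) the model gives the exposure's atom-percent excess,

> 5 ml of a 100-ml headspace replaced with 98 atom % ¹⁵N₂:
> (74.1 · 0.3663 + 5 · 98) / 79.1 − 0.3663 = **6.17 atom % excess**.

**Isotope conversions and %Ndfa.** IRMS delivers δ¹⁵N‰ (at-air). With
R = R_std·(1 + δ/1000),

- atom %¹⁵N = 100·R/(1+R),
- %Ndfa = 100 · (¹⁵N_sam atom% − ¹⁵N_ref atom%) / ¹⁵N atmosphere atom% excess,
- rate (mg N kg⁻¹ d⁻¹) = (%Ndfa/100) · tissue-N fraction · 10⁶ / exposure days,

where the reference is the mean atom % of undosed controls and samples
whose excess is within twice the control spread are flagged below
detection (BDL).

**ARA quantification.** Ethylene per gram from GC peak areas via an OLS
standard curve, an undosed baseline, and fold-over-baseline positive calls
(default threshold 2).

**CFU plating.** CFU g⁻¹ = colonies / dilution / plated volume ×
extraction ratio, with TNTC lower bounds, single-colony detection limits,
and order-of-magnitude variability summaries.

**Group comparison.** Subsamples are averaged to plant-level experimental
units; a one-way cell-means fit with pooled residual variance yields
least-squares means and pairwise t contrasts.

**Synthetic studies.** `simulate_study()` generates complete IRMS/ARA/plate
tables with per-cutting ground truth under heterogeneous colonization
(about half of dosed cuttings active, true %Ndfa in 0.03–0.8), so every
stage is testable end to end.

## Worked example

```r
library(diazoquant)

# the dosing regime the cuttings experienced
reg <- hydroponic_regime()
regime_excess(reg$flask, reg$events)                  # 6.171536
regime_excess(reg$flask, reg$events, "time_weighted") # 4.858645

# acetylene reduction on 18 stem vials (bundled survey data)
res <- ara_analysis(example_dataset("ara_stems"), fold_threshold = 2)
attr(res, "baseline")   # 5.11  (undosed mean ethylene per g)
sum(res$positive)       # 3     (dosed vials >= 2x baseline)
sort(res$fold_over_baseline[res$dosed])
#> 0.83 1.11 1.13 1.21 1.67 1.77 4.04 12.02 20.92

# a full synthetic study through the %Ndfa chain
st <- simulate_study(sim_config(seed = 7))
nd <- ndfa_table(st$irms, atmosphere_excess_atom_pct = 6.17,
                 exposure_days = 14)
truth_recovery_report(nd, st$truth)$ndfa_rmse  # ~0.0017 (%Ndfa units)
```

The regime numbers say the flasks sat at 6.17 atom % excess after the
5-ml doses (4.86 averaged over the whole two weeks); the ARA fold vector
shows six dosed vials indistinguishable from background and three clear
positives (4-, 12-, and 21-fold); the recovery RMSE shows that with
0.3‰ IRMS noise the chain recovers per-cutting %Ndfa to a few thousandths
of a percentage point.

The numbered scripts under `analysis/` run the complete workflow —
simulate, dose model, %Ndfa, ARA, CFU, group comparison — and write their
tables under `results/`.

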