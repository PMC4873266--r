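#!/usr/bin/env Rscript
# Acetylene reduction assay: quantify the bundled stem-sample survey
# (pre-quantified ethylene per gram) and the synthetic study's raw GC
# peak areas through a re-fitted standard curve; call positives at the
# 2-fold threshold.

library(diazoquant)

# Field survey: 9 undosed + 9 acetylene-dosed stem vials from one tree
ara <- example_dataset("ara_stems")
res <- ara_analysis(ara, fold_threshold = 2)
write_table(res, "results/ara_field_calls.csv")
cat(sprintf("Undosed baseline: %.2f (rounds to %d) ethylene units per g\n",
            attr(res, "baseline"), round(attr(res, "baseline"))))
dosed <- res[res$dosed, ]
cat("Dosed-vial folds over baseline:",
    paste(sprintf("%.1f", sort(dosed$fold_over_baseline)), collapse = ", "),
    "\n")
cat("Positive calls at 2-fold:", sum(res$positive), "->",
    paste(dosed$vial_id[dosed$positive], collapse = ", "), "\n")

# Synthetic study: full curve -> quantify -> call chain on raw peak areas
vials <- read_table("results/synthetic/ara_vials.csv", "ara_vials")
stds <- read_table("results/synthetic/ara_standards.csv", "ara_standards")
curve <- fit_standard_curve(stds)
print(curve)
sim_res <- ara_analysis(vials, standards = stds)
write_table(sim_res, "results/ara_synthetic_calls.csv")
cat("Synthetic study:", sum(sim_res$positive), "of", sum(sim_res$dosed),
    "dosed vials positive\n")
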