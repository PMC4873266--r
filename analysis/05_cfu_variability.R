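#!/usr/bin/env Rscript
# Culturable endophyte population: dilution-plating quantification of the
# synthetic study's plate counts, and variability summaries of the bundled
# section survey (ten sections of one tree on three media).

library(diazoquant)

# Synthetic plate counts -> CFU/g (1:1000 dilution, 100 ul plated,
# 5 ml extract per gram)
plates <- read_table("results/synthetic/plates.csv", "plates")
cfu <- cfu_per_gram(plates)
write_table(cfu, "results/cfu_synthetic.csv")
cat("Synthetic plates:", nrow(cfu), "; flags:",
    paste(names(table(cfu$flag)), table(cfu$flag), collapse = ", "), "\n")

# Field section survey: spread within one tree
sections <- example_dataset("cfu_sections")
sections$flag <- ifelse(sections$tntc, "tntc_lower_bound", "ok")
for (med in unique(sections$medium)) {
  vs <- variability_summary(sections[sections$medium == med, ])
  cat(sprintf(
    "%-7s n=%2d  %.1e - %.1e CFU/g  (%.2f orders of magnitude%s)\n",
    med, vs$overall$n, vs$overall$min_cfu_per_g, vs$overall$max_cfu_per_g,
    vs$overall$log10_spread,
    if (vs$overall$n_excluded) paste0("; ", vs$overall$n_excluded,
                                      " TNTC excluded") else ""))
}
stems <- sections[sections$tissue == "stem" & sections$medium == "MG/L", ]
adj <- stems$cfu_per_g[stems$sample_id %in% c(3, 4)]
cat(sprintf("Adjacent stem sections differ %.1f-fold on MG/L\n",
            max(adj) / min(adj)))
vs_all <- variability_summary(sections)
write_table(vs_all$by_tissue, "results/cfu_by_tissue.csv")
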