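#!/usr/bin/env Rscript
# What determines complex formation: per-Kd linear abundance/share fits,
# their slopes across tissues, and the interpolated affinity x abundance x
# share surface for one illustrative tissue.

suppressPackageStartupMessages(library(raswiring))

panel <- read_panel("results/data/panel.csv")
profiles <- read_abundances("results/data/abundances.csv", panel)

fits <- do.call(rbind, lapply(profiles, function(p) {
  fit_abundance_complex_lines(solve_tissue(p, panel), panel, p$effectors)
}))
utils::write.csv(fits, "results/slopes.csv", row.names = FALSE, quote = FALSE)

summ <- slope_summary(fits)
utils::write.csv(summ, "results/slope_summary.csv", row.names = FALSE,
                 quote = FALSE)
cat(sprintf("slopes: %d fits; per-tissue averages %.4f - %.4f %%/nM\n",
            nrow(fits), min(summ$avg_slope), max(summ$avg_slope)))
cat(sprintf("low-affinity robustness: max slope for Kd > 1 uM = %.3f %%/nM\n",
            max(fits$slope[fits$kd_um > 1])))
cat(sprintf("most affinity-sensitive tissue: %s; least: %s\n",
            summ$tissue[nrow(summ)], summ$tissue[1]))

one <- fits[fits$tissue == "lymph node", ]
sg <- surface_grid(one, abundance_grid = seq(0, 500, by = 10))
utils::write.csv(sg, "results/surface_grid_lymph_node.csv", row.names = FALSE,
                 quote = FALSE)
cat(sprintf("surface grid (lymph node): %d (Kd, abundance) nodes\n", nrow(sg)))
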