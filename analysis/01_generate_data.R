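#!/usr/bin/env Rscript
# Generate the synthetic study inputs: the 56-effector panel (literature Kd
# anchors kept, the rest sampled), 29 tissue abundance profiles in the
# competitive regime, and marker expression for the composition analysis.
# Everything downstream reads from results/data/.

suppressPackageStartupMessages(library(raswiring))

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synthesis_config(seed = seed)
panel <- generate_panel(cfg)
profiles <- generate_tissues(cfg, panel)

write_panel(panel, "results/data/panel.csv")
write_abundances(profiles, "results/data/abundances.csv")

markers <- read_marker_sets()
expr <- generate_marker_expression(cfg, markers, profiles)
utils::write.csv(data.frame(tissue = rownames(expr), expr,
                            check.names = FALSE),
                 "results/data/marker_expression.csv", row.names = FALSE,
                 quote = FALSE)

cc <- vapply(profiles, function(p) {
  competition_check(p, gtp_scenario(), panel)$competition
}, logical(1))
cat(sprintf("generated %d tissues x %d effectors (seed %d)\n",
            length(profiles), nrow(panel), seed))
cat(sprintf("competitive regime (sum effectors > active Ras at 20%% GTP): %d/%d tissues\n",
            sum(cc), length(cc)))
cat(sprintf("Kd span: %.3g - %.3g uM; %d effectors with Kd <= 1 uM\n",
            min(panel$kd_um), max(panel$kd_um), sum(panel$kd_um <= 1)))
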