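#!/usr/bin/env Rscript
# Stage 2: de novo marker discovery on the public-style cohort.
#
# 70/30 discovery split; rank-sum screening with the stringent |delta-beta|
# >= 0.3 cutoff on three contrasts; three-algorithm consensus feature
# selection; marker-class assignment (H3-specific vs IDH-specific); and a
# simulated primer-validation subset down to 76 assayable sites.

suppressPackageStartupMessages(library(bsgdiag))

betas <- read_beta_matrix("results/public_tissue_betas.tsv")
lab_df <- utils::read.csv("results/public_tissue_labels.csv")
labels <- setNames(lab_df$subtype, lab_df$sample_id)[rownames(betas)]

sp <- split_discovery(labels, frac = 0.7, seed = 11L)
message(sprintf("-- discovery %d samples / held-out %d samples",
                length(sp$discovery), length(sp$test)))
disc <- betas[sp$discovery, ]
disc_lab <- labels[sp$discovery]

contrasts <- list(c("H3K27M", "IDH"), c("H3K27M", "DW"), c("IDH", "DW"))
dm <- do.call(rbind, lapply(contrasts, function(pr) {
  hits <- find_dm_cpgs(disc, disc_lab, pr, delta_min = 0.3, alpha = 0.05)
  message(sprintf("   %s vs %s: %d sites pass", pr[1], pr[2], nrow(hits)))
  hits
}))
candidates <- unique(dm$cpg_id)
message(sprintf("-- %d unique candidate CpGs across contrasts", length(candidates)))

k <- min(80L, length(candidates))
selected <- select_consensus_features(disc, disc_lab, candidates, k = k, seed = 13L)
message(sprintf("-- consensus selection kept %d of %d candidates",
                length(selected), length(candidates)))

panel_full <- assign_marker_classes(disc, disc_lab, selected, margin = 0.2)
sz <- panel_sizes(panel_full)
message(sprintf("-- marker classes: %d H3-specific, %d IDH-specific",
                sz["n_h3"], sz["n_idh"]))

# wet-lab reduction: only 76 primers survive design/validation
panel <- if (nrow(panel_full) > 76) subset_panel(panel_full, 76, seed = 17L) else panel_full
write_marker_panel(panel, "results/marker_panel.tsv")
sz <- panel_sizes(panel)
message(sprintf("-- final assayable panel: %d sites (%d H3 / %d IDH) -> results/marker_panel.tsv",
                nrow(panel), sz["n_h3"], sz["n_idh"]))

# sanity on the held-out split: panel separates the subtypes by MSS
test_mss <- compute_mss_matrix(betas[sp$test, ], panel)
med <- tapply(test_mss$mss, labels[sp$test], stats::median)
message(sprintf("-- held-out MSS medians: H3K27M %.3f | DW %.3f | IDH %.3f",
                med["H3K27M"], med["DW"], med["IDH"]))
stopifnot(med["H3K27M"] > med["DW"], med["DW"] > med["IDH"])
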