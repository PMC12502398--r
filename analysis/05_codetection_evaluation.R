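#!/usr/bin/env Rscript
# Stage 5: the mutation-methylation co-detection diagnosis (BSGdiag) in CSF.
#
# Fuses per-sample mutation-predicted probabilities with the methylation
# classifier's probabilities (ALOD samples only carry mutation data; BLOD
# samples are diagnosed from methylation alone), then compares fused,
# mutation-only and methylation-only performance for the H3K27M subtype and
# reports the three-class macro/micro AUCs with bootstrap intervals.

suppressPackageStartupMessages(library(bsgdiag))

panel <- read_marker_panel("results/marker_panel.tsv")
model <- readRDS("scratch/methylation_model.rds")
csf <- read_beta_matrix("results/csf_A_betas.tsv")
muts <- read_mutation_table("results/csf_A_mutations.tsv")
meta <- utils::read.csv("results/csf_A_meta.csv")
c_lab <- utils::read.csv("results/csf_A_labels.csv")
truth <- setNames(c_lab$subtype, c_lab$sample_id)[rownames(csf)]

res <- classify_samples(model, csf[, panel$cpg_id], muts,
                        tested = meta$lod_flag == "ALOD")
utils::write.table(res, "results/csf_A_diagnosis.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("-- %d CSF samples diagnosed (%d fused, %d methylation-only)",
                nrow(res), sum(res$evidence == "fused"),
                sum(res$evidence == "methylation_only")))

report <- function(name, calls) {
  bm <- binary_metrics(calls, truth, "H3K27M")
  message(sprintf("   %-18s sens %.1f%% (%.1f-%.1f) spec %.1f%% (%.1f-%.1f)",
                  name, 100 * bm$sensitivity, 100 * bm$ci_sens["low"],
                  100 * bm$ci_sens["high"], 100 * bm$specificity,
                  100 * bm$ci_spec["low"], 100 * bm$ci_spec["high"]))
}
message("-- H3K27M detection (Agresti-Coull 95% CIs):")
report("BSGdiag (fused)", res$predicted_class)
mut_call <- ifelse(!is.na(res$mut_h3) & res$mut_h3 == 1, "H3K27M",
                   ifelse(!is.na(res$mut_idh) & res$mut_idh == 1, "IDH", "DW"))
report("mutation only", mut_call)
meth_call <- c("H3K27M", "IDH", "DW")[
  max.col(res[, c("p_h3_meth", "p_idh_meth", "p_dw_meth")])]
report("methylation only", meth_call)

auc_fused <- roc_auc(res$p_h3_combined, truth == "H3K27M")
ci <- bootstrap_auc_ci(res$p_h3_combined, truth == "H3K27M", R = 100, seed = 23L)
message(sprintf("-- fused H3K27M AUC %.3f (bootstrap 95%% CI %.3f-%.3f, R = 100)",
                auc_fused, ci["low"], ci["high"]))

fused_probs <- as.matrix(res[, c("p_h3_combined", "p_idh_combined", "p_dw_combined")])
colnames(fused_probs) <- c("H3K27M", "IDH", "DW")
mc <- multiclass_auc(fused_probs, truth)
message(sprintf("-- three-class fused: macro-AUC %.3f, micro-AUC %.3f",
                mc$macro_auc, mc$micro_auc))
meth_probs <- as.matrix(res[, c("p_h3_meth", "p_idh_meth", "p_dw_meth")])
colnames(meth_probs) <- c("H3K27M", "IDH", "DW")
mc_meth <- multiclass_auc(meth_probs, truth)
message(sprintf("-- three-class methylation-only: macro-AUC %.3f, micro-AUC %.3f",
                mc_meth$macro_auc, mc_meth$micro_auc))
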