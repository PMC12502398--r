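#!/usr/bin/env Rscript
# Stage 1: simulate every cohort the downstream analyses consume.
#
#  - a "public array" tissue cohort used for de novo marker discovery
#  - the study tissue cohort (with driver/concurrent mutation calls)
#  - pre-operative (A) and post-operative (C) CSF draws from the study
#    cohort, with tumor-fraction dilution, probe dropout and 5 ng
#    BLOD/ALOD gating
#  - an independent CSF-type cohort used only to train the methylation
#    classifier (kept separate from everything that is evaluated)
#  - a clinical table with simulated overall survival
#
# All outputs are plain TSV/CSV under results/.

suppressPackageStartupMessages(library(bsgdiag))
dir.create("results", showWarnings = FALSE)

write_labels <- function(labels, path) {
  utils::write.csv(data.frame(sample_id = names(labels),
                              subtype = as.character(labels)),
                   path, row.names = FALSE)
}

message("-- public-style discovery cohort (60 per subtype)")
public_cfg <- cohort_config(n_per_subtype = c(H3K27M = 60, IDH = 60, DW = 60),
                            seed = 101L)
public <- generate_tissue_cohort(public_cfg)
write_beta_matrix(public$betas, "results/public_tissue_betas.tsv")
write_labels(public$labels, "results/public_tissue_labels.csv")

message("-- study tissue cohort (45 per subtype) with mutation calls")
study_cfg <- cohort_config(seed = 202L)
study <- generate_tissue_cohort(study_cfg)
write_beta_matrix(study$betas, "results/study_tissue_betas.tsv")
write_mutation_table(study$mutations, "results/study_tissue_mutations.tsv")
write_labels(study$labels, "results/study_tissue_labels.csv")

message("-- CSF draws at timepoints A (pre-op) and C (post-op)")
for (tp in c("A", "C")) {
  csf <- derive_csf_samples(study, timepoint = tp)
  write_beta_matrix(csf$betas, sprintf("results/csf_%s_betas.tsv", tp))
  write_mutation_table(csf$mutations, sprintf("results/csf_%s_mutations.tsv", tp))
  utils::write.csv(csf$meta, sprintf("results/csf_%s_meta.csv", tp),
                   row.names = FALSE)
  write_labels(csf$labels, sprintf("results/csf_%s_labels.csv", tp))
  message(sprintf("   timepoint %s: %d samples, %d BLOD (methylation only)",
                  tp, nrow(csf$meta), sum(csf$meta$lod_flag == "BLOD")))
}

message("-- independent CSF-type training cohort for the classifier")
train_src <- generate_tissue_cohort(cohort_config(seed = 303L))
csf_train <- derive_csf_samples(train_src, timepoint = "A")
write_beta_matrix(csf_train$betas, "results/csf_train_betas.tsv")
write_labels(csf_train$labels, "results/csf_train_labels.csv")

message("-- simulated overall survival for the study cohort")
# latent risk: tumor fraction of the pre-op CSF carries prognosis beyond
# subtype, mirroring a ctDNA-burden effect
csf_a <- derive_csf_samples(study, timepoint = "A")
sv <- generate_survival(study, latent_risk = csf_a$meta$tumor_fraction,
                        survival_config(base_median_months = 40,
                                        beta_risk = log(3), beta_h3 = log(4),
                                        horizon_months = 60, seed = 404L))
utils::write.csv(sv, "results/study_clinical.csv", row.names = FALSE)
message(sprintf("   %d patients, %d deaths within the 60-month horizon",
                nrow(sv), sum(sv$event)))
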