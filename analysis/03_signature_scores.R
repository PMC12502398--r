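#!/usr/bin/env Rscript
# Stage 3: Methylation Signature Scores in tissue and CSF.
#
# Scores every study tissue and pre-operative CSF sample over the discovered
# panel, summarizes the per-subtype distributions, and quantifies (i)
# tissue-vs-CSF score concordance and (ii) the correlation between driver
# VAF and CSF MSS.

suppressPackageStartupMessages(library(bsgdiag))

panel <- read_marker_panel("results/marker_panel.tsv")
tissue <- read_beta_matrix("results/study_tissue_betas.tsv")
csf <- read_beta_matrix("results/csf_A_betas.tsv")
labels <- utils::read.csv("results/study_tissue_labels.csv")
meta <- utils::read.csv("results/csf_A_meta.csv")

t_mss <- compute_mss_matrix(tissue, panel)
c_mss <- compute_mss_matrix(csf, panel)
utils::write.table(t_mss, "results/tissue_mss.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(c_mss, "results/csf_A_mss.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

subtype <- setNames(labels$subtype, labels$sample_id)
med_t <- tapply(t_mss$mss, subtype[t_mss$sample_id], stats::median)
message(sprintf("-- tissue MSS medians: H3K27M %.3f | DW %.3f | IDH %.3f",
                med_t["H3K27M"], med_t["DW"], med_t["IDH"]))
med_c <- tapply(c_mss$mss, subtype[meta$patient_id], stats::median)
message(sprintf("-- CSF    MSS medians: H3K27M %.3f | DW %.3f | IDH %.3f",
                med_c["H3K27M"], med_c["DW"], med_c["IDH"]))

conc <- pearson_concordance(t_mss$mss, c_mss$mss)
message(sprintf("-- tissue/CSF MSS concordance: r = %.2f (p = %.3g, n = %d)",
                conc$r, conc$p, conc$n))

muts <- read_mutation_table("results/csf_A_mutations.tsv")
h3_calls <- muts[is_h3_driver_call(muts$gene, muts$variant), ]
paired <- merge(h3_calls[, c("sample_id", "vaf")], c_mss,
                by = "sample_id")
vaf_cor <- pearson_concordance(paired$vaf, paired$mss)
message(sprintf("-- CSF driver VAF vs MSS: r = %.2f (p = %.3g, n = %d)",
                vaf_cor$r, vaf_cor$p, vaf_cor$n))

blod <- meta$lod_flag == "BLOD"
h3 <- subtype[meta$patient_id] == "H3K27M"
message(sprintf("-- H3K27M CSF MSS by ctDNA mass: BLOD median %.4f vs ALOD median %.4f",
                stats::median(c_mss$mss[h3 & blod]),
                stats::median(c_mss$mss[h3 & !blod])))
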