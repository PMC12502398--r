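# Shared fixtures, built in code at test time.

# Small, fast cohort with the default (published-pattern) site means.
small_config <- function(n = 20, seed = 42, ...) {
  cohort_config(n_per_subtype = c(H3K27M = n, IDH = n, DW = n),
                n_noise_sites = 20, seed = seed, ...)
}

# Site means planting a uniform delta-beta of 0.5 between tumor classes and
# the rest (used for the screening-power and feature-recovery conditions).
planted_delta_means <- function() {
  m <- rbind(H3K27M = c(0.70, 0.20, 0.30),
             IDH    = c(0.20, 0.70, 0.30),
             DW     = c(0.20, 0.20, 0.30))
  colnames(m) <- c("H3_specific", "IDH_specific", "noise")
  m
}

# Ground-truth panel from the generator's planted site classes.
truth_panel_of <- function(cohort) {
  tp <- cohort$truth_panel[cohort$truth_panel$site_class != "noise", ]
  marker_panel(data.frame(cpg_id = tp$cpg_id, marker_class = tp$site_class,
                          stringsAsFactors = FALSE))
}

# Closed-form expectation of the MSS under the tumor-fraction mixture:
# E[beta_csf] = f * beta_tumor + (1 - f) * background_mean at every site.
expected_mss <- function(tumor_betas, panel, f, background_mean = 0.10) {
  h3 <- panel$cpg_id[panel$marker_class == "H3_specific"]
  idh <- panel$cpg_id[panel$marker_class == "IDH_specific"]
  e <- f * tumor_betas + (1 - f) * background_mean
  (sum(e[h3]) + (1 - sum(e[idh]))) / (length(h3) + length(idh))
}

# A CSF-trained classifier shared across tests (built once per run).
.fixture_cache <- new.env(parent = emptyenv())
get_csf_model <- function() {
  if (is.null(.fixture_cache$csf_model)) {
    coh <- generate_tissue_cohort(cohort_config(seed = 99))
    csf <- derive_csf_samples(coh, timepoint = "A")
    .fixture_cache$csf_model <-
      train_methylation_classifier(csf$betas, csf$labels, seed = 3)
  }
  .fixture_cache$csf_model
}
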