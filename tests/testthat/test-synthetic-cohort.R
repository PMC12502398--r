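test_that("an all-zero sample plan yields an empty cohort", {
  coh <- generate_tissue_cohort(small_config(n = 0))
  expect_equal(nrow(coh$betas), 0)
  expect_equal(length(coh$labels), 0)
  expect_equal(nrow(coh$mutations), 0)
  expect_error(derive_csf_samples(coh), "empty")
})

test_that("invalid configuration values are rejected by field name", {
  expect_error(small_config(missing_rate = 1.5), "missing_rate")
  expect_error(small_config(dispersion = -1), "dispersion")
  expect_error(cohort_config(n_per_subtype = c(H3K27M = -1, IDH = 1, DW = 1)),
               "n_per_subtype")
  m <- default_site_means(); m[1, 1] <- 2
  expect_error(small_config(subtype_site_means = m), "subtype_site_means")
})

test_that("configured site-class means are recovered empirically", {
  cfg <- cohort_config(n_per_subtype = c(H3K27M = 50, IDH = 0, DW = 0),
                       n_noise_sites = 0, seed = 7)
  coh <- generate_tissue_cohort(cfg)
  h3_cols <- coh$truth_panel$cpg_id[coh$truth_panel$site_class == "H3_specific"]
  expect_lt(abs(mean(coh$betas[, h3_cols]) - 0.80), 0.03)
  idh_cols <- coh$truth_panel$cpg_id[coh$truth_panel$site_class == "IDH_specific"]
  expect_lt(abs(mean(coh$betas[, idh_cols]) - 0.15), 0.03)
})

test_that("all generator operations are deterministic under a fixed seed", {
  cfg <- small_config(seed = 5)
  c1 <- generate_tissue_cohort(cfg)
  c2 <- generate_tissue_cohort(cfg)
  expect_identical(c1$betas, c2$betas)
  expect_identical(c1$mutations, c2$mutations)

  s1 <- derive_csf_samples(c1, timepoint = "B")
  s2 <- derive_csf_samples(c2, timepoint = "B")
  expect_identical(s1$betas, s2$betas)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$mutations, s2$mutations)

  sv1 <- generate_survival(c1, rep(0, 60))
  sv2 <- generate_survival(c2, rep(0, 60))
  expect_identical(sv1, sv2)

  panel <- truth_panel_of(c1)
  phases <- data.frame(day = c(0, 30, 90), timepoint = c("A", "C", "D"),
                       phase = c("pre-op", "post-op", "follow-up"),
                       f_multiplier = c(1, 0.2, 0.5))
  l1 <- generate_longitudinal(c1$betas[1, ], panel, phases, seed = 9)
  l2 <- generate_longitudinal(c1$betas[1, ], panel, phases, seed = 9)
  expect_identical(l1, l2)
})

test_that("CSF betas stay in [0,1] and missingness matches the configured rate", {
  cfg <- small_config(n = 40, missing_rate = 0.08, seed = 11)
  csf <- derive_csf_samples(generate_tissue_cohort(cfg), timepoint = "A")
  v <- csf$betas
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  n_cells <- length(v)
  rate <- mean(is.na(v))
  se <- sqrt(0.08 * 0.92 / n_cells)
  expect_lt(abs(rate - 0.08), 4 * se)
})

test_that("BLOD/ALOD gating is exactly the 5 ng threshold and BLOD samples carry no calls", {
  cfg <- small_config(n = 40, seed = 13)
  csf <- derive_csf_samples(generate_tissue_cohort(cfg), timepoint = "A")
  expect_identical(csf$meta$lod_flag, ifelse(csf$meta$dna_mass_ng < 5, "BLOD", "ALOD"))
  blod_ids <- csf$meta$sample_id[csf$meta$lod_flag == "BLOD"]
  expect_gt(length(blod_ids), 0)  # the mass law does produce BLOD samples
  expect_false(any(csf$mutations$sample_id %in% blod_ids))

  # forced masses pin the flags on both sides of the threshold
  forced <- derive_csf_samples(generate_tissue_cohort(cfg),
                               timepoint = "A",
                               dna_mass = rep(c(4.99, 5), length.out = 120))
  expect_identical(forced$meta$lod_flag, rep(c("BLOD", "ALOD"), length.out = 120))
})

test_that("driver-call detection rate matches the configured sensitivity", {
  cfg <- cohort_config(n_per_subtype = c(H3K27M = 200, IDH = 0, DW = 0),
                       mutation_detect_sens = 0.95, seed = 17)
  coh <- generate_tissue_cohort(cfg)
  csf <- derive_csf_samples(coh, timepoint = "A", dna_mass = 10)  # all ALOD
  fl <- driver_flags(csf$mutations, csf$meta$sample_id)
  rate <- mean(fl$h3_driver)
  expect_gte(rate, 0.91)  # binomial 99% band around 0.95 at n = 200
  expect_lte(rate, 0.98)
})

test_that("pure-tumor and zero-tumor limits of the CSF mixture", {
  cfg <- small_config(n = 5, missing_rate = 0, seed = 19)
  coh <- generate_tissue_cohort(cfg)
  csf <- derive_csf_samples(coh, timepoint = "A", tumor_fraction = 1)
  expect_equal(unname(csf$betas), unname(coh$betas))

  t <- coh$betas; b <- matrix(0.1, nrow(t), ncol(t))
  expect_equal(mix_csf_betas(t, 0, b), b, ignore_attr = TRUE)
  expect_equal(mix_csf_betas(t, 1, b), t)
})

test_that("MSS is strictly increasing in the tumor fraction", {
  coh <- generate_tissue_cohort(small_config(seed = 23))
  panel <- truth_panel_of(coh)
  tumor <- coh$betas[1, ]  # an H3K27M patient
  set.seed(1)
  bg <- runif(length(tumor), 0.05, 0.15)
  names(bg) <- names(tumor)
  mss_f <- vapply(seq(0.1, 0.9, by = 0.1), function(f) {
    compute_mss(mix_csf_betas(tumor, f, bg), panel)$value
  }, numeric(1))
  expect_true(all(diff(mss_f) > 0))
})

test_that("survival generation recovers the configured median and a null has no separation", {
  cfg <- cohort_config(n_per_subtype = c(H3K27M = 0, IDH = 0, DW = 500),
                       n_noise_sites = 0, seed = 29)
  coh <- generate_tissue_cohort(cfg)
  sv <- generate_survival(coh, rep(1, 500),
                          survival_config(base_median_months = 11 * 2.5^(1 / 1.2),
                                          beta_risk = log(2.5), horizon_months = 200,
                                          seed = 31))
  # linear predictor log(2.5) shrinks the configured base back to 11 months
  km <- km_median(sv$os_months, sv$event)
  expect_lt(abs(km$median - 11), 1.5)

  grp <- rep(c(0, 1), length.out = 500)  # arbitrary split, identical hazards
  sd <- survival::survdiff(survival::Surv(sv$os_months, sv$event) ~ grp)
  expect_gt(stats::pchisq(sd$chisq, 1, lower.tail = FALSE), 0.01)

  expect_error(survival_config(horizon_months = -1), "horizon")
})

test_that("longitudinal series follow the phase multipliers and detection floors", {
  coh <- generate_tissue_cohort(small_config(seed = 37))
  panel <- truth_panel_of(coh)
  tumor <- coh$betas[1, ]

  flat <- data.frame(day = c(0, 10, 20, 30), timepoint = "A", phase = "stable",
                     f_multiplier = 1)
  lf <- generate_longitudinal(tumor, panel, flat, f0 = 0.4, seed = 41)
  e <- expected_mss(tumor, panel, 0.4)
  expect_true(all(abs(lf$mss - e) < 0.05))

  traj <- data.frame(day = c(0, 30), timepoint = c("A", "C"),
                     phase = c("pre-op", "post-op"), f_multiplier = c(1, 0.1))
  lt <- generate_longitudinal(tumor, panel, traj, f0 = 0.4, seed = 43)
  expect_lt(abs(lt$mss[2] - expected_mss(tumor, panel, 0.04)), 0.05)

  # tumor fraction between the mutation floor and methylation visibility:
  # VAF undetectable while methylation signal persists (the MRD scenario)
  mrd <- data.frame(day = c(0, 60), timepoint = c("A", "D"),
                    phase = c("pre-op", "post-RT"), f_multiplier = c(1, 0.1))
  lm <- generate_longitudinal(tumor, panel, mrd, f0 = 0.4, mutation_floor = 0.1,
                              seed = 47)
  expect_true(is.na(lm$vaf[2]))
  bg_mss <- expected_mss(tumor, panel, 0)
  expect_gt(lm$mss[2], bg_mss)

  bad <- data.frame(day = c(0, 0), timepoint = "A", phase = "x", f_multiplier = 1)
  expect_error(generate_longitudinal(tumor, panel, bad), "strictly increasing")
})
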