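#' Configuration for the synthetic brainstem-glioma cohort generator
#'
#' Defines the statistical structure of a simulated cohort spanning the three
#' molecular subtypes (H3K27M-mutant, IDH-mutant, double-wildtype). Tissue
#' beta values are drawn from beta distributions parameterized by a
#' (subtype x site-class) mean and a shared concentration; CSF samples are a
#' tumor-fraction mixture of the tissue profile with a low-methylation
#' background, with DNA-mass-based detection-limit gating and probe dropout.
#'
#' Default site-class means encode the published pattern: H3K27M tumors are
#' hypermethylated at H3-specific sites and hypomethylated at IDH-specific
#' sites; IDH tumors are hypermethylated across the panel (strongest at
#' IDH-specific sites); double-wildtype tumors are hypomethylated at panel
#' sites. Noise sites share one mean across subtypes and carry no signal.
#'
#' @param n_per_subtype Named counts of samples per subtype,
#'   `c(H3K27M = , IDH = , DW = )`.
#' @param n_h3_sites,n_idh_sites,n_noise_sites Panel composition: numbers of
#'   planted H3-specific, IDH-specific and uninformative CpG sites.
#' @param subtype_site_means 3x3 numeric matrix of mean beta values, rows
#'   `H3K27M`/`IDH`/`DW`, columns `H3_specific`/`IDH_specific`/`noise`.
#' @param dispersion Concentration of the beta-value noise: draws are
#'   `Beta(mean * dispersion, (1 - mean) * dispersion)`.
#' @param background_mean Mean methylation of the CSF background profile that
#'   tumor signal is diluted into (low at all panel sites).
#' @param tumor_fraction_shape Two shape parameters of the Beta law for the
#'   CSF tumor fraction f.
#' @param dna_mass_meanlog,dna_mass_sdlog,dna_mass_f_coef Lognormal law for
#'   CSF DNA mass (ng): `meanlog = dna_mass_meanlog + dna_mass_f_coef * f`,
#'   coupling recoverable DNA mass to tumor content.
#' @param missing_rate Probability that a CSF probe is unobserved.
#' @param mutation_detect_sens Probability that a true mutation call is
#'   detected in an ALOD CSF sample.
#' @param h3f3a_fraction Fraction of H3K27M tumors driven by H3F3A (the rest
#'   carry HIST1H3B).
#' @param vaf_noise_sd Lognormal sd of the multiplicative noise on CSF VAFs.
#' @param seed Integer RNG seed; fixed seed gives byte-identical cohorts.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_subtype = c(H3K27M = 45, IDH = 45, DW = 45),
                          n_h3_sites = 40,
                          n_idh_sites = 36,
                          n_noise_sites = 40,
                          subtype_site_means = default_site_means(),
                          dispersion = 20,
                          background_mean = 0.10,
                          tumor_fraction_shape = c(2, 4),
                          dna_mass_meanlog = log(2.5),
                          dna_mass_sdlog = 0.35,
                          dna_mass_f_coef = 2.5,
                          missing_rate = 0.05,
                          mutation_detect_sens = 0.95,
                          h3f3a_fraction = 0.9,
                          vaf_noise_sd = 0.10,
                          seed = 1L) {
  if (is.null(names(n_per_subtype)) || !setequal(names(n_per_subtype), SUBTYPES)) {
    stop_field("n_per_subtype", "must be named with H3K27M, IDH, DW")
  }
  check_count(n_per_subtype, "n_per_subtype")
  check_count(n_h3_sites, "n_h3_sites")
  check_count(n_idh_sites, "n_idh_sites")
  check_count(n_noise_sites, "n_noise_sites")
  if (!is.matrix(subtype_site_means) ||
      !identical(rownames(subtype_site_means), SUBTYPES) ||
      !identical(colnames(subtype_site_means), c(MARKER_CLASSES, "noise"))) {
    stop_field("subtype_site_means",
               "must be a 3x3 matrix with rows H3K27M/IDH/DW and columns H3_specific/IDH_specific/noise")
  }
  check_unit_interval(subtype_site_means, "subtype_site_means")
  if (!is.numeric(dispersion) || !is.finite(dispersion) || dispersion <= 0) {
    stop_field("dispersion", "must be a positive number")
  }
  check_unit_interval(background_mean, "background_mean")
  if (length(tumor_fraction_shape) != 2 || any(tumor_fraction_shape <= 0)) {
    stop_field("tumor_fraction_shape", "must be two positive shape parameters")
  }
  if (!is.finite(dna_mass_meanlog) || !is.finite(dna_mass_sdlog) || dna_mass_sdlog < 0) {
    stop_field("dna_mass_sdlog", "mass law parameters must be finite, sdlog >= 0")
  }
  check_unit_interval(missing_rate, "missing_rate")
  check_unit_interval(mutation_detect_sens, "mutation_detect_sens")
  check_unit_interval(h3f3a_fraction, "h3f3a_fraction")
  if (!is.finite(vaf_noise_sd) || vaf_noise_sd < 0) {
    stop_field("vaf_noise_sd", "must be finite and >= 0")
  }
  if (length(seed) != 1 || !is.finite(seed)) stop_field("seed", "must be a single integer")
  structure(list(
    n_per_subtype = n_per_subtype[SUBTYPES],
    n_h3_sites = as.integer(n_h3_sites),
    n_idh_sites = as.integer(n_idh_sites),
    n_noise_sites = as.integer(n_noise_sites),
    subtype_site_means = subtype_site_means,
    dispersion = dispersion,
    background_mean = background_mean,
    tumor_fraction_shape = tumor_fraction_shape,
    dna_mass_meanlog = dna_mass_meanlog,
    dna_mass_sdlog = dna_mass_sdlog,
    dna_mass_f_coef = dna_mass_f_coef,
    missing_rate = missing_rate,
    mutation_detect_sens = mutation_detect_sens,
    h3f3a_fraction = h3f3a_fraction,
    vaf_noise_sd = vaf_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default subtype-by-site-class mean methylation
#'
#' @return 3x3 matrix of beta means (rows: subtypes, columns: site classes).
#' @export
default_site_means <- function() {
  m <- rbind(
    H3K27M = c(0.80, 0.15, 0.30),
    IDH    = c(0.50, 0.90, 0.30),
    DW     = c(0.12, 0.15, 0.30)
  )
  colnames(m) <- c(MARKER_CLASSES, "noise")
  m
}

rbeta_mean <- function(n, mean, concentration) {
  # Degenerate means would give a zero shape parameter; clamp just inside (0,1).
  mean <- pmin(pmax(mean, 1e-6), 1 - 1e-6)
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Generate a synthetic tissue cohort
#'
#' Draws per-site beta values from the configured beta laws, assigns subtype
#' labels, and plants driver (and frequent concurrent) mutation calls: every
#' H3K27M sample carries an H3F3A or HIST1H3B K27M call, every IDH sample an
#' IDH1 R132H call, double-wildtype samples carry neither.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list with elements `betas` (samples x CpGs),
#'   `labels` (named factor), `mutations` (mutation table), `truth_panel`
#'   (planted site classes) and `config`.
#' @export
generate_tissue_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  site_class <- rep(c(MARKER_CLASSES, "noise"),
                    times = c(config$n_h3_sites, config$n_idh_sites, config$n_noise_sites))
  cpg_ids <- sprintf("cg%07d", seq_along(site_class))
  n <- config$n_per_subtype
  labels <- factor(rep(SUBTYPES, times = n), levels = SUBTYPES)
  sample_ids <- sprintf("T%03d", seq_along(labels))
  names(labels) <- sample_ids

  betas <- matrix(NA_real_, length(labels), length(site_class),
                  dimnames = list(sample_ids, cpg_ids))
  for (st in SUBTYPES) {
    rows <- which(labels == st)
    if (length(rows) == 0) next
    for (cl in c(MARKER_CLASSES, "noise")) {
      cols <- which(site_class == cl)
      if (length(cols) == 0) next
      betas[rows, cols] <- rbeta_mean(length(rows) * length(cols),
                                      config$subtype_site_means[st, cl],
                                      config$dispersion)
    }
  }

  mutations <- generate_tissue_mutations(labels, config)
  truth_panel <- data.frame(cpg_id = cpg_ids, site_class = site_class,
                            stringsAsFactors = FALSE)
  structure(list(betas = betas, labels = labels, mutations = mutations,
                 truth_panel = truth_panel, config = config),
            class = "synthetic_cohort")
}

# Driver + frequent concurrent calls; concurrent-gene rates follow the
# mutation landscape reported for this disease (TP53 ~0.76 and ATRX ~0.52 in
# H3K27M tumors, TERT restricted to double-wildtype).
generate_tissue_mutations <- function(labels, config) {
  rows <- list()
  for (i in seq_along(labels)) {
    sid <- names(labels)[i]
    st <- as.character(labels[i])
    calls <- NULL
    if (st == "H3K27M") {
      gene <- if (stats::runif(1) < config$h3f3a_fraction) "H3F3A" else "HIST1H3B"
      calls <- data.frame(sample_id = sid, gene = gene, variant = "K27M",
                          vaf = stats::rbeta(1, 8, 12), stringsAsFactors = FALSE)
      if (stats::runif(1) < 0.76) {
        calls <- rbind(calls, data.frame(sample_id = sid, gene = "TP53",
                                         variant = "missense", vaf = stats::rbeta(1, 8, 12)))
      }
      if (stats::runif(1) < 0.52) {
        calls <- rbind(calls, data.frame(sample_id = sid, gene = "ATRX",
                                         variant = "truncating", vaf = stats::rbeta(1, 8, 12)))
      }
    } else if (st == "IDH") {
      calls <- data.frame(sample_id = sid, gene = "IDH1", variant = "R132H",
                          vaf = stats::rbeta(1, 8, 12), stringsAsFactors = FALSE)
      if (stats::runif(1) < 0.6) {
        calls <- rbind(calls, data.frame(sample_id = sid, gene = "TP53",
                                         variant = "missense", vaf = stats::rbeta(1, 8, 12)))
      }
    } else {
      if (stats::runif(1) < 0.25) {
        calls <- data.frame(sample_id = sid, gene = "TERT", variant = "promoter",
                            vaf = stats::rbeta(1, 8, 12), stringsAsFactors = FALSE)
      }
    }
    if (!is.null(calls)) rows[[length(rows) + 1]] <- calls
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(), gene = character(),
               variant = character(), vaf = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Mix tumor methylation into a CSF background
#'
#' The CSF beta value at each site is the convex combination
#' `f * beta_tumor + (1 - f) * beta_background` with tumor fraction `f`.
#'
#' @param tumor_betas Numeric matrix (samples x CpGs) or vector of tumor
#'   beta values.
#' @param f Tumor fraction in \[0, 1\]; scalar or one value per sample (row).
#' @param background_betas Background draws with the same shape as
#'   `tumor_betas`.
#' @return Mixed beta values, same shape as the inputs.
#' @export
mix_csf_betas <- function(tumor_betas, f, background_betas) {
  check_unit_interval(f, "f")
  if (is.matrix(tumor_betas)) {
    stopifnot(identical(dim(tumor_betas), dim(background_betas)))
    if (length(f) == 1) f <- rep(f, nrow(tumor_betas))
    stopifnot(length(f) == nrow(tumor_betas))
    tumor_betas * f + background_betas * (1 - f)
  } else {
    stopifnot(length(tumor_betas) == length(background_betas), length(f) == 1)
    tumor_betas * f + background_betas * (1 - f)
  }
}

#' Derive CSF samples from a tissue cohort
#'
#' For each patient, draws a tumor fraction and a DNA mass, mixes the tumor
#' methylation profile with a low-methylation background, masks probes as
#' missing, gates the sample BLOD/ALOD at the 5 ng mass threshold, and -- for
#' ALOD samples only -- emits each true mutation call with the configured
#' detection sensitivity and a VAF of `f / 2` (heterozygous driver) times
#' multiplicative noise. BLOD samples never carry mutation calls.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config The [cohort_config()] governing the CSF laws (usually
#'   `cohort$config`).
#' @param timepoint Collection timepoint, one of `"A"` (pre-op), `"B"`
#'   (intra-op), `"C"` (post-op), `"D"` (follow-up).
#' @param tumor_fraction Optional override: scalar or per-patient tumor
#'   fractions instead of draws from the configured law.
#' @param dna_mass Optional override for the DNA mass (ng).
#' @return A `csf_cohort` list: `betas` (CSF beta matrix, `NA` = missing),
#'   `meta` (sample_id, patient_id, timepoint, tumor_fraction, dna_mass_ng,
#'   lod_flag), `mutations` (detected calls, ALOD samples only), `labels`
#'   (true subtype per CSF sample).
#' @export
derive_csf_samples <- function(cohort, config = cohort$config, timepoint = "A",
                               tumor_fraction = NULL, dna_mass = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tp <- match(timepoint, c("A", "B", "C", "D"))
  if (length(timepoint) != 1 || is.na(tp)) {
    stop("unknown timepoint '", paste(timepoint, collapse = ","),
         "'; must be one of A, B, C, D")
  }
  n <- nrow(cohort$betas)
  if (n == 0) stop("cohort is empty")
  p <- ncol(cohort$betas)
  set.seed(config$seed + 1000L * tp)

  background <- matrix(rbeta_mean(n * p, config$background_mean, config$dispersion), n, p)
  f <- tumor_fraction %||%
    stats::rbeta(n, config$tumor_fraction_shape[1], config$tumor_fraction_shape[2])
  if (length(f) == 1) f <- rep(f, n)
  check_unit_interval(f, "tumor_fraction")

  betas <- mix_csf_betas(cohort$betas, f, background)
  if (config$missing_rate > 0) {
    betas[matrix(stats::runif(n * p) < config$missing_rate, n, p)] <- NA_real_
  }
  mass <- dna_mass %||%
    stats::rlnorm(n, meanlog = config$dna_mass_meanlog + config$dna_mass_f_coef * f,
                  sdlog = config$dna_mass_sdlog)
  if (length(mass) == 1) mass <- rep(mass, n)
  lod <- ifelse(mass < BLOD_THRESHOLD_NG, "BLOD", "ALOD")

  patient_ids <- rownames(cohort$betas)
  sample_ids <- paste0(patient_ids, "_", timepoint)
  dimnames(betas) <- list(sample_ids, colnames(cohort$betas))

  mut_rows <- list()
  for (i in seq_len(n)) {
    if (lod[i] != "ALOD") next
    true_calls <- cohort$mutations[cohort$mutations$sample_id == patient_ids[i], , drop = FALSE]
    if (nrow(true_calls) == 0) next
    detected <- stats::runif(nrow(true_calls)) < config$mutation_detect_sens
    if (!any(detected)) next
    calls <- true_calls[detected, , drop = FALSE]
    noise <- exp(stats::rnorm(nrow(calls), 0, config$vaf_noise_sd))
    calls$vaf <- pmin(1, f[i] / 2 * noise)
    calls$sample_id <- sample_ids[i]
    mut_rows[[length(mut_rows) + 1]] <- calls
  }
  mutations <- if (length(mut_rows) > 0) do.call(rbind, mut_rows) else
    data.frame(sample_id = character(), gene = character(),
               variant = character(), vaf = numeric(), stringsAsFactors = FALSE)
  rownames(mutations) <- NULL
  class(mutations) <- c("mutation_table", "data.frame")

  labels <- cohort$labels
  names(labels) <- sample_ids
  structure(list(
    betas = betas,
    meta = data.frame(sample_id = sample_ids, patient_id = patient_ids,
                      timepoint = timepoint, tumor_fraction = f,
                      dna_mass_ng = mass, lod_flag = lod,
                      stringsAsFactors = FALSE),
    mutations = mutations,
    labels = labels
  ), class = "csf_cohort")
}

#' Configuration for synthetic overall-survival generation
#'
#' Event times follow a Weibull proportional-hazards law whose scale shrinks
#' with the latent risk and with H3K27M status, with administrative censoring
#' at a fixed horizon.
#'
#' @param base_median_months Median OS (months) for a patient with linear
#'   predictor zero.
#' @param shape Weibull shape parameter.
#' @param beta_risk Log hazard ratio per unit of latent risk.
#' @param beta_h3 Additional log hazard ratio for H3K27M status.
#' @param horizon_months Administrative censoring horizon (> 0).
#' @param seed RNG seed.
#' @return A `survival_sim_config` list.
#' @export
survival_config <- function(base_median_months = 36, shape = 1.2,
                            beta_risk = log(2.5), beta_h3 = log(3),
                            horizon_months = 60, seed = 7L) {
  if (!is.finite(horizon_months) || horizon_months <= 0) {
    stop_field("horizon_months", "must be a positive number of months")
  }
  if (!is.finite(base_median_months) || base_median_months <= 0) {
    stop_field("base_median_months", "must be positive")
  }
  if (!is.finite(shape) || shape <= 0) stop_field("shape", "must be positive")
  structure(list(base_median_months = base_median_months, shape = shape,
                 beta_risk = beta_risk, beta_h3 = beta_h3,
                 horizon_months = horizon_months, seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Generate an overall-survival table for a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @param latent_risk Per-patient risk value aligned with the cohort rows
#'   (higher = worse prognosis); enters the hazard on the log scale through
#'   `beta_risk`.
#' @param config A [survival_config()].
#' @return A `data.frame` with `patient_id`, `os_months` (> 0), `event`
#'   (1 = death), `latent_risk`, `subtype`, `h3_status`.
#' @export
generate_survival <- function(cohort, latent_risk, config = survival_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(config, "survival_sim_config"))
  n <- nrow(cohort$betas)
  if (length(latent_risk) != n) {
    stop("latent_risk must have one value per patient (", n, ")")
  }
  set.seed(config$seed)
  k <- config$shape
  scale0 <- config$base_median_months / log(2)^(1 / k)
  lp <- config$beta_risk * latent_risk +
    config$beta_h3 * (cohort$labels == "H3K27M")
  t_event <- scale0 * (-log(stats::runif(n)))^(1 / k) * exp(-lp / k)
  t_event <- pmax(t_event, 0.01)  # os_months strictly positive
  event <- as.integer(t_event <= config$horizon_months)
  os <- pmin(t_event, config$horizon_months)
  data.frame(patient_id = rownames(cohort$betas), os_months = os,
             event = event, latent_risk = latent_risk,
             subtype = as.character(cohort$labels),
             h3_status = as.integer(cohort$labels == "H3K27M"),
             stringsAsFactors = FALSE)
}

#' Generate a longitudinal CSF monitoring series for one patient
#'
#' Tumor fraction follows per-phase multipliers of a baseline fraction
#' (resection and radiotherapy shrink it, progression raises it). At each
#' point the methylation signature score is computed from a fresh
#' background mixture, while the mutation VAF is set to the undetectable
#' sentinel (`NA`) whenever the tumor fraction falls below the mutation
#' detection floor -- the methylation signal has no such floor, so it can
#' persist when the VAF cannot, which is the minimal-residual-disease
#' scenario this generator is built to emulate.
#'
#' @param patient_betas Named numeric vector of the patient's tumor beta
#'   values (names = CpG ids covering the panel).
#' @param panel A [marker_panel()] used to score each point.
#' @param phases `data.frame` with columns `day` (strictly increasing),
#'   `timepoint` (A-D), `phase` (free-text annotation), `f_multiplier`
#'   (>= 0 multiplier on the baseline tumor fraction).
#' @param f0 Baseline (pre-treatment) tumor fraction.
#' @param mutation_floor Tumor fraction below which mutation calls drop out
#'   (VAF becomes the undetectable sentinel).
#' @param background_mean,dispersion Background mixture law, as in
#'   [cohort_config()].
#' @param vaf_noise_sd Lognormal sd of VAF noise (0 = noiseless `f / 2`).
#' @param seed RNG seed.
#' @return A `data.frame` of class `longitudinal_series`: `day`, `timepoint`,
#'   `phase`, `tumor_fraction`, `mss`, `coverage`, `qc_pass`, `vaf` (`NA` =
#'   undetectable).
#' @export
generate_longitudinal <- function(patient_betas, panel, phases,
                                  f0 = 0.4, mutation_floor = 0.02,
                                  background_mean = 0.10, dispersion = 20,
                                  vaf_noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(phases),
            all(c("day", "timepoint", "phase", "f_multiplier") %in% colnames(phases)))
  if (any(diff(phases$day) <= 0)) {
    stop("phase days must be strictly increasing")
  }
  if (any(phases$f_multiplier < 0)) stop("f_multiplier must be >= 0")
  check_unit_interval(f0, "f0")
  set.seed(seed)
  pts <- lapply(seq_len(nrow(phases)), function(i) {
    f <- min(1, f0 * phases$f_multiplier[i])
    bg <- rbeta_mean(length(patient_betas), background_mean, dispersion)
    names(bg) <- names(patient_betas)
    mixed <- mix_csf_betas(patient_betas, f, bg)
    mss <- compute_mss(mixed, panel)
    vaf <- if (f < mutation_floor) NA_real_ else {
      min(1, f / 2 * exp(stats::rnorm(1, 0, vaf_noise_sd)))
    }
    data.frame(day = phases$day[i], timepoint = phases$timepoint[i],
               phase = phases$phase[i], tumor_fraction = f,
               mss = mss$value, coverage = mss$coverage,
               qc_pass = mss$qc_pass, vaf = vaf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pts)
  class(out) <- c("longitudinal_series", "data.frame")
  out
}
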