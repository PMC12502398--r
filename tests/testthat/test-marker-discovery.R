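test_that("discovery split is stratified, exact at round fractions, and seeded", {
  labels <- factor(rep(c("H3K27M", "IDH", "DW"), each = 100))
  names(labels) <- sprintf("S%03d", seq_along(labels))

  all_in <- split_discovery(labels, frac = 1)
  expect_equal(length(all_in$discovery), 300)
  expect_equal(length(all_in$test), 0)

  sp <- split_discovery(labels, frac = 0.7, seed = 2)
  per_class <- table(labels[sp$discovery])
  expect_true(all(per_class == 70))
  expect_equal(sort(c(sp$discovery, sp$test)), sort(names(labels)))

  expect_identical(sp, split_discovery(labels, frac = 0.7, seed = 2))
  expect_false(identical(sp, split_discovery(labels, frac = 0.7, seed = 3)))

  empty <- factor(rep("H3K27M", 10), levels = c("H3K27M", "IDH"))
  expect_error(split_discovery(empty), "IDH")
})

test_that("null data yield no screened sites; planted sites are recovered with power", {
  set.seed(101)
  null_betas <- matrix(rbeta(40 * 200, 10, 10), 40, 200,
                       dimnames = list(NULL, sprintf("cg%07d", 1:200)))
  labels <- rep(c("A", "B"), each = 20)
  expect_equal(nrow(find_dm_cpgs(null_betas, labels, c("A", "B"))), 0)

  cfg <- cohort_config(n_per_subtype = c(H3K27M = 30, IDH = 30, DW = 0),
                       subtype_site_means = planted_delta_means(),
                       n_noise_sites = 60, seed = 103)
  coh <- generate_tissue_cohort(cfg)
  dm <- find_dm_cpgs(coh$betas, coh$labels, c("H3K27M", "IDH"), delta_min = 0.3)
  planted <- coh$truth_panel$cpg_id[coh$truth_panel$site_class != "noise"]
  expect_gte(mean(planted %in% dm$cpg_id), 0.95)
  expect_false(any(dm$cpg_id %in%
                     coh$truth_panel$cpg_id[coh$truth_panel$site_class == "noise"]))
  # sorted by effect size
  expect_true(all(diff(abs(dm$delta_beta)) <= 1e-12))
})

test_that("the delta-beta cutoff excludes sites below threshold regardless of p", {
  set.seed(7)
  n <- 30
  # one site at delta 0.28 (clearly separated, p tiny), one at delta 0.50
  betas <- cbind(
    cg_border = c(rnorm(n, 0.60, 0.005), rnorm(n, 0.32, 0.005)),
    cg_strong = c(rnorm(n, 0.75, 0.005), rnorm(n, 0.25, 0.005))
  )
  betas <- pmin(pmax(betas, 0), 1)
  labels <- rep(c("A", "B"), each = n)
  dm <- find_dm_cpgs(betas, labels, c("A", "B"), delta_min = 0.3)
  expect_false("cg_border" %in% dm$cpg_id)
  expect_true("cg_strong" %in% dm$cpg_id)
})

test_that("screening is symmetric up to the sign of delta-beta", {
  cfg <- cohort_config(n_per_subtype = c(H3K27M = 15, IDH = 15, DW = 0),
                       subtype_site_means = planted_delta_means(),
                       n_noise_sites = 10, seed = 107)
  coh <- generate_tissue_cohort(cfg)
  ab <- find_dm_cpgs(coh$betas, coh$labels, c("H3K27M", "IDH"))
  ba <- find_dm_cpgs(coh$betas, coh$labels, c("IDH", "H3K27M"))
  expect_equal(ab$cpg_id, ba$cpg_id)
  expect_equal(ab$delta_beta, -ba$delta_beta)
  expect_equal(ab$q_value, ba$q_value)
})

test_that("sites unobserved in one group are excluded, not fatal", {
  set.seed(5)
  betas <- matrix(rbeta(20 * 4, 5, 5), 20, 4,
                  dimnames = list(NULL, paste0("cg", 1:4)))
  labels <- rep(c("A", "B"), each = 10)
  betas[labels == "A", "cg2"] <- NA
  expect_message(dm <- find_dm_cpgs(betas, labels, c("A", "B")), "excluding 1")
  expect_false("cg2" %in% dm$cpg_id)
})

test_that("consensus selection recovers planted features and is order-invariant", {
  cfg <- cohort_config(n_per_subtype = c(H3K27M = 30, IDH = 30, DW = 30),
                       n_h3_sites = 5, n_idh_sites = 5, n_noise_sites = 40,
                       subtype_site_means = planted_delta_means(), seed = 109)
  coh <- generate_tissue_cohort(cfg)
  planted <- coh$truth_panel$cpg_id[coh$truth_panel$site_class != "noise"]
  cands <- colnames(coh$betas)

  sel <- select_consensus_features(coh$betas, coh$labels, cands, k = 10, seed = 1)
  expect_setequal(sel, planted)

  shuffled <- select_consensus_features(coh$betas, coh$labels,
                                        sample(cands), k = 10, seed = 1)
  expect_setequal(shuffled, sel)

  all_of_them <- select_consensus_features(coh$betas, coh$labels, cands,
                                           k = length(cands), seed = 1)
  expect_setequal(all_of_them, cands)

  expect_error(select_consensus_features(coh$betas, coh$labels, cands, k = 0),
               "positive")
})

test_that("marker classes follow the hyper/hypo pattern rules", {
  # constructed group patterns with tiny within-group noise
  set.seed(11)
  mk <- function(m_h3, m_idh, m_dw) {
    c(rnorm(10, m_h3, 0.01), rnorm(10, m_idh, 0.01), rnorm(10, m_dw, 0.01))
  }
  betas <- cbind(cg_h3 = mk(0.85, 0.15, 0.10),
                 cg_idh = mk(0.10, 0.90, 0.12),
                 cg_flat = mk(0.30, 0.30, 0.30))
  betas <- pmin(pmax(betas, 0), 1)
  labels <- rep(c("H3K27M", "IDH", "DW"), each = 10)
  expect_message(panel <- assign_marker_classes(betas, labels, colnames(betas),
                                                margin = 0.2),
                 "dropping 1")
  expect_equal(panel$marker_class[panel$cpg_id == "cg_h3"], "H3_specific")
  expect_equal(panel$marker_class[panel$cpg_id == "cg_idh"], "IDH_specific")
  expect_false("cg_flat" %in% panel$cpg_id)

  expect_error(assign_marker_classes(betas[1:20, ], labels[1:20],
                                     colnames(betas)),
               "non-H3K27M, non-IDH")
  # a set with no qualifying IDH-specific site cannot form a panel
  expect_error(suppressMessages(
    assign_marker_classes(betas, labels, c("cg_h3", "cg_flat"))),
    "undefined")
})

test_that("the planted H3/IDH site partition is recovered exactly", {
  coh <- generate_tissue_cohort(cohort_config(seed = 113))
  dm_sites <- coh$truth_panel$cpg_id  # classify every site; noise must drop out
  panel <- suppressMessages(
    assign_marker_classes(coh$betas, coh$labels, dm_sites, margin = 0.2))
  truth <- coh$truth_panel[coh$truth_panel$site_class != "noise", ]
  expect_equal(nrow(panel), nrow(truth))
  expect_identical(
    panel$marker_class[match(truth$cpg_id, panel$cpg_id)],
    truth$site_class)
})

test_that("panel construction validates classes and wet-lab subsetting preserves both", {
  entries <- data.frame(cpg_id = paste0("cg", 1:6),
                        marker_class = rep(c("H3_specific", "IDH_specific"), 3))
  p <- marker_panel(entries)
  expect_equal(unname(panel_sizes(p)), c(3, 3))
  expect_error(marker_panel(entries[entries$marker_class == "H3_specific", ]),
               "undefined")

  sub <- subset_panel(p, 3, seed = 5)
  expect_equal(nrow(sub), 3)
  expect_true(all(c("H3_specific", "IDH_specific") %in% sub$marker_class))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_panel(p, path)
  expect_equal(read_marker_panel(path)$cpg_id, p$cpg_id)
})
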