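calls_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[1], variant = r[2], vaf = as.numeric(r[3]),
               stringsAsFactors = FALSE)
  }))
}

test_that("the mutation rule maps driver calls to deterministic probabilities", {
  expect_equal(unname(mutation_probs(calls_df(c("IDH1", "R132H", 0.2)))),
               c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(unname(mutation_probs(calls_df(c("H3F3A", "K27M", 0.475)))),
               c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(unname(mutation_probs(calls_df(c("HIST1H3C", "K27M", 0.1)))),
               c(1, 0, 0), ignore_attr = TRUE)
  # concurrent genes alone are never positive evidence for a subtype
  expect_equal(unname(mutation_probs(calls_df(c("TP53", "missense", 0.3),
                                              c("ATRX", "truncating", 0.2)))),
               c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(unname(mutation_probs(NULL)), c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(unname(mutation_probs(calls_df(c("H3F3A", "G34R", 0.3)))),
               c(0, 0, 0), ignore_attr = TRUE)  # non-K27M histone variant is not this driver

  both <- mutation_probs(calls_df(c("H3F3A", "K27M", 0.3), c("IDH2", "R172K", 0.2)))
  expect_equal(unname(both), c(1, 1, 0), ignore_attr = TRUE)
  expect_true(attr(both, "conflict"))
})

test_that("fusion takes the per-class maximum and applies the tie-break priority", {
  mut0 <- c(H3K27M = 0, IDH = 0, DW = 0)

  d <- fuse_bsgdiag(mut0, c(H3K27M = 0.778, IDH = 0.111, DW = 0.111))
  expect_equal(d$predicted_class, "H3K27M")
  expect_equal(unname(d$combined_probs["H3K27M"]), 0.778)
  expect_equal(d$mrs, 0.778)
  expect_equal(d$evidence, "fused")

  # a detected driver forces the call no matter what methylation says
  d2 <- fuse_bsgdiag(c(H3K27M = 1, IDH = 0, DW = 0),
                     c(H3K27M = 0.01, IDH = 0.01, DW = 0.98))
  expect_equal(d2$predicted_class, "H3K27M")
  expect_equal(unname(d2$combined_probs["H3K27M"]), 1)

  tie <- fuse_bsgdiag(mut0, c(H3K27M = 1, IDH = 1, DW = 1) / 3)
  expect_equal(tie$predicted_class, "H3K27M")

  blod <- fuse_bsgdiag(NULL, c(H3K27M = 0.2, IDH = 0.3, DW = 0.5))
  expect_equal(blod$evidence, "methylation_only")
  expect_equal(blod$predicted_class, "DW")

  mut_only <- fuse_bsgdiag(c(H3K27M = 0, IDH = 1, DW = 0), NULL)
  expect_equal(mut_only$evidence, "mutation_only")
  expect_equal(mut_only$predicted_class, "IDH")

  expect_error(fuse_bsgdiag(mut0, c(H3K27M = 0.5, IDH = 0.2, DW = 0.2)),
               "sum to 1")
  expect_error(fuse_bsgdiag(NULL, NULL), "evidence")
})

test_that("fusion never lowers per-class evidence and drivers dominate", {
  set.seed(7)
  for (i in 1:100) {
    meth <- runif(3)
    meth <- meth / sum(meth)
    names(meth) <- c("H3K27M", "IDH", "DW")
    driver <- sample(c("none", "H3K27M", "IDH"), 1)
    mut <- c(H3K27M = 0, IDH = 0, DW = 0)
    if (driver != "none") mut[driver] <- 1
    d <- fuse_bsgdiag(mut, meth)
    expect_true(all(d$combined_probs >= meth - 1e-12))
    expect_true(all(d$combined_probs >= mut - 1e-12))
    if (driver != "none") expect_equal(d$predicted_class, driver)
  }
})

test_that("the methylation classifier separates the subtypes on held-out data", {
  cfg <- small_config(n = 30, seed = 211)
  coh <- generate_tissue_cohort(cfg)
  sp <- split_discovery(coh$labels, frac = 0.7, seed = 2)
  expect_warning(
    model <- train_methylation_classifier(coh$betas[sp$discovery, ],
                                          coh$labels[sp$discovery],
                                          n_folds = 10, seed = 5),
    regexp = NA)  # 21 per class supports 10 folds without reduction
  probs <- predict_methylation_probs(model, coh$betas[sp$test, ])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
  rep_auc <- multiclass_auc(probs, coh$labels[sp$test])
  expect_gte(rep_auc$micro_auc, 0.95)
  # on this cleanly separated cohort the argmax recovers the true label
  pred <- colnames(probs)[max.col(probs)]
  expect_gte(mean(pred == as.character(coh$labels[sp$test])), 0.9)
})

test_that("training is deterministic under a seed and validates inputs", {
  cfg <- small_config(n = 12, seed = 223)
  coh <- generate_tissue_cohort(cfg)
  m1 <- suppressWarnings(train_methylation_classifier(coh$betas, coh$labels, seed = 9))
  m2 <- suppressWarnings(train_methylation_classifier(coh$betas, coh$labels, seed = 9))
  expect_identical(m1$cv_report, m2$cv_report)
  p1 <- predict_methylation_probs(m1, coh$betas)
  p2 <- predict_methylation_probs(m2, coh$betas)
  expect_identical(p1, p2)

  one_class <- coh$betas[coh$labels == "IDH", ]
  expect_error(train_methylation_classifier(one_class,
                                            rep("IDH", nrow(one_class))),
               "at least two classes")
})

test_that("prediction imputes missing probes but rejects empty samples", {
  cfg <- small_config(n = 15, seed = 227)
  coh <- generate_tissue_cohort(cfg)
  model <- suppressWarnings(
    train_methylation_classifier(coh$betas, coh$labels, n_folds = 5, seed = 1))
  s <- coh$betas[1, ]
  s[1:30] <- NA
  probs <- predict_methylation_probs(model, s)
  expect_equal(sum(probs), 1, tolerance = 1e-9)

  s[] <- NA
  expect_error(predict_methylation_probs(model, s), "all panel probes missing")
})

test_that("cohort-level classification fuses per-sample mutation and methylation", {
  cfg <- small_config(n = 15, seed = 229, mutation_detect_sens = 1,
                      missing_rate = 0)
  coh <- generate_tissue_cohort(cfg)
  model <- suppressWarnings(
    train_methylation_classifier(coh$betas, coh$labels, n_folds = 5, seed = 1))
  res <- classify_samples(model, coh$betas, coh$mutations)
  expect_equal(nrow(res), nrow(coh$betas))
  # tissue with perfect mutation detection: every driver-positive sample is
  # called by its driver with certainty
  h3 <- res$sample_id %in% coh$mutations$sample_id[coh$mutations$gene %in%
                                                     c("H3F3A", "HIST1H3B")]
  expect_true(all(res$p_h3_combined[h3] == 1))
  expect_true(all(res$predicted_class[h3] == "H3K27M"))
  expect_true(all(res$evidence == "fused"))

  # untested samples fall back to methylation alone
  res2 <- classify_samples(model, coh$betas, coh$mutations,
                           tested = rep(FALSE, nrow(coh$betas)))
  expect_true(all(res2$evidence == "methylation_only"))
})
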