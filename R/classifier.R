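#' Train the three-class methylation classifier
#'
#' Fits a random forest on panel-restricted beta values to separate the
#' H3K27M-mutant, IDH-mutant and double-wildtype subtypes. Hyperparameters
#' are chosen from a small grid by stratified cross-validation (default ten
#' folds, reduced with a warning when a class is smaller than the fold
#' count), scored by pooled micro-AUC; the final forest is refit on all
#' training data. Missing beta values are imputed with class-agnostic
#' training medians, which are stored on the model and reused at predict
#' time so no label information leaks through imputation.
#'
#' @param betas Training beta matrix restricted to the marker panel.
#' @param labels Subtype labels aligned with rows.
#' @param n_folds Number of CV folds (default 10).
#' @param seed RNG seed; fixing it makes the CV report and the fitted forest
#'   reproducible.
#' @param ntree Trees per forest (default 500).
#' @param grid Optional `data.frame` of hyperparameters with columns `mtry`
#'   and `nodesize`; defaults to `sqrt(p)` and `p/3` features per split.
#' @return A `methylation_classifier` with elements `forest`, `cpgs`,
#'   `medians`, `classes`, `chosen` (winning grid row), `cv_report`
#'   (per-fold, per-class one-vs-rest AUC plus micro-AUC for the winning
#'   parameters), `n_folds`, `seed`.
#' @importFrom randomForest randomForest
#' @export
train_methylation_classifier <- function(betas, labels, n_folds = 10, seed = 1L,
                                         ntree = 500, grid = NULL) {
  x <- as.matrix(betas)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) {
    stop("training requires at least two classes; got only: ",
         paste(levels(y), collapse = ", "))
  }
  if (nrow(x) != length(y)) stop("betas and labels are not aligned")

  medians <- apply(x, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(medians))) stop("some panel columns have no observed values")
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[j]
  }

  min_class <- min(table(y))
  if (n_folds > min_class) {
    warning("reducing folds from ", n_folds, " to ", min_class,
            " (smallest class size)")
    n_folds <- min_class
  }
  p <- ncol(x)
  grid <- grid %||% data.frame(
    mtry = unique(pmax(1, c(floor(sqrt(p)), floor(p / 3)))),
    nodesize = 1
  )

  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep(seq_len(n_folds), length.out = length(i)))
  }

  cv_probs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    probs <- matrix(NA_real_, length(y), nlevels(y),
                    dimnames = list(NULL, levels(y)))
    for (kf in seq_len(n_folds)) {
      tr <- fold != kf
      rf <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                       ntree = ntree, mtry = grid$mtry[g],
                                       nodesize = grid$nodesize[g])
      probs[!tr, ] <- stats::predict(rf, x[!tr, , drop = FALSE], type = "prob")
    }
    cv_probs[[g]] <- probs
  }
  micro <- vapply(cv_probs, function(pr) multiclass_auc(pr, y)$micro_auc, numeric(1))
  best <- which.max(micro)

  cv_report <- do.call(rbind, lapply(seq_len(n_folds), function(kf) {
    held <- fold == kf
    aucs <- vapply(levels(y), function(cl) {
      truth <- y[held] == cl
      if (length(unique(truth)) < 2) return(NA_real_)
      roc_auc(cv_probs[[best]][held, cl], truth)
    }, numeric(1))
    data.frame(fold = kf, t(aucs), check.names = FALSE)
  }))
  cv_report$micro_auc_overall <- micro[best]

  set.seed(seed + 1L)
  forest <- randomForest::randomForest(x, y, ntree = ntree,
                                       mtry = grid$mtry[best],
                                       nodesize = grid$nodesize[best])
  structure(list(forest = forest, cpgs = colnames(x), medians = medians,
                 classes = levels(y), chosen = grid[best, , drop = FALSE],
                 cv_report = cv_report, cv_micro_auc = micro[best],
                 n_folds = n_folds, seed = seed),
            class = "methylation_classifier")
}

#' Predict subtype probabilities from methylation
#'
#' Returns the forest's vote fractions as a probability triple over
#' \{H3K27M, IDH, DW\}; the Methylation Risk Score (MRS) is the H3K27M
#' component. Probes missing from a sample are imputed with the training-set
#' medians stored on the model; a sample with every panel probe missing is
#' an error.
#'
#' @param model A `methylation_classifier`.
#' @param sample_betas Named numeric vector (one sample) or beta matrix.
#' @return A matrix (samples x classes) of probabilities summing to 1 per
#'   row, with the MRS available via [mrs()].
#' @export
predict_methylation_probs <- function(model, sample_betas) {
  stopifnot(inherits(model, "methylation_classifier"))
  x <- if (is.matrix(sample_betas)) sample_betas else
    matrix(sample_betas, nrow = 1, dimnames = list("sample", names(sample_betas)))
  missing_cols <- setdiff(model$cpgs, colnames(x))
  if (length(missing_cols) > 0) {
    x <- cbind(x, matrix(NA_real_, nrow(x), length(missing_cols),
                         dimnames = list(NULL, missing_cols)))
  }
  x <- x[, model$cpgs, drop = FALSE]
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop("sample(s) with all panel probes missing: ",
         paste(rownames(x)[all_missing], collapse = ", "))
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- model$medians[j]
  }
  probs <- stats::predict(model$forest, x, type = "prob")
  probs <- probs / rowSums(probs)
  probs
}

#' Methylation Risk Score
#'
#' The methylation model's predicted probability of the H3K27M class.
#'
#' @param probs Probability matrix from [predict_methylation_probs()].
#' @return Numeric vector of MRS values in \[0, 1\].
#' @export
mrs <- function(probs) {
  if (!"H3K27M" %in% colnames(probs)) stop("no H3K27M probability column")
  probs[, "H3K27M"]
}

#' Mutation-predicted subtype probabilities
#'
#' Implements the deterministic driver rule: a K27M call in H3F3A or
#' HIST1H3B/C sets the H3K27M probability to 1; any IDH1/IDH2 call sets the
#' IDH probability to 1; the double-wildtype probability is always 0 (absence
#' of drivers is never positive evidence). Unknown genes are ignored. When
#' both mutually-exclusive drivers are present the triple carries a
#' `conflict` attribute rather than silently dropping one.
#'
#' @param calls `data.frame` of one sample's calls with columns `gene`,
#'   `variant`, `vaf` (zero rows = no mutations detected).
#' @return Named numeric triple `c(H3K27M, IDH, DW)` with entries in
#'   \{0, 1\} and attribute `conflict`.
#' @export
mutation_probs <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) {
    return(structure(c(H3K27M = 0, IDH = 0, DW = 0), conflict = FALSE))
  }
  stopifnot(all(c("gene", "variant") %in% colnames(calls)))
  h3 <- any(is_h3_driver_call(calls$gene, calls$variant))
  idh <- any(toupper(calls$gene) %in% IDH_DRIVER_GENES)
  structure(c(H3K27M = as.numeric(h3), IDH = as.numeric(idh), DW = 0),
            conflict = h3 && idh)
}

#' Fuse mutation and methylation evidence (BSGdiag)
#'
#' Combines the deterministic mutation-predicted probabilities with the
#' methylation classifier's probability triple by taking the per-class
#' maximum: a detected driver sets its class probability to certainty, while
#' in the absence of drivers the methylation probabilities carry through
#' unchanged. The final diagnosis is the class with the highest combined
#' probability, ties broken by the priority H3K27M > IDH > DW (the clinically
#' conservative order). The combined triple is deliberately not renormalized:
#' the argmax is unaffected and renormalization would dilute a driver's
#' certainty.
#'
#' For a BLOD sample (no mutation testing), pass `mut = NULL`; the diagnosis
#' is then methylation-only.
#'
#' @param mut Mutation triple from [mutation_probs()], or `NULL` when no
#'   mutation data exist.
#' @param meth Methylation triple (named, sums to 1), or `NULL`.
#' @return A `bsg_diagnosis` list: `predicted_class`, `combined_probs`,
#'   `mrs`, `evidence` (one of `mutation_only`, `methylation_only`,
#'   `fused`), `conflict_flag`.
#' @export
fuse_bsgdiag <- function(mut = NULL, meth = NULL) {
  if (is.null(mut) && is.null(meth)) stop("need mutation or methylation evidence")
  if (!is.null(meth)) {
    meth <- meth[SUBTYPES]
    if (any(is.na(meth))) stop("meth must be named with H3K27M, IDH, DW")
    check_unit_interval(unname(meth), "meth")
    if (abs(sum(meth) - 1) > 1e-6) {
      stop("methylation probabilities must sum to 1 (got ", format(sum(meth)), ")")
    }
  }
  conflict <- FALSE
  if (!is.null(mut)) {
    conflict <- isTRUE(attr(mut, "conflict"))
    mut <- mut[SUBTYPES]
    if (any(is.na(mut)) || !all(mut %in% c(0, 1))) {
      stop("mut must be a named triple with entries in {0, 1}")
    }
    conflict <- conflict || (mut["H3K27M"] == 1 && mut["IDH"] == 1)
  }
  combined <- if (is.null(mut)) meth else if (is.null(meth)) mut else pmax(mut, meth)
  evidence <- if (is.null(mut)) "methylation_only" else
    if (is.null(meth)) "mutation_only" else "fused"
  predicted <- SUBTYPES[which.max(combined[SUBTYPES])]
  structure(list(
    predicted_class = predicted,
    combined_probs = combined[SUBTYPES],
    mrs = if (is.null(meth)) NA_real_ else unname(meth["H3K27M"]),
    evidence = evidence,
    conflict_flag = unname(conflict)
  ), class = "bsg_diagnosis")
}

#' @export
print.bsg_diagnosis <- function(x, ...) {
  cat(sprintf("BSGdiag: %s (%s%s)  combined: H3K27M %.3f | IDH %.3f | DW %.3f  MRS %.3f\n",
              x$predicted_class, x$evidence,
              if (x$conflict_flag) ", DRIVER CONFLICT" else "",
              x$combined_probs["H3K27M"], x$combined_probs["IDH"],
              x$combined_probs["DW"], x$mrs))
  invisible(x)
}

#' Classify a cohort of samples with BSGdiag
#'
#' Runs the methylation classifier over a beta matrix, builds each sample's
#' mutation triple from a call table, and fuses the two per sample. Samples
#' without mutation testing (e.g. BLOD) are classified from methylation
#' alone.
#'
#' @param model A `methylation_classifier`.
#' @param betas Beta matrix of the samples to classify.
#' @param mutations Optional mutation table (`sample_id`, `gene`, `variant`,
#'   `vaf`); `NULL` means no sample had mutation testing.
#' @param tested Optional logical vector (or character vector of sample ids)
#'   marking which samples underwent mutation testing; defaults to all
#'   samples when `mutations` is supplied, none otherwise. An ALOD sample
#'   with no calls is a tested negative, not missing data.
#' @return `data.frame` with one row per sample: methylation probabilities,
#'   `mrs`, mutation flags, combined probabilities, `predicted_class`,
#'   `evidence`, `conflict_flag`.
#' @export
classify_samples <- function(model, betas, mutations = NULL, tested = NULL) {
  probs <- predict_methylation_probs(model, betas)
  ids <- rownames(betas)
  if (is.character(tested)) tested <- ids %in% tested
  tested <- tested %||% rep(!is.null(mutations), length(ids))
  stopifnot(length(tested) == length(ids))

  rows <- lapply(seq_along(ids), function(i) {
    meth <- probs[i, SUBTYPES]
    meth <- meth / sum(meth)
    mut <- if (tested[i]) {
      calls <- if (is.null(mutations)) NULL else
        mutations[mutations$sample_id == ids[i], , drop = FALSE]
      mutation_probs(calls)
    } else NULL
    d <- fuse_bsgdiag(mut, meth)
    data.frame(sample_id = ids[i],
               p_h3_meth = meth["H3K27M"], p_idh_meth = meth["IDH"],
               p_dw_meth = meth["DW"], mrs = d$mrs,
               mut_h3 = if (tested[i]) mut["H3K27M"] else NA_real_,
               mut_idh = if (tested[i]) mut["IDH"] else NA_real_,
               p_h3_combined = d$combined_probs["H3K27M"],
               p_idh_combined = d$combined_probs["IDH"],
               p_dw_combined = d$combined_probs["DW"],
               predicted_class = d$predicted_class,
               evidence = d$evidence,
               conflict_flag = d$conflict_flag,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
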