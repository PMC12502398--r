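#' Stratified discovery/test split
#'
#' Splits sample ids into a discovery and a held-out test set, stratified by
#' class so that each class contributes (to within rounding) the same
#' fraction to discovery.
#'
#' @param labels Class labels, optionally named with sample ids.
#' @param frac Discovery fraction in (0, 1]; the default mirrors the
#'   conventional 70/30 split used for marker screening.
#' @param seed RNG seed.
#' @return A list with `discovery` and `test` id vectors (names of `labels`,
#'   or indices when unnamed).
#' @export
split_discovery <- function(labels, frac = 0.7, seed = 1L) {
  if (!is.numeric(frac) || frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("class with no samples: ", names(counts)[counts == 0][1])
  }
  ids <- names(labels) %||% as.character(seq_along(labels))
  set.seed(seed)
  disc <- unlist(lapply(levels(labels), function(cl) {
    i <- which(labels == cl)
    n_take <- if (frac == 1) length(i) else round(frac * length(i))
    sample(i, n_take)
  }))
  disc <- sort(disc)
  list(discovery = ids[disc], test = ids[setdiff(seq_along(labels), disc)])
}

#' Screen differentially methylated CpG sites between two classes
#'
#' For each site, compares the two groups with the Wilcoxon rank-sum test and
#' computes the delta-beta effect size (difference of available-case group
#' means). Sites pass when `|delta_beta| >= delta_min` and the
#' Benjamini-Hochberg adjusted p-value is below `alpha`. Sites with no
#' observed value in one of the groups are excluded (a message reports the
#' count), not an error.
#'
#' @param betas Beta matrix (samples x CpGs, `NA` = missing).
#' @param labels Class labels aligned with the rows of `betas`.
#' @param pair Character vector of the two classes to contrast `(A, B)`;
#'   `delta_beta = mean(A) - mean(B)`.
#' @param delta_min Minimum absolute delta-beta; default 0.3, the stringent
#'   screening cutoff used for this assay.
#' @param alpha Significance level on the adjusted p-value.
#' @return `data.frame` with `cpg_id`, `group_pair`, `delta_beta`, `p_value`,
#'   `q_value`, sorted by decreasing `|delta_beta|`.
#' @export
find_dm_cpgs <- function(betas, labels, pair, delta_min = 0.3, alpha = 0.05) {
  stopifnot(length(pair) == 2)
  if (!is.numeric(delta_min) || delta_min < 0 || delta_min > 1) {
    stop("delta_min must be in [0, 1]")
  }
  labels <- as.character(labels)
  a <- betas[labels == pair[1], , drop = FALSE]
  b <- betas[labels == pair[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("both classes need at least 2 samples (", pair[1], ": ", nrow(a),
         ", ", pair[2], ": ", nrow(b), ")")
  }
  n_obs_a <- colSums(!is.na(a))
  n_obs_b <- colSums(!is.na(b))
  usable <- n_obs_a > 0 & n_obs_b > 0
  if (any(!usable)) {
    message("find_dm_cpgs: excluding ", sum(!usable),
            " site(s) with no observed values in one group")
  }
  cols <- which(usable)
  if (length(cols) == 0) {
    return(data.frame(cpg_id = character(), group_pair = character(),
                      delta_beta = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  delta <- colMeans(a[, cols, drop = FALSE], na.rm = TRUE) -
    colMeans(b[, cols, drop = FALSE], na.rm = TRUE)
  p <- vapply(cols, function(j) {
    x <- a[, j][!is.na(a[, j])]
    y <- b[, j][!is.na(b[, j])]
    pv <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    if (is.na(pv)) 1 else pv  # fully tied sites carry no evidence
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  keep <- abs(delta) >= delta_min & q < alpha
  out <- data.frame(cpg_id = colnames(betas)[cols][keep],
                    group_pair = rep(paste(pair[1], "vs", pair[2]), sum(keep)),
                    delta_beta = unname(delta[keep]),
                    p_value = unname(p[keep]),
                    q_value = unname(q[keep]),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$delta_beta)), , drop = FALSE]
}

#' Consensus feature selection over three algorithms
#'
#' Ranks candidate CpGs by (i) random-forest impurity importance, (ii)
#' aggregated weight magnitude of a linear support-vector machine, and (iii)
#' entry order along an L1-regularized multinomial path. A site is a
#' consensus feature when it appears in the top-`k` of at least two of the
#' three rankings; the consensus set is truncated to `k` by mean rank (it may
#' be smaller than `k` when the methods disagree). Candidates are first put
#' in canonical (sorted) order, so the result is invariant to the order in
#' which they are supplied.
#'
#' @param betas Beta matrix; missing values are imputed with column medians
#'   for the fitters.
#' @param labels Class labels aligned with rows.
#' @param candidates Candidate CpG ids (subset of `colnames(betas)`).
#' @param k Target panel size (> 0, <= number of candidates).
#' @param seed RNG seed (forest bootstrap).
#' @return Character vector of selected CpG ids, ordered by mean rank.
#' @export
select_consensus_features <- function(betas, labels, candidates, k, seed = 1L) {
  if (!is.numeric(k) || k <= 0) stop("k must be positive")
  candidates <- sort(unique(as.character(candidates)))
  if (!all(candidates %in% colnames(betas))) {
    stop("candidates must be a subset of the matrix columns")
  }
  if (k > length(candidates)) stop("k exceeds the number of candidates")
  if (length(candidates) < 2) return(candidates[seq_len(k)])

  x <- betas[, candidates, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  y <- droplevels(as.factor(labels))

  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = 500, importance = TRUE)
  imp_rf <- rf$importance[, "MeanDecreaseGini"]

  sv <- e1071::svm(x, y, kernel = "linear", scale = TRUE)
  w <- t(sv$coefs) %*% sv$SV          # stacked binary-machine weights
  imp_svm <- colSums(abs(w))[candidates]

  fit <- glmnet::glmnet(x, y, family = "multinomial",
                        type.multinomial = "grouped", standardize = TRUE)
  entry <- rep(Inf, length(candidates))
  names(entry) <- candidates
  nz <- Reduce(`+`, lapply(fit$beta, function(b) as.matrix(b) != 0))
  for (v in candidates) {
    idx <- which(nz[v, ] > 0)
    if (length(idx) > 0) entry[v] <- min(idx)
  }

  r_rf <- rank(-imp_rf, ties.method = "average")
  r_svm <- rank(-imp_svm, ties.method = "average")
  r_lasso <- rank(entry, ties.method = "average")
  votes <- (r_rf <= k) + (r_svm <= k) + (r_lasso <= k)
  mean_rank <- (r_rf + r_svm + r_lasso) / 3
  consensus <- candidates[votes >= 2]
  consensus <- consensus[order(mean_rank[consensus])]
  if (length(consensus) > k) consensus <- consensus[seq_len(k)]
  consensus
}

#' Assign marker classes to a CpG set
#'
#' Classifies each site by its group-mean methylation pattern: H3-specific
#' sites are consistently hypermethylated in H3K27M samples (mean at least
#' `margin` above both the IDH-mutant and remaining samples); IDH-specific
#' sites are hypermethylated in IDH-mutant samples while H3K27M samples stay
#' low (within `margin` of the remaining samples). Sites matching neither
#' rule are dropped with a message.
#'
#' @param betas Beta matrix.
#' @param labels Labels containing `H3K27M` and `IDH`; every other label
#'   (double-wildtype, controls) forms the reference group.
#' @param cpgs CpG ids to classify.
#' @param margin Required mean-beta separation (default 0.2).
#' @return A [marker_panel()].
#' @export
assign_marker_classes <- function(betas, labels, cpgs, margin = 0.2) {
  labels <- as.character(labels)
  for (cl in c("H3K27M", "IDH")) {
    if (!any(labels == cl)) stop("labels must contain class ", cl)
  }
  if (!all(cpgs %in% colnames(betas))) stop("cpgs must be columns of the beta matrix")
  other <- !(labels %in% c("H3K27M", "IDH"))
  if (!any(other)) stop("labels must contain at least one non-H3K27M, non-IDH sample")
  m_h3 <- colMeans(betas[labels == "H3K27M", cpgs, drop = FALSE], na.rm = TRUE)
  m_idh <- colMeans(betas[labels == "IDH", cpgs, drop = FALSE], na.rm = TRUE)
  m_other <- colMeans(betas[other, cpgs, drop = FALSE], na.rm = TRUE)

  h3_spec <- m_h3 >= m_idh + margin & m_h3 >= m_other + margin
  idh_spec <- !h3_spec & m_idh >= m_h3 + margin & m_h3 <= m_other + margin
  dropped <- !h3_spec & !idh_spec
  if (any(dropped)) {
    message("assign_marker_classes: dropping ", sum(dropped),
            " site(s) matching neither marker-class pattern")
  }
  entries <- data.frame(
    cpg_id = cpgs[h3_spec | idh_spec],
    marker_class = ifelse(h3_spec[h3_spec | idh_spec], "H3_specific", "IDH_specific"),
    mean_h3 = m_h3[h3_spec | idh_spec],
    mean_idh = m_idh[h3_spec | idh_spec],
    mean_other = m_other[h3_spec | idh_spec],
    stringsAsFactors = FALSE
  )
  rownames(entries) <- NULL
  marker_panel(entries)
}

#' Construct a marker panel
#'
#' A marker panel is an ordered CpG set in which every site carries one of
#' two class labels: `H3_specific` or `IDH_specific`. Both classes must be
#' non-empty, otherwise the methylation signature score is undefined.
#'
#' @param entries `data.frame` with columns `cpg_id` and `marker_class`
#'   (additional provenance columns are preserved).
#' @return The panel, classed `marker_panel`.
#' @export
marker_panel <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("cpg_id", "marker_class") %in% colnames(entries)))
  if (anyDuplicated(entries$cpg_id)) stop("duplicate CpG ids in panel")
  if (!all(entries$marker_class %in% MARKER_CLASSES)) {
    stop("marker_class must be one of: ", paste(MARKER_CLASSES, collapse = ", "))
  }
  n_h3 <- sum(entries$marker_class == "H3_specific")
  n_idh <- sum(entries$marker_class == "IDH_specific")
  if (n_h3 == 0 || n_idh == 0) {
    stop("panel must contain both H3-specific and IDH-specific sites ",
         "(got ", n_h3, " / ", n_idh, "); the signature score is undefined otherwise")
  }
  structure(entries, class = c("marker_panel", "data.frame"))
}

#' Panel composition counts
#'
#' @param panel A [marker_panel()].
#' @return Named integer vector `c(n_h3 = , n_idh = )`.
#' @export
panel_sizes <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  c(n_h3 = sum(panel$marker_class == "H3_specific"),
    n_idh = sum(panel$marker_class == "IDH_specific"))
}

#' Read / write a marker panel as TSV
#'
#' @param path File path.
#' @return For `read_marker_panel`, a [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  marker_panel(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_marker_panel
#' @param panel A [marker_panel()].
#' @export
write_marker_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  atomic_write(function(tmp) {
    utils::write.table(panel, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Simulate the wet-lab reduction of a candidate panel
#'
#' Primer design and validation shrink a discovered CpG set to the sites that
#' can be assayed; this is modeled as a seeded random subset that preserves
#' at least one site of each marker class.
#'
#' @param panel A [marker_panel()].
#' @param n Target panel size.
#' @param seed RNG seed.
#' @return A [marker_panel()] with `n` sites.
#' @export
subset_panel <- function(panel, n, seed = 1L) {
  stopifnot(inherits(panel, "marker_panel"))
  if (n > nrow(panel) || n < 2) stop("n must be in [2, panel size]")
  set.seed(seed)
  repeat {
    keep <- sort(sample(nrow(panel), n))
    cls <- panel$marker_class[keep]
    if (all(MARKER_CLASSES %in% cls)) break
  }
  marker_panel(panel[keep, , drop = FALSE])
}
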