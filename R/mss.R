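#' Methylation Signature Score (MSS)
#'
#' Panel-level summary of a sample's methylation pattern:
#' \deqn{MSS = \frac{\sum \beta_{H3} + (1 - \sum \beta_{IDH})}{N}}
#' where the sums run over the H3-specific and IDH-specific marker sites and
#' `N` is the total probe number of the panel. High scores indicate the
#' H3K27M hyper/hypo pattern; strongly negative scores the IDH pattern. The
#' score is bounded by `(1 - n_idh)/N <= MSS <= (n_h3 + 1)/N`, which always
#' lies within \[-1, 1\].
#'
#' Missing probes are handled by rescaling each class sum to the full class
#' size (`sum_observed * n_class / n_observed`), which leaves the score
#' unbiased under probes missing completely at random. Coverage below
#' `min_coverage` flags the result as failing QC; the value is still
#' returned.
#'
#' @param sample_betas Named numeric vector of beta values (`NA` = missing);
#'   panel probes absent from the vector count as missing.
#' @param panel A [marker_panel()].
#' @param min_coverage Minimum fraction of panel probes observed for
#'   `qc_pass` (default 0.5).
#' @return An `mss_result` list: `value`, `n_observed_h3`, `n_observed_idh`,
#'   `coverage`, `qc_pass`.
#' @export
compute_mss <- function(sample_betas, panel, min_coverage = 0.5) {
  stopifnot(inherits(panel, "marker_panel"))
  check_unit_interval(min_coverage, "min_coverage")
  h3_ids <- panel$cpg_id[panel$marker_class == "H3_specific"]
  idh_ids <- panel$cpg_id[panel$marker_class == "IDH_specific"]
  v_h3 <- sample_betas[h3_ids]
  v_idh <- sample_betas[idh_ids]
  check_unit_interval(v_h3, "sample_betas", allow_na = TRUE)
  check_unit_interval(v_idh, "sample_betas", allow_na = TRUE)
  obs_h3 <- v_h3[!is.na(v_h3)]
  obs_idh <- v_idh[!is.na(v_idh)]
  if (length(obs_h3) == 0 || length(obs_idh) == 0) {
    stop("MSS undefined: zero observed probes in the ",
         if (length(obs_h3) == 0) "H3-specific" else "IDH-specific", " class")
  }
  n_h3 <- length(h3_ids)
  n_idh <- length(idh_ids)
  N <- n_h3 + n_idh
  s_h3 <- sum(obs_h3) * n_h3 / length(obs_h3)
  s_idh <- sum(obs_idh) * n_idh / length(obs_idh)
  coverage <- (length(obs_h3) + length(obs_idh)) / N
  structure(list(
    value = (s_h3 + (1 - s_idh)) / N,
    n_observed_h3 = length(obs_h3),
    n_observed_idh = length(obs_idh),
    coverage = coverage,
    qc_pass = coverage >= min_coverage
  ), class = "mss_result")
}

#' @export
print.mss_result <- function(x, ...) {
  cat(sprintf("MSS %.4f (coverage %.0f%%, qc %s; %d H3 + %d IDH probes observed)\n",
              x$value, 100 * x$coverage, if (x$qc_pass) "pass" else "FAIL",
              x$n_observed_h3, x$n_observed_idh))
  invisible(x)
}

#' Methylation Signature Scores for a whole beta matrix
#'
#' Row-wise application of [compute_mss()]. Samples with zero observed
#' probes in either marker class get `NA` values and a failing QC flag
#' (with a warning) instead of an error, so that cohort-level scoring does
#' not abort on a few empty samples.
#'
#' @param betas Beta matrix (samples x CpGs).
#' @param panel A [marker_panel()].
#' @param min_coverage Passed to [compute_mss()].
#' @return `data.frame` with one row per sample: `sample_id`, `mss`,
#'   `coverage`, `qc_pass`, `n_observed_h3`, `n_observed_idh`.
#' @export
compute_mss_matrix <- function(betas, panel, min_coverage = 0.5) {
  rows <- lapply(seq_len(nrow(betas)), function(i) {
    res <- tryCatch(compute_mss(betas[i, ], panel, min_coverage),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(sample_id = rownames(betas)[i], mss = NA_real_,
                 coverage = 0, qc_pass = FALSE,
                 n_observed_h3 = 0L, n_observed_idh = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = rownames(betas)[i], mss = res$value,
                 coverage = res$coverage, qc_pass = res$qc_pass,
                 n_observed_h3 = res$n_observed_h3,
                 n_observed_idh = res$n_observed_idh,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$mss))) {
    warning(sum(is.na(out$mss)),
            " sample(s) had zero observed probes in a marker class; MSS set to NA")
  }
  out
}
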