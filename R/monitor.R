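#' Pearson concordance between paired measurements
#'
#' Sample Pearson correlation with the two-sided t-based p-value, used for
#' tissue-vs-CSF signature-score concordance and VAF-vs-MSS agreement.
#'
#' @param x,y Paired numeric vectors (>= 3 complete finite pairs, neither
#'   constant).
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-interval MSS dynamics
#'
#' Computes the change in Methylation Signature Score between consecutive
#' monitoring points and versus the baseline (first) point, labelling each
#' change `decrease`, `increase` or `stable` within a configurable stability
#' band. QC-failed points are excluded with a message. Direction labels
#' depend only on the ordering of the points, not on the absolute
#' timestamps.
#'
#' @param series A `longitudinal_series` (or any `data.frame` with `day` and
#'   `mss`, optionally `qc_pass`).
#' @param stability_band Absolute MSS change treated as stable (default
#'   0.005).
#' @return `data.frame` per retained point: `day`, `mss`, `delta_prev`,
#'   `delta_baseline`, `direction_prev`, `direction_baseline` (baseline row:
#'   `NA` deltas and `"baseline"` labels).
#' @export
mss_dynamics <- function(series, stability_band = 0.005) {
  stopifnot(is.data.frame(series), all(c("day", "mss") %in% colnames(series)))
  if ("qc_pass" %in% colnames(series)) {
    drop <- !series$qc_pass | is.na(series$mss)
    if (any(drop)) {
      message("mss_dynamics: excluding ", sum(drop), " QC-failed point(s)")
      series <- series[!drop, , drop = FALSE]
    }
  }
  if (nrow(series) < 2) stop("need at least 2 usable points")
  series <- series[order(series$day), , drop = FALSE]
  direction <- function(d) {
    ifelse(abs(d) < stability_band, "stable",
           ifelse(d > 0, "increase", "decrease"))
  }
  delta_prev <- c(NA, diff(series$mss))
  delta_base <- series$mss - series$mss[1]
  data.frame(
    day = series$day,
    mss = series$mss,
    delta_prev = delta_prev,
    delta_baseline = c(NA, delta_base[-1]),
    direction_prev = c("baseline", direction(delta_prev[-1])),
    direction_baseline = c("baseline", direction(delta_base[-1])),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Minimal-residual-disease flag for a monitoring point
#'
#' A point is MRD-positive when the mutation VAF is undetectable (the `NA`
#' sentinel -- never a measured 0) while the methylation signature remains
#' above the detection floor. A QC-failed MSS makes the flag indeterminate
#' (`NA`), not negative.
#'
#' @param vaf VAF value(s); `NA` = undetectable.
#' @param mss MSS value(s).
#' @param mss_floor Methylation detection floor; see
#'   [mss_detection_floor()] for a data-driven calibration.
#' @param qc_pass Logical QC flag(s) for the MSS measurement.
#' @return Logical vector (`NA` = indeterminate).
#' @export
mrd_flag <- function(vaf, mss, mss_floor, qc_pass = TRUE) {
  if (!is.finite(mss_floor) || mss_floor < 0) stop("mss_floor must be >= 0")
  n <- max(length(vaf), length(mss))
  vaf <- rep_len(vaf, n); mss <- rep_len(mss, n); qc_pass <- rep_len(qc_pass, n)
  out <- is.na(vaf) & mss > mss_floor
  out[!qc_pass | is.na(mss)] <- NA
  out
}

#' Calibrate the MSS detection floor from background samples
#'
#' The methylation detection floor is not a published constant; it is
#' calibrated here as an upper quantile (default 95th percentile) of the
#' MSS distribution in background / double-wildtype samples, i.e. the level
#' below which a score is indistinguishable from no tumor signal.
#'
#' @param background_mss MSS values of background or tumor-free samples.
#' @param prob Quantile (default 0.95).
#' @return The floor value.
#' @export
mss_detection_floor <- function(background_mss, prob = 0.95) {
  background_mss <- background_mss[is.finite(background_mss)]
  if (length(background_mss) < 5) stop("need at least 5 background scores")
  unname(stats::quantile(background_mss, prob))
}
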