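#' Stratify patients by Methylation Risk Score
#'
#' Dichotomizes MRS at a fixed cutoff; the shipped default of 0.44 is the
#' published operating point for separating high- and low-risk CSF
#' methylation groups. The boundary convention is strict: a score exactly at
#' the cutoff is low-risk.
#'
#' @param mrs MRS values in \[0, 1\].
#' @param cutoff Risk threshold (default 0.44).
#' @return Factor with levels `low`, `high`.
#' @export
stratify_by_mrs <- function(mrs, cutoff = 0.44) {
  check_unit_interval(mrs, "mrs")
  factor(ifelse(mrs > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier median survival
#'
#' Product-limit estimate of median overall survival with its confidence
#' interval. When the survival curve never falls to 0.5 the median is not
#' reached: `reached` is `FALSE` and the estimate is `NA` (the sentinel),
#' as is conventional for low-risk strata.
#'
#' @param times Follow-up times (> 0).
#' @param events Event indicators (1 = death, 0 = censored).
#' @param conf Confidence level.
#' @return A `km_median` list: `median`, `lcl`, `ucl`, `reached`, `n`,
#'   `events`.
#' @export
km_median <- function(times, events, conf = 0.95) {
  if (length(times) == 0) stop("group is empty")
  if (all(times <= 0)) stop("all observations censored at time 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.int = conf)
  tab <- summary(fit)$table
  # median = earliest time the product-limit curve reaches 0.5 (no averaging
  # over an exact-0.5 plateau)
  hit <- fit$surv <= 0.5 + 1e-12
  med <- if (any(hit)) min(fit$time[hit]) else NA_real_
  structure(list(
    median = med,
    lcl = unname(tab[grep("LCL", names(tab))]),
    ucl = unname(tab[grep("UCL", names(tab))]),
    reached = !is.na(med),
    n = unname(tab["records"]),
    events = unname(tab["events"])
  ), class = "km_median")
}

#' @export
print.km_median <- function(x, ...) {
  cat(sprintf("KM median OS: %s months (95%% CI %s-%s; %d patients, %d events)\n",
              if (x$reached) format(round(x$median, 1)) else "Not Reached",
              if (is.na(x$lcl)) "NR" else format(round(x$lcl, 1)),
              if (is.na(x$ucl)) "NR" else format(round(x$ucl, 1)),
              x$n, x$events))
  invisible(x)
}

#' Kaplan-Meier medians per group
#'
#' @param times,events As in [km_median()].
#' @param group Grouping vector.
#' @param conf Confidence level.
#' @return `data.frame` with one row per group: `group`, `n`, `events`,
#'   `median` (`NA` = not reached), `lcl`, `ucl`.
#' @export
km_by_group <- function(times, events, group, conf = 0.95) {
  group <- as.factor(group)
  rows <- lapply(levels(group), function(g) {
    i <- group == g
    km <- km_median(times[i], events[i], conf)
    data.frame(group = g, n = km$n, events = km$events, median = km$median,
               lcl = km$lcl, ucl = km$ucl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for the given
#' covariates, reporting per-covariate hazard ratios with Wald confidence
#' intervals and p-values, plus Harrell's concordance index. Monotone
#' likelihood (complete separation) is detected and flagged.
#'
#' @param data `data.frame` with time/event columns and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param time_col,event_col Column names (defaults `os_months`, `event`).
#' @param conf Confidence level for the hazard-ratio intervals.
#' @return A `cox_fit` list: `table` (term, hr, lcl, ucl, p),
#'   `concordance`, `flagged` (TRUE when the likelihood is monotone), `fit`.
#' @export
fit_cox <- function(data, covariates, time_col = "os_months",
                    event_col = "event", conf = 0.95) {
  stopifnot(all(c(time_col, event_col, covariates) %in% colnames(data)))
  if (sum(data[[event_col]]) > 0 &&
      length(unique(data[[time_col]][data[[event_col]] == 1])) < 2) {
    stop("need at least 2 distinct event times")
  }
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) stop("covariate is constant: ", cv)
  }
  fml <- stats::as.formula(paste0("survival::Surv(", time_col, ", ", event_col,
                                  ") ~ ", paste(covariates, collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit, conf.int = conf)
  tab <- data.frame(
    term = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    lcl = unname(s$conf.int[, 3]),
    ucl = unname(s$conf.int[, 4]),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  if (any(abs(stats::coef(fit)) > 15)) flagged <- TRUE
  structure(list(table = tab, concordance = unname(s$concordance["C"]),
                 flagged = flagged, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("%s: HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                x$table$term[i], x$table$hr[i], x$table$lcl[i],
                x$table$ucl[i], x$table$p[i]))
  }
  cat(sprintf("concordance index %.2f%s\n", x$concordance,
              if (x$flagged) "  [monotone likelihood flagged]" else ""))
  invisible(x)
}

#' Search for an MRS risk cutoff (maximally selected log-rank)
#'
#' Scans a grid of candidate cutoffs and returns the one maximizing the
#' two-group log-rank statistic, subject to each group retaining at least
#' `min_group_frac` of the patients. The statistic at the optimum is
#' selection-inflated and is reported as exploratory only -- it must not be
#' read as a valid p-value. The shipped stratification default remains the
#' fixed published cutoff (see [stratify_by_mrs()]).
#'
#' @param mrs MRS values in \[0, 1\].
#' @param times,events Survival data aligned with `mrs`.
#' @param grid Candidate cutoffs.
#' @param min_group_frac Minimum fraction of patients per group (default
#'   0.15).
#' @return A list: `cutoff`, `statistic` (log-rank chi-square),
#'   `p_exploratory`, `n_admissible`.
#' @export
find_mrs_cutoff <- function(mrs, times, events,
                            grid = seq(0.05, 0.95, by = 0.01),
                            min_group_frac = 0.15) {
  check_unit_interval(mrs, "mrs")
  if (length(mrs) < 10) stop("need at least 10 patients")
  if (sum(events) < 5) stop("need at least 5 events")
  stat <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    high <- mrs > grid[i]
    frac <- mean(high)
    if (frac < min_group_frac || frac > 1 - min_group_frac) next
    sd <- survival::survdiff(survival::Surv(times, events) ~ high)
    stat[i] <- sd$chisq
  }
  if (all(is.na(stat))) stop("no admissible grid point under the group-size constraint")
  best <- which.max(stat)
  list(cutoff = grid[best], statistic = stat[best],
       p_exploratory = stats::pchisq(stat[best], df = 1, lower.tail = FALSE),
       n_admissible = sum(!is.na(stat)))
}
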