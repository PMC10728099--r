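#' Stratify samples into methylation-high and -low groups at the cohort mean
#'
#' @param scores Numeric vector of per-sample methylation scores.
#' @return Factor with levels `low`, `high`: `high` for scores strictly
#'   above the mean, `low` otherwise (a score exactly at the mean is `low`).
#' @export
split_by_mean <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples to split")
  if (anyNA(scores)) stop("scores contain missing values")
  m <- mean(scores)
  if (all(scores == scores[1])) stop("degenerate split: scores are constant")
  factor(ifelse(scores > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring; thin wrapper around
#' [survival::survfit()] returning the step function as a data frame.
#'
#' @param time Survival times (> 0).
#' @param event Event indicator: 1 = event, 0 = censored.
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `surv`
#'   (non-increasing, starting from S(0) = 1 implicitly).
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) via [survival::survdiff()], plus the
#' observed-minus-expected event count of the `high` group, which carries
#' the direction information used by [signed_p()].
#'
#' @param groups Factor with levels `low`/`high` from [split_by_mean()].
#' @param time,event Survival time and event indicator.
#' @return List: `chi_square`, `p`, `obs_minus_exp_high`.
#' @export
logrank_test <- function(groups, time, event) {
  if (nlevels(droplevels(groups)) < 2) stop("one group is empty")
  if (sum(event) == 0) stop("no events in cohort")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  hi <- which(grepl("high$", names(sd$n)))
  chi <- sd$chisq
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       obs_minus_exp_high = unname(sd$obs[hi] - sd$exp[hi]))
}

#' Signed log-rank P value
#'
#' The log-rank P value carrying the direction of the effect: positive when
#' the methylation-high group shows the better survival (fewer observed
#' events than expected, the hypothesized direction), negative when the
#' methylation-low group does. The sign makes P values from opposite-
#' direction splits comparable on one axis: large positive = strongly
#' confirming, near +/-1 = no effect, large negative = strongly reversed.
#' A high group with observed events exactly equal to expected takes the
#' positive sign.
#'
#' The signed value is a reporting convention, not a monotone performance
#' scale: a weak wrong-direction result (-0.9) sits below a strong
#' confirming one (+0.001). For ranking predictors, `directional_p` is also
#' returned: the one-sided P value for the hypothesized direction,
#' `(1 - sign * (1 - p)) / 2`, which runs continuously from ~0 (strongly
#' confirming) through 0.5 (no effect) to ~1 (strongly reversed).
#'
#' @inheritParams logrank_test
#' @return List of class `signed_p`: `p`, `sign` (+1/-1), `signed_value`,
#'   `directional_p`.
#' @export
signed_p <- function(groups, time, event) {
  lr <- logrank_test(groups, time, event)
  sgn <- if (lr$obs_minus_exp_high <= 0) 1 else -1
  structure(list(p = lr$p, sign = sgn, signed_value = sgn * lr$p,
                 directional_p = (1 - sgn * (1 - lr$p)) / 2,
                 chi_square = lr$chi_square),
            class = "signed_p")
}

#' Bootstrap distribution of signed log-rank P values
#'
#' Patients are resampled with replacement (each drawn patient keeps its
#' score-time-event triple intact); each resample is re-split at its own
#' mean and the signed log-rank P recorded. Degenerate resamples (constant
#' scores, an empty group, or zero events) are redrawn, not dropped, so the
#' result always holds exactly `resamples` values and stays pairable across
#' predictors.
#'
#' When `scores` is a matrix or data frame (one column per predictor), the
#' same resampled patients are used for every predictor in each replicate,
#' so the resulting distributions are paired by construction — the pairing
#' assumed by [compare_predictors()]. A replicate is redrawn if degenerate
#' for any predictor.
#'
#' @param scores Numeric vector of per-sample scores, or a matrix/data
#'   frame with one predictor per column.
#' @param time,event Survival time and event indicator per sample.
#' @param resamples Number of bootstrap resamples (1000 or 5000 typical).
#' @param seed Integer seed.
#' @param max_redraw Attempts per replicate before giving up.
#' @return For a vector: object of class `bootstrap_result` with
#'   `signed_values` (length `resamples`), `resamples`, `seed`, `skipped`
#'   (degenerate draws redrawn). For a matrix: named list of
#'   `bootstrap_result`, one per column, sharing resamples.
#' @export
bootstrap_signed_p <- function(scores, time, event, resamples = 1000,
                               seed = 1L, max_redraw = 100L) {
  multi <- is.matrix(scores) || is.data.frame(scores)
  S <- if (multi) as.matrix(scores) else matrix(scores, ncol = 1)
  n <- nrow(S)
  stopifnot(length(time) == n, length(event) == n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- matrix(NA_real_, nrow = resamples, ncol = ncol(S))
  skipped <- 0L
  for (r in seq_len(resamples)) {
    ok <- FALSE
    for (attempt in seq_len(max_redraw)) {
      idx <- sample.int(n, n, replace = TRUE)
      sp <- rep(NA_real_, ncol(S))
      good <- TRUE
      for (j in seq_len(ncol(S))) {
        res <- tryCatch({
          g <- split_by_mean(S[idx, j])
          signed_p(g, time[idx], event[idx])$signed_value
        }, error = function(e) NA_real_)
        if (is.na(res)) { good <- FALSE; break }
        sp[j] <- res
      }
      if (good) { vals[r, ] <- sp; ok <- TRUE; break }
      skipped <- skipped + 1L
    }
    if (!ok) stop("cohort too small: no valid resample in ", max_redraw, " attempts")
  }
  mk <- function(v) structure(list(signed_values = v, resamples = resamples,
                                   seed = seed, skipped = skipped),
                              class = "bootstrap_result")
  if (!multi) return(mk(vals[, 1]))
  out <- lapply(seq_len(ncol(S)), function(j) mk(vals[, j]))
  names(out) <- colnames(S)
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap signed-P: %d resamples (seed %d, %d degenerate redraws)\n",
              x$resamples, x$seed, x$skipped))
  cat(sprintf("  median signed P: %.4g;  positive sign: %.1f%%\n",
              stats::median(x$signed_values),
              100 * mean(x$signed_values > 0)))
  invisible(x)
}

#' Compare two predictors' bootstrap signed-P distributions
#'
#' Two-sided Wilcoxon signed-rank test on the paired signed P values
#' (paired by resample index; use the matrix form of
#' [bootstrap_signed_p()] so pairs share resampled patients).
#'
#' @param result_a,result_b `bootstrap_result` objects of equal length, or
#'   bare numeric vectors of signed P values.
#' @return List: `p`, `statistic`, `stars` (significance band: `****` <
#'   1e-4, `***` < 1e-3, `**` < 1e-2, `*` < 0.05, `ns` otherwise).
#' @export
compare_predictors <- function(result_a, result_b) {
  a <- if (inherits(result_a, "bootstrap_result")) result_a$signed_values else result_a
  b <- if (inherits(result_b, "bootstrap_result")) result_b$signed_values else result_b
  if (length(a) != length(b)) stop("signed-P collections differ in length")
  if (all(a == b)) return(list(p = 1, statistic = NA_real_, stars = "ns"))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       stars = p_stars(wt$p.value))
}

#' Significance stars for a P value
#'
#' @param p P value.
#' @return `"****"` (< 1e-4), `"***"` (< 1e-3), `"**"` (< 0.01),
#'   `"*"` (< 0.05) or `"ns"`.
#' @export
p_stars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***"
  else if (p < 1e-2) "**" else if (p < 0.05) "*" else "ns"
}
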