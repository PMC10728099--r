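#' Select distinctive probes by standard deviation
#'
#' Drops the probe with the smallest across-sample standard deviation and
#' every probe with SD below `threshold` (default 0.015); the remaining
#' probes carry enough between-sample variation to classify responses.
#' The smallest-SD probe is dropped even when its SD clears the threshold.
#' Ties for the smallest SD go to the first (leftmost) probe.
#'
#' @param beta_matrix Samples x probes matrix/data frame of betas.
#' @param threshold SD threshold below which probes are dropped.
#' @return List of class `probe_selection`: `kept`, `dropped_smallest_sd`,
#'   `dropped_below_threshold`, `sd` (per probe), `threshold`.
#' @export
select_probes_by_sd <- function(beta_matrix, threshold = 0.015) {
  bm <- as.matrix(as.data.frame(beta_matrix))
  if (nrow(bm) < 2) stop("need at least 2 samples to compute SDs")
  sds <- apply(bm, 2, stats::sd, na.rm = TRUE)
  smallest <- names(sds)[which.min(sds)]
  below <- names(sds)[sds < threshold]
  kept <- setdiff(colnames(bm), union(smallest, below))
  if (length(kept) < 2) stop("fewer than 2 probes would remain after SD filtering")
  structure(list(kept = kept, dropped_smallest_sd = smallest,
                 dropped_below_threshold = setdiff(below, smallest),
                 sd = sds, threshold = threshold),
            class = "probe_selection")
}

#' Fit a binomial GLM of responder status on selected probes
#'
#' Logistic regression of the durable-clinical-benefit label on the
#' selected probes' betas; returns in-sample fitted probabilities, which
#' feed [roc_auc()]. Perfect separation is flagged (the fitted scores are
#' still monotone in the linear predictor and usable for ranking).
#'
#' @param selected_betas Samples x kept-probes matrix/data frame.
#' @param responses Factor or character: `"DCB"` (responder) vs `"NDB"`;
#'   or a 0/1 vector (1 = responder).
#' @return List of class `response_glm`: `fitted` (per-sample probability
#'   of DCB), `coefficients`, `separation` (logical), `model`.
#' @export
fit_response_glm <- function(selected_betas, responses) {
  X <- as.data.frame(selected_betas)
  y <- response_to_binary(responses)
  if (length(unique(y)) < 2) stop("both response classes must be present")
  if (nrow(X) <= ncol(X)) stop("need more samples than probes for the GLM fit")
  dat <- cbind(X, .resp = y)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.resp ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  structure(list(fitted = unname(stats::fitted(fit)),
                 coefficients = stats::coef(fit),
                 separation = sep, model = fit),
            class = "response_glm")
}

response_to_binary <- function(responses) {
  if (is.numeric(responses)) {
    stopifnot(all(responses %in% c(0, 1)))
    return(as.integer(responses))
  }
  r <- as.character(responses)
  bad <- setdiff(unique(r), c("DCB", "NDB"))
  if (length(bad) > 0) stop("unknown response label(s): ", paste(bad, collapse = ", "))
  as.integer(r == "DCB")
}

#' ROC area under the curve
#'
#' AUC as the Mann-Whitney rank statistic: the probability that a randomly
#' chosen responder scores above a randomly chosen non-responder, with ties
#' credited 0.5.
#'
#' @param scores Numeric prediction scores (higher = more responder-like).
#' @param labels Responses as accepted by [fit_response_glm()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- response_to_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties with 0.5 credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Response-prediction accuracy: SD filter + GLM + ROC-AUC
#'
#' Composes [select_probes_by_sd()], [fit_response_glm()] and [roc_auc()]
#' into the in-sample prediction-accuracy evaluation.
#'
#' @param beta_matrix Samples x probes betas.
#' @param responses Per-sample response labels (`DCB`/`NDB` or 0/1).
#' @param sd_threshold Passed to [select_probes_by_sd()].
#' @return List: `auc`, `selection`, `glm`.
#' @export
predict_auc <- function(beta_matrix, responses, sd_threshold = 0.015) {
  sel <- select_probes_by_sd(beta_matrix, threshold = sd_threshold)
  X <- as.data.frame(beta_matrix)[, sel$kept, drop = FALSE]
  fit <- fit_response_glm(X, responses)
  list(auc = roc_auc(fit$fitted, responses), selection = sel, glm = fit)
}
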