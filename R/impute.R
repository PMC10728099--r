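#' Fit linear imputation models for the non-CpG probes
#'
#' Some tissue samples fail to yield beta values for the non-CpG probes
#' P8-P10. Their values are imputed from the seven CpG probes: one ordinary
#' least-squares multiple regression per response probe, with P1-P7 as
#' explanatory variables, trained on samples whose ten-probe vectors are
#' complete.
#'
#' @param beta_matrix Numeric matrix or data frame, samples x probes, with
#'   columns named by probe id (P1..P10 for the default panel).
#' @param response_probes Probes to build models for (default P8, P9, P10).
#' @param predictor_probes Explanatory probes (default P1-P7).
#' @return Named list of `imputation_model` objects, each with
#'   `response_probe`, `coefficients` (intercept + one slope per predictor),
#'   `n_train` and `r_squared`.
#' @export
fit_imputation_models <- function(beta_matrix,
                                  response_probes = c("P8", "P9", "P10"),
                                  predictor_probes = paste0("P", 1:7)) {
  bm <- as.data.frame(beta_matrix)
  missing_cols <- setdiff(c(response_probes, predictor_probes), names(bm))
  if (length(missing_cols) > 0) {
    stop("beta matrix lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  complete <- stats::complete.cases(bm[, c(predictor_probes, response_probes)])
  n_par <- length(predictor_probes) + 1L
  if (sum(complete) < n_par + 1L) {
    stop(sprintf("need at least %d complete samples to fit, have %d",
                 n_par + 1L, sum(complete)))
  }
  train <- bm[complete, , drop = FALSE]
  X <- as.matrix(train[, predictor_probes, drop = FALSE])
  if (qr(cbind(1, X))$rank < n_par) {
    sds <- apply(X, 2, stats::sd)
    stop("rank-deficient design; collinear or constant predictors: ",
         paste(predictor_probes[sds == 0], collapse = ", "))
  }
  models <- lapply(response_probes, function(rp) {
    fit <- stats::lm(stats::reformulate(predictor_probes, response = rp), data = train)
    # noiseless training data gives an exact fit; the summary warning about
    # it is not actionable here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    structure(list(response_probe = rp,
                   coefficients = stats::coef(fit),
                   n_train = nrow(train),
                   r_squared = r2),
              class = "imputation_model")
  })
  names(models) <- response_probes
  models
}

#' Impute missing probe betas in a sample
#'
#' Missing entries among the modelled probes are replaced by the linear
#' model predictions from the observed predictor probes, clipped to
#' `[0, 1]`. A sample with nothing missing is returned unchanged.
#'
#' @param sample A `beta_vector` (from [quantify_sample()]) or a named
#'   numeric vector of betas.
#' @param models Output of [fit_imputation_models()].
#' @return The input with missing modelled probes filled in; imputed (and
#'   clipped) probe names recorded in attributes `imputed` and `clipped`
#'   (on the beta vector).
#' @export
impute_missing <- function(sample, models) {
  is_bv <- inherits(sample, "beta_vector")
  beta <- if (is_bv) sample$beta else sample
  predictors <- names(models[[1]]$coefficients)[-1]
  if (anyNA(beta[predictors])) {
    stop("cannot impute: predictor probe(s) missing: ",
         paste(predictors[is.na(beta[predictors])], collapse = ", "))
  }
  imputed <- character(0); clipped <- character(0)
  for (m in models) {
    rp <- m$response_probe
    if (rp %in% names(beta) && is.na(beta[rp])) {
      pred <- sum(m$coefficients * c(1, beta[predictors]))
      if (pred < 0 || pred > 1) clipped <- c(clipped, rp)
      beta[rp] <- min(1, max(0, pred))
      imputed <- c(imputed, rp)
    }
  }
  attr(beta, "imputed") <- imputed
  attr(beta, "clipped") <- clipped
  if (is_bv) { sample$beta <- beta; sample } else beta
}

#' Impute every incomplete row of a beta matrix
#'
#' Convenience wrapper: fits models on the complete rows and applies them to
#' rows missing one or more of the response probes.
#'
#' @inheritParams fit_imputation_models
#' @return List with `beta_matrix` (imputed), `models`, and `imputed_rows`.
#' @export
impute_beta_matrix <- function(beta_matrix,
                               response_probes = c("P8", "P9", "P10"),
                               predictor_probes = paste0("P", 1:7)) {
  models <- fit_imputation_models(beta_matrix, response_probes, predictor_probes)
  bm <- as.data.frame(beta_matrix)
  rows <- which(!stats::complete.cases(bm[, response_probes, drop = FALSE]))
  for (i in rows) {
    v <- unlist(bm[i, c(predictor_probes, response_probes)])
    bm[i, c(predictor_probes, response_probes)] <- impute_missing(v, models)
  }
  list(beta_matrix = bm, models = models, imputed_rows = rows)
}
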