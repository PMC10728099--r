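#' Convert per-probe selection counts to a weight vector
#'
#' In the randomized weighting scheme, a candidate weight vector arises from
#' drawing `set_size` probes with replacement; each probe's weight is the
#' number of times it was chosen divided by the set size (a probe chosen 6
#' times in a set of 30 gets weight 0.2). Weights are therefore non-negative
#' rationals summing to exactly 1.
#'
#' @param counts Named integer vector of per-probe selection counts.
#' @param set_size Size of the simulated probe set; must equal `sum(counts)`.
#' @return Object of class `weight_vector`: `weights` (named numeric),
#'   `counts`, `set_size`.
#' @examples
#' w <- weight_from_counts(c(P1 = 6, P2 = 24), 30)
#' w$weights["P1"]  # 0.2
#' @export
weight_from_counts <- function(counts, set_size) {
  if (set_size <= 0) stop("set_size must be positive")
  if (sum(counts) != set_size) {
    stop(sprintf("counts sum to %d, expected set_size = %d", sum(counts), set_size))
  }
  structure(list(weights = counts / set_size,
                 counts = counts, set_size = as.integer(set_size)),
            class = "weight_vector")
}

#' Generate randomized candidate probe-weight vectors
#'
#' For each simulated set size, probes are drawn uniformly with replacement
#' `set_size` at a time, for `iterations` independent draws; counts become
#' weights via [weight_from_counts()]. The defaults — set sizes 10, 15, 20,
#' 30, 50, 75, 100, 150, 200, 300 with 5000 iterations each — produce
#' 50,000 candidate weight vectors.
#'
#' @param probe_ids Probe labels to weight.
#' @param set_sizes Simulated probe-set sizes.
#' @param iterations Random draws per set size.
#' @param seed Integer seed; recorded in the output for provenance.
#' @return Object of class `weight_candidates`: `weights` (candidates x
#'   probes matrix), `counts` (integer matrix), `set_size` and `iteration`
#'   per candidate, `seed`.
#' @export
simulate_weight_sets <- function(probe_ids,
                                 set_sizes = c(10, 15, 20, 30, 50, 75, 100, 150, 200, 300),
                                 iterations = 5000, seed = 1L) {
  stopifnot(length(probe_ids) > 0, iterations > 0)
  k <- length(probe_ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- do.call(rbind, lapply(set_sizes, function(s) {
    t(stats::rmultinom(iterations, size = s, prob = rep(1 / k, k)))
  }))
  colnames(counts) <- probe_ids
  sizes <- rep(set_sizes, each = iterations)
  structure(list(weights = counts / sizes,
                 counts = counts,
                 set_size = sizes,
                 iteration = rep(seq_len(iterations), times = length(set_sizes)),
                 seed = seed),
            class = "weight_candidates")
}

#' @export
print.weight_candidates <- function(x, ...) {
  cat(sprintf("%d candidate weight vectors over %d probes (set sizes: %s; seed %d)\n",
              nrow(x$weights), ncol(x$weights),
              paste(unique(x$set_size), collapse = ", "), x$seed))
  invisible(x)
}

#' Weighted average methylation score of a sample
#'
#' @param beta A `beta_vector` or named numeric vector of per-probe betas.
#' @param w A `weight_vector`, or a named numeric weight vector.
#' @return The scalar score `sum(w_i * beta_i)`.
#' @export
weighted_average <- function(beta, w) {
  if (inherits(beta, "beta_vector")) beta <- beta$beta
  if (inherits(w, "weight_vector")) w <- w$weights
  if (is.null(names(w)) || is.null(names(beta))) {
    stopifnot(length(w) == length(beta))
  } else {
    beta <- beta[names(w)]
  }
  active <- w > 0
  if (anyNA(beta[active])) {
    stop("missing beta at positively weighted probe(s): ",
         paste(names(w)[active & is.na(beta)], collapse = ", "))
  }
  sum(w[active] * beta[active])
}

#' Select the best-performing candidate weight vector on a training cohort
#'
#' Every candidate's weighted scores stratify the training cohort at its
#' mean and are scored by the signed log-rank P (see [signed_p()]).
#' Selection minimizes its monotone form, the one-sided `directional_p`:
#' the best candidate is the one most strongly confirming the hypothesized
#' direction (methylation-high group survives longer). On a cohort with a
#' direction-consistent effect this coincides with picking the smallest
#' confirming signed P; unlike minimizing the raw signed value, it never
#' prefers a wrong-direction split. Ties go to the earliest candidate.
#' Candidates producing a degenerate split are skipped.
#'
#' Weights trained on one cohort are meant to be applied unchanged to
#' another (cross-cancer or cross-specimen weighting); this function never
#' refits anything on the application cohort.
#'
#' @param candidates A `weight_candidates` object, or a candidates x probes
#'   numeric matrix.
#' @param training_betas Samples x probes matrix/data frame of betas,
#'   columns named by probe.
#' @param training_clinical Data frame with `time` and `event` columns,
#'   rows matching `training_betas`.
#' @return A `weight_vector` with attributes `signed_p` (its training
#'   performance) and `candidate_index`.
#' @export
select_best_weights <- function(candidates, training_betas, training_clinical) {
  W <- if (inherits(candidates, "weight_candidates")) candidates$weights else candidates
  if (nrow(W) == 0) stop("no candidate weight vectors")
  bm <- as.matrix(as.data.frame(training_betas)[, colnames(W), drop = FALSE])
  if (anyNA(bm)) stop("training beta matrix has missing values; impute first")
  scores <- bm %*% t(W)  # samples x candidates
  time <- training_clinical$time
  event <- training_clinical$event
  best_val <- Inf; best_i <- NA_integer_; best_signed <- NA_real_
  for (j in seq_len(ncol(scores))) {
    sp <- tryCatch({
      g <- split_by_mean(scores[, j])
      signed_p(g, time, event)
    }, error = function(e) NULL)
    if (!is.null(sp) && sp$directional_p < best_val) {
      best_val <- sp$directional_p; best_i <- j; best_signed <- sp$signed_value
    }
  }
  if (is.na(best_i)) stop("degenerate training cohort: no candidate produced a valid split")
  is_wc <- inherits(candidates, "weight_candidates")
  out <- structure(list(weights = W[best_i, ],
                        counts = if (is_wc) candidates$counts[best_i, ],
                        set_size = if (is_wc) candidates$set_size[best_i]),
                   class = "weight_vector")
  attr(out, "signed_p") <- best_signed
  attr(out, "directional_p") <- best_val
  attr(out, "candidate_index") <- best_i
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
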