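#' Paired per-probe methylation differences between two timepoints
#'
#' Inner-joins two beta matrices on patient id and returns per-probe deltas
#' `later - baseline`, so that hypomethylation at the later timepoint (e.g.
#' tumor progression) appears as a negative delta. Patients present at only
#' one timepoint are reported, not silently dropped.
#'
#' @param betas_t0,betas_t1 Data frames with a `patient_id` column and one
#'   column per probe (baseline and later timepoint respectively).
#' @param probes Probe columns to difference (default: all shared columns
#'   other than `patient_id`).
#' @return Data frame of class `paired_deltas`: `patient_id` plus one delta
#'   column per probe, with attribute `unmatched` listing patients missing
#'   from either timepoint.
#' @export
paired_deltas <- function(betas_t0, betas_t1, probes = NULL) {
  t0 <- as.data.frame(betas_t0); t1 <- as.data.frame(betas_t1)
  stopifnot("patient_id" %in% names(t0), "patient_id" %in% names(t1))
  if (is.null(probes)) {
    probes <- setdiff(intersect(names(t0), names(t1)), "patient_id")
  }
  common <- intersect(t0$patient_id, t1$patient_id)
  if (length(common) == 0) stop("no patients matched between timepoints")
  i0 <- match(common, t0$patient_id); i1 <- match(common, t1$patient_id)
  d <- as.data.frame(t1[i1, probes, drop = FALSE] - t0[i0, probes, drop = FALSE])
  out <- cbind(data.frame(patient_id = common, stringsAsFactors = FALSE), d)
  rownames(out) <- NULL
  attr(out, "unmatched") <- list(
    t0_only = setdiff(t0$patient_id, common),
    t1_only = setdiff(t1$patient_id, common))
  class(out) <- c("paired_deltas", class(out))
  out
}

#' One-sided test for methylation loss per probe
#'
#' One-sample t-test of mean(delta) < 0 for each probe, the test for
#' progressive hypomethylation between timepoints. Zero-variance deltas are
#' a degenerate limit: P is 0 if the common delta is negative, 1 if
#' positive, and 0.5 if every delta is exactly zero.
#'
#' @param deltas A `paired_deltas` data frame (or any data frame of delta
#'   columns, a `patient_id` column being ignored).
#' @return Data frame: `probe`, `mean_delta`, `p` (one-sided, less), `stars`.
#' @export
test_hypomethylation <- function(deltas) {
  d <- as.data.frame(deltas)
  d$patient_id <- NULL
  res <- lapply(names(d), function(pr) {
    x <- d[[pr]][!is.na(d[[pr]])]
    if (length(x) < 3) stop("probe ", pr, ": need at least 3 paired observations")
    if (stats::sd(x) == 0) {
      p <- if (mean(x) < 0) 0 else if (mean(x) > 0) 1 else 0.5
    } else {
      p <- stats::t.test(x, mu = 0, alternative = "less")$p.value
    }
    data.frame(probe = pr, mean_delta = mean(x), p = p,
               stars = p_stars(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Count samples with increased/decreased methylation per probe
#'
#' @param deltas A `paired_deltas` data frame.
#' @return Data frame: `probe`, `n_increase` (delta > 0), `n_decrease`
#'   (delta < 0), `n_zero`.
#' @export
direction_counts <- function(deltas) {
  d <- as.data.frame(deltas)
  d$patient_id <- NULL
  do.call(rbind, lapply(names(d), function(pr) {
    x <- d[[pr]][!is.na(d[[pr]])]
    data.frame(probe = pr, n_increase = sum(x > 0), n_decrease = sum(x < 0),
               n_zero = sum(x == 0), stringsAsFactors = FALSE)
  }))
}

#' Named probe subsets used for monitoring summaries
#'
#' `five_probe_subset()` returns P2, P3, P5, P8, P9 — the probes with the
#' most significant methylation loss at disease progression;
#' `four_probe_subset()` returns P2, P3, P8, P9, the set used for
#' early-during-treatment comparisons where P5's direction is inconsistent.
#'
#' @return Character vector of probe ids.
#' @export
five_probe_subset <- function() c("P2", "P3", "P5", "P8", "P9")

#' @rdname five_probe_subset
#' @export
four_probe_subset <- function() c("P2", "P3", "P8", "P9")

#' Unweighted mean beta over a probe subset
#'
#' @param beta A `beta_vector` or named numeric vector of betas.
#' @param probes Probe ids to average (e.g. [five_probe_subset()]).
#' @return Mean of the requested betas.
#' @export
subset_average <- function(beta, probes) {
  if (inherits(beta, "beta_vector")) beta <- beta$beta
  missing_p <- setdiff(probes, names(beta))
  if (length(missing_p) > 0) stop("probes absent: ", paste(missing_p, collapse = ", "))
  vals <- beta[probes]
  if (anyNA(vals)) {
    stop("missing beta for probe(s): ", paste(probes[is.na(vals)], collapse = ", "))
  }
  mean(vals)
}
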