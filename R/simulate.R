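#' Specification of a synthetic ICB cohort
#'
#' Defines the generative model for in silico cohorts. Each patient carries
#' a true tumor methylation vector over the panel probes, generated on the
#' logit scale as a probe-level mean plus a shared patient-level global
#' methylation factor (genome-wide hypomethylation shifts all probes
#' together) plus probe-level noise. Specimens are two-component mixtures
#' of tumor and non-malignant DNA:
#' \deqn{tissue_j = p \cdot m_j + (1-p) \cdot normal,\qquad
#'       cfDNA_j = f \cdot m_j + (1-f) \cdot normal,}
#' with tissue tumor purity `p` and ctDNA fraction `f` drawn independently
#' of each other — the construction under which tissue betas are confounded
#' by purity while cfDNA betas are not. PBMC samples are the normal
#' compartment alone. Observed betas add binomial measurement noise at the
#' assay read depth.
#'
#' Survival is exponential with a log-linear hazard in the patient's mean
#' tumor methylation, `h = h0 * exp(-gamma * (mbar - mean(mbar)))`, so
#' hypomethylated tumors progress faster when `gamma > 0`; `gamma = 0` is
#' the null. Durable clinical benefit (DCB) is assigned when the
#' methylation-linked latent score (mbar plus noise) exceeds the cohort
#' quantile implied by `response_rate`.
#'
#' @param n_patients Number of patients.
#' @param probe_means Per-probe mean tumor methylation (defaults: ten
#'   values in 0.45-0.65, non-CpG probes lowest).
#' @param patient_sd SD of the patient-level global factor (logit scale).
#' @param probe_noise_sd SD of per-probe noise (logit scale).
#' @param normal_level Methylation of non-malignant (PBMC-like) DNA.
#' @param purity_range Uniform range for tissue tumor purity `p`.
#' @param ctdna_range Uniform range for cfDNA tumor fraction `f`.
#' @param pbmc_noise_sd Gaussian jitter on the PBMC level (pre-binomial).
#' @param assay_depth Reads per probe for binomial measurement noise.
#' @param h0 Baseline hazard (per month).
#' @param gamma Survival effect size of mean methylation (>= 0).
#' @param censor_time Administrative censoring horizon (months).
#' @param response_rate Expected fraction of DCB responders.
#' @param response_noise_sd Noise on the response latent score.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100,
                        probe_means = c(P1 = 0.62, P2 = 0.58, P3 = 0.65,
                                        P4 = 0.60, P5 = 0.55, P6 = 0.63,
                                        P7 = 0.59, P8 = 0.52, P9 = 0.48,
                                        P10 = 0.45),
                        patient_sd = 0.4, probe_noise_sd = 0.15,
                        normal_level = 0.85,
                        purity_range = c(0.1, 0.9),
                        ctdna_range = c(0.15, 0.25),
                        pbmc_noise_sd = 0.01,
                        assay_depth = 5000,
                        h0 = 0.08, gamma = 6,
                        censor_time = 36,
                        response_rate = 0.35, response_noise_sd = 0.05,
                        seed = 1L) {
  stopifnot(n_patients >= 2, gamma >= 0,
            all(probe_means > 0 & probe_means < 1),
            normal_level >= 0 && normal_level <= 1,
            all(purity_range >= 0 & purity_range <= 1),
            all(ctdna_range >= 0 & ctdna_range <= 1),
            response_rate > 0 && response_rate < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a full cohort: beta matrices, clinical table, and ground truth
#'
#' Deterministic under `spec$seed`. Produces per-specimen-source beta
#' matrices (tissue, cfDNA, PBMC), a clinical table with survival and
#' response labels, and the truth table of latent quantities (true tumor
#' methylation, purity, ctDNA fraction) that tests can condition on.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `simulated_cohort`: `tissue`, `cfdna`, `pbmc`
#'   (data frames: `sample_id`, `patient_id`, probe columns), `clinical`
#'   (`sample_id`, `patient_id`, `time`, `event`, `response`,
#'   `endpoint_kind`, `timepoint`), `truth` (per-patient `m` matrix,
#'   `purity`, `ctdna_fraction`, `mbar`, noise-free mixture betas), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  truth <- draw_truth(spec)
  tissue <- measure_betas(truth$tissue_true, spec$assay_depth)
  cfdna <- measure_betas(truth$cfdna_true, spec$assay_depth)
  pbmc <- measure_betas(truth$pbmc_true, spec$assay_depth)
  clin <- draw_clinical(spec, truth$mbar)
  pid <- sprintf("PT%03d", seq_len(spec$n_patients))
  as_df <- function(b) cbind(data.frame(sample_id = pid, patient_id = pid,
                                        stringsAsFactors = FALSE),
                             as.data.frame(b))
  structure(list(tissue = as_df(tissue), cfdna = as_df(cfdna),
                 pbmc = as_df(pbmc),
                 clinical = cbind(data.frame(sample_id = pid, patient_id = pid,
                                             stringsAsFactors = FALSE), clin),
                 truth = truth, spec = spec),
            class = "simulated_cohort")
}

draw_truth <- function(spec) {
  n <- spec$n_patients
  k <- length(spec$probe_means)
  z <- stats::rnorm(n, 0, spec$patient_sd)
  eps <- matrix(stats::rnorm(n * k, 0, spec$probe_noise_sd), n, k)
  m <- stats::plogis(sweep(eps, 2, stats::qlogis(spec$probe_means), `+`) + z)
  colnames(m) <- names(spec$probe_means)
  p <- stats::runif(n, spec$purity_range[1], spec$purity_range[2])
  f <- stats::runif(n, spec$ctdna_range[1], spec$ctdna_range[2])
  nl <- spec$normal_level
  pbmc_lvl <- matrix(nl + stats::rnorm(n * k, 0, spec$pbmc_noise_sd), n, k,
                     dimnames = list(NULL, colnames(m)))
  pbmc_lvl[pbmc_lvl < 0] <- 0
  pbmc_lvl[pbmc_lvl > 1] <- 1
  list(m = m, purity = p, ctdna_fraction = f, mbar = rowMeans(m),
       tissue_true = p * m + (1 - p) * nl,
       cfdna_true = f * m + (1 - f) * nl,
       pbmc_true = pbmc_lvl)
}

measure_betas <- function(true_beta, depth) {
  obs <- matrix(stats::rbinom(length(true_beta), depth, as.vector(true_beta)) / depth,
                nrow = nrow(true_beta), dimnames = dimnames(true_beta))
  obs
}

draw_clinical <- function(spec, mbar) {
  n <- length(mbar)
  hazard <- spec$h0 * exp(-spec$gamma * (mbar - mean(mbar)))
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- pmin(spec$censor_time, stats::runif(n, spec$censor_time / 3, spec$censor_time))
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  latent <- mbar + stats::rnorm(n, 0, spec$response_noise_sd)
  thr <- stats::quantile(latent, 1 - spec$response_rate)
  data.frame(time = time, event = event,
             response = ifelse(latent > thr, "DCB", "NDB"),
             endpoint_kind = "overall", timepoint = "baseline",
             stringsAsFactors = FALSE)
}

#' Simulate matched baseline and progression cfDNA beta matrices
#'
#' Reuses one cohort's latent truth, then models disease progression as a
#' downward drift of the true tumor methylation together with a rise in
#' ctDNA fraction (higher tumor burden), and re-measures cfDNA betas at
#' both timepoints. With `drift = 0` the cohort is stable and the paired
#' deltas are pure measurement noise.
#'
#' @param spec A [cohort_spec()].
#' @param drift Absolute decrease in true tumor methylation at progression.
#' @param f_gain Absolute increase in ctDNA fraction at progression
#'   (capped at 0.95).
#' @return List: `baseline` and `progression` beta data frames (with
#'   `patient_id`), plus `truth`.
#' @export
simulate_progression <- function(spec, drift = 0.08, f_gain = 0.15) {
  stopifnot(inherits(spec, "cohort_spec"), drift >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  truth <- draw_truth(spec)
  m1 <- pmax(truth$m - drift, 0.01)
  f1 <- pmin(truth$ctdna_fraction + f_gain, 0.95)
  nl <- spec$normal_level
  t0 <- measure_betas(truth$cfdna_true, spec$assay_depth)
  t1 <- measure_betas(f1 * m1 + (1 - f1) * nl, spec$assay_depth)
  pid <- sprintf("PT%03d", seq_len(spec$n_patients))
  list(baseline = cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
                        as.data.frame(t0)),
       progression = cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
                           as.data.frame(t1)),
       truth = c(truth, list(m_progression = m1, ctdna_fraction_progression = f1)))
}

#' Simulate bisulfite amplicon reads with known truth
#'
#' Generates reads from the panel's probes under the measurement model the
#' quantification pipeline inverts: each read picks a strand uniformly;
#' each target cytosine is methylated with the probe's probability `m`
#' (independently per read and site); every unmethylated or naive cytosine
#' converts (C to T on Watson, G to A on Crick in Watson coordinates) with
#' probability `conversion_rate`. Crick reads are emitted as the
#' reverse-complement of their Watson-coordinate representation, i.e. as
#' sequenced. Reads optionally carry a single 1-nt insertion or deletion at
#' a uniform position with probability `indel_rate`.
#'
#' Under this model the expected uncorrected methylation fraction is
#' `m + (1 - m) * (1 - c)` and the conversion-corrected beta converges to
#' `(m + (1 - m) * (1 - c)) * c`.
#'
#' @param panel An `amplicon_panel`.
#' @param m Per-probe methylation probability: named vector or single value
#'   recycled over probes.
#' @param conversion_rate Bisulfite conversion probability in (0, 1].
#' @param depth Reads per probe.
#' @param indel_rate Per-read probability of one random 1-nt indel.
#' @param seed Integer seed.
#' @param fastq Optional path; if given, reads are also written as FASTQ.
#' @return List of class `simulated_reads`: `reads` (named
#'   `DNAStringSet`), `truth` (data frame: `read_id`, `probe_id`, `strand`,
#'   `has_indel`), `m`, `conversion_rate`.
#' @export
simulate_reads <- function(panel, m, conversion_rate = 1, depth = 1000,
                           indel_rate = 0, seed = 1L, fastq = NULL) {
  stopifnot(conversion_rate > 0, conversion_rate <= 1,
            all(m >= 0 & m <= 1), indel_rate >= 0, indel_rate <= 1)
  pids <- vapply(panel, `[[`, "", "probe_id")
  if (length(m) == 1) m <- setNames(rep(m, length(pids)), pids)
  if (is.null(names(m))) names(m) <- pids
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (depth == 0) {
    warning("depth 0: returning empty read set")
    return(structure(list(reads = Biostrings::DNAStringSet(),
                          truth = data.frame(), m = m,
                          conversion_rate = conversion_rate),
                     class = "simulated_reads"))
  }
  all_seq <- character(0); truth <- list()
  for (p in panel) {
    strands <- sample(c("watson", "crick"), depth, replace = TRUE)
    seqs <- character(depth)
    nw <- sum(strands == "watson")
    if (nw > 0) {
      seqs[strands == "watson"] <-
        sim_strand_reads(p, nw, m[[p$probe_id]], conversion_rate, "watson")
    }
    if (depth - nw > 0) {
      seqs[strands == "crick"] <-
        sim_strand_reads(p, depth - nw, m[[p$probe_id]], conversion_rate, "crick")
    }
    has_indel <- stats::runif(depth) < indel_rate
    seqs[has_indel] <- vapply(seqs[has_indel], add_random_indel, "")
    ids <- sprintf("%s_read%05d", p$probe_id, seq_len(depth))
    all_seq <- c(all_seq, setNames(seqs, ids))
    truth[[p$probe_id]] <- data.frame(read_id = ids, probe_id = p$probe_id,
                                      strand = strands, has_indel = has_indel,
                                      stringsAsFactors = FALSE)
  }
  reads <- Biostrings::DNAStringSet(all_seq)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  structure(list(reads = reads, truth = do.call(rbind, truth), m = m,
                 conversion_rate = conversion_rate),
            class = "simulated_reads")
}

# one strand's reads for one probe, in sequencing orientation
sim_strand_reads <- function(p, n, m, c_rate, strand) {
  rc <- strsplit(p$reference_seq, "")[[1]]
  L <- length(rc)
  mat <- matrix(rc, nrow = n, ncol = L, byrow = TRUE)
  if (strand == "watson") {
    tgt_cols <- p$target_offsets + 1L
    for (col in which(rc == "C")) {
      if (col %in% tgt_cols) {
        meth <- stats::runif(n) < m
        conv <- stats::runif(n) < c_rate
        mat[, col] <- ifelse(meth, "C", ifelse(conv, "T", "C"))
      } else {
        mat[, col] <- ifelse(stats::runif(n) < c_rate, "T", "C")
      }
    }
    apply(mat, 1, paste, collapse = "")
  } else {
    # Crick-strand cytosines sit opposite Watson guanines; the guanine
    # paired with a CpG target's Crick cytosine is at offset + 1
    cpg_g_cols <- p$target_offsets[p$site_context == "CpG"] + 2L
    for (col in which(rc == "G")) {
      if (col %in% cpg_g_cols) {
        meth <- stats::runif(n) < m
        conv <- stats::runif(n) < c_rate
        mat[, col] <- ifelse(meth, "G", ifelse(conv, "A", "G"))
      } else {
        mat[, col] <- ifelse(stats::runif(n) < c_rate, "A", "G")
      }
    }
    rev_comp_vec(apply(mat, 1, paste, collapse = ""))
  }
}

add_random_indel <- function(seq) {
  L <- nchar(seq)
  pos <- sample(2:(L - 1), 1)
  if (stats::runif(1) < 0.5) {
    paste0(substr(seq, 1, pos), sample(c("A", "C", "G", "T"), 1),
           substr(seq, pos + 1, L))
  } else {
    paste0(substr(seq, 1, pos - 1), substr(seq, pos + 1, L))
  }
}

#' Write reads to FASTQ
#'
#' @param reads A named `DNAStringSet`.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads),
           function(w) paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}
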