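#' Assign bisulfite amplicon reads to panel probes and strands
#'
#' Each read is compared, in both orientations, against the two bisulfite
#' templates of every probe (Watson: all C->T; Crick in Watson coordinates:
#' all G->A). A read is assigned to the (probe, strand) whose template it
#' matches best. Bisulfite-consistent differences — a retained (methylated
#' or unconverted) C where the Watson template has T, or a retained G where
#' the Crick template has A — are not counted as mismatches.
#'
#' Reads whose length equals the template length are scored by direct
#' per-position comparison; remaining reads (typically those carrying
#' indels) fall back to global gapped alignment, from which indel intervals
#' in template coordinates are recovered.
#'
#' @param reads A `DNAStringSet`, character vector of read sequences, or a
#'   path to a FASTQ file.
#' @param panel An `amplicon_panel` from [load_panel()].
#' @param max_mismatch_frac Maximum tolerated fraction of (bisulfite-
#'   inconsistent) mismatches for a read to be assigned; reads above it are
#'   returned with `probe_id = NA`.
#' @param min_read_length Reads shorter than this are dropped before
#'   assignment (adapter-trimming length floor).
#'
#' @return A data frame of class `assigned_reads`, one row per retained
#'   read: `read_id`, `probe_id` (NA if unassigned), `strand`
#'   (`"watson"`/`"crick"`), `n_mismatches`, `has_indel`, `aligned` (the
#'   read in template coordinates, deletions as `-`), and list columns
#'   `indel_start`/`indel_end` (0-based half-open template intervals).
#' @export
assign_reads <- function(reads, panel, max_mismatch_frac = 0.1,
                         min_read_length = 30L) {
  reads <- as_read_strings(reads)
  if (length(reads) == 0) return(empty_assigned())
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  keep <- nchar(reads) >= min_read_length
  n_short <- sum(!keep)
  reads <- reads[keep]; ids <- ids[keep]
  if (length(reads) == 0) {
    out <- empty_assigned(); attr(out, "n_short") <- n_short; return(out)
  }

  tmpl <- template_table(panel)
  fwd <- toupper(reads)
  rev <- rev_comp_vec(fwd)

  n <- length(reads)
  best_mm <- rep(Inf, n); best_t <- rep(NA_integer_, n); best_or <- rep(NA_integer_, n)
  # fast path: ungapped per-position scoring where read length == template length
  for (ti in seq_len(nrow(tmpl))) {
    tlen <- tmpl$len[ti]
    idx <- which(nchar(fwd) == tlen)
    if (length(idx) == 0) next
    for (ori in 1:2) {
      obs <- if (ori == 1) fwd[idx] else rev[idx]
      mm <- ungapped_mismatches(obs, tmpl$seq[ti], tmpl$strand[ti])
      upd <- mm < best_mm[idx]
      best_mm[idx[upd]] <- mm[upd]; best_t[idx[upd]] <- ti; best_or[idx[upd]] <- ori
    }
  }
  tlen_of <- tmpl$len
  ok_fast <- !is.na(best_t) & best_mm / tlen_of[pmax(best_t, 1L)] <= max_mismatch_frac

  rows <- vector("list", n)
  for (i in which(ok_fast)) {
    ti <- best_t[i]
    rows[[i]] <- list(probe_id = tmpl$probe_id[ti], strand = tmpl$strand[ti],
                      n_mismatches = best_mm[i], has_indel = FALSE,
                      aligned = if (best_or[i] == 1) fwd[i] else rev[i],
                      indel_start = integer(), indel_end = integer())
  }

  slow <- which(!ok_fast)
  if (length(slow) > 0) {
    srows <- gapped_assign(fwd[slow], rev[slow], tmpl, max_mismatch_frac)
    for (k in seq_along(slow)) rows[[slow[k]]] <- srows[[k]]
  }

  out <- data.frame(
    read_id = ids,
    probe_id = vapply(rows, function(r) r$probe_id, ""),
    strand = vapply(rows, function(r) r$strand, ""),
    n_mismatches = vapply(rows, function(r) r$n_mismatches, 0),
    has_indel = vapply(rows, function(r) r$has_indel, FALSE),
    aligned = vapply(rows, function(r) r$aligned, ""),
    stringsAsFactors = FALSE
  )
  out$probe_id[out$probe_id == ""] <- NA_character_
  out$strand[out$strand == ""] <- NA_character_
  out$indel_start <- I(lapply(rows, function(r) r$indel_start))
  out$indel_end <- I(lapply(rows, function(r) r$indel_end))
  class(out) <- c("assigned_reads", class(out))
  attr(out, "n_short") <- n_short
  out
}

as_read_strings <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  if (inherits(reads, "XStringSet")) {
    out <- as.character(reads)
    names(out) <- names(reads)
    return(out)
  }
  if (is.character(reads)) return(reads)
  stop("reads must be a DNAStringSet, character vector, or FASTQ path")
}

empty_assigned <- function() {
  out <- data.frame(read_id = character(), probe_id = character(),
                    strand = character(), n_mismatches = numeric(),
                    has_indel = logical(), aligned = character(),
                    stringsAsFactors = FALSE)
  out$indel_start <- I(list()); out$indel_end <- I(list())
  class(out) <- c("assigned_reads", class(out))
  out
}

template_table <- function(panel) {
  refs <- bisulfite_references(panel)
  pid <- rep(names(refs), each = 2)
  strand <- rep(c("watson", "crick"), length(refs))
  seqs <- unlist(lapply(refs, function(r) c(r$watson, r$crick)), use.names = FALSE)
  data.frame(probe_id = pid, strand = strand, seq = seqs,
             len = nchar(seqs), stringsAsFactors = FALSE)
}

# mismatches against a same-length template, ignoring bisulfite-consistent
# retained bases (C@T for watson templates, G@A for crick templates)
ungapped_mismatches <- function(obs, template, strand) {
  tb <- strsplit(template, "")[[1]]
  ob <- matrix(unlist(strsplit(obs, ""), use.names = FALSE),
               nrow = length(obs), byrow = TRUE)
  tmat <- matrix(tb, nrow = length(obs), ncol = length(tb), byrow = TRUE)
  diff <- ob != tmat
  if (strand == "watson") {
    diff[ob == "C" & tmat == "T"] <- FALSE
  } else {
    diff[ob == "G" & tmat == "A"] <- FALSE
  }
  rowSums(diff)
}

# gapped fallback: align both orientations against every template,
# pick the best-scoring combination, recover indels from the gapped strings
gapped_assign <- function(fwd, rev, tmpl, max_mismatch_frac) {
  n <- length(fwd)
  nt <- nrow(tmpl)
  scores <- array(-Inf, dim = c(n, nt, 2))
  alns <- vector("list", nt * 2)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (ti in seq_len(nt)) {
    for (ori in 1:2) {
      pat <- Biostrings::DNAStringSet(if (ori == 1) fwd else rev)
      al <- Biostrings::pairwiseAlignment(
        pat, Biostrings::DNAString(tmpl$seq[ti]), type = "global",
        substitutionMatrix = submat, gapOpening = 4, gapExtension = 1
      )
      scores[, ti, ori] <- Biostrings::score(al)
      alns[[(ti - 1) * 2 + ori]] <- al
    }
  }
  lapply(seq_len(n), function(i) {
    flat <- scores[i, , ]
    best <- which(flat == max(flat), arr.ind = TRUE)[1, ]
    ti <- best[1]; ori <- best[2]
    al <- alns[[(ti - 1) * 2 + ori]][i]
    parsed <- parse_gapped(al, tmpl$strand[ti])
    if (parsed$n_mismatches / tmpl$len[ti] > max_mismatch_frac) {
      return(list(probe_id = "", strand = "", n_mismatches = parsed$n_mismatches,
                  has_indel = FALSE, aligned = "",
                  indel_start = integer(), indel_end = integer()))
    }
    list(probe_id = tmpl$probe_id[ti], strand = tmpl$strand[ti],
         n_mismatches = parsed$n_mismatches,
         has_indel = length(parsed$indel_start) > 0,
         aligned = parsed$aligned,
         indel_start = parsed$indel_start, indel_end = parsed$indel_end)
  })
}

# walk the gapped pattern/subject strings once; produce the read in subject
# (template) coordinates and 0-based half-open indel intervals
parse_gapped <- function(al, strand) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  aligned <- character(0)
  ins_s <- integer(0); ins_e <- integer(0)
  del_s <- integer(0); del_e <- integer(0)
  spos <- 0L  # subject bases consumed
  mism <- 0L
  j <- 1L
  while (j <= length(p)) {
    if (s[j] == "-") {               # insertion in read
      ins_s <- c(ins_s, spos); ins_e <- c(ins_e, spos + 1L)
      j <- j + 1L
      next
    }
    if (p[j] == "-") {               # deletion in read
      d0 <- spos
      while (j <= length(p) && s[j] != "-" && p[j] == "-") {
        aligned <- c(aligned, "-"); spos <- spos + 1L; j <- j + 1L
      }
      del_s <- c(del_s, d0); del_e <- c(del_e, spos)
      next
    }
    aligned <- c(aligned, p[j])
    consistent <- (strand == "watson" && p[j] == "C" && s[j] == "T") ||
                  (strand == "crick" && p[j] == "G" && s[j] == "A")
    if (p[j] != s[j] && !consistent) mism <- mism + 1L
    spos <- spos + 1L
    j <- j + 1L
  }
  starts <- c(ins_s, del_s); ends <- c(ins_e, del_e)
  o <- order(starts)
  list(aligned = paste(aligned, collapse = ""), n_mismatches = mism,
       indel_start = starts[o], indel_end = ends[o])
}

#' Remove reads with indels near the target region
#'
#' Reads carrying an insertion or deletion inside the probe's target region
#' extended by `window` nucleotides on each side (the half-open interval
#' `[region_start - window, region_end + window)`) are removed; the count
#' of removed reads is attached as attribute `n_removed`.
#'
#' @param assigned An `assigned_reads` data frame from [assign_reads()].
#' @param panel The `amplicon_panel` the reads were assigned to.
#' @param window Flank width in nucleotides (default 30).
#' @return The filtered `assigned_reads` data frame.
#' @export
filter_indel_reads <- function(assigned, panel, window = 30L) {
  if (window < 0) stop("window must be non-negative")
  if (nrow(assigned) == 0) return(assigned)
  drop <- vapply(seq_len(nrow(assigned)), function(i) {
    pid <- assigned$probe_id[i]
    if (is.na(pid) || !assigned$has_indel[i]) return(FALSE)
    p <- panel[[pid]]
    lo <- max(0L, p$region_start - window)
    hi <- p$region_end + window
    any(assigned$indel_start[[i]] < hi & assigned$indel_end[[i]] > lo)
  }, FALSE)
  out <- assigned[!drop, , drop = FALSE]
  class(out) <- class(assigned)
  attr(out, "n_removed") <- sum(drop)
  attr(out, "n_short") <- attr(assigned, "n_short")
  out
}

#' Count methylated and converted bases for one probe
#'
#' Pools methylation evidence over all target sites and both strands of a
#' probe. At a CpG target with cytosine offset `i`, Watson-strand reads are
#' scored at `i` (C = methylated, T = converted) and Crick-strand reads at
#' `i + 1`, the guanine paired with the Crick-strand cytosine (G =
#' methylated, A = converted). CpA methylation is strand-asymmetric, so CpA
#' targets are scored on Watson reads only. Other bases (including deletions)
#' contribute nothing.
#'
#' @param assigned Filtered `assigned_reads` for this probe's sample.
#' @param probe A `probe_target` from the panel.
#' @param context_mode `"cpg_and_cpa"` scores every annotated target;
#'   `"cpg_only"` restricts to CpG-context targets (used when comparing
#'   against methylation-array readouts of the non-CpG probes).
#' @return List of class `probe_counts`: `probe_id`, `M`, `U`, `depth`.
#' @export
count_methylation <- function(assigned, probe,
                              context_mode = c("cpg_and_cpa", "cpg_only")) {
  context_mode <- match.arg(context_mode)
  if (length(probe$target_offsets) == 0) {
    stop("probe ", probe$probe_id, " has no target offsets")
  }
  keep_ctx <- if (context_mode == "cpg_only") "CpG" else c("CpG", "CpA")
  offs <- probe$target_offsets[probe$site_context %in% keep_ctx]
  ctxs <- probe$site_context[probe$site_context %in% keep_ctx]
  rows <- assigned[!is.na(assigned$probe_id) & assigned$probe_id == probe$probe_id, ]
  w <- rows$aligned[rows$strand == "watson"]
  c_ <- rows$aligned[rows$strand == "crick"]
  M <- 0L; U <- 0L
  for (k in seq_along(offs)) {
    off <- offs[k]
    if (length(w) > 0) {
      b <- substr(w, off + 1L, off + 1L)
      M <- M + sum(b == "C"); U <- U + sum(b == "T")
    }
    if (ctxs[k] == "CpG" && length(c_) > 0) {
      b <- substr(c_, off + 2L, off + 2L)
      M <- M + sum(b == "G"); U <- U + sum(b == "A")
    }
  }
  structure(list(probe_id = probe$probe_id, M = M, U = U, depth = nrow(rows)),
            class = "probe_counts")
}

#' Estimate the per-sample bisulfite conversion rate
#'
#' At each annotated naive cytosine (non-CpG/CpA context, assumed
#' unmethylated), the conversion fraction is the proportion of Watson-strand
#' reads showing T (converted) among T + C calls. The sample conversion rate
#' is the unweighted mean of the per-position fractions over positions with
#' at least one observation.
#'
#' @param assigned Filtered `assigned_reads` for the sample.
#' @param panel The `amplicon_panel`.
#' @return List of class `conversion_estimate`: `rate`, `n_observations`,
#'   `n_positions`.
#' @export
estimate_conversion_rate <- function(assigned, panel) {
  fracs <- numeric(0); n_obs <- 0L
  for (p in panel) {
    w <- assigned$aligned[!is.na(assigned$probe_id) &
                            assigned$probe_id == p$probe_id &
                            assigned$strand == "watson"]
    if (length(w) == 0) next
    for (off in p$naive_c_offsets) {
      b <- substr(w, off + 1L, off + 1L)
      conv <- sum(b == "T"); unconv <- sum(b == "C")
      if (conv + unconv > 0) {
        fracs <- c(fracs, conv / (conv + unconv))
        n_obs <- n_obs + conv + unconv
      }
    }
  }
  if (length(fracs) == 0) stop("conversion rate unavailable: no naive cytosine observations")
  structure(list(rate = mean(fracs), n_observations = n_obs,
                 n_positions = length(fracs)),
            class = "conversion_estimate")
}

#' Conversion-corrected beta value from methylation counts
#'
#' The raw methylation fraction `M / (U + M)` is multiplied by the sample
#' bisulfite conversion rate, correcting for unconverted (falsely
#' methylated-looking) cytosines, and clipped to `[0, 1]`. Probes with no
#' informative calls or with read depth below `min_depth` yield `NA`.
#'
#' @param counts A `probe_counts` object, or a numeric `M`.
#' @param conversion A `conversion_estimate`, or a numeric rate in `[0, 1]`.
#' @param U Unmethylated count (when `counts` is numeric `M`).
#' @param min_depth Minimum contributing reads for a reportable beta.
#' @return Beta value in `[0, 1]`, or `NA_real_` if unquantifiable.
#' @examples
#' compute_beta(90, 0.99, U = 10)  # 0.891
#' @export
compute_beta <- function(counts, conversion, U = NULL, min_depth = 0L) {
  if (inherits(counts, "probe_counts")) {
    M <- counts$M; U <- counts$U; depth <- counts$depth
  } else {
    M <- counts; depth <- Inf
  }
  rate <- if (inherits(conversion, "conversion_estimate")) conversion$rate else conversion
  if (is.na(rate) || rate < 0 || rate > 1) stop("conversion rate must be in [0, 1]")
  if (M + U == 0 || depth < min_depth) return(NA_real_)
  min(1, max(0, M / (U + M) * rate))
}

#' Quantify one sample from raw reads to a beta vector
#'
#' Runs the full per-sample pipeline: read assignment, indel-read filtering,
#' strand-separated methylation counting per probe, conversion-rate
#' estimation from naive cytosines, and conversion-corrected beta values.
#'
#' @param reads Reads as accepted by [assign_reads()], or an already
#'   assigned `assigned_reads` data frame (e.g. from [assigned_from_bam()]).
#' @param panel An `amplicon_panel`.
#' @param sample_id Sample label.
#' @param window Indel filter flank (nt), see [filter_indel_reads()].
#' @param min_depth Minimum per-probe read depth for a reportable beta.
#' @param context_mode `"auto"` scores every annotated target per probe
#'   (CpG and, where annotated, CpA); `"cpg_only"` restricts all probes to
#'   CpG-context targets.
#' @param ... Passed to [assign_reads()].
#' @return Object of class `beta_vector`: `sample_id`, `beta` (named numeric
#'   per probe, `NA` = missing), `conversion_rate`, `per_probe_depth`, and a
#'   `qc` list (reads in, assigned, indel-removed, short-removed).
#' @export
quantify_sample <- function(reads, panel, sample_id = "sample",
                            window = 30L, min_depth = 100L,
                            context_mode = c("auto", "cpg_only"), ...) {
  context_mode <- match.arg(context_mode)
  assigned <- if (inherits(reads, "assigned_reads")) reads
              else assign_reads(reads, panel, ...)
  n_in <- nrow(assigned) + (attr(assigned, "n_short") %||% 0L)
  filtered <- filter_indel_reads(assigned, panel, window = window)
  conv <- tryCatch(estimate_conversion_rate(filtered, panel),
                   error = function(e) NULL)
  mode <- if (context_mode == "auto") "cpg_and_cpa" else "cpg_only"
  beta <- depth <- setNames(rep(NA_real_, length(panel)),
                            vapply(panel, `[[`, "", "probe_id"))
  for (p in panel) {
    cnt <- count_methylation(filtered, p, context_mode = mode)
    depth[p$probe_id] <- cnt$depth
    beta[p$probe_id] <- if (is.null(conv)) NA_real_
      else compute_beta(cnt, conv, min_depth = min_depth)
  }
  structure(list(
    sample_id = sample_id,
    beta = beta,
    conversion_rate = if (is.null(conv)) NA_real_ else conv$rate,
    per_probe_depth = depth,
    qc = list(
      n_reads = n_in,
      n_assigned = sum(!is.na(filtered$probe_id)),
      n_indel_removed = attr(filtered, "n_removed") %||% 0L,
      n_short_removed = attr(assigned, "n_short") %||% 0L,
      conversion_available = !is.null(conv)
    )
  ), class = "beta_vector")
}

#' @export
print.beta_vector <- function(x, ...) {
  cat(sprintf("Sample %s: conversion rate %.4f, %d/%d probes quantified\n",
              x$sample_id, x$conversion_rate, sum(!is.na(x$beta)), length(x$beta)))
  print(round(x$beta, 4))
  invisible(x)
}

#' Ingest pre-aligned reads from SAM/BAM
#'
#' For users who align reads externally against the panel's bisulfite
#' templates: reference names must be `<probe_id>_watson` or
#' `<probe_id>_crick`. CIGAR strings are parsed to place read bases in
#' template coordinates and to recover indel intervals; positions the read
#' does not cover are padded with `.` and contribute no counts.
#'
#' @param path Path to a BAM file, or a SAM text file (converted on the fly).
#' @param panel The `amplicon_panel` the references correspond to.
#' @return An `assigned_reads` data frame, as from [assign_reads()].
#' @export
assigned_from_bam <- function(path, panel) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq")))[[1]]
  tmpl <- template_table(panel)
  tlen <- setNames(tmpl$len, paste(tmpl$probe_id, tmpl$strand, sep = "_"))
  tseq <- setNames(tmpl$seq, paste(tmpl$probe_id, tmpl$strand, sep = "_"))
  n <- length(b$qname)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- as.character(b$rname[i])
    if (is.na(ref) || !ref %in% names(tlen)) next
    parts <- strsplit(ref, "_")[[1]]
    strand <- parts[length(parts)]
    pid <- paste(parts[-length(parts)], collapse = "_")
    parsed <- apply_cigar(as.character(b$seq[i]), b$cigar[i], b$pos[i], tlen[[ref]])
    mm <- gapped_mismatch_count(parsed$aligned, tseq[[ref]], strand)
    rows[[i]] <- list(read_id = b$qname[i], probe_id = pid, strand = strand,
                      n_mismatches = mm,
                      has_indel = length(parsed$indel_start) > 0,
                      aligned = parsed$aligned,
                      indel_start = parsed$indel_start,
                      indel_end = parsed$indel_end)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_assigned())
  out <- data.frame(
    read_id = vapply(rows, `[[`, "", "read_id"),
    probe_id = vapply(rows, `[[`, "", "probe_id"),
    strand = vapply(rows, `[[`, "", "strand"),
    n_mismatches = vapply(rows, `[[`, 0, "n_mismatches"),
    has_indel = vapply(rows, `[[`, FALSE, "has_indel"),
    aligned = vapply(rows, `[[`, "", "aligned"),
    stringsAsFactors = FALSE
  )
  out$indel_start <- I(lapply(rows, `[[`, "indel_start"))
  out$indel_end <- I(lapply(rows, `[[`, "indel_end"))
  class(out) <- c("assigned_reads", class(out))
  out
}

# place read bases in 0-based template coordinates per CIGAR (M/=/X/I/D/S/H)
apply_cigar <- function(seq, cigar, pos, tlen) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]", "", ops))
  codes <- sub("\\d+", "", ops)
  out <- rep(".", tlen)
  spos <- pos - 1L  # 0-based template cursor
  rpos <- 1L        # 1-based read cursor
  ins_s <- integer(0); ins_e <- integer(0); del_s <- integer(0); del_e <- integer(0)
  for (k in seq_along(codes)) {
    L <- lens[k]
    switch(codes[k],
      "M" = , "=" = , "X" = {
        idx <- spos + seq_len(L)
        ok <- idx >= 1 & idx <= tlen
        out[idx[ok]] <- strsplit(substr(seq, rpos, rpos + L - 1L), "")[[1]][ok]
        spos <- spos + L; rpos <- rpos + L
      },
      "I" = { ins_s <- c(ins_s, spos); ins_e <- c(ins_e, spos + 1L); rpos <- rpos + L },
      "D" = , "N" = {
        idx <- spos + seq_len(L)
        out[idx[idx >= 1 & idx <= tlen]] <- "-"
        del_s <- c(del_s, spos); del_e <- c(del_e, spos + L)
        spos <- spos + L
      },
      "S" = { rpos <- rpos + L },
      "H" = , "P" = {}
    )
  }
  list(aligned = paste(out, collapse = ""),
       indel_start = c(ins_s, del_s), indel_end = c(ins_e, del_e))
}

gapped_mismatch_count <- function(aligned, template, strand) {
  a <- strsplit(aligned, "")[[1]]
  t <- strsplit(template, "")[[1]]
  cov <- a %in% c("A", "C", "G", "T")
  diff <- cov & a != t
  if (strand == "watson") diff[a == "C" & t == "T"] <- FALSE
  else diff[a == "G" & t == "A"] <- FALSE
  sum(diff)
}

rev_comp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
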