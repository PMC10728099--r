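#' Load an amplicon panel from FASTA and a site annotation table
#'
#' An amplicon panel bundles the unconverted (genomic, Watson-strand)
#' reference sequence of each LINE-1 probe amplicon together with the
#' annotated cytosine positions used downstream: *target* cytosines (CpG
#' context, plus CpA context for the non-CpG probes) whose methylation is
#' scored, and *naive* cytosines (CpC/CpT context, assumed unmethylated)
#' used to estimate the per-sample bisulfite conversion rate.
#'
#' All offsets are 0-based; the target region of a probe is the half-open
#' interval `[region_start, region_end)` spanning its target offsets.
#'
#' @param panel_fasta Path to a FASTA file whose record names are probe ids.
#' @param sites_table Path to a tab-separated table with columns
#'   `probe_id`, `offset` (0-based), `context` (`CpG`/`CpA` for targets,
#'   `CpC`/`CpT` for naive cytosines) and `role` (`target` or `naive`).
#' @param primer_length Number of terminal bases on each end treated as the
#'   forward/reverse primer footprint (default 20).
#'
#' @return An object of class `amplicon_panel`: a list of `probe_target`
#'   records (fields `probe_id`, `reference_seq`, `target_offsets`,
#'   `site_context`, `naive_c_offsets`, `primer_fwd`, `primer_rev`,
#'   `region_start`, `region_end`) with attribute `total_naive_c`.
#'
#' @examples
#' panel <- default_panel()
#' length(panel)           # 10 probes
#' total_naive_c(panel)    # 92 naive cytosines
#' @export
load_panel <- function(panel_fasta, sites_table, primer_length = 20L) {
  seqs <- Biostrings::readDNAStringSet(panel_fasta)
  sites <- utils::read.delim(sites_table, stringsAsFactors = FALSE)
  required <- c("probe_id", "offset", "context", "role")
  if (!all(required %in% names(sites))) {
    stop("sites table must have columns: ", paste(required, collapse = ", "))
  }
  build_panel(setNames(as.character(seqs), names(seqs)), sites, primer_length)
}

#' @rdname load_panel
#' @param sequences Named character vector of probe reference sequences.
#' @param sites Data frame of site annotations (see `sites_table`).
#' @export
build_panel <- function(sequences, sites, primer_length = 20L) {
  unknown <- setdiff(unique(sites$probe_id), names(sequences))
  if (length(unknown) > 0) {
    stop("sites table references unknown probe(s): ", paste(unknown, collapse = ", "))
  }
  probes <- lapply(names(sequences), function(pid) {
    seq <- toupper(sequences[[pid]])
    len <- nchar(seq)
    ps <- sites[sites$probe_id == pid, , drop = FALSE]
    validate_sites(pid, seq, ps)
    tgt <- ps[ps$role == "target", , drop = FALSE]
    tgt <- tgt[order(tgt$offset), , drop = FALSE]
    nai <- sort(ps$offset[ps$role == "naive"])
    structure(list(
      probe_id = pid,
      reference_seq = seq,
      target_offsets = as.integer(tgt$offset),
      site_context = as.character(tgt$context),
      naive_c_offsets = as.integer(nai),
      primer_fwd = substr(seq, 1L, primer_length),
      primer_rev = rev_comp(substr(seq, len - primer_length + 1L, len)),
      region_start = if (nrow(tgt)) min(tgt$offset) else NA_integer_,
      region_end = if (nrow(tgt)) max(tgt$offset) + 1L else NA_integer_
    ), class = "probe_target")
  })
  names(probes) <- names(sequences)
  if (anyDuplicated(names(probes))) stop("duplicate probe ids in panel")
  structure(probes, class = "amplicon_panel",
            total_naive_c = sum(sites$role == "naive"))
}

validate_sites <- function(pid, seq, ps) {
  bases <- strsplit(seq, "")[[1]]
  len <- length(bases)
  for (i in seq_len(nrow(ps))) {
    off <- ps$offset[i]
    if (off < 0 || off >= len) {
      stop(sprintf("probe %s: offset %d out of range [0, %d)", pid, off, len))
    }
    if (bases[off + 1L] != "C") {
      stop(sprintf("probe %s: base at offset %d is '%s', expected 'C'",
                   pid, off, bases[off + 1L]))
    }
    nxt <- if (off + 2L <= len) bases[off + 2L] else "N"
    ctx <- ps$context[i]
    want <- c(CpG = "G", CpA = "A", CpC = "C", CpT = "T")[ctx]
    if (!is.na(want) && nxt != want) {
      stop(sprintf("probe %s: offset %d annotated %s but next base is '%s'",
                   pid, off, ctx, nxt))
    }
    role <- ps$role[i]
    if (role == "target" && !ctx %in% c("CpG", "CpA")) {
      stop(sprintf("probe %s: target at offset %d must be CpG or CpA context", pid, off))
    }
    if (role == "naive" && ctx %in% c("CpG", "CpA")) {
      stop(sprintf("probe %s: naive cytosine at offset %d must not be CpG/CpA", pid, off))
    }
  }
  both <- intersect(ps$offset[ps$role == "target"], ps$offset[ps$role == "naive"])
  if (length(both) > 0) {
    stop(sprintf("probe %s: offsets annotated both target and naive: %s",
                 pid, paste(both, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @rdname load_panel
#' @export
default_panel <- function() {
  load_panel(
    system.file("extdata", "line1_panel_synthetic.fasta", package = "amplibeta"),
    system.file("extdata", "line1_panel_synthetic_sites.tsv", package = "amplibeta")
  )
}

#' @rdname load_panel
#' @param panel An `amplicon_panel`.
#' @export
total_naive_c <- function(panel) attr(panel, "total_naive_c")

#' @export
`[.amplicon_panel` <- function(x, i) {
  probes <- unclass(x)[i]
  structure(probes, class = "amplicon_panel",
            total_naive_c = sum(vapply(probes, function(p)
              length(p$naive_c_offsets), 0L)))
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d probes, %d target sites, %d naive cytosines\n",
              length(x), sum(vapply(x, function(p) length(p$target_offsets), 0L)),
              total_naive_c(x)))
  for (p in x) {
    cat(sprintf("  %-4s %4d nt, %d targets (%s), %d naive\n",
                p$probe_id, nchar(p$reference_seq), length(p$target_offsets),
                paste(unique(p$site_context), collapse = "+"),
                length(p$naive_c_offsets)))
  }
  invisible(x)
}

#' Write a panel back to FASTA + sites table
#'
#' Inverse of [load_panel()]; re-loading the written files reproduces the
#' panel's sequences, offsets and contexts exactly.
#'
#' @param panel An `amplicon_panel`.
#' @param panel_fasta,sites_table Output paths.
#' @export
write_panel <- function(panel, panel_fasta, sites_table) {
  seqs <- Biostrings::DNAStringSet(vapply(panel, `[[`, "", "reference_seq"))
  names(seqs) <- vapply(panel, `[[`, "", "probe_id")
  Biostrings::writeXStringSet(seqs, panel_fasta)
  rows <- lapply(panel, function(p) {
    bases <- strsplit(p$reference_seq, "")[[1]]
    nai_ctx <- ifelse(bases[p$naive_c_offsets + 2L] == "C", "CpC", "CpT")
    rbind(
      data.frame(probe_id = p$probe_id, offset = p$target_offsets,
                 context = p$site_context, role = "target"),
      if (length(p$naive_c_offsets))
        data.frame(probe_id = p$probe_id, offset = p$naive_c_offsets,
                   context = nai_ctx, role = "naive")
    )
  })
  utils::write.table(do.call(rbind, rows), sites_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Bisulfite-converted template sequences for a panel
#'
#' Full bisulfite conversion turns every unmethylated cytosine into thymine.
#' Reads from the converted Watson strand therefore align to the reference
#' with all C replaced by T; reads from the converted Crick strand, expressed
#' in Watson coordinates, align to the reference with all G replaced by A.
#' These two templates per probe are the alignment targets for read
#' assignment. The function is idempotent: converting a converted template
#' leaves it unchanged.
#'
#' @param panel An `amplicon_panel`.
#' @return Named list (per probe) of `list(watson =, crick =)` template
#'   strings, each the same length as the probe reference.
#' @examples
#' bisulfite_references(default_panel())$P1$watson  # contains no "C"
#' @export
bisulfite_references <- function(panel) {
  out <- lapply(panel, function(p) {
    list(watson = chartr("C", "T", p$reference_seq),
         crick  = chartr("G", "A", p$reference_seq))
  })
  names(out) <- vapply(panel, `[[`, "", "probe_id")
  out
}

#' Sequencing depth needed for a given per-locus methylation resolution
#'
#' For a panel of amplicons mapping to `n_loci` genomic copies, resolving
#' methylation differences of `resolution` (e.g. 0.005 for 0.5%) at each
#' locus requires `1/resolution` informative reads per locus, i.e.
#' `n_loci / resolution` reads in total. With the roughly 2000 genomic
#' LINE-1 copies covered by the 10-probe panel this gives the 400,000-read
#' per-sample target.
#'
#' @param resolution Smallest methylation difference to resolve, in (0, 1).
#' @param n_loci Number of genomic loci covered by the panel.
#' @return Total number of reads required.
#' @examples
#' reads_required(0.005, 2000)  # 400000
#' @export
reads_required <- function(resolution = 0.005, n_loci = 2000) {
  stopifnot(resolution > 0, resolution < 1, n_loci > 0)
  (1 / resolution) * n_loci
}

rev_comp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}
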