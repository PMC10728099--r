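# Fixtures and independent oracles shared across the suite.
# All fixtures are built in code; offsets below are hand-derived from the
# written sequences and frozen.

# Two-probe toy panel (40 nt each).
# T1: CpG targets at 7, 12, 26; naive cytosines at 16, 17, 32.
# T2: CpG targets at 5, 12, 31; CpA target at 22; naive at 4, 21.
toy_sequences <- function() {
  c(T1 = paste0("ATTGGAACGTTACGTACCTA", "GGATTACGAATTCCGGATAA"),
    T2 = paste0("TTAACCGGTTAACGTTGGCA", "ACCATTGGCAACGTATTGCA"))
}

toy_sites <- function() {
  rbind(
    data.frame(probe_id = "T1", offset = c(7L, 12L, 26L), context = "CpG",
               role = "target"),
    data.frame(probe_id = "T1", offset = c(16L, 17L, 32L),
               context = c("CpC", "CpT", "CpC"), role = "naive"),
    data.frame(probe_id = "T2", offset = c(5L, 12L, 31L), context = "CpG",
               role = "target"),
    data.frame(probe_id = "T2", offset = 22L, context = "CpA", role = "target"),
    data.frame(probe_id = "T2", offset = c(4L, 21L),
               context = c("CpC", "CpC"), role = "naive")
  )
}

toy_panel <- function() build_panel(toy_sequences(), toy_sites(), primer_length = 5L)

# hand-built assigned_reads rows (bypasses the aligner) for counting tests
make_assigned <- function(probe_id, strand, aligned,
                          indel_start = NULL, indel_end = NULL) {
  n <- length(aligned)
  if (is.null(indel_start)) indel_start <- replicate(n, integer(), simplify = FALSE)
  if (is.null(indel_end)) indel_end <- replicate(n, integer(), simplify = FALSE)
  out <- data.frame(read_id = paste0("r", seq_len(n)),
                    probe_id = rep_len(probe_id, n),
                    strand = rep_len(strand, n),
                    n_mismatches = 0,
                    has_indel = lengths(indel_start) > 0,
                    aligned = aligned, stringsAsFactors = FALSE)
  out$indel_start <- I(indel_start)
  out$indel_end <- I(indel_end)
  class(out) <- c("assigned_reads", class(out))
  out
}

rbind_assigned <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    class(x) <- "data.frame"; x
  }))
  class(out) <- c("assigned_reads", class(out))
  out
}

# set one 1-based position of a template string
with_base <- function(template, pos1, base) {
  substr(template, pos1, pos1) <- base
  template
}

# ---- independent oracles ----

# AUC by exhaustive positive-negative pair counting
auc_brute_force <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hand-written log-rank chi-square (textbook O-E-V formula)
logrank_chisq_hand <- function(group1, time, event) {
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tk in times) {
    at_risk <- time >= tk
    n <- sum(at_risk); n1 <- sum(at_risk & group1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# exact permutation P for the log-rank statistic over all label assignments
logrank_permutation_p <- function(group1, time, event) {
  n <- length(time)
  k <- sum(group1)
  obs <- logrank_chisq_hand(group1, time, event)
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2, function(idx) {
    g <- rep(FALSE, n); g[idx] <- TRUE
    logrank_chisq_hand(g, time, event)
  })
  mean(stats >= obs - 1e-12)
}

# closed-form OLS via normal equations
ols_hand <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  drop(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}
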