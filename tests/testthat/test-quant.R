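panel <- toy_panel()
refs <- bisulfite_references(panel)

test_that("template-identical reads are assigned to probe and strand", {
  a <- assign_reads(c(w = refs$T1$watson), panel)
  expect_equal(a$probe_id, "T1")
  expect_equal(a$strand, "watson")
  expect_equal(a$n_mismatches, 0)
  expect_false(a$has_indel)

  # reverse-complement of the Crick template: strand symmetry
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(refs$T1$crick)))
  a <- assign_reads(c(c = rc), panel)
  expect_equal(a$probe_id, "T1")
  expect_equal(a$strand, "crick")
  expect_equal(a$n_mismatches, 0)
})

test_that("methylated bases are not counted as mismatches", {
  # Watson read with retained C at both CpG targets: bisulfite-consistent
  r <- refs$T1$watson
  r <- with_base(r, 8, "C")   # offset 7
  r <- with_base(r, 13, "C")  # offset 12
  a <- assign_reads(c(m = r), panel)
  expect_equal(a$probe_id, "T1")
  expect_equal(a$n_mismatches, 0)
})

test_that("simulated reads are assigned in >= 99% agreement with truth", {
  sr <- simulate_reads(panel, m = c(T1 = 0.8, T2 = 0.3),
                       conversion_rate = 0.99, depth = 500, seed = 42)
  a <- assign_reads(sr$reads, panel)
  truth <- sr$truth[match(a$read_id, sr$truth$read_id), ]
  agree <- !is.na(a$probe_id) & a$probe_id == truth$probe_id &
    a$strand == truth$strand
  expect_gte(mean(agree), 0.99)
})

test_that("empty and malformed read input are handled", {
  a <- assign_reads(character(0), panel)
  expect_equal(nrow(a), 0)
  expect_error(assign_reads(list(1, 2), panel), "reads must be")
})

test_that("indel reads near the target region are filtered, half-open", {
  # single-CpG probe with region [60, 61); filter window [30, 91)
  seq <- paste0(strrep("AT", 30), "CG", strrep("TA", 19))
  p <- build_panel(c(Z = seq),
                   data.frame(probe_id = "Z", offset = 60L, context = "CpG",
                              role = "target"), primer_length = 5L)
  tmpl <- bisulfite_references(p)$Z$watson
  mk <- function(s, e) make_assigned("Z", "watson", tmpl,
                                     indel_start = list(s), indel_end = list(e))
  inside <- mk(60L, 61L)      # deletion in the target region
  at_29 <- mk(29L, 30L)       # 31 nt before region start: outside window
  at_30 <- mk(30L, 31L)       # exactly at window edge: inside
  expect_equal(nrow(filter_indel_reads(inside, p, 30)), 0)
  expect_equal(nrow(filter_indel_reads(at_29, p, 30)), 1)
  expect_equal(nrow(filter_indel_reads(at_30, p, 30)), 0)
  expect_error(filter_indel_reads(inside, p, -1), "non-negative")
})

test_that("indel filtering removes exactly the in-window reads, any order", {
  p1 <- panel$T1  # region [7, 27), window -> [0, 57)
  tmpl <- refs$T1$watson
  clean <- make_assigned("T1", "watson", rep(tmpl, 7))
  bad <- make_assigned("T1", "watson", rep(tmpl, 3),
                       indel_start = list(10L, 20L, 25L),
                       indel_end = list(11L, 22L, 26L))
  mixed <- rbind_assigned(clean, bad)
  out <- filter_indel_reads(mixed, panel, 30)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "n_removed"), 3)
  shuffled <- mixed[c(8, 1, 9, 2, 10, 3:7), ]
  class(shuffled) <- class(mixed)
  out2 <- filter_indel_reads(shuffled, panel, 30)
  expect_setequal(out2$read_id, out$read_id)
})

test_that("methylation counting pools sites and strands", {
  # single-CpG probe: Watson scored at the C, Crick at the paired G
  seq <- paste0(strrep("AT", 10), "CG", strrep("TA", 10))
  p <- build_panel(c(S = seq),
                   data.frame(probe_id = "S", offset = 20L, context = "CpG",
                              role = "target"), primer_length = 5L)
  wt <- bisulfite_references(p)$S$watson
  ct <- bisulfite_references(p)$S$crick
  w_meth <- make_assigned("S", "watson", rep(with_base(wt, 21, "C"), 10))
  expect_equal(count_methylation(w_meth, p$S)$M, 10)
  expect_equal(count_methylation(w_meth, p$S)$U, 0)

  mixed <- rbind_assigned(
    make_assigned("S", "watson", rep(with_base(wt, 21, "C"), 5)),
    make_assigned("S", "watson", rep(wt, 5)),                      # T at target
    make_assigned("S", "crick", rep(with_base(ct, 22, "G"), 5)),   # methylated G
    make_assigned("S", "crick", rep(ct, 5)))                       # converted A
  cnt <- count_methylation(mixed, p$S)
  expect_equal(cnt$M, 10)
  expect_equal(cnt$U, 10)
  expect_equal(cnt$depth, 20)
})

test_that("cpg_only mode drops CpA contributions on non-CpG probes", {
  wt <- refs$T2$watson
  # methylated at CpA target offset 22 only
  r <- make_assigned("T2", "watson", rep(with_base(wt, 23, "C"), 4))
  all_ctx <- count_methylation(r, panel$T2, context_mode = "cpg_and_cpa")
  cpg <- count_methylation(r, panel$T2, context_mode = "cpg_only")
  expect_equal(all_ctx$M, 4)
  expect_equal(cpg$M, 0)
  # CpA sites are Watson-asymmetric: Crick reads add nothing at them
  ct <- refs$T2$crick
  cr <- make_assigned("T2", "crick", rep(ct, 4))
  both <- rbind_assigned(r, cr)
  expect_equal(count_methylation(both, panel$T2, context_mode = "cpg_and_cpa")$M, 4)
  expect_error(count_methylation(r, list(probe_id = "E", target_offsets = integer())),
               "no target offsets")
})

test_that("counting recovers simulated per-site methylation at depth", {
  sr <- simulate_reads(panel["T1"], m = 0.7, conversion_rate = 1,
                       depth = 5000, seed = 9)
  a <- assign_reads(sr$reads, panel["T1"])
  cnt <- count_methylation(a, panel$T1)
  expect_lt(abs(cnt$M / (cnt$M + cnt$U) - 0.7), 0.02)
})

test_that("conversion rate is the mean of per-position fractions", {
  wt <- refs$T1$watson  # naive offsets 16, 17, 32; template has T there
  # position 16: 98/100 converted; positions 17, 32: fully converted
  unconv <- with_base(wt, 17, "C")
  reads <- rbind_assigned(make_assigned("T1", "watson", rep(wt, 98)),
                          make_assigned("T1", "watson", rep(unconv, 2)))
  est <- estimate_conversion_rate(reads, panel["T1"])
  expect_equal(est$rate, mean(c(0.98, 1, 1)))
  expect_equal(est$n_positions, 3)

  all_conv <- make_assigned("T1", "watson", rep(wt, 10))
  expect_equal(estimate_conversion_rate(all_conv, panel["T1"])$rate, 1.0)

  crick_only <- make_assigned("T1", "crick", rep(refs$T1$crick, 10))
  expect_error(estimate_conversion_rate(crick_only, panel["T1"]),
               "conversion rate unavailable")
})

test_that("conversion estimate approaches truth under simulation", {
  sr <- simulate_reads(panel, m = 0.5, conversion_rate = 0.99,
                       depth = 3000, seed = 21)
  a <- assign_reads(sr$reads, panel)
  est <- estimate_conversion_rate(a, panel)
  expect_lt(abs(est$rate - 0.99), 0.005)
})

test_that("beta formula multiplies the raw fraction by the conversion rate", {
  expect_equal(compute_beta(50, 1.0, U = 50), 0.5)
  expect_equal(compute_beta(0, 0.99, U = 200), 0)
  expect_equal(compute_beta(90, 0.99, U = 10), 0.891)
  expect_true(is.na(compute_beta(0, 1, U = 0)))
  expect_error(compute_beta(1, 1.2, U = 1), "must be in")
  cnt <- structure(list(probe_id = "X", M = 10, U = 10, depth = 20),
                   class = "probe_counts")
  expect_true(is.na(compute_beta(cnt, 1, min_depth = 100)))
  expect_equal(compute_beta(cnt, 0.5), 0.25)
})

test_that("beta is monotone in M and scale-invariant in (M, U)", {
  b <- vapply(1:20, function(m) compute_beta(m, 0.98, U = 10), 0)
  expect_true(all(diff(b) > 0))
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(compute_beta(30, 0.97, U = 70),
               compute_beta(3000, 0.97, U = 7000))
})

test_that("quantify_sample composes the pipeline and reports QC", {
  sr <- simulate_reads(panel, m = c(T1 = 0.9, T2 = 0.4), conversion_rate = 0.99,
                       depth = 800, indel_rate = 0.05, seed = 4)
  bv <- quantify_sample(sr$reads, panel, sample_id = "s1", min_depth = 50)
  closed_form <- function(m, c) (m + (1 - m) * (1 - c)) * c
  expect_lt(abs(bv$beta[["T1"]] - closed_form(0.9, 0.99)), 0.02)
  expect_lt(abs(bv$beta[["T2"]] - closed_form(0.4, 0.99)), 0.02)
  expect_gt(bv$qc$n_indel_removed, 0)
  expect_equal(bv$sample_id, "s1")

  empty <- quantify_sample(character(0), panel)
  expect_true(all(is.na(empty$beta)))
  expect_false(empty$qc$conversion_available)
})

test_that("pre-aligned SAM records are ingested with CIGAR placement", {
  tmpl <- refs$T1$watson
  del_seq <- paste0(substr(tmpl, 1, 10), substr(tmpl, 12, 40))  # 1-nt deletion
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:T1_watson\tLN:40"),
    paste0("@SQ\tSN:T1_crick\tLN:40"),
    paste(c("r1", "0", "T1_watson", "1", "60", "40M", "*", "0", "0",
            with_base(tmpl, 8, "C"), strrep("I", 40)), collapse = "\t"),
    paste(c("r2", "0", "T1_watson", "1", "60", "10M1D29M", "*", "0", "0",
            del_seq, strrep("I", 39)), collapse = "\t")
  )
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  a <- assigned_from_bam(path, panel)
  expect_equal(nrow(a), 2)
  expect_equal(a$probe_id, c("T1", "T1"))
  expect_equal(a$strand, c("watson", "watson"))
  expect_false(a$has_indel[1])
  expect_true(a$has_indel[2])
  expect_equal(a$n_mismatches[1], 0)  # retained C is bisulfite-consistent
  expect_equal(substr(a$aligned[2], 11, 11), "-")
  cnt <- count_methylation(a[1, ], panel$T1)
  expect_equal(cnt$M, 1)  # the methylated CpG at offset 7
})
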