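test_that("only locus-spanning, non-duplicate reads are fetched", {
  g <- ac10_genome()
  chrom <- as.character(g$reference[[1]])
  locus <- g$loci
  spanning <- ac10_read(chrom, k = 10, left = 20L)       # [80, 160)
  dup <- ac10_read(chrom, k = 10, left = 15L)
  bam <- write_test_bam(c(
    sam_line("span", "chr1", spanning$start0, spanning$seq, spanning$cigar),
    sam_line("late", "chr1", 105L, substr(chrom, 106L, 160L)),  # [105, 160)
    sam_line("dup", "chr1", dup$start0, dup$seq, dup$cigar, flag = 1024L)
  ), c(chr1 = 400L))
  reads <- fetch_spanning_reads(bam, locus, flank = 1L)
  expect_equal(reads$qname, "span")
  expect_equal(reads$aln_start0, 80L)
  expect_equal(reads$aln_end0, 160L)
  expect_equal(attr(reads, "n_not_spanning"), 1L)
})

test_that("a locus on a contig missing from the BAM is skipped with warning", {
  g <- ac10_genome()
  chrom <- as.character(g$reference[[1]])
  r <- ac10_read(chrom, k = 10)
  bam <- write_test_bam(
    sam_line("a", "chr1", r$start0, r$seq, r$cigar), c(chr1 = 400L))
  other <- msi_loci("chrMissing", 100L, 120L, "AC", 10L)
  expect_warning(reads <- fetch_spanning_reads(bam, other), "absent")
  expect_equal(nrow(reads), 0L)
})

test_that("length and mean-quality filters use strict < with first-failure", {
  mk <- function(len, q) data.frame(
    qname = "r", seq = strrep("A", len), qual = q,
    cigar = paste0(len, "M"), aln_start0 = 0L, aln_end0 = len,
    rejection = NA_character_, repeat_count = NA_integer_,
    stringsAsFactors = FALSE
  )
  cfg <- msi_config(min_read_length = 35, min_read_quality = 20)
  expect_equal(apply_read_filters(mk(30L, strrep("I", 30)), cfg)$rejection,
               "too_short")
  # mean quality 19.9 < 20 fails; exactly 20.0 passes
  q_low <- paste0(strrep("5", 39), "4")   # 39 x Q20 + 1 x Q19
  expect_equal(apply_read_filters(mk(40L, q_low), cfg)$rejection,
               "low_read_quality")
  q_edge <- strrep("5", 40)               # Q20 everywhere
  expect_true(is.na(apply_read_filters(mk(40L, q_edge), cfg)$rejection))
  # a short low-quality read reports only the first failure
  expect_equal(apply_read_filters(mk(30L, strrep("4", 30)), cfg)$rejection,
               "too_short")
})

test_that("repeat counting matches a brute-force string scan", {
  g <- ac10_genome()
  chrom <- as.character(g$reference[[1]])
  locus <- g$loci
  lines <- character(0)
  truth <- c(ins = 12L, refk = 10L, del = 6L)
  for (nm in names(truth)) {
    r <- ac10_read(chrom, k = truth[[nm]], left = 20L)
    lines <- c(lines, sam_line(nm, "chr1", r$start0, r$seq, r$cigar))
  }
  bam <- write_test_bam(lines, c(chr1 = 400L))
  reads <- count_repeats(apply_read_filters(fetch_spanning_reads(bam, locus)),
                         locus)
  got <- stats::setNames(reads$repeat_count, reads$qname)
  expect_equal(got[names(truth)], truth)
  # independent oracle: count copies by scanning the read string directly
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    best <- 0L
    for (p in seq_len(nchar(s) - 1L)) {
      n <- 0L
      while (substr(s, p + 2L * n, p + 2L * n + 1L) == "AC") n <- n + 1L
      best <- max(best, n)
    }
    expect_equal(reads$repeat_count[i], best)
  }
})

test_that("runs touching a read end are rejected as truncated", {
  g <- ac10_genome()
  chrom <- as.character(g$reference[[1]])
  locus <- g$loci
  # read ends exactly at the last run base: 80 bases over [40, 120)
  seq_right <- substr(chrom, 41, 120)
  # read starting exactly at the first run base: [100, 170)
  seq_left <- substr(chrom, 101, 170)
  bam <- write_test_bam(c(
    sam_line("trunc_right", "chr1", 40L, seq_right),
    sam_line("trunc_left", "chr1", 100L, seq_left)
  ), c(chr1 = 400L))
  reads <- count_repeats(
    apply_read_filters(fetch_spanning_reads(bam, locus, flank = 0L)), locus)
  expect_equal(stats::setNames(reads$rejection, reads$qname),
               c(trunc_right = "truncated_run", trunc_left = "truncated_run"))
})

test_that("low-quality runs are rejected after counting", {
  g <- ac10_genome()
  chrom <- as.character(g$reference[[1]])
  locus <- g$loci
  r <- ac10_read(chrom, k = 10, left = 20L)
  # Q40 flanks but Q10 ('+') across the 20-base run
  qual <- paste0(strrep("I", 20), strrep("+", 20), strrep("I", 40))
  bam <- write_test_bam(
    sam_line("lowrun", "chr1", r$start0, r$seq, r$cigar, qual = qual),
    c(chr1 = 400L))
  reads <- count_repeats(
    apply_read_filters(fetch_spanning_reads(bam, locus)), locus,
    msi_config(min_locus_quality = 25))
  expect_equal(reads$rejection, "low_locus_quality")
})

test_that("distributions count accepted reads only and conserve totals", {
  obs <- data.frame(
    qname = letters[1:6],
    seq = "x", qual = "x", cigar = "1M", aln_start0 = 0L, aln_end0 = 1L,
    rejection = c(NA, NA, NA, "too_short", "motif_not_found", NA),
    repeat_count = c(10L, 10L, 12L, NA, NA, 11L),
    stringsAsFactors = FALSE
  )
  d <- build_distribution(obs, "tumor")
  expect_equal(as.vector(d[c("10", "11", "12")]), c(2L, 1L, 1L))
  expect_equal(sum(d), sum(!is.na(obs$repeat_count)))
  expect_equal(attr(d, "role"), "tumor")
  expect_equal(sum(attr(d, "rejections")), 2L)
  empty <- build_distribution(obs[4:5, ], "normal")
  expect_equal(length(empty), 0L)
})

test_that("error-free simulated reads reproduce the drawn distribution", {
  g <- make_reference(n_loci = 4, seed = 13)
  specs <- lapply(seq_len(nrow(g$loci)), function(i) {
    k <- g$loci$ref_repeats[i]
    sim_locus_spec(stats::setNames(c(0.6, 0.4), c(k, k + 2)),
                   depth_normal = 40L)
  })
  sim <- simulate_pair(g$reference, g$loci, specs, seed = 17)
  for (i in seq_len(nrow(g$loci))) {
    locus <- g$loci[i, ]
    d <- count_repeats(apply_read_filters(
      fetch_spanning_reads(sim$normal_bam, locus)), locus)
    emp <- build_distribution(d, "normal")
    tr <- sim$truth[sim$truth$locus == paste0(locus$chrom, ":", locus$start,
                                              "-", locus$end) &
                      sim$truth$role == "normal", ]
    expect_equal(as.vector(emp[as.character(tr$repeat_count)]), tr$reads)
    expect_equal(sum(emp), 40L)
  }
})
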