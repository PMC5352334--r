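test_that("identical seeds give identical genomes and reads", {
  g1 <- make_reference(n_loci = 6, seed = 61)
  g2 <- make_reference(n_loci = 6, seed = 61)
  expect_identical(as.character(g1$reference), as.character(g2$reference))
  expect_identical(as.data.frame(g1$loci), as.data.frame(g2$loci))
  g3 <- make_reference(n_loci = 6, seed = 62)
  expect_false(identical(as.character(g1$reference),
                         as.character(g3$reference)))

  spec <- lapply(g1$loci$ref_repeats, function(k)
    sim_locus_spec(stats::setNames(c(0.7, 0.3), c(k, k - 1)),
                   depth_normal = 15L))
  s1 <- simulate_pair(g1$reference, g1$loci, spec, seed = 9)
  s2 <- simulate_pair(g1$reference, g1$loci, spec, seed = 9)
  reads <- function(bam) Rsamtools::scanBam(bam)[[1]][c("qname", "pos",
                                                        "cigar", "seq")]
  expect_equal(reads(s1$normal_bam), reads(s2$normal_bam))
  expect_identical(s1$truth, s2$truth)
})

test_that("FASTA and truth BED written to disk round-trip", {
  dir <- tempfile("genome")
  g <- make_reference(n_loci = 5, seed = 67, dir = dir)
  expect_true(file.exists(g$fasta))
  expect_true(file.exists(paste0(g$fasta, ".fai")))
  back <- parse_bed(g$bed, reference = g$fasta)
  expect_equal(as.data.frame(back), as.data.frame(g$loci),
               ignore_attr = TRUE)
})

test_that("planted runs cannot extend or re-phase into their flanks", {
  g <- make_reference(n_loci = 10, seed = 71)
  for (i in seq_len(nrow(g$loci))) {
    chrom <- as.character(g$reference[[g$loci$chrom[i]]])
    motif <- g$loci$motif[i]
    u <- nchar(motif)
    left <- substr(chrom, g$loci$start[i], g$loci$start[i])
    right <- substr(chrom, g$loci$end[i] + 1L, g$loci$end[i] + 1L)
    expect_false(left == substr(motif, u, u))
    expect_false(right == substr(motif, 1L, 1L))
  }
})

test_that("overlapping plants are rejected", {
  bad <- data.frame(chrom = "chr1", start = c(300L, 305L),
                    end = c(320L, 325L), motif = "AC",
                    ref_repeats = 10L)
  expect_error(make_reference(loci = bad, seed = 3), "overlap")
})

test_that("read counts conserve the requested depth", {
  g <- make_reference(n_loci = 3, seed = 73)
  specs <- lapply(g$loci$ref_repeats, function(k)
    sim_locus_spec(stats::setNames(1, k), depth_normal = 12L,
                   depth_tumor = 19L))
  sim <- simulate_pair(g$reference, g$loci, specs, seed = 79)
  truth <- sim$truth
  agg <- aggregate(reads ~ locus + role, truth, sum)
  expect_true(all(agg$reads[agg$role == "normal"] == 12L))
  expect_true(all(agg$reads[agg$role == "tumor"] == 19L))
  n_reads <- length(Rsamtools::scanBam(sim$normal_bam)[[1]]$pos)
  expect_equal(n_reads, 3L * 12L)
})

test_that("simulated pairs recover analytic scores through the pipeline", {
  g <- make_reference(n_loci = 4, seed = 83)
  cfg <- msi_config(min_locus_coverage = 20)
  # identical tumor and normal: aggregate exactly 0
  id_specs <- lapply(g$loci$ref_repeats, function(k)
    sim_locus_spec(stats::setNames(c(0.5, 0.5), c(k, k - 1)),
                   depth_normal = 30L))
  sim0 <- simulate_pair(g$reference, g$loci, id_specs, seed = 89)
  # same drawn reads for tumor: copy the normal draw by reusing the seed
  res0 <- score_pair(sim0$normal_bam, sim0$normal_bam, g$loci,
                     g$reference, cfg)
  expect_identical(res0$aggregate_score, 0)
  expect_equal(res0$call, "MSI-negative")

  # per-locus distance equals the L1 distance between the *drawn*
  # empirical distributions (truth table as oracle)
  res <- score_pair(sim0$normal_bam, sim0$tumor_bam, g$loci,
                    g$reference, cfg)
  for (i in seq_len(nrow(g$loci))) {
    id <- paste0(g$loci$chrom[i], ":", g$loci$start[i], "-", g$loci$end[i])
    tr <- sim0$truth[sim0$truth$locus == id, ]
    emp <- function(role) {
      sub <- tr[tr$role == role, ]
      normalize_distribution(
        stats::setNames(sub$reads, sub$repeat_count))
    }
    expect_equal(res$locus_results$distance[i],
                 stepwise_difference(emp("tumor"), emp("normal")),
                 tolerance = 1e-9)
  }
})

test_that("base errors outside the run leave repeat counts intact", {
  g <- make_reference(n_loci = 3, seed = 97)
  specs <- lapply(g$loci$ref_repeats, function(k)
    sim_locus_spec(stats::setNames(1, k), depth_normal = 30L))
  sim <- simulate_pair(g$reference, g$loci, specs, seed = 101,
                       base_error_rate = 0.01)
  res <- score_pair(sim$normal_bam, sim$normal_bam, g$loci, g$reference,
                    msi_config(min_locus_coverage = 10))
  expect_identical(res$aggregate_score, 0)
})
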