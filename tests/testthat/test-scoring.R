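test_that("normalization divides by total support and keeps keys", {
  expect_equal(normalize_distribution(c(`10` = 5, `12` = 15)),
               c(`10` = 0.25, `12` = 0.75))
  expect_equal(normalize_distribution(c(`12` = 30)), c(`12` = 1))
  d <- c(`8` = 3, `9` = 7, `11` = 2)
  expect_equal(normalize_distribution(d), normalize_distribution(d * 10))
  expect_error(normalize_distribution(stats::setNames(numeric(0),
                                                      character(0))),
               "empty")
})

test_that("stepwise difference spans [0,2] with exact endpoints", {
  a <- normalize_distribution(c(`12` = 10, `13` = 30))
  expect_identical(stepwise_difference(a, a), 0)
  expect_identical(stepwise_difference(c(`12` = 1), c(`15` = 1)), 2)
  # |0.5 - 1| + |0.5 - 0| = 1
  expect_equal(stepwise_difference(c(`15` = 0.5, `12` = 0.5), c(`15` = 1)), 1)
})

test_that("stepwise difference equals a dense L1 oracle and is symmetric", {
  set.seed(402)
  for (rep in 1:200) {
    t <- normalize_distribution(random_dist())
    n <- normalize_distribution(random_dist())
    d <- stepwise_difference(t, n)
    # dense-vector L1 over the full integer range of observed lengths
    lo <- min(as.integer(c(names(t), names(n))))
    hi <- max(as.integer(c(names(t), names(n))))
    grid <- as.character(lo:hi)
    tv <- ifelse(grid %in% names(t), t[grid], 0)
    nv <- ifelse(grid %in% names(n), n[grid], 0)
    expect_equal(d, sum(abs(tv - nv)), tolerance = 1e-12)
    expect_identical(d, stepwise_difference(n, t))
    expect_gte(d, 0); expect_lte(d, 2)
    if (length(intersect(names(t), names(n))) == 0L) expect_equal(d, 2)
  }
})

test_that("moving tumor mass to a novel length never decreases d", {
  set.seed(403)
  for (rep in 1:50) {
    n <- normalize_distribution(random_dist())
    t <- n
    shared <- names(t)[1]
    novel <- as.character(max(as.integer(c(names(t), names(n)))) + 1L)
    for (eps in c(0.1, 0.25, 0.5)) {
      moved <- t
      moved[shared] <- t[shared] - eps * t[shared]
      moved[novel] <- eps * t[shared]
      expect_gte(stepwise_difference(moved, n),
                 stepwise_difference(t, n) - 1e-12)
    }
  }
})

test_that("aggregate score averages passing loci and classifies strictly", {
  expect_equal(aggregate_score(c(0, 1, 2)), 1)
  expect_equal(aggregate_score(0.37), 0.37)
  expect_equal(aggregate_score(c(0, 0, NA)), 0)   # discarded loci excluded
  expect_error(aggregate_score(c(NA_real_, NA_real_)), "no evaluable loci")
  expect_equal(classify_msi(0.5, 0.4), "MSI-positive")
  expect_equal(classify_msi(0.4, 0.4), "MSI-negative")
  expect_equal(classify_msi(0, 0.4), "MSI-negative")
})

test_that("depth scaling of either sample leaves the score unchanged", {
  set.seed(404)
  normals <- replicate(15, random_dist(), simplify = FALSE)
  tumors <- replicate(15, random_dist(), simplify = FALSE)
  agg <- function(ns, ts) aggregate_score(mapply(function(n, t) {
    stepwise_difference(normalize_distribution(t), normalize_distribution(n))
  }, ns, ts))
  base <- agg(normals, tumors)
  for (k in c(2L, 10L, 100L)) {
    expect_equal(agg(lapply(normals, `*`, k), tumors), base,
                 tolerance = 1e-12)
    expect_equal(agg(normals, lapply(tumors, `*`, k)), base,
                 tolerance = 1e-12)
  }
})

test_that("score_pair runs end-to-end and writes the two output files", {
  g <- make_reference(n_loci = 6, seed = 29)
  specs <- lapply(seq_len(nrow(g$loci)), function(i) {
    k <- g$loci$ref_repeats[i]
    # half the loci diverge completely, half are identical: mean d = 1
    if (i %% 2 == 1L)
      sim_locus_spec(stats::setNames(1, k), stats::setNames(1, k + 3),
                     depth_normal = 30L)
    else sim_locus_spec(stats::setNames(1, k), depth_normal = 30L)
  })
  sim <- simulate_pair(g$reference, g$loci, specs, seed = 5)
  prefix <- file.path(tempfile("out"), "pair1")
  dir.create(dirname(prefix))
  res <- score_pair(sim$normal_bam, sim$tumor_bam, g$loci, g$reference,
                    msi_config(min_locus_coverage = 20), prefix)
  expect_s3_class(res, "msi_pair")
  expect_equal(res$aggregate_score, 1)
  expect_equal(res$call, "MSI-positive")
  expect_equal(res$n_pass, 6L)

  loci_tab <- read.table(paste0(prefix, ".loci.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(loci_tab), 6L)
  expect_equal(sort(unique(loci_tab$difference)),
               c(0, 2))
  summ <- read.table(paste0(prefix, ".summary.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(summ$V2[summ$V1 == "Average_Difference"], "1.000000")
  expect_equal(summ$V2[summ$V1 == "Call"], "MSI-positive")
})

test_that("locus order does not change any output", {
  g <- make_reference(n_loci = 5, seed = 37)
  # per-locus specs keyed to each locus' own reference count
  specs <- lapply(g$loci$ref_repeats, function(k)
    sim_locus_spec(stats::setNames(c(0.5, 0.5), c(k, k + 2)),
                   depth_normal = 25L))
  sim <- simulate_pair(g$reference, g$loci, specs, seed = 41)
  fwd <- score_pair(sim$normal_bam, sim$tumor_bam, g$loci, g$reference,
                    msi_config(min_locus_coverage = 10))
  rev_loci <- validate_msi_loci(as.data.frame(g$loci)[nrow(g$loci):1, ])
  rev <- score_pair(sim$normal_bam, sim$tumor_bam, rev_loci, g$reference,
                    msi_config(min_locus_coverage = 10))
  expect_equal(fwd$aggregate_score, rev$aggregate_score)
  key <- function(r) r$locus_results[order(r$locus_results$start), ]
  expect_equal(key(fwd), key(rev), ignore_attr = TRUE)
})
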