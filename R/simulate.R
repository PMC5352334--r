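# Deterministic simulation of the caller's inputs: a reference genome
# with planted microsatellites, and paired normal/tumor BAMs whose reads
# carry repeat counts drawn from configurable per-locus distributions.
# Reads are written pre-aligned with computed CIGARs rather than run
# through an aligner: the caller consumes alignments and the method is
# aligner-agnostic, so this removes aligner dependence while keeping the
# truth exactly known.

DNA <- c("A", "C", "G", "T")

#' Generate a reference genome with planted microsatellite loci
#'
#' Builds seeded random background sequence and writes each locus'
#' motif run at its coordinates. Bases immediately flanking a planted
#' run are constrained so the run cannot be extended or re-phased
#' (the left flank never equals the motif's last base, the right flank
#' never its first), and background that happens to form a qualifying
#' microsatellite under `scan_specs` is broken by point substitution,
#' so a scan of the output recovers exactly the planted loci.
#'
#' @param loci an [msi_loci] table to plant, or NULL to auto-place
#'   `n_loci` random loci (motif units 1-6, spaced well apart, away
#'   from chromosome ends).
#' @param n_loci number of loci to auto-place when `loci` is NULL.
#' @param min_ref_repeats lower bound on auto-placed reference copy
#'   numbers (useful when simulated tumors shift repeat counts down and
#'   every locus must leave room for the shift).
#' @param n_chroms,chrom_length genome shape for auto-placement.
#' @param seed RNG seed; identical seeds give identical genomes.
#' @param scan_specs [motif_specs()] the background is scrubbed against.
#' @param dir when non-NULL, writes `<dir>/reference.fa` (with .fai
#'   index) and `<dir>/truth.bed`.
#' @return list with `reference` ([Biostrings::DNAStringSet]), `loci`
#'   (validated [msi_loci]), and when `dir` is given, `fasta` and `bed`
#'   paths.
#' @export
make_reference <- function(loci = NULL, n_loci = 10L, n_chroms = 1L,
                           chrom_length = 4000L, seed = 1L,
                           scan_specs = motif_specs(), dir = NULL,
                           min_ref_repeats = 2L) {
  with_seed(seed, {
    if (is.null(loci))
      loci <- random_locus_plan(n_loci, n_chroms, chrom_length, scan_specs,
                                min_ref_repeats)
    loci <- loci[order(match(loci$chrom, unique(loci$chrom)), loci$start), ]
    chroms <- unique(loci$chrom)
    if (any(loci$start < 0L))
      stop("planted locus out of chromosome bounds")
    seqs <- list()
    for (chrom in chroms) {
      sub <- loci[loci$chrom == chrom, ]
      if (any(sub$end > chrom_length))
        stop("planted locus out of chromosome bounds")
      if (nrow(sub) > 1L &&
          any(sub$start[-1L] < sub$end[-nrow(sub)]))
        stop("planted loci overlap on ", chrom)
      x <- sample(DNA, chrom_length, replace = TRUE)
      for (i in seq_len(nrow(sub))) {
        run <- strsplit(strrep(sub$motif[i], sub$ref_repeats[i]), "")[[1]]
        x[(sub$start[i] + 1L):sub$end[i]] <- run
      }
      x <- fix_flanks(x, sub)
      seqs[[chrom]] <- x
    }
    seqs <- scrub_background(seqs, loci, scan_specs)
    ref <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1), collapse = "")
    )
    names(ref) <- names(seqs)
    loci <- validate_msi_loci(as.data.frame(loci), reference = ref)
    out <- list(reference = ref, loci = loci)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      fasta <- file.path(dir, "reference.fa")
      Biostrings::writeXStringSet(ref, fasta)
      Rsamtools::indexFa(fasta)
      bed <- file.path(dir, "truth.bed")
      write_loci_bed(loci, bed)
      out$fasta <- fasta
      out$bed <- bed
    }
    out
  })
}

# Random but well-separated locus plan covering motif units 1-6.
random_locus_plan <- function(n_loci, n_chroms, chrom_length, scan_specs,
                              min_ref_repeats = 2L) {
  margin <- 200L
  gap <- 80L
  motif_pool <- c("A", "T", "AC", "AG", "CT", "AAG", "ACT", "AGC",
                  "AATC", "AAAGT", "AACGTC")
  motif_pool <- motif_pool[nchar(motif_pool) <= max(scan_specs$unit_length)]
  # cover every unit length first (when n_loci allows), then draw freely
  units <- unique(nchar(motif_pool))
  fixed <- vapply(units, function(u)
    sample(motif_pool[nchar(motif_pool) == u], 1L), character(1))
  motifs <- c(fixed, sample(motif_pool, max(0L, n_loci - length(fixed)),
                            replace = TRUE))[seq_len(n_loci)]
  motifs <- sample(motifs)
  per_chrom <- ceiling(n_loci / n_chroms)
  rows <- list()
  k <- 0L
  for (ci in seq_len(n_chroms)) {
    pos <- margin
    for (j in seq_len(per_chrom)) {
      if (k >= n_loci) break
      motif <- motifs[k + 1L]
      u <- nchar(motif)
      minrep <- max(scan_specs$min_repeats[match(u, scan_specs$unit_length)],
                    min_ref_repeats)
      reps <- sample(minrep:(minrep + ifelse(u == 1L, 10L, 5L)), 1L)
      span <- u * reps
      if (pos + span > chrom_length - margin)
        stop("chromosome too short for ", n_loci, " loci; increase ",
             "chrom_length or n_chroms")
      k <- k + 1L
      rows[[k]] <- data.frame(
        chrom = paste0("chr", ci), start = pos, end = pos + span,
        motif = motif, ref_repeats = reps, stringsAsFactors = FALSE
      )
      pos <- pos + span + gap + sample(0:40, 1L)
    }
  }
  do.call(rbind, rows)
}

# Left flank must differ from the motif's last base (else the run
# re-phases one base earlier); right flank from its first (else it
# extends). Applies to every planted locus on one chromosome.
fix_flanks <- function(x, sub) {
  for (i in seq_len(nrow(sub))) {
    u <- nchar(sub$motif[i])
    lastb <- substr(sub$motif[i], u, u)
    firstb <- substr(sub$motif[i], 1L, 1L)
    lp <- sub$start[i]            # 1-based index of base before the run
    if (lp >= 1L && x[lp] == lastb)
      x[lp] <- sample(setdiff(DNA, c(lastb, x[max(1L, lp - 1L)])), 1L)
    rp <- sub$end[i] + 1L         # 1-based index of base after the run
    if (rp <= length(x) && x[rp] == firstb)
      x[rp] <- sample(setdiff(DNA, c(firstb, x[min(length(x), rp + 1L)])), 1L)
  }
  x
}

# Break any background run that the scanner would report but that was
# not planted, by substituting one base outside all planted runs.
scrub_background <- function(seqs, loci, scan_specs) {
  planted_key <- paste(loci$chrom, loci$start, loci$end, loci$motif)
  for (iter in seq_len(60L)) {
    ref <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1), collapse = "")
    )
    names(ref) <- names(seqs)
    found <- scan_reference(ref, scan_specs)
    key <- paste(found$chrom, found$start, found$end, found$motif)
    spur <- found[!key %in% planted_key, ]
    if (nrow(spur) == 0L) {
      if (!all(planted_key %in% key))
        stop("planted locus lost during background scrubbing")
      return(seqs)
    }
    for (i in seq_len(nrow(spur))) {
      chrom <- spur$chrom[i]
      x <- seqs[[chrom]]
      cand <- (spur$start[i] + 1L):spur$end[i]   # 1-based positions
      inside <- rep(FALSE, length(cand))
      guard <- loci[loci$chrom == chrom, ]
      for (j in seq_len(nrow(guard))) {
        # exclude planted runs and their guarded flank bases
        inside <- inside | (cand >= guard$start[j] &
                            cand <= guard$end[j] + 1L)
      }
      cand <- cand[!inside]
      if (length(cand) == 0L) next   # junction-only; flank fix holds it
      pos <- cand[ceiling(length(cand) / 2)]
      nb <- c(if (pos > 1L) x[pos - 1L], if (pos < length(x)) x[pos + 1L])
      repl <- setdiff(DNA, c(x[pos], nb))
      if (length(repl) == 0L) repl <- setdiff(DNA, x[pos])
      x[pos] <- sample(repl, 1L)
      seqs[[chrom]] <- x
    }
  }
  stop("background scrubbing did not converge")
}

#' Locus simulation specification
#'
#' Per-locus repeat-length distributions and depths for [simulate_pair()].
#'
#' @param normal_dist,tumor_dist named probability vectors (names are
#'   repeat counts); each must sum to 1.
#' @param depth_normal,depth_tumor reads drawn per sample.
#' @return list of class `"sim_locus_spec"`.
#' @export
sim_locus_spec <- function(normal_dist, tumor_dist = normal_dist,
                           depth_normal = 50L, depth_tumor = depth_normal) {
  chk <- function(d, nm) {
    if (is.null(names(d)) || abs(sum(d) - 1) > 1e-9)
      stop(nm, " must be a named probability vector summing to 1")
    if (any(as.integer(names(d)) < 1L)) stop(nm, " repeat counts must be >= 1")
  }
  chk(normal_dist, "normal_dist"); chk(tumor_dist, "tumor_dist")
  if (depth_normal < 1L || depth_tumor < 1L) stop("depths must be >= 1")
  structure(list(normal_dist = normal_dist, tumor_dist = tumor_dist,
                 depth_normal = as.integer(depth_normal),
                 depth_tumor = as.integer(depth_tumor)),
            class = "sim_locus_spec")
}

#' Simulate an aligned tumor-normal pair
#'
#' For each locus and sample, draws per-read repeat counts from the
#' spec's distribution and synthesizes reads that carry reference flank
#' sequence around the locus run replaced by the drawn number of motif
#' copies, with CIGARs encoding the insertion or deletion relative to
#' the reference run. Base errors are applied outside the run at
#' `base_error_rate` (never inside it unless `errors_in_run = TRUE`, so
#' drawn distributions stay exactly recoverable); base qualities are
#' drawn around `quality_mean`. Writes coordinate-sorted, indexed BAMs.
#'
#' @param reference FASTA path or `DNAStringSet` (from
#'   [make_reference()]).
#' @param loci [msi_loci] table of loci to simulate.
#' @param specs list of [sim_locus_spec()] parallel to `loci` rows (a
#'   single spec is recycled).
#' @param read_length read length in bases; must exceed every simulated
#'   run span plus 8 flank bases.
#' @param base_error_rate substitution error probability per non-run base.
#' @param errors_in_run when TRUE, errors may also fall inside the run.
#' @param quality_mean mean Phred base quality.
#' @param seed RNG seed; identical seeds give identical BAMs.
#' @param dir output directory (created).
#' @param prefix file name prefix.
#' @return list with `normal_bam`, `tumor_bam` (indexed BAM paths) and
#'   `truth` (data.frame: `locus`, `role`, `repeat_count`, `reads` -
#'   the drawn distributions).
#' @export
simulate_pair <- function(reference, loci, specs, read_length = 100L,
                          base_error_rate = 0, errors_in_run = FALSE,
                          quality_mean = 35, seed = 1L,
                          dir = tempfile("simpair"), prefix = "pair") {
  ref <- load_reference(reference)
  if (inherits(specs, "sim_locus_spec")) specs <- list(specs)
  if (length(specs) == 1L) specs <- rep(specs, nrow(loci))
  if (length(specs) != nrow(loci))
    stop("need one sim_locus_spec per locus (or a single one to recycle)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  with_seed(seed, {
    chrom_seqs <- stats::setNames(
      lapply(names(ref), function(n) as.character(ref[[n]])), names(ref)
    )
    truth <- list()
    sams <- list(normal = character(0), tumor = character(0))
    for (i in seq_len(nrow(loci))) {
      locus <- loci[i, ]
      spec <- specs[[i]]
      for (role in c("normal", "tumor")) {
        dist <- if (role == "normal") spec$normal_dist else spec$tumor_dist
        depth <- if (role == "normal") spec$depth_normal else spec$depth_tumor
        ks <- as.integer(names(dist))[
          sample.int(length(dist), depth, replace = TRUE, prob = dist)
        ]
        tab <- table(ks)
        truth[[length(truth) + 1L]] <- data.frame(
          locus = locus_id(locus), role = role,
          repeat_count = as.integer(names(tab)),
          reads = as.integer(tab), stringsAsFactors = FALSE
        )
        sams[[role]] <- c(sams[[role]], synth_reads(
          chrom_seqs[[locus$chrom]], locus, ks, read_length,
          base_error_rate, errors_in_run, quality_mean,
          sprintf("%s_%s_L%04d", prefix, role, i)
        ))
      }
    }
    paths <- list()
    for (role in c("normal", "tumor")) {
      sam <- file.path(dir, paste0(prefix, ".", role, ".sam"))
      header <- c("@HD\tVN:1.6\tSO:unknown",
                  paste0("@SQ\tSN:", names(ref), "\tLN:", Biostrings::width(ref)))
      writeLines(c(header, sams[[role]]), sam)
      bam <- Rsamtools::asBam(
        sam, file.path(dir, paste0(prefix, ".", role)),
        overwrite = TRUE, indexDestination = TRUE
      )
      unlink(sam)
      paths[[paste0(role, "_bam")]] <- bam
    }
    list(normal_bam = paths$normal_bam, tumor_bam = paths$tumor_bam,
         truth = do.call(rbind, truth))
  })
}

# SAM alignment lines for `length(ks)` reads over one locus. The drawn
# run (motif x k) replaces the reference run; flank lengths are drawn so
# the read always spans the locus with anchor bases to spare.
synth_reads <- function(chrom_seq, locus, ks, read_length,
                        base_error_rate, errors_in_run, quality_mean,
                        qname_prefix) {
  u <- nchar(locus$motif)
  run_ref <- locus$end - locus$start
  out <- character(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    run_read <- u * k
    if (read_length < run_read + 8L)
      stop("read_length too short for a run of ", k, " x ", locus$motif)
    max_left <- read_length - run_read - 4L
    left <- sample(4:max_left, 1L)
    right <- read_length - left - run_read
    rstart0 <- locus$start - left
    right_ref_end <- locus$end + right
    if (rstart0 < 0L || right_ref_end > nchar(chrom_seq))
      stop("locus too close to chromosome edge for read_length ",
           read_length)
    seq <- paste0(
      substr(chrom_seq, rstart0 + 1L, locus$start),
      strrep(locus$motif, k),
      substr(chrom_seq, locus$end + 1L, right_ref_end)
    )
    cigar <- if (k == locus$ref_repeats) {
      paste0(read_length, "M")
    } else if (k < locus$ref_repeats) {
      paste0(left + run_read, "M", run_ref - run_read, "D", right, "M")
    } else {
      paste0(left + run_ref, "M", run_read - run_ref, "I", right, "M")
    }
    if (base_error_rate > 0) {
      x <- strsplit(seq, "")[[1]]
      eligible <- if (errors_in_run) seq_len(read_length) else
        c(seq_len(left), (left + run_read + 1L):read_length)
      hit <- eligible[stats::runif(length(eligible)) < base_error_rate]
      for (pos in hit) x[pos] <- sample(setdiff(DNA, x[pos]), 1L)
      seq <- paste(x, collapse = "")
    }
    q <- pmin(40L, pmax(2L, round(stats::rnorm(read_length, quality_mean, 3))))
    out[j] <- paste(
      sprintf("%s_%05d", qname_prefix, j), 0L, locus$chrom, rstart0 + 1L,
      60L, cigar, "*", 0L, 0L, seq, int_to_phred(q), sep = "\t"
    )
  }
  out
}

#' Simulate and score a labeled cohort of tumor-normal pairs
#'
#' Builds one reference with planted loci, then for each pair simulates
#' reads and runs the full scoring pipeline. MSS pairs draw tumor reads
#' from the same distribution as the normal (a point mass at the
#' reference repeat count). MSI-H pairs shift half of the tumor
#' probability mass `shift` repeat units below the reference count at
#' the `divergent_loci`, giving an expected per-locus distance of 1 at
#' those loci.
#'
#' @param n_msih,n_mss pairs of each label.
#' @param n_loci planted loci.
#' @param divergent_loci indices of loci that diverge in MSI-H tumors
#'   (default: all).
#' @param depth reads per sample per locus.
#' @param shift tumor repeat-count shift in motif copies.
#' @param shift_mass tumor probability mass moved to the shifted count
#'   in MSI-H pairs (0.5 gives expected distance 1).
#' @param cfg an [msi_config()].
#' @param seed RNG seed.
#' @param dir working directory for BAMs and results.
#' @param base_error_rate,read_length passed to [simulate_pair()].
#' @return list: `results` (named list of `"msi_pair"`), `scores`
#'   (named vector), `labels` (data.frame), `reference`, `loci`,
#'   `divergent_loci` (locus ids), `table` (cohort locus table).
#' @export
simulate_cohort <- function(n_msih = 10L, n_mss = 10L, n_loci = 50L,
                            divergent_loci = seq_len(n_loci),
                            depth = 50L, shift = 2L, shift_mass = 0.5,
                            cfg = msi_config(), seed = 1L,
                            dir = tempfile("simcohort"),
                            base_error_rate = 0, read_length = 100L) {
  genome <- make_reference(
    n_loci = n_loci,
    n_chroms = max(1L, ceiling(n_loci / 15L)),
    seed = seed
  )
  loci <- genome$loci
  point <- function(k) stats::setNames(1, k)
  labels <- data.frame(
    pair_id = sprintf("pair%02d", seq_len(n_msih + n_mss)),
    label = c(rep("MSI-H", n_msih), rep("MSS", n_mss)),
    stringsAsFactors = FALSE
  )
  results <- list()
  for (p in seq_len(nrow(labels))) {
    msih <- labels$label[p] == "MSI-H"
    specs <- lapply(seq_len(nrow(loci)), function(i) {
      ref_k <- loci$ref_repeats[i]
      ndist <- point(ref_k)
      tdist <- if (msih && i %in% divergent_loci) {
        stats::setNames(c(1 - shift_mass, shift_mass),
                        c(ref_k, max(2L, ref_k - shift)))
      } else ndist
      sim_locus_spec(ndist, tdist, depth_normal = depth)
    })
    sim <- simulate_pair(
      genome$reference, loci, specs, read_length = read_length,
      base_error_rate = base_error_rate,
      seed = seed + 1000L + p,
      dir = file.path(dir, labels$pair_id[p]), prefix = labels$pair_id[p]
    )
    results[[labels$pair_id[p]]] <- score_pair(
      sim$normal_bam, sim$tumor_bam, loci, genome$reference, cfg,
      output_prefix = file.path(dir, labels$pair_id[p])
    )
  }
  scores <- vapply(results, `[[`, numeric(1), "aggregate_score")
  list(
    results = results,
    scores = scores,
    labels = labels,
    reference = genome$reference,
    loci = loci,
    divergent_loci = locus_id(loci[divergent_loci, ]),
    table = cohort_locus_table(results, labels)
  )
}
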