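# Read-level processing: extract locus-spanning reads from a BAM,
# apply two-stage quality control, and count motif repeats per read.
# Rejection reasons are assigned in a fixed order (spanning -> length ->
# read quality -> motif location -> truncation -> locus quality); a read
# carries exactly its first failure.

#' Quality-control configuration
#'
#' Thresholds for read- and locus-level filtering, the outlier rule and
#' the classification threshold. Defaults follow whole-exome guidance:
#' reads shorter than 35 bases or with mean base quality below 20 are
#' dropped; the repeat run itself must average Phred >= 25; a locus needs
#' at least 20 supporting reads in each sample; repeat lengths beyond 3
#' standard deviations of a sample's locus mean are discarded as
#' outliers; pairs scoring above 0.4 are called MSI-positive.
#'
#' @param min_read_length minimum read length in bases.
#' @param min_read_quality minimum mean Phred score over the whole read.
#' @param min_locus_quality minimum mean Phred score over the repeat run
#'   within the read.
#' @param min_locus_coverage minimum accepted reads per sample per locus
#'   (applied after outlier removal).
#' @param outlier_sd standard-deviation multiplier for repeat-length
#'   outlier removal.
#' @param flank anchor bases required on each side of the locus for a
#'   read to count as spanning.
#' @param search_window bases around the alignment-projected locus start
#'   searched for the first motif copy within a read.
#' @param threshold instability score above which (strictly) a pair is
#'   called MSI-positive.
#' @return list of class `"msi_config"`.
#' @export
msi_config <- function(min_read_length = 35, min_read_quality = 20,
                       min_locus_quality = 25, min_locus_coverage = 20,
                       outlier_sd = 3.0, flank = 1L, search_window = 2L,
                       threshold = 0.4) {
  if (outlier_sd <= 0) stop("outlier_sd must be > 0")
  if (min(min_read_length, min_read_quality, min_locus_quality,
          min_locus_coverage) < 0)
    stop("quality thresholds must be >= 0")
  structure(list(
    min_read_length = min_read_length,
    min_read_quality = min_read_quality,
    min_locus_quality = min_locus_quality,
    min_locus_coverage = as.integer(min_locus_coverage),
    outlier_sd = outlier_sd,
    flank = as.integer(flank),
    search_window = as.integer(search_window),
    threshold = threshold
  ), class = "msi_config")
}

bam_targets <- function(bam) {
  if (methods::is(bam, "BamFile")) {
    Rsamtools::scanBamHeader(bam)$targets
  } else {
    Rsamtools::scanBamHeader(bam)[[1]]$targets
  }
}

#' Fetch reads spanning a microsatellite locus
#'
#' Extracts reads overlapping the locus from an indexed BAM and keeps
#' those whose aligned reference span fully contains the locus plus
#' `flank` anchor bases on each side. Unmapped, secondary, supplementary
#' and duplicate-flagged reads are excluded at the source.
#'
#' @param bam path to an indexed BAM, or a [Rsamtools::BamFile].
#' @param locus single-row [msi_loci] table (realigned).
#' @param flank anchor bases required on each side.
#' @return data.frame with one row per spanning read: `qname`, `seq`,
#'   `qual` (Phred+33 string), `cigar`, `aln_start0`, `aln_end0`
#'   (0-based half-open), `rejection` (NA), `repeat_count` (NA). The
#'   number of overlapping-but-not-spanning reads is attached as
#'   attribute `"n_not_spanning"`. A locus on a contig absent from the
#'   BAM header yields an empty frame with a warning.
#' @export
fetch_spanning_reads <- function(bam, locus, flank = 1L) {
  targets <- bam_targets(bam)
  empty <- data.frame(
    qname = character(0), seq = character(0), qual = character(0),
    cigar = character(0), aln_start0 = integer(0), aln_end0 = integer(0),
    rejection = character(0), repeat_count = integer(0),
    stringsAsFactors = FALSE
  )
  if (!locus$chrom %in% names(targets)) {
    warning("contig absent from BAM header, locus skipped: ", locus$chrom)
    attr(empty, "n_not_spanning") <- 0L
    return(empty)
  }
  which <- GenomicRanges::GRanges(
    locus$chrom, IRanges::IRanges(locus$start + 1L, locus$end)
  )
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE
    )
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$pos)
  if (n == 0L) {
    attr(empty, "n_not_spanning") <- 0L
    return(empty)
  }
  aln_start0 <- res$pos - 1L
  aln_end0 <- aln_start0 + cigar_ref_width(res$cigar)
  span <- aln_start0 <= locus$start - flank & aln_end0 >= locus$end + flank
  out <- data.frame(
    qname = res$qname[span],
    seq = as.character(res$seq)[span],
    qual = as.character(res$qual)[span],
    cigar = res$cigar[span],
    aln_start0 = aln_start0[span],
    aln_end0 = aln_end0[span],
    rejection = NA_character_,
    repeat_count = NA_integer_,
    stringsAsFactors = FALSE
  )
  attr(out, "n_not_spanning") <- sum(!span)
  out
}

#' Stage-1 read filters: length and mean base quality
#'
#' Marks reads shorter than `min_read_length` as `too_short` and reads
#' whose mean base quality is strictly below `min_read_quality` as
#' `low_read_quality`. Already-rejected reads are left untouched.
#'
#' @param reads data.frame from [fetch_spanning_reads()].
#' @param cfg an [msi_config()].
#' @return the same data.frame with `rejection` filled in.
#' @export
apply_read_filters <- function(reads, cfg = msi_config()) {
  if (nrow(reads) == 0L) return(reads)
  open <- is.na(reads$rejection)
  short <- open & nchar(reads$seq) < cfg$min_read_length
  reads$rejection[short] <- "too_short"
  open <- is.na(reads$rejection)
  if (any(open)) {
    mq <- vapply(reads$qual[open], function(q) mean(phred_to_int(q)),
                 numeric(1), USE.NAMES = FALSE)
    reads$rejection[open][mq < cfg$min_read_quality] <- "low_read_quality"
  }
  reads
}

#' Count motif repeats within each read
#'
#' For every read that passed stage-1 filtering, the locus start is
#' projected through the alignment into read coordinates, the first
#' motif copy is located by exact match within `search_window` bases of
#' that position, and maximal consecutive whole copies of the motif are
#' counted from the run's left-anchored start (partial trailing copies
#' are ignored). Secondary QC then rejects reads whose run touches
#' either end of the read sequence (`truncated_run` - the run may
#' continue beyond the read) and reads whose mean base quality over the
#' run is below `min_locus_quality` (`low_locus_quality`). Exact string
#' matching is deliberate: indels in the run are the signal and must not
#' be repaired through the CIGAR.
#'
#' @param reads data.frame from [apply_read_filters()].
#' @param locus single-row realigned [msi_loci] table.
#' @param cfg an [msi_config()].
#' @return the data.frame with `repeat_count` set for accepted reads and
#'   `rejection` set to `motif_not_found`, `truncated_run` or
#'   `low_locus_quality` otherwise.
#' @export
count_repeats <- function(reads, locus, cfg = msi_config()) {
  if (nrow(reads) == 0L) return(reads)
  motif <- locus$motif
  u <- nchar(motif)
  for (i in which(is.na(reads$rejection))) {
    seq <- reads$seq[i]
    len <- nchar(seq)
    proj <- query_pos_at_ref(reads$cigar[i], reads$aln_start0[i], locus$start)
    if (is.na(proj)) proj <- locus$start - reads$aln_start0[i]
    # nearest exact motif copy within the search window
    run_start <- NA_integer_
    for (off in order(abs(seq(-cfg$search_window, cfg$search_window)))) {
      q <- proj + seq(-cfg$search_window, cfg$search_window)[off]
      if (q < 0L || q + u > len) next
      if (substr(seq, q + 1L, q + u) == motif) { run_start <- q; break }
    }
    if (is.na(run_start)) {
      reads$rejection[i] <- "motif_not_found"
      next
    }
    # left-anchor: extend backwards by whole copies
    while (run_start - u >= 0L &&
           substr(seq, run_start - u + 1L, run_start) == motif)
      run_start <- run_start - u
    copies <- 1L
    while (run_start + (copies + 1L) * u <= len &&
           substr(seq, run_start + copies * u + 1L,
                  run_start + (copies + 1L) * u) == motif)
      copies <- copies + 1L
    run_end <- run_start + copies * u
    # base-level extent of the run (partial copies included), for the
    # truncation test: a run reaching a read edge may continue beyond it
    ext_start <- run_start
    while (ext_start > 0L &&
           substr(seq, ext_start, ext_start) ==
           substr(motif, u - (run_start - ext_start) %% u, u - (run_start - ext_start) %% u))
      ext_start <- ext_start - 1L
    ext_end <- run_end
    while (ext_end < len &&
           substr(seq, ext_end + 1L, ext_end + 1L) ==
           substr(motif, (ext_end - run_start) %% u + 1L, (ext_end - run_start) %% u + 1L))
      ext_end <- ext_end + 1L
    if (ext_start == 0L || ext_end == len) {
      reads$rejection[i] <- "truncated_run"
      next
    }
    runq <- phred_to_int(reads$qual[i])[(run_start + 1L):run_end]
    if (mean(runq) < cfg$min_locus_quality) {
      reads$rejection[i] <- "low_locus_quality"
      next
    }
    reads$repeat_count[i] <- copies
  }
  reads
}

#' Build a repeat-length distribution from processed reads
#'
#' Tallies accepted reads by repeat count. Rejected reads contribute
#' nothing; their rejection tallies are kept for logging.
#'
#' @param reads data.frame from [count_repeats()].
#' @param role `"normal"` or `"tumor"`.
#' @return named integer vector (names are repeat counts, values are
#'   supporting-read counts) with attributes `"role"` and `"rejections"`
#'   (a named tally of rejection reasons).
#' @export
build_distribution <- function(reads, role = c("normal", "tumor")) {
  role <- match.arg(role)
  acc <- reads$repeat_count[!is.na(reads$repeat_count)]
  counts <- if (length(acc)) {
    tab <- table(acc)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  rej <- reads$rejection[!is.na(reads$rejection)]
  attr(counts, "role") <- role
  attr(counts, "rejections") <-
    if (length(rej)) table(rej) else table(character(0))
  counts
}

# Full per-sample, per-locus path: fetch -> filter -> count -> tally.
locus_distribution <- function(bam, locus, cfg = msi_config(),
                               role = "normal") {
  reads <- fetch_spanning_reads(bam, locus, flank = cfg$flank)
  reads <- apply_read_filters(reads, cfg)
  reads <- count_repeats(reads, locus, cfg)
  build_distribution(reads, role)
}
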