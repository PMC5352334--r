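#' Motif length specifications for the microsatellite scanner
#'
#' Defines which repeat unit lengths are scanned and how many consecutive
#' copies a run needs before it is reported. Defaults report homopolymer
#' runs of at least 6 bases and runs of at least 3 copies for units of
#' 2-6 bp; exome microsatellite panels are dominated by mononucleotide
#' runs, which are only informative once reasonably long, while even short
#' multi-base repeats are worth cataloguing.
#'
#' @param min_repeats_mono minimum copies for 1-bp (homopolymer) motifs.
#' @param min_repeats_multi minimum copies for 2-6 bp motifs.
#' @param max_unit largest motif length scanned (1-6).
#' @return data.frame with columns `unit_length`, `min_repeats`.
#' @examples
#' motif_specs()
#' @export
motif_specs <- function(min_repeats_mono = 6L, min_repeats_multi = 3L,
                        max_unit = 6L) {
  max_unit <- as.integer(max_unit)
  if (max_unit < 1L || max_unit > 6L) stop("max_unit must be in [1,6]")
  data.frame(
    unit_length = seq_len(max_unit),
    min_repeats = as.integer(
      ifelse(seq_len(max_unit) == 1L, min_repeats_mono, min_repeats_multi)
    )
  )
}

#' Scan a reference genome for microsatellite loci
#'
#' Finds every maximal run of a primitive 1-6 bp motif meeting the
#' per-unit-length minimum copy number. Runs are reported once, under
#' their primitive motif (a run of `ACACAC` is reported as `(AC)3`, never
#' `(ACAC)1`), left-anchored, with the copy number truncated to whole
#' motif copies. Ambiguous bases (anything other than A/C/G/T) terminate
#' a run. Only the forward strand is scanned: reads are
#' reference-aligned, so both strands observe the forward-strand motif.
#'
#' @param reference FASTA path or [Biostrings::DNAStringSet].
#' @param specs data.frame from [motif_specs()].
#' @return An [msi_loci] table sorted by (chrom, start); chromosome order
#'   follows the reference.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "GGAAAAAATT"))
#' scan_reference(ref, motif_specs())
#' @export
scan_reference <- function(reference, specs = motif_specs()) {
  ref <- load_reference(reference)
  if (!is.data.frame(specs) || nrow(specs) == 0L)
    stop("specs must be a non-empty data.frame (see motif_specs())")
  if (any(specs$unit_length < 1L | specs$unit_length > 6L))
    stop("unit_length must be in [1,6]")
  if (any(specs$min_repeats < 2L))
    stop("min_repeats must be >= 2")

  out <- list()
  for (chrom in names(ref)) {
    x <- strsplit(as.character(ref[[chrom]]), "", fixed = TRUE)[[1]]
    valid <- x %in% c("A", "C", "G", "T")
    L <- length(x)
    for (k in seq_len(nrow(specs))) {
      u <- specs$unit_length[k]
      minrep <- specs$min_repeats[k]
      if (L < u * minrep) next
      idx <- seq_len(L - u)
      m <- (x[idx] == x[idx + u]) & valid[idx] & valid[idx + u]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & (r$lengths + u) %/% u >= minrep)
      for (h in hit) {
        i <- starts[h]                      # 1-based start of match run
        copies <- (r$lengths[h] + u) %/% u
        motif <- paste(x[i:(i + u - 1L)], collapse = "")
        if (!motif_is_primitive(motif)) next   # reported at a shorter unit
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = i - 1L, end = i - 1L + copies * u,
          motif = motif, ref_repeats = copies, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(validate_msi_loci(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      motif = character(0), ref_repeats = integer(0)
    )))
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(match(loci$chrom, names(ref)), loci$start), ]
  validate_msi_loci(loci, reference = ref)
}

#' Write loci to an annotated 6-column BED file
#'
#' The name field encodes the motif and its reference copy number as
#' `(AC)12`; score is a `0` placeholder and strand is `+`. Coordinates
#' are BED-style 0-based half-open.
#'
#' @param loci an [msi_loci] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  loci <- validate_msi_loci(loci)
  lines <- if (nrow(loci)) {
    paste(loci$chrom, loci$start, loci$end, motif_annotation(loci),
          "0", "+", sep = "\t")
  } else character(0)
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write BED file: ", path)
  invisible(path)
}
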