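#' Parse an annotated microsatellite BED file
#'
#' Reads the 6-column BED dialect whose name field carries the motif and
#' its reference copy number, e.g. `(AC)12`. Malformed lines (wrong
#' column count, bad coordinates, name not matching `(<ACGT>)<n>`) are
#' skipped with a warning that carries the line number. Columns 5-6
#' (score, strand) are read but ignored; the scoring algorithm never
#' uses them.
#'
#' @param path BED file path.
#' @param reference optional reference (FASTA path or `DNAStringSet`);
#'   when given, parsed loci are immediately realigned with
#'   [realign_loci()] and only usable loci are returned.
#' @return An [msi_loci] table (coordinates 0-based half-open). The
#'   number of skipped lines is attached as attribute `"n_skipped"`;
#'   when `reference` is given the unusable-locus table from realignment
#'   is attached as attribute `"unusable"`.
#' @export
parse_bed <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  parsed <- vector("list", length(lines))
  bad <- integer(0)
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    ok <- length(f) >= 4L &&
      grepl("^\\d+$", f[2]) && grepl("^\\d+$", f[3]) &&
      grepl("^\\(([ACGT]+)\\)(\\d+)$", f[4])
    if (ok) {
      motif <- sub("^\\(([ACGT]+)\\)(\\d+)$", "\\1", f[4])
      reps <- as.integer(sub("^\\(([ACGT]+)\\)(\\d+)$", "\\2", f[4]))
      start <- as.integer(f[2]); end <- as.integer(f[3])
      ok <- end > start && nchar(motif) <= 6L && reps >= 2L &&
        motif_is_primitive(motif)
    }
    if (!ok) {
      bad <- c(bad, i)
      next
    }
    parsed[[i]] <- data.frame(
      chrom = f[1], start = start, end = end, motif = motif,
      ref_repeats = reps, stringsAsFactors = FALSE
    )
  }
  if (length(bad))
    warning("skipped ", length(bad), " malformed BED line(s): ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "")
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  if (length(parsed) == 0L) stop("no parsable loci in BED file: ", path)
  loci <- do.call(rbind, parsed)
  # Coordinate invariants are only certain after realignment (the file
  # may be 1-based); defer strict validation until then.
  class(loci) <- c("msi_loci", "data.frame")

  if (!is.null(reference)) {
    re <- realign_loci(loci, reference)
    loci <- re$loci
    attr(loci, "unusable") <- re$unusable
  }
  attr(loci, "n_skipped") <- length(bad)
  loci
}

#' Realign loci against the reference genome
#'
#' BED files in the wild disagree about 0- versus 1-based starts. Each
#' locus is re-anchored by testing offsets 0, -1, +1 of its stated start
#' for a copy of the motif, then extended (or trimmed) to the maximal
#' run of whole motif copies at that position, updating `ref_repeats`.
#' Displacements beyond one base are treated as data errors, not
#' silently repaired: such loci are flagged unusable and excluded.
#'
#' @param loci an [msi_loci] table (coordinates possibly off by one).
#' @param reference FASTA path or `DNAStringSet`.
#' @return list with elements `loci` (validated [msi_loci] of usable,
#'   realigned loci) and `unusable` (data.frame of excluded loci with a
#'   `reason` column).
#' @export
realign_loci <- function(loci, reference) {
  ref <- load_reference(reference)
  keep <- vector("list", nrow(loci))
  drop <- list()
  for (i in seq_len(nrow(loci))) {
    r <- realign_locus(loci[i, ], ref)
    if (is.null(r)) {
      drop[[length(drop) + 1L]] <- cbind(
        as.data.frame(loci[i, ]),
        reason = if (loci$chrom[i] %in% names(ref)) "motif_not_at_locus"
                 else "chrom_not_in_reference"
      )
    } else {
      keep[[i]] <- r
    }
  }
  keep <- keep[!vapply(keep, is.null, logical(1))]
  usable <- if (length(keep)) do.call(rbind, keep) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               motif = character(0), ref_repeats = integer(0))
  list(
    loci = validate_msi_loci(usable, reference = ref),
    unusable = if (length(drop)) do.call(rbind, drop) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 motif = character(0), ref_repeats = integer(0),
                 reason = character(0))
  )
}

#' @rdname realign_loci
#' @param locus a single-row locus table.
#' @return `realign_locus` returns the corrected single-row data.frame,
#'   or `NULL` when no motif copy is found at offsets 0/-1/+1.
#' @export
realign_locus <- function(locus, reference) {
  ref <- load_reference(reference)
  if (!locus$chrom %in% names(ref)) return(NULL)
  chrom_seq <- as.character(ref[[locus$chrom]])
  L <- nchar(chrom_seq)
  motif <- locus$motif
  u <- nchar(motif)
  for (off in c(0L, -1L, 1L)) {
    s <- locus$start + off
    if (s < 0L || s + u > L) next
    if (substr(chrom_seq, s + 1L, s + u) != motif) next
    # extend to the maximal run of whole motif copies, keeping phase
    while (s - u >= 0L && substr(chrom_seq, s - u + 1L, s) == motif) s <- s - u
    e <- s + u
    while (e + u <= L && substr(chrom_seq, e + 1L, e + u) == motif) e <- e + u
    copies <- (e - s) %/% u
    if (copies < 2L) next
    return(data.frame(chrom = locus$chrom, start = s, end = e,
                      motif = motif, ref_repeats = copies,
                      stringsAsFactors = FALSE))
  }
  NULL
}
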