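#' Microsatellite locus table
#'
#' Constructs and validates the table of microsatellite loci that every
#' other function in the package consumes. Coordinates are 0-based
#' half-open (BED convention) throughout the package.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open interval of the
#'   repeat run in the reference.
#' @param motif character vector of uppercase DNA motifs (1-6 bp); each
#'   must be primitive, i.e. not itself a repetition of a shorter motif.
#' @param ref_repeats integer vector, number of consecutive motif copies
#'   in the reference (at least 2).
#' @param reference optional [Biostrings::DNAStringSet] (or FASTA path);
#'   when supplied, each locus' reference substring is checked to equal
#'   `motif` repeated `ref_repeats` times.
#'
#' @return A `data.frame` of class `"msi_loci"` with columns `chrom`,
#'   `start`, `end`, `motif`, `ref_repeats`.
#' @examples
#' msi_loci("chr1", 100L, 124L, "AC", 12L)
#' @export
msi_loci <- function(chrom, start, end, motif, ref_repeats,
                     reference = NULL) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    motif = toupper(as.character(motif)),
    ref_repeats = as.integer(ref_repeats),
    stringsAsFactors = FALSE
  )
  validate_msi_loci(df, reference = reference)
}

#' @rdname msi_loci
#' @param x a data.frame with the five locus columns.
#' @export
validate_msi_loci <- function(x, reference = NULL) {
  required <- c("chrom", "start", "end", "motif", "ref_repeats")
  if (!all(required %in% names(x)))
    stop("locus table must have columns: ", paste(required, collapse = ", "))
  x <- x[required]
  if (nrow(x)) {
    ulen <- nchar(x$motif)
    if (any(ulen < 1L | ulen > 6L))
      stop("motif length must be in [1,6]")
    if (any(!grepl("^[ACGT]+$", x$motif)))
      stop("motif must contain only A/C/G/T")
    if (any(x$ref_repeats < 2L))
      stop("ref_repeats must be >= 2")
    if (any(x$end - x$start != ulen * x$ref_repeats))
      stop("end - start must equal motif length * ref_repeats")
    if (any(!vapply(x$motif, motif_is_primitive, logical(1))))
      stop("motif must be primitive (not a power of a shorter motif)")
    if (!is.null(reference)) {
      ref <- load_reference(reference)
      obs <- vapply(seq_len(nrow(x)), function(i) {
        substr_ref(ref, x$chrom[i], x$start[i], x$end[i])
      }, character(1))
      bad <- obs != strrep(x$motif, x$ref_repeats)
      if (any(bad))
        stop("locus sequence does not match motif x ref_repeats at rows: ",
             paste(which(bad), collapse = ", "))
    }
  }
  class(x) <- c("msi_loci", "data.frame")
  rownames(x) <- NULL
  x
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not an exact repetition of any shorter
#' motif ("ACAC" is not primitive; "AC" is).
#'
#' @param motif a single DNA string.
#' @return logical scalar.
#' @export
motif_is_primitive <- function(motif) {
  n <- nchar(motif)
  if (n <= 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L && strrep(substr(motif, 1L, d), n %/% d) == motif)
      return(FALSE)
  }
  TRUE
}

# Smallest period of a string; the primitive unit is substr(s, 1, period).
smallest_period <- function(s) {
  n <- nchar(s)
  for (d in seq_len(n)) {
    if (n %% d == 0L && strrep(substr(s, 1L, d), n %/% d) == s) return(d)
  }
  n
}

locus_id <- function(loci) {
  paste0(loci$chrom, ":", loci$start, "-", loci$end)
}

motif_annotation <- function(loci) {
  paste0("(", loci$motif, ")", loci$ref_repeats)
}

#' @export
print.msi_loci <- function(x, ...) {
  cat("Microsatellite loci: ", nrow(x), " loci\n", sep = "")
  NextMethod()
}
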