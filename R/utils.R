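# Internal helpers shared across modules: reference loading, substring
# access, Phred decoding and CIGAR arithmetic. Coordinates are 0-based
# half-open unless a name says otherwise.

#' Load a reference genome
#'
#' Accepts either a path to a FASTA file or an existing
#' [Biostrings::DNAStringSet] and returns a `DNAStringSet` whose names are
#' the sequence identifiers (description stripped at the first space).
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @return A [Biostrings::DNAStringSet].
#' @export
load_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    ref <- reference
  } else {
    if (!is.character(reference) || length(reference) != 1L ||
        !file.exists(reference))
      stop("reference FASTA not readable: ", reference)
    ref <- Biostrings::readDNAStringSet(reference)
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

# Reference substring over 0-based half-open [start, end).
substr_ref <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) stop("chromosome not in reference: ", chrom)
  as.character(Biostrings::subseq(ref[[chrom]], start + 1L, end))
}

# Phred+33 quality string -> integer vector.
phred_to_int <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

int_to_phred <- function(q) {
  intToUtf8(q + 33L)
}

# Parse a CIGAR string into op/length vectors.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(op = character(0), len = integer(0)))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(
    op = substr(toks, nchar(toks), nchar(toks)),
    len = as.integer(substr(toks, 1L, nchar(toks) - 1L))
  )
}

# Reference bases consumed by an alignment (M/D/N/=/X ops).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Project a 0-based reference position onto the 0-based query (read)
# coordinate by walking the CIGAR. Returns NA when the position falls in
# a deletion/skip or outside the aligned span.
query_pos_at_ref <- function(cigar, aln_start0, ref_pos0) {
  p <- parse_cigar(cigar)
  rpos <- aln_start0
  qpos <- 0L
  for (i in seq_along(p$op)) {
    op <- p$op[i]
    len <- p$len[i]
    if (op %in% c("M", "=", "X")) {
      if (ref_pos0 < rpos + len)
        return(if (ref_pos0 >= rpos) qpos + (ref_pos0 - rpos) else NA_integer_)
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (ref_pos0 < rpos + len) return(NA_integer_)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
  }
  NA_integer_
}

# Deterministic RNG scope: evaluates expr with a locally set seed and
# restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
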