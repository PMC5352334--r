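# Locus ranking across a labeled cohort: difference of averages a,
# coverage proportion c, locus score l = a * c^2, and top-N panels.

#' Assemble a cohort locus table
#'
#' Combines per-pair locus results with gold-standard labels into the
#' long table consumed by [rank_loci()]. A locus' distance is present
#' for a pair only when the locus passed quality control in that pair.
#'
#' @param results named list of `"msi_pair"` objects (names are pair
#'   ids), or a directory of `<pair_id>.loci.tsv` files written by
#'   [score_pair()].
#' @param labels data.frame with columns `pair_id` and `label`
#'   (`"MSI-H"` or `"MSS"`), or a path to a two-column TSV (no header).
#' @return data.frame with one row per (pair, locus): locus coordinates
#'   and motif, `pair_id`, `label`, `distance` (NA when the locus did
#'   not pass QC in that pair).
#' @export
cohort_locus_table <- function(results, labels) {
  if (is.character(labels)) {
    labels <- utils::read.table(labels, sep = "\t", header = FALSE,
                                col.names = c("pair_id", "label"),
                                stringsAsFactors = FALSE)
  }
  if (!all(c("pair_id", "label") %in% names(labels)))
    stop("labels must have columns pair_id and label")
  if (!all(labels$label %in% c("MSI-H", "MSS")))
    stop("labels must be 'MSI-H' or 'MSS'")

  if (is.character(results) && length(results) == 1L && dir.exists(results)) {
    files <- list.files(results, pattern = "\\.loci\\.tsv$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no .loci.tsv files in ", results)
    results <- stats::setNames(
      lapply(files, read_locus_tsv),
      sub("\\.loci\\.tsv$", "", basename(files))
    )
  } else {
    results <- lapply(results, function(r) {
      if (inherits(r, "msi_pair")) r$locus_results else r
    })
  }
  missing <- setdiff(names(results), labels$pair_id)
  if (length(missing))
    stop("pairs without a label: ", paste(missing, collapse = ", "))

  rows <- lapply(names(results), function(pid) {
    lr <- results[[pid]]
    data.frame(
      pair_id = pid,
      label = labels$label[match(pid, labels$pair_id)],
      chrom = lr$chrom, start = lr$start, end = lr$end,
      motif = lr$motif, ref_repeats = lr$ref_repeats,
      distance = ifelse(lr$status == "pass", lr$distance, NA_real_),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Read a .loci.tsv written by write_pair_results back into the
# locus_results layout.
read_locus_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  coord <- regmatches(tab$locus,
                      regexec("^(.+):(\\d+)-(\\d+)$", tab$locus))
  ann <- regmatches(tab$motif,
                    regexec("^\\(([ACGT]+)\\)(\\d+)$", tab$motif))
  data.frame(
    chrom = vapply(coord, `[`, character(1), 2),
    start = as.integer(vapply(coord, `[`, character(1), 3)),
    end = as.integer(vapply(coord, `[`, character(1), 4)),
    motif = vapply(ann, `[`, character(1), 2),
    ref_repeats = as.integer(vapply(ann, `[`, character(1), 3)),
    status = ifelse(tab$status == "pass", "pass", "discarded"),
    distance = suppressWarnings(as.numeric(tab$difference)),
    stringsAsFactors = FALSE
  )
}

#' Difference of averages for one locus
#'
#' The mean per-locus distance among MSI-H pairs covering the locus
#' minus the mean among MSS pairs covering it. Positive values mark
#' discriminative loci; negative values (anti-discriminative) are
#' allowed. Pairs in which the locus failed QC are excluded from both
#' means, never imputed as zero. Undefined (NA) when no covering MSI-H
#' or no covering MSS pair exists.
#'
#' @param table cohort table from [cohort_locus_table()].
#' @param locus locus id `"chrom:start-end"` (see [rank_loci()] output).
#' @return a single number, or NA when undefined.
#' @export
difference_of_averages <- function(table, locus) {
  id <- paste0(table$chrom, ":", table$start, "-", table$end)
  sub <- table[id == locus & !is.na(table$distance), ]
  h <- sub$distance[sub$label == "MSI-H"]
  s <- sub$distance[sub$label == "MSS"]
  if (length(h) == 0L || length(s) == 0L) return(NA_real_)
  mean(h) - mean(s)
}

#' Locus score from difference of averages and coverage
#'
#' Weights a locus' discriminative power by the square of the
#' proportion of pairs with sufficient coverage at the locus, demoting
#' loci that are rarely evaluable.
#'
#' @param a difference of averages.
#' @param c coverage proportion in \[0, 1\].
#' @return `a * c^2`.
#' @export
locus_score <- function(a, c) {
  if (any(c < 0 | c > 1, na.rm = TRUE)) stop("c must be in [0,1]")
  a * c^2
}

#' Rank loci by discriminative power across a cohort
#'
#' Computes, for every locus, the difference of averages `a`, the
#' coverage proportion `c` (fraction of pairs in which the locus passed
#' the same coverage QC used in scoring), and the locus score
#' `l = a * c^2`. Loci are sorted by `l` descending; ties break by
#' higher `c`, then (chrom, start). Loci with undefined `a` rank last.
#'
#' @param table cohort table from [cohort_locus_table()].
#' @return data.frame with columns `locus`, `chrom`, `start`, `end`,
#'   `motif`, `ref_repeats`, `a`, `c`, `l`, sorted as described.
#' @export
rank_loci <- function(table) {
  table$locus <- paste0(table$chrom, ":", table$start, "-", table$end)
  n_pairs <- length(unique(table$pair_id))
  per <- split(table, table$locus)
  rows <- lapply(per, function(sub) {
    covered <- !is.na(sub$distance)
    h <- sub$distance[covered & sub$label == "MSI-H"]
    s <- sub$distance[covered & sub$label == "MSS"]
    a <- if (length(h) && length(s)) mean(h) - mean(s) else NA_real_
    c <- sum(covered) / n_pairs
    data.frame(
      locus = sub$locus[1], chrom = sub$chrom[1], start = sub$start[1],
      end = sub$end[1], motif = sub$motif[1],
      ref_repeats = sub$ref_repeats[1],
      a = a, c = c, l = locus_score(a, c), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ord <- order(is.na(out$l), -ifelse(is.na(out$l), -Inf, out$l),
               -out$c, out$chrom, out$start)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Select the top-N loci and optionally write a BED panel
#'
#' @param rankings output of [rank_loci()].
#' @param n number of loci to keep; when `n` exceeds the available
#'   loci, all are returned with a warning.
#' @param bed_path optional path; when given, the selected loci are
#'   written in the annotated 6-column BED dialect.
#' @return the first `n` rows of `rankings`.
#' @export
top_n_loci <- function(rankings, n, bed_path = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (n > nrow(rankings)) {
    warning("requested ", n, " loci but only ", nrow(rankings),
            " available; returning all")
    n <- nrow(rankings)
  }
  top <- rankings[seq_len(n), ]
  if (!is.null(bed_path)) {
    loci <- validate_msi_loci(top[c("chrom", "start", "end", "motif",
                                    "ref_repeats")])
    write_loci_bed(loci, bed_path)
  }
  top
}
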