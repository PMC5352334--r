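# Scoring: normalization, the per-locus stepwise difference d, the
# pair-level aggregate instability score, and the end-to-end pipeline.

#' Normalize a repeat-length distribution
#'
#' Converts supporting-read counts to fractions of the sample's total at
#' that locus, so tumor and normal are comparable regardless of
#' sequencing depth.
#'
#' @param dist named count vector with positive total support.
#' @return named numeric vector of fractions summing to 1.
#' @examples
#' normalize_distribution(c(`10` = 5, `12` = 15))
#' @export
normalize_distribution <- function(dist) {
  total <- sum(dist)
  if (length(dist) == 0L || total <= 0)
    stop("cannot normalize an empty distribution")
  stats::setNames(as.numeric(dist) / total, names(dist))
}

#' Stepwise difference between two normalized distributions
#'
#' The per-locus instability distance: the sum of absolute differences
#' between the tumor's and the normal's normalized fractions over the
#' union of repeat lengths observed in either sample (an L1 distance on
#' the length histograms). Ranges from 0 (identical distributions) to 2
#' (no shared repeat length).
#'
#' @param tumor,normal named fraction vectors from
#'   [normalize_distribution()].
#' @return the distance, a number in \[0, 2\].
#' @examples
#' stepwise_difference(c(`12` = 0.5, `15` = 0.5), c(`15` = 1))
#' @export
stepwise_difference <- function(tumor, normal) {
  lengths <- union(names(tumor), names(normal))
  tv <- ifelse(lengths %in% names(tumor), tumor[lengths], 0)
  nv <- ifelse(lengths %in% names(normal), normal[lengths], 0)
  sum(abs(tv - nv))
}

#' Aggregate instability score for a pair
#'
#' The arithmetic mean of the per-locus distances over quality-passing
#' loci only; discarded loci are excluded from numerator and
#' denominator. Averaging across many loci lets the pair-level score
#' benefit from the law of large numbers, damping sequencing error and
#' individual poorly behaved loci.
#'
#' @param distances numeric vector of per-locus distances (passing loci).
#' @return the mean distance.
#' @export
aggregate_score <- function(distances) {
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0L)
    stop("no evaluable loci: every locus was discarded by quality control")
  mean(distances)
}

#' Classify an instability score
#'
#' A pair is called MSI-positive when its aggregate score strictly
#' exceeds the threshold; a score exactly at the threshold is negative.
#'
#' @param score aggregate instability score in \[0, 2\].
#' @param threshold decision threshold (default 0.4).
#' @return `"MSI-positive"` or `"MSI-negative"`.
#' @export
classify_msi <- function(score, threshold = 0.4) {
  if (score > threshold) "MSI-positive" else "MSI-negative"
}

#' Score a tumor-normal pair
#'
#' Runs the full pipeline: loci are realigned against the reference;
#' for each locus, spanning reads are extracted from each BAM, filtered,
#' and repeat-counted; per-sample distributions are outlier-stripped and
#' coverage-gated; surviving loci are normalized and scored with the
#' stepwise difference; the mean over passing loci is the pair's
#' instability score, classified against the threshold. Per-locus
#' computations are independent, so locus order never changes any
#' result; outputs preserve the input locus order.
#'
#' @param normal_bam,tumor_bam paths to indexed BAMs.
#' @param loci an [msi_loci] table or a path to an annotated BED file.
#' @param reference FASTA path or `DNAStringSet`.
#' @param cfg an [msi_config()].
#' @param output_prefix when non-NULL, writes `<prefix>.loci.tsv`
#'   (per-locus table) and `<prefix>.summary.tsv`.
#' @return object of class `"msi_pair"`: list with `locus_results`
#'   (data.frame), `aggregate_score`, `threshold`, `call`, `n_pass`,
#'   `n_discarded`.
#' @export
score_pair <- function(normal_bam, tumor_bam, loci, reference,
                       cfg = msi_config(), output_prefix = NULL) {
  ref <- load_reference(reference)
  if (is.character(loci) && length(loci) == 1L) loci <- parse_bed(loci)
  re <- realign_loci(loci, ref)
  aligned <- re$loci
  unusable <- re$unusable

  # NB: keep the BamFiles closed; scanBam opens per query. An open
  # BamFile only honors `which` on its first query.
  nb <- Rsamtools::BamFile(normal_bam)
  tb <- Rsamtools::BamFile(tumor_bam)

  rows <- vector("list", nrow(aligned))
  for (i in seq_len(nrow(aligned))) {
    locus <- aligned[i, ]
    ndist <- locus_distribution(nb, locus, cfg, role = "normal")
    tdist <- locus_distribution(tb, locus, cfg, role = "tumor")
    ndist <- remove_outliers(ndist, cfg$outlier_sd)
    tdist <- remove_outliers(tdist, cfg$outlier_sd)

    status <- "pass"; reason <- NA_character_; d <- NA_real_
    if (length(ndist) == 0L || length(tdist) == 0L) {
      status <- "discarded"; reason <- "no_support"
    } else if (!locus_passes_coverage(ndist, tdist, cfg$min_locus_coverage)) {
      status <- "discarded"; reason <- "low_coverage"
    } else {
      d <- stepwise_difference(normalize_distribution(tdist),
                               normalize_distribution(ndist))
    }
    rows[[i]] <- data.frame(
      chrom = locus$chrom, start = locus$start, end = locus$end,
      motif = locus$motif, ref_repeats = locus$ref_repeats,
      status = status, reason = reason,
      normal_counts = format_counts(ndist),
      tumor_counts = format_counts(tdist),
      distance = d, stringsAsFactors = FALSE
    )
  }
  locus_results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               motif = character(0), ref_repeats = integer(0),
               status = character(0), reason = character(0),
               normal_counts = character(0), tumor_counts = character(0),
               distance = numeric(0))
  if (nrow(unusable)) {
    locus_results <- rbind(locus_results, data.frame(
      chrom = unusable$chrom, start = unusable$start, end = unusable$end,
      motif = unusable$motif, ref_repeats = unusable$ref_repeats,
      status = "discarded", reason = unusable$reason,
      normal_counts = "", tumor_counts = "", distance = NA_real_,
      stringsAsFactors = FALSE
    ))
  }

  score <- aggregate_score(locus_results$distance)
  res <- structure(list(
    locus_results = locus_results,
    aggregate_score = score,
    threshold = cfg$threshold,
    call = classify_msi(score, cfg$threshold),
    n_pass = sum(locus_results$status == "pass"),
    n_discarded = sum(locus_results$status == "discarded")
  ), class = "msi_pair")

  if (!is.null(output_prefix)) write_pair_results(res, output_prefix)
  res
}

format_counts <- function(dist) {
  if (length(dist) == 0L) return("")
  paste0(names(dist), ":", as.integer(dist), collapse = ",")
}

parse_counts <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
                  vapply(parts, `[`, character(1), 1))
}

#' Write per-locus and summary result files for a scored pair
#'
#' `<prefix>.loci.tsv` has columns `locus` (chrom:start-end), `motif`
#' (`(AC)12` annotation), `status` (`pass` or `discarded(reason)`),
#' post-QC raw `normal` and `tumor` counts as `r1:c1,r2:c2,...`, and
#' `difference` to 6 decimals. `<prefix>.summary.tsv` holds the
#' aggregate score, threshold, call and locus tallies.
#'
#' @param res an `"msi_pair"` object from [score_pair()].
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_pair_results <- function(res, prefix) {
  lr <- res$locus_results
  loci_path <- paste0(prefix, ".loci.tsv")
  summary_path <- paste0(prefix, ".summary.tsv")
  out <- data.frame(
    locus = paste0(lr$chrom, ":", lr$start, "-", lr$end),
    motif = paste0("(", lr$motif, ")", lr$ref_repeats),
    status = ifelse(lr$status == "pass", "pass",
                    paste0("discarded(", lr$reason, ")")),
    normal = lr$normal_counts,
    tumor = lr$tumor_counts,
    difference = ifelse(is.na(lr$distance), "NA",
                        sprintf("%.6f", lr$distance)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, loci_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- data.frame(
    key = c("Average_Difference", "Threshold", "Call", "Passing_Loci",
            "Discarded_Loci"),
    value = c(sprintf("%.6f", res$aggregate_score),
              format(res$threshold), res$call,
              res$n_pass, res$n_discarded),
    stringsAsFactors = FALSE
  )
  utils::write.table(summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(loci_path, summary_path))
}

#' @export
print.msi_pair <- function(x, ...) {
  cat("Tumor-normal microsatellite instability result\n")
  cat(sprintf("  Aggregate instability score: %.6f\n", x$aggregate_score))
  cat(sprintf("  Call: %s (threshold %g, strict >)\n", x$call, x$threshold))
  cat(sprintf("  Loci: %d passing, %d discarded\n", x$n_pass, x$n_discarded))
  invisible(x)
}
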