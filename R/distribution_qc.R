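# Per-locus distribution post-processing: outlier stripping and the
# coverage gate. Both are applied to the normal and tumor distributions
# of a locus before any normalization or scoring.

#' Remove outlier repeat lengths from a distribution
#'
#' Computes the support-weighted mean and support-weighted population
#' standard deviation of the repeat counts and removes every repeat
#' length lying strictly more than `outlier_sd` standard deviations from
#' the mean. Applied once (no iteration) and to each sample's
#' distribution separately. With a single observed length the standard
#' deviation is 0 and nothing is removed.
#'
#' @param dist named numeric vector: names are repeat counts, values are
#'   supporting-read counts.
#' @param outlier_sd positive standard-deviation multiplier.
#' @return the distribution with outlier lengths dropped (attributes
#'   preserved). An empty distribution is returned unchanged.
#' @examples
#' remove_outliers(c(`15` = 99, `40` = 1))
#' @export
remove_outliers <- function(dist, outlier_sd = 3.0) {
  if (outlier_sd <= 0) stop("outlier_sd must be > 0")
  if (length(dist) == 0L || sum(dist) == 0) return(dist)
  r <- as.numeric(names(dist))
  w <- as.numeric(dist)
  mu <- sum(r * w) / sum(w)
  sigma <- sqrt(sum(w * (r - mu)^2) / sum(w))
  keep <- abs(r - mu) <= outlier_sd * sigma
  out <- dist[keep]
  for (a in setdiff(names(attributes(dist)), "names"))
    attr(out, a) <- attr(dist, a)
  out
}

#' Does a locus have sufficient coverage in both samples?
#'
#' Checked after outlier removal, so outlier stripping can disqualify a
#' locus. Both the normal and the tumor distribution must retain at
#' least `min_locus_coverage` supporting reads.
#'
#' @param normal,tumor repeat-length distributions (named count vectors).
#' @param min_locus_coverage minimum total support per sample.
#' @return logical scalar.
#' @export
locus_passes_coverage <- function(normal, tumor, min_locus_coverage = 20L) {
  sum(normal) >= min_locus_coverage && sum(tumor) >= min_locus_coverage
}
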