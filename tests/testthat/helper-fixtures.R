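# Shared fixtures, built in code at test time.

# One (AC)10 locus planted at chr1:100-120 in a 400 bp chromosome.
ac10_genome <- function() {
  make_reference(
    loci = msi_loci("chr1", 100L, 120L, "AC", 10L),
    chrom_length = 400L, seed = 11
  )
}

# Write hand-built SAM alignment lines to an indexed BAM; `chroms` is a
# named integer vector of sequence lengths.
write_test_bam <- function(lines, chroms, dir = tempfile("testbam")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(chroms), "\tLN:", chroms))
  writeLines(c(header, lines), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"),
                   overwrite = TRUE, indexDestination = TRUE)
}

# A SAM line for a read aligned at 0-based `start0` with uniform quality.
sam_line <- function(qname, chrom, start0, seq, cigar = paste0(nchar(seq), "M"),
                     flag = 0L, qual = strrep("I", nchar(seq))) {
  paste(qname, flag, chrom, start0 + 1L, 60L, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}

# Reads over the ac10 genome carrying k motif copies, flanked by real
# reference sequence; mirrors the aligned-read layout the caller expects
# but is built independently of simulate_pair.
ac10_read <- function(chrom_seq, k, left = 20L, read_length = 80L,
                      locus_start = 100L, locus_end = 120L, motif = "AC") {
  u <- nchar(motif)
  run_read <- u * k
  right <- read_length - left - run_read
  start0 <- locus_start - left
  seq <- paste0(
    substr(chrom_seq, start0 + 1L, locus_start),
    strrep(motif, k),
    substr(chrom_seq, locus_end + 1L, locus_end + right)
  )
  run_ref <- locus_end - locus_start
  cigar <- if (run_read == run_ref) paste0(read_length, "M")
  else if (run_read < run_ref)
    paste0(left + run_read, "M", run_ref - run_read, "D", right, "M")
  else paste0(left + run_ref, "M", run_read - run_ref, "I", right, "M")
  list(seq = seq, cigar = cigar, start0 = start0)
}

# Random repeat-length count distribution for property tests.
random_dist <- function(max_lengths = 6L, max_count = 40L) {
  n <- sample(1:max_lengths, 1)
  lengths <- sample(5:30, n)
  stats::setNames(sample(1:max_count, n, replace = TRUE), lengths)
}
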