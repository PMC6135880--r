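#' Assembly statistics
#'
#' Summary metrics for a set of scaffolds/contigs. N50 is the length of the
#' contig at which the cumulative sum of descending lengths first reaches
#' half the total assembly size. Size-class proportions are computed over
#' contig counts with strict inequalities ("< 1,000 bp", "> 10,000 bp").
#'
#' @param scaffolds Named character vector of sequences, or a numeric vector
#'   of contig lengths.
#' @return list: genome_size_bp, n_contigs, mean_length_bp, n50_bp,
#'   prop_lt_1kb, prop_gt_10kb.
#' @export
assembly_stats <- function(scaffolds) {
  lens <- if (is.numeric(scaffolds)) scaffolds else nchar(scaffolds)
  if (length(lens) == 0L) stop_arg("assembly_stats() needs >= 1 scaffold")
  lens <- as.numeric(lens)
  total <- sum(lens)
  desc <- sort(lens, decreasing = TRUE)
  n50 <- desc[which(cumsum(desc) >= total / 2)[1]]
  list(genome_size_bp = total,
       n_contigs = length(lens),
       mean_length_bp = mean(lens),
       n50_bp = n50,
       prop_lt_1kb = mean(lens < 1000),
       prop_gt_10kb = mean(lens > 10000))
}

#' Sliding-window GC profile with a homogeneity verdict
#'
#' Windows start at offsets 0, step, 2*step, ... while a full window fits.
#' The scaffold is called homogeneous iff the spread between the largest and
#' smallest window GC does not exceed `band`.
#'
#' @param scaffold A single DNA string.
#' @param window_bp,step_bp Window and step sizes; `window_bp >= step_bp >= 1`.
#' @param band Maximum allowed max-min window GC spread (default 0.10).
#' @return list: `windows` (data.frame start / gc) and `homogeneous`
#'   (logical).
#' @export
gc_profile <- function(scaffold, window_bp, step_bp, band = 0.10) {
  if (step_bp < 1 || window_bp < step_bp)
    stop_arg("need window_bp >= step_bp >= 1")
  L <- nchar(scaffold)
  if (L < window_bp) stop_arg("scaffold shorter than one window")
  starts <- seq(1L, L - window_bp + 1L, by = step_bp)
  seqs <- substring(scaffold, starts, starts + window_bp - 1L)
  gc <- vapply(seqs, function(s)
    sum(Biostrings::letterFrequency(Biostrings::DNAString(s),
                                    c("G", "C"))) / nchar(s),
    numeric(1), USE.NAMES = FALSE)
  list(windows = data.frame(start = starts, gc = gc),
       homogeneous = (max(gc) - min(gc)) <= band)
}

#' GC fraction of one or more sequences, pooled
#' @param seqs Character vector of DNA sequences.
#' @return GC fraction of the concatenated input.
#' @export
gc_content <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  freq <- colSums(Biostrings::letterFrequency(x, c("G", "C", "A", "T")))
  (freq[["G"]] + freq[["C"]]) / sum(freq)
}
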