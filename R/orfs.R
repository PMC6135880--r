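#' Translate DNA to protein
#'
#' Standard genetic code. Stops are rendered as `*`; a single terminal stop
#' is stripped from the returned protein. Codons containing N translate to
#' `X`. Frames are 0/1/2 on the chosen strand; on the minus strand the
#' sequence is reverse-complemented before framing.
#'
#' @param dna DNA string over A/C/G/T/N.
#' @param frame 0, 1 or 2.
#' @param strand "+" or "-".
#' @return Protein string (internal stops kept as `*`, terminal stop
#'   removed).
#' @export
translate_dna <- function(dna, frame = 0, strand = "+") {
  if (grepl("[^ACGTN]", dna))
    stop_arg("translate_dna() accepts only A/C/G/T/N")
  if (strand == "-") dna <- reverse_complement(dna)
  dna <- substr(dna, frame + 1, nchar(dna))
  usable <- 3 * (nchar(dna) %/% 3)
  if (usable < 3) stop_arg("sequence shorter than one codon after framing")
  dna <- substr(dna, 1, usable)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

# Codon lookup table (standard code); codons with ambiguity map to X.
CODON_TABLE <- Biostrings::GENETIC_CODE
AA_TO_CODONS <- split(names(CODON_TABLE), CODON_TABLE)

# Vectorized codon-table translation for the generator and scanner hot
# paths; avoids per-call S4 dispatch overhead. Keeps stops as '*'.
fast_translate <- function(dna) {
  usable <- 3L * (nchar(dna) %/% 3L)
  if (usable < 3L) return("")
  starts <- seq.int(1L, usable, 3L)
  aa <- unname(CODON_TABLE[substring(dna, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

fast_revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Frame translation used by the ORF scanner: keeps all stops (no terminal
# stripping) so stop positions delimit ORFs.
frame_translation <- function(dna, frame) {
  fast_translate(substr(dna, frame + 1, nchar(dna)))
}

#' Reverse complement of a DNA string
#' @param dna DNA string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Six-frame ORF prediction
#'
#' Deterministic ORF caller for intron-free genomes: an ORF is an ATG
#' followed by in-frame codons up to the first stop, with no internal stop.
#' All six frames are scanned; within one frame, overlapping ATGs sharing a
#' stop yield only the longest ORF (first ATG after the previous stop).
#' Coordinates are 1-based inclusive on the plus strand and include the stop
#' codon.
#'
#' @param scaffolds Named character vector of scaffold sequences (or a
#'   single unnamed sequence).
#' @param min_len_aa Minimum protein length (stop excluded) reported.
#' @return data.frame of ORF records sorted by (scaffold, start): gene_id,
#'   scaffold_id, start, end, strand, frame, protein, length_aa.
#' @export
find_orfs <- function(scaffolds, min_len_aa = 50) {
  if (min_len_aa < 1) stop_arg("min_len_aa must be >= 1")
  if (is.null(names(scaffolds)))
    names(scaffolds) <- paste0("scaffold_", seq_along(scaffolds))
  out <- list()
  for (sc in names(scaffolds)) {
    seq_fwd <- scaffolds[[sc]]
    L <- nchar(seq_fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else fast_revcomp(seq_fwd)
      for (frame in 0:2) {
        prot <- frame_translation(s, frame)
        if (!nzchar(prot)) next
        # first ATG after each stop through to that stop: leftmost match of
        # M[^*]*\* per stop gives the longest ORF per stop
        mt <- gregexpr("M[^*]*\\*", prot)[[1]]
        if (mt[1] == -1) next
        for (k in seq_along(mt)) {
          a <- mt[k]                            # aa index of M
          len <- attr(mt, "match.length")[k]    # includes the stop
          aa_len <- len - 1L
          if (aa_len < min_len_aa) next
          start_local <- frame + 3 * (a - 1) + 1
          end_local <- frame + 3 * (a - 1 + len)
          if (strand == "+") {
            start <- start_local; end <- end_local
          } else {
            start <- L - end_local + 1; end <- L - start_local + 1
          }
          out[[length(out) + 1L]] <- data.frame(
            scaffold_id = sc, start = start, end = end, strand = strand,
            frame = frame,
            protein = substr(prot, a, a + aa_len - 1L),
            length_aa = aa_len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), scaffold_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      protein = character(), length_aa = integer(),
                      stringsAsFactors = FALSE))
  orfs <- do.call(rbind, out)
  orfs <- orfs[order(orfs$scaffold_id, orfs$start, orfs$end), , drop = FALSE]
  orfs <- cbind(gene_id = sprintf("orf_%05d", seq_len(nrow(orfs))), orfs,
                stringsAsFactors = FALSE)
  rownames(orfs) <- NULL
  orfs
}
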