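#' Read and write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors so
#' that downstream code is container-agnostic. An empty file yields an empty
#' vector, not an error.
#'
#' @param path File path.
#' @param type "dna" or "protein".
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- tryCatch({
    if (type == "dna") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path)
  }, error = function(e) {
    if (file.exists(path) && file.size(path) == 0)
      return(if (type == "dna") Biostrings::DNAStringSet()
             else Biostrings::AAStringSet())
    stop_arg("malformed FASTA '%s': %s", path, conditionMessage(e))
  })
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param records Named character vector of sequences.
#' @export
write_fasta <- function(records, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(records)
         else Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write ORF annotations as GFF3
#'
#' ORF records are serialized as CDS features with 1-based inclusive
#' coordinates (GFF3 convention); the gene id travels in the `ID` attribute
#' and the reading frame on its own strand in a `frame` attribute. When the
#' originating scaffolds are supplied to the reader, protein translations
#' are reconstructed so the round trip restores full OrfRecord rows.
#'
#' @param orfs data.frame with columns gene_id, scaffold_id, start, end,
#'   strand, frame (and optionally protein).
#' @param path File path.
#' @export
write_gff3 <- function(orfs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$scaffold_id,
    ranges = IRanges::IRanges(start = orfs$start, end = orfs$end),
    strand = orfs$strand)
  gr$source <- "amoebahgt"
  gr$type <- "CDS"
  gr$phase <- 0L  # ORFs start at their first codon
  gr$ID <- orfs$gene_id
  gr$frame <- as.character(orfs$frame)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @param scaffolds Optional named character vector of scaffold sequences
#'   used to re-derive protein translations.
#' @return `read_gff3()`: data.frame of ORF records sorted by
#'   (scaffold, start).
#' @export
read_gff3 <- function(path, scaffolds = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop_arg("malformed GFF3 '%s': %s", path,
                            conditionMessage(e)))
  orfs <- data.frame(
    gene_id = as.character(gr$ID),
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame = as.integer(gr$frame %||% 0L),
    stringsAsFactors = FALSE)
  if (any(orfs$end < orfs$start))
    stop_arg("GFF3 '%s' contains a feature with end < start", path)
  if (!is.null(scaffolds)) {
    orfs$protein <- vapply(seq_len(nrow(orfs)), function(i) {
      seq <- substr(scaffolds[[orfs$scaffold_id[i]]], orfs$start[i],
                    orfs$end[i])
      if (orfs$strand[i] == "-") seq <- fast_revcomp(seq)
      sub("\\*$", "", fast_translate(seq))
    }, character(1))
    orfs$length_aa <- nchar(orfs$protein)
  }
  orfs <- orfs[order(orfs$scaffold_id, orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Read and write tab-separated tables (truth tables, taxonomy maps)
#'
#' @param x data.frame to write.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
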