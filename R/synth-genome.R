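# DNA with independent sites at the requested GC fraction.
random_dna <- function(n, gc) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# n non-stop codons at the requested GC bias.
random_codons <- function(n, gc) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    nts <- sample(c("G", "C", "A", "T"), 3 * (need + 4), replace = TRUE,
                  prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
    cods <- apply(matrix(nts, nrow = 3), 2, paste, collapse = "")
    out <- c(out, cods[!cods %in% STOP_CODONS])
  }
  out[seq_len(n)]
}

# ATG + (len_aa - 1) non-stop codons + stop: an ORF whose protein has
# length len_aa.
random_gene_dna <- function(len_aa, gc) {
  paste0("ATG", paste(random_codons(len_aa - 1L, gc), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Generate a synthetic multi-scaffold host genome
#'
#' Builds `n_scaffolds` scaffolds, each carrying `orfs_per_scaffold`
#' intron-free host ORFs separated by intergenic spacers drawn uniformly
#' from `spacer_range`. Every ORF begins with ATG, ends with a stop and has
#' no internal in-frame stop; an in-frame stop codon is placed immediately
#' upstream of every gene so the deterministic longest-ORF-per-stop caller
#' recovers truth ORFs at exact coordinates. Genome GC tracks `gc_target`
#' (default 0.583, the amoebal host background).
#'
#' @param n_scaffolds,orfs_per_scaffold Counts (>= 1).
#' @param gc_target Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param orf_len_range Host ORF protein lengths, drawn uniformly (aa).
#' @param spacer_range Intergenic spacer lengths, drawn uniformly (nt).
#' @param genome_id Label used in gene ids and the truth table.
#' @param out_dir Optional directory: writes `genome.fasta`, `orfs.gff3`
#'   and `truth.tsv`.
#' @return list of class `synthetic_genome`: `scaffolds` (named character),
#'   `orfs` (OrfRecord data.frame), `truth` (truth-table data.frame),
#'   `genome_id`, `gc_target`.
#' @export
generate_host_genome <- function(n_scaffolds, orfs_per_scaffold,
                                 gc_target = 0.583, seed = 1L,
                                 orf_len_range = c(80, 250),
                                 spacer_range = c(30, 300),
                                 genome_id = "host", out_dir = NULL) {
  if (gc_target <= 0 || gc_target >= 1)
    stop_arg("gc_target must lie strictly between 0 and 1")
  if (n_scaffolds < 1 || orfs_per_scaffold < 1)
    stop_arg("n_scaffolds and orfs_per_scaffold must be >= 1")
  withr::with_seed(seed, {
    scaffolds <- character(n_scaffolds)
    names(scaffolds) <- sprintf("scaffold_%03d", seq_len(n_scaffolds))
    orfs <- list(); truth <- list(); gcount <- 0L
    for (s in seq_len(n_scaffolds)) {
      pieces <- character(0); pos <- 0L
      for (g in seq_len(orfs_per_scaffold)) {
        spacer <- random_dna(sample(spacer_range[1]:spacer_range[2], 1L),
                             gc_target)
        len_aa <- sample(orf_len_range[1]:orf_len_range[2], 1L)
        gene <- random_gene_dna(len_aa, gc_target)
        strand <- sample(c("+", "-"), 1L)
        oriented <- if (strand == "+") gene else fast_revcomp(gene)
        # stop-codon guards flank the gene in its own reading frame
        block <- paste0("TAA", oriented, "TTA")
        pieces <- c(pieces, spacer, block)
        start <- pos + nchar(spacer) + 3L + 1L
        end <- start + nchar(gene) - 1L
        pos <- pos + nchar(spacer) + nchar(block)
        gcount <- gcount + 1L
        gene_id <- sprintf("%s_g%04d", genome_id, gcount)
        orfs[[gcount]] <- data.frame(
          gene_id = gene_id, scaffold_id = names(scaffolds)[s],
          start = start, end = end, strand = strand, frame = 0L,
          protein = sub("\\*$", "", fast_translate(gene)), length_aa = len_aa,
          stringsAsFactors = FALSE)
        truth[[gcount]] <- data.frame(
          gene_id = gene_id, source_category = "host",
          source_protein_id = NA_character_, divergence = 0,
          scaffold_id = names(scaffolds)[s], start = start, end = end,
          strand = strand, stringsAsFactors = FALSE)
      }
      tail_spacer <- random_dna(sample(spacer_range[1]:spacer_range[2], 1L),
                                gc_target)
      scaffolds[s] <- paste(c(pieces, tail_spacer), collapse = "")
    }
  })
  genome <- structure(list(scaffolds = scaffolds,
                           orfs = fix_frames(do.call(rbind, orfs), scaffolds),
                           truth = do.call(rbind, truth),
                           genome_id = genome_id, gc_target = gc_target),
                      class = "synthetic_genome")
  if (!is.null(out_dir)) write_genome(genome, out_dir)
  genome
}

# Reading frame on the ORF's own strand, from final plus-strand coordinates.
fix_frames <- function(orfs, scaffolds) {
  L <- nchar(scaffolds)[match(orfs$scaffold_id, names(scaffolds))]
  orfs$frame <- ifelse(orfs$strand == "+", (orfs$start - 1L) %% 3L,
                       (L - orfs$end) %% 3L)
  rownames(orfs) <- NULL
  orfs
}

#' Write a synthetic genome to disk
#' @param genome A `synthetic_genome`.
#' @param dir Output directory (created if needed).
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(genome$scaffolds, file.path(dir, "genome.fasta"), type = "dna")
  write_gff3(genome$orfs, file.path(dir, "orfs.gff3"))
  write_tsv(genome$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Implant viral transfers into a synthetic host genome
#'
#' Samples `n_transfers` proteins (without replacement) from the viral
#' panels, applies amino-acid substitutions at the stated per-site rate,
#' reverse-translates them with uniform codon choice, and inserts each gene
#' (with in-frame stop-codon guards) at a random intergenic position. No
#' existing ORF is disrupted; downstream coordinates are shifted and the
#' truth table records family, divergence and final coordinates.
#'
#' @param genome A `synthetic_genome` from [generate_host_genome()].
#' @param panels A panels object from [generate_reference_panels()] (or a
#'   named list family -> named protein vector).
#' @param n_transfers Number of genes to implant (<= total panel proteins).
#' @param divergence Per-site amino-acid substitution rate in `[0, 0.6]`.
#' @param seed Integer seed.
#' @param out_dir Optional output directory, as in [generate_host_genome()].
#' @return The modified `synthetic_genome` (ORFs, truth table and scaffold
#'   sequences updated).
#' @export
implant_transfers <- function(genome, panels, n_transfers, divergence,
                              seed = 1L, out_dir = NULL) {
  viral <- if (!is.null(panels$viral)) panels$viral else panels
  flat <- unlist(unname(viral))
  fam_of <- rep(names(viral), vapply(viral, length, integer(1)))
  names(fam_of) <- names(flat)
  if (n_transfers > length(flat))
    stop_arg("n_transfers exceeds the number of panel proteins")
  if (divergence < 0 || divergence > 0.6)
    stop_arg("divergence must be in [0, 0.6]")
  scaffolds <- genome$scaffolds
  orfs <- genome$orfs
  truth <- genome$truth
  withr::with_seed(seed, {
    picks <- sample(names(flat), n_transfers)
    for (k in seq_len(n_transfers)) {
      pid <- picks[k]
      aa <- mutate_protein(flat[[pid]], divergence)
      strand <- sample(c("+", "-"), 1L)
      gene <- reverse_translate(aa)
      oriented <- if (strand == "+") gene else fast_revcomp(gene)
      ins <- paste0("TAA", oriented, "TTA")
      gaps <- intergenic_gaps(scaffolds, orfs, min_width = 30L)
      if (nrow(gaps) == 0L)
        stop_arg("insufficient intergenic space on scaffold %s",
                 names(scaffolds)[1])
      gp <- gaps[sample.int(nrow(gaps), 1L), ]
      slots <- seq.int(gp$start + 14L, gp$end - 15L)
      u <- if (length(slots) == 1L) slots else sample(slots, 1L)
      sc <- gp$scaffold_id
      scaffolds[[sc]] <- paste0(substr(scaffolds[[sc]], 1L, u), ins,
                                substr(scaffolds[[sc]], u + 1L,
                                       nchar(scaffolds[[sc]])))
      shift <- nchar(ins)
      move <- orfs$scaffold_id == sc & orfs$start > u
      orfs$start[move] <- orfs$start[move] + shift
      orfs$end[move] <- orfs$end[move] + shift
      tmove <- truth$scaffold_id == sc & truth$start > u
      truth$start[tmove] <- truth$start[tmove] + shift
      truth$end[tmove] <- truth$end[tmove] + shift
      gene_id <- sprintf("implant_%03d", k)
      start <- u + 3L + 1L
      end <- start + nchar(gene) - 1L
      orfs <- rbind(orfs, data.frame(
        gene_id = gene_id, scaffold_id = sc, start = start, end = end,
        strand = strand, frame = 0L, protein = aa,
        length_aa = nchar(aa), stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        gene_id = gene_id,
        source_category = paste0("viral:", fam_of[[pid]]),
        source_protein_id = pid, divergence = divergence,
        scaffold_id = sc, start = start, end = end, strand = strand,
        stringsAsFactors = FALSE))
    }
  })
  orfs <- orfs[order(orfs$scaffold_id, orfs$start), , drop = FALSE]
  truth <- truth[order(truth$scaffold_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  genome$scaffolds <- scaffolds
  genome$orfs <- fix_frames(orfs, scaffolds)
  genome$truth <- truth
  if (!is.null(out_dir)) write_genome(genome, out_dir)
  genome
}

# Free intervals between gene blocks (guards included in the occupied
# region) wide enough to take an insertion.
intergenic_gaps <- function(scaffolds, orfs, min_width = 30L) {
  out <- list()
  for (sc in names(scaffolds)) {
    L <- nchar(scaffolds[[sc]])
    sub <- orfs[orfs$scaffold_id == sc, , drop = FALSE]
    occ_start <- sub$start - 3L
    occ_end <- sub$end + 3L
    o <- order(occ_start)
    cur <- 1L
    for (i in o) {
      if (occ_start[i] - 1L >= cur) {
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = sc, start = cur, end = occ_start[i] - 1L,
          stringsAsFactors = FALSE)
      }
      cur <- max(cur, occ_end[i] + 1L)
    }
    if (L >= cur)
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = sc, start = cur, end = L, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gaps <- do.call(rbind, out)
  gaps[gaps$end - gaps$start + 1L >= min_width, , drop = FALSE]
}
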