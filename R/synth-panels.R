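AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Random protein; always Met-initiated so reverse-translated implants are
# callable ORFs.
random_protein <- function(len_aa) {
  paste0("M", paste(sample(AA20, len_aa - 1L, replace = TRUE), collapse = ""))
}

draw_lengths <- function(n, length_distribution, floor_aa = 30L) {
  mu <- length_distribution[[1]]; sdv <- length_distribution[[2]]
  pmax(floor_aa, as.integer(round(rnorm(n, mu, sdv))))
}

#' Mutate a protein at a fixed per-site substitution rate
#'
#' Each site (except the initial Met, which anchors the start codon) is
#' replaced, with probability `divergence`, by a uniformly chosen different
#' residue. No rate matrix is used: downstream filters depend only on the
#' identity fraction.
#'
#' @param protein Protein string.
#' @param divergence Per-site substitution probability in `[0, 1]`.
#' @return Mutated protein string.
#' @export
mutate_protein <- function(protein, divergence) {
  if (divergence < 0 || divergence > 1)
    stop_arg("divergence must be in [0, 1]")
  if (divergence == 0) return(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- which(rbinom(length(chars), 1, divergence) == 1L)
  hit <- hit[hit > 1L]  # keep the start Met
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Uniform choice among synonymous codons, plus a random stop. GC is not
# re-tuned afterwards, so implants keep a detectable compositional signal.
reverse_translate <- function(protein) {
  by_aa <- AA_TO_CODONS
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop_arg("cannot reverse-translate residue '%s'", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  paste0(paste(codons, collapse = ""), sample(by_aa[["*"]], 1L))
}

default_family_names <- function(n) {
  base <- c("pandoravirus", "mimivirus", "marseillevirus",
            "pithovirus", "mollivirus")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("virfam%02d", seq_len(n - length(base)) + length(base)))
}

CELLULAR_CATEGORIES <- c("amoebozoa", "other_eukaryote", "bacteria", "archaea")

#' Generate labeled reference panels
#'
#' Emits `n_families` giant-virus ORFome panels plus four labeled cellular
#' decoy panels (amoebozoa, other_eukaryote, bacteria, archaea) with a
#' taxonomy map. Protein lengths are drawn from a normal distribution
#' (rounded, floored at 30 aa); sequences are uniform over the 20-letter
#' alphabet and Met-initiated. Deterministic for a fixed seed.
#'
#' @param n_families Number of viral families (>= 1).
#' @param genes_per_family Proteins per viral family (>= 1).
#' @param length_distribution Numeric `(mean_aa, sd_aa)`; mean >= 60.
#' @param seed Integer seed.
#' @param cellular_per_panel Proteins per cellular decoy panel.
#' @param out_dir Optional directory: writes one FASTA per panel plus
#'   `taxonomy.tsv`.
#' @return list with `viral` (named list family -> named proteins),
#'   `cellular` (named list category -> named proteins), `taxonomy`
#'   (data.frame protein_id / category / family) and `proteins` (flat named
#'   vector of every reference protein).
#' @export
generate_reference_panels <- function(n_families, genes_per_family,
                                      length_distribution = c(200, 40),
                                      seed = 1L,
                                      cellular_per_panel = genes_per_family,
                                      out_dir = NULL) {
  if (n_families < 1 || genes_per_family < 1)
    stop_arg("n_families and genes_per_family must be >= 1")
  if (length_distribution[[1]] < 60)
    stop_arg("mean protein length must be >= 60 aa")
  withr::with_seed(seed, {
    fams <- default_family_names(n_families)
    viral <- lapply(fams, function(f) {
      lens <- draw_lengths(genes_per_family, length_distribution)
      setNames(vapply(lens, random_protein, character(1)),
               sprintf("%s_p%03d", f, seq_len(genes_per_family)))
    })
    names(viral) <- fams
    cellular <- lapply(CELLULAR_CATEGORIES, function(cat) {
      lens <- draw_lengths(cellular_per_panel, length_distribution)
      setNames(vapply(lens, random_protein, character(1)),
               sprintf("%s_p%03d", cat, seq_len(cellular_per_panel)))
    })
    names(cellular) <- CELLULAR_CATEGORIES
  })
  taxonomy <- rbind(
    do.call(rbind, lapply(fams, function(f)
      data.frame(protein_id = names(viral[[f]]), category = "virus",
                 family = f, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(CELLULAR_CATEGORIES, function(cat)
      data.frame(protein_id = names(cellular[[cat]]), category = cat,
                 family = NA_character_, stringsAsFactors = FALSE))))
  rownames(taxonomy) <- NULL
  panels <- list(viral = viral, cellular = cellular, taxonomy = taxonomy,
                 proteins = c(unlist(unname(lapply(viral, identity))),
                              unlist(unname(lapply(cellular, identity)))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in fams)
      write_fasta(viral[[f]], file.path(out_dir,
                  sprintf("viral_%s.fasta", f)), type = "protein")
    for (cat in CELLULAR_CATEGORIES)
      write_fasta(cellular[[cat]], file.path(out_dir,
                  sprintf("cellular_%s.fasta", cat)), type = "protein")
    write_tsv(taxonomy, file.path(out_dir, "taxonomy.tsv"))
  }
  panels
}

#' Derive amoebozoa reference proteins from host ORFs
#'
#' Emulates proteomes of related amoebae (the role the *A. castellanii*
#' reference plays for a real host genome): a subset of host ORF proteins is
#' copied at a controlled divergence and labeled amoebozoa, so best-hit
#' taxonomy can recognise host-background genes.
#'
#' @param proteins Named character vector of host proteins.
#' @param divergence Per-site substitution rate applied to each copy.
#' @param seed Integer seed.
#' @param n Number of references to derive (default: all).
#' @param prefix Protein-id prefix for the derived references.
#' @return list with `proteins` (named vector) and `taxonomy` rows.
#' @export
make_amoeba_references <- function(proteins, divergence = 0.2, seed = 1L,
                                   n = length(proteins),
                                   prefix = "amoeba_ref") {
  withr::with_seed(seed, {
    pick <- sort(sample(seq_along(proteins), min(n, length(proteins))))
    refs <- vapply(proteins[pick], mutate_protein, character(1),
                   divergence = divergence)
  })
  names(refs) <- sprintf("%s_p%03d", prefix, seq_along(refs))
  list(proteins = refs,
       taxonomy = data.frame(protein_id = names(refs),
                             category = "amoebozoa", family = NA_character_,
                             source_gene = names(proteins)[pick],
                             stringsAsFactors = FALSE))
}

#' Build a mosaic gene from labeled source segments
#'
#' Concatenates fixed-length segments copied from named reference proteins
#' (one per row of `segment_spec`), optionally at a per-site divergence, and
#' returns residue-exact truth intervals that tile the product without gaps
#' or overlap. At least two segments of >= 20 aa each are required.
#'
#' @param segment_spec data.frame with columns `category`, `protein_id`,
#'   `length_aa`.
#' @param references Named character vector covering every `protein_id`.
#' @param seed Integer seed (segment start positions are drawn uniformly).
#' @param divergence Per-site substitution rate applied to each segment.
#' @return list with `protein` (string) and `truth` (data.frame start / end /
#'   category / protein_id / src_start / src_end).
#' @export
make_mosaic_gene <- function(segment_spec, references, seed = 1L,
                             divergence = 0) {
  if (nrow(segment_spec) < 2L)
    stop_arg("a mosaic gene needs at least 2 segments")
  if (any(segment_spec$length_aa < 20))
    stop_arg("each mosaic segment must be >= 20 aa")
  missing <- setdiff(segment_spec$protein_id, names(references))
  if (length(missing))
    stop_arg("unknown source protein id(s): %s",
             paste(missing, collapse = ", "))
  withr::with_seed(seed, {
    pieces <- character(nrow(segment_spec))
    truth <- vector("list", nrow(segment_spec))
    pos <- 0L
    for (i in seq_len(nrow(segment_spec))) {
      src <- references[[segment_spec$protein_id[i]]]
      L <- segment_spec$length_aa[i]
      if (nchar(src) < L)
        stop_arg("source %s shorter than requested segment (%d aa)",
                 segment_spec$protein_id[i], L)
      a <- sample.int(nchar(src) - L + 1L, 1L)
      seg <- substr(src, a, a + L - 1L)
      if (divergence > 0) seg <- mutate_segment(seg, divergence)
      pieces[i] <- seg
      truth[[i]] <- data.frame(
        start = pos + 1L, end = pos + L,
        category = segment_spec$category[i],
        protein_id = segment_spec$protein_id[i],
        src_start = a, src_end = a + L - 1L, stringsAsFactors = FALSE)
      pos <- pos + L
    }
  })
  list(protein = paste(pieces, collapse = ""), truth = do.call(rbind, truth))
}

# Like mutate_protein() but with no protected first position (mosaic
# segments are not ORF starts).
mutate_segment <- function(seg, divergence) {
  chars <- strsplit(seg, "", fixed = TRUE)[[1]]
  hit <- which(rbinom(length(chars), 1, divergence) == 1L)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}
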