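#' Fenestrate a protein into sliding windows
#'
#' Fragments start at offsets 0, step, 2*step, ... while a full window fits
#' (`floor((L - window)/step) + 1` fragments for L >= window). Proteins
#' shorter than one window yield a single whole-length fragment; trailing
#' residues beyond the last full window get no extra anchored window, so
#' fragment statistics stay comparable across genes.
#'
#' @param protein Protein string (non-empty).
#' @param window_aa Window width (default 40 aa).
#' @param step_aa Sliding step (default 20 aa); `window_aa >= step_aa >= 1`.
#' @return data.frame: fragment_id, start, end (1-based inclusive residue
#'   coordinates), seq.
#' @export
fenestrate <- function(protein, window_aa = 40, step_aa = 20) {
  if (!nzchar(protein)) stop_arg("cannot fenestrate an empty protein")
  if (step_aa < 1 || window_aa < step_aa)
    stop_arg("need window_aa >= step_aa >= 1")
  L <- nchar(protein)
  starts <- if (L < window_aa) 1L else seq(1L, L - window_aa + 1L, by = step_aa)
  ends <- pmin(starts + window_aa - 1L, L)
  data.frame(fragment_id = sprintf("frag_%03d", seq_along(starts)),
             start = starts, end = ends,
             seq = substring(protein, starts, ends),
             stringsAsFactors = FALSE)
}

# Domain-level origin for rhizome classification.
domain_of_category <- function(category) {
  c(virus = "virus", amoebozoa = "eukaryote", other_eukaryote = "eukaryote",
    bacteria = "bacteria", archaea = "archaea")[category]
}

#' Classify gene fragments by best-hit origin
#'
#' Each fragment is searched against the labeled reference database and
#' takes the domain-level category (virus / eukaryote / bacteria / archaea)
#' of its best passing hit; fragments with no passing hit are unclassified.
#' The coverage threshold is waived by default (fragments are already
#' short); the waiver is recorded in the returned attributes.
#'
#' @param fragments Output of [fenestrate()].
#' @param references Named character vector of reference proteins.
#' @param taxonomy_map taxonomy map covering the references.
#' @param thresholds A [hit_thresholds()]; default scan thresholds with
#'   coverage waived.
#' @param scoring A [scoring_scheme()].
#' @return `fragments` with origin, subject_id, pident, evalue columns.
#' @export
classify_fragments <- function(fragments, references, taxonomy_map,
                               thresholds = hit_thresholds(min_coverage = 0),
                               scoring = scoring_scheme()) {
  queries <- setNames(fragments$seq, fragments$fragment_id)
  hits <- search_best_hits(queries, references, thresholds = thresholds,
                           scoring = scoring)
  idx <- match(hits$sseqid, taxonomy_map$protein_id)
  fragments$origin <- ifelse(is.na(hits$sseqid), "unclassified",
                             domain_of_category(taxonomy_map$category[idx]))
  fragments$subject_id <- hits$sseqid
  fragments$pident <- hits$pident
  fragments$evalue <- hits$evalue
  attr(fragments, "coverage_waived") <- thresholds$min_coverage == 0
  fragments
}

#' Rhizome profile of one gene
#'
#' Fenestrates, classifies, and computes the mosaicism index: distinct
#' classified origins / classified fragments (undefined, NA, when no
#' fragment classifies).
#'
#' @param gene_id Label.
#' @param protein Protein string.
#' @param references,taxonomy_map,thresholds,scoring As in
#'   [classify_fragments()].
#' @param window_aa,step_aa As in [fenestrate()].
#' @return list of class `rhizome_profile`: gene_id, window_aa, step_aa,
#'   fragments, mosaicism_index.
#' @export
rhizome_profile <- function(gene_id, protein, references, taxonomy_map,
                            window_aa = 40, step_aa = 20,
                            thresholds = hit_thresholds(min_coverage = 0),
                            scoring = scoring_scheme()) {
  frags <- fenestrate(protein, window_aa, step_aa)
  frags <- classify_fragments(frags, references, taxonomy_map, thresholds,
                              scoring)
  classified <- frags$origin[frags$origin != "unclassified"]
  mi <- if (length(classified)) length(unique(classified)) /
    length(classified) else NA_real_
  structure(list(gene_id = gene_id, window_aa = window_aa, step_aa = step_aa,
                 fragments = frags, mosaicism_index = mi),
            class = "rhizome_profile")
}

RHIZOME_CATEGORIES <- c("virus", "eukaryote", "bacteria", "archaea")

#' Circos-ready rhizome cross-tabulation
#'
#' One row per fragment, one column per origin category, cell 1 for the
#' assigned origin (all zeros for unclassified fragments); suitable for
#' table-viewer-style circular plotting.
#'
#' @param profile A [rhizome_profile()].
#' @param path Optional TSV output path.
#' @return data.frame fragment x category (invisible when written).
#' @export
rhizome_report <- function(profile, path = NULL) {
  frags <- profile$fragments
  m <- matrix(0L, nrow(frags), length(RHIZOME_CATEGORIES),
              dimnames = list(frags$fragment_id, RHIZOME_CATEGORIES))
  for (i in seq_len(nrow(frags)))
    if (frags$origin[i] %in% RHIZOME_CATEGORIES)
      m[i, frags$origin[i]] <- 1L
  out <- data.frame(fragment_id = frags$fragment_id, m,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path)) {
    write_tsv(out, path)
    return(invisible(out))
  }
  out
}
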