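#' Seed HGT candidates from viral best hits
#'
#' One candidate per virus-labeled gene, with the length flag taken from the
#' ORF record (protein length >= `min_len_aa`).
#'
#' @param labels Output of [assign_taxonomy()].
#' @param orfs ORF records (data.frame with gene_id, scaffold_id,
#'   length_aa).
#' @param min_len_aa Length threshold (default 100 aa).
#' @return data.frame of candidates: gene_id, scaffold_id, viral_family,
#'   best-hit columns, length_aa, length_ge_100.
#' @export
flag_viral_best_hits <- function(labels, orfs, min_len_aa = 100) {
  v <- labels[labels$category == "virus", , drop = FALSE]
  idx <- match(v$gene_id, orfs$gene_id)
  if (anyNA(idx)) stop_arg("candidate gene(s) missing from the ORF table")
  out <- data.frame(gene_id = v$gene_id,
                    scaffold_id = orfs$scaffold_id[idx],
                    viral_family = v$viral_family,
                    sseqid = v$sseqid, pident = v$pident,
                    qcovs = v$qcovs, evalue = v$evalue,
                    length_aa = orfs$length_aa[idx],
                    length_ge_100 = orfs$length_aa[idx] >= min_len_aa,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scan a genome for viral homologs (tBLASTn-style)
#'
#' Aligns every viral protein against the six-frame translations of every
#' scaffold and reports each (viral gene, locus) pair passing all three
#' thresholds, with plus-strand nucleotide coordinates and frame. The best
#' local alignment per (gene, scaffold, strand, frame) is reported.
#'
#' @param viral_proteomes Named character vector of viral proteins.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param thresholds A [hit_thresholds()] list (defaults: identity >= 30,
#'   e-value <= 1e-2, coverage >= 30).
#' @param scoring A [scoring_scheme()].
#' @return data.frame of passing hits: qseqid, scaffold_id, strand, frame,
#'   nt_start, nt_end, pident, qcovs, evalue, raw_score.
#' @export
viral_homolog_scan <- function(viral_proteomes, scaffolds,
                               thresholds = hit_thresholds(),
                               scoring = scoring_scheme()) {
  frames <- list()
  for (sc in names(scaffolds)) {
    fwd <- scaffolds[[sc]]
    rev <- reverse_complement(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      for (f in 0:2) {
        prot <- frame_translation(s, f)
        if (!nzchar(prot))
          next
        frames[[sprintf("%s|%s|%d", sc, strand, f)]] <- prot
      }
    }
  }
  if (length(frames) == 0L)
    stop_arg("scaffolds too short for six-frame translation")
  frames_v <- unlist(frames)
  db_len <- sum(nchar(frames_v))
  qenc <- encode_proteome(viral_proteomes, scoring)
  denc <- encode_proteome(frames_v, scoring)
  scores <- sw_score_matrix(qenc, denc, scoring$submat,
                            scoring$gap_open, scoring$gap_extend)
  rows <- list()
  for (i in seq_along(viral_proteomes)) {
    qlen <- nchar(viral_proteomes[[i]])
    smin <- max(scoring$min_score,
                min_passing_score(qlen, db_len, thresholds$max_evalue,
                                  scoring))
    for (j in which(scores[i, ] >= smin)) {
      tb <- sw_traceback(qenc[[i]], denc[[j]], scoring$submat,
                         scoring$gap_open, scoring$gap_extend)
      hit <- hit_from_traceback(tb, viral_proteomes[[i]], frames_v[[j]],
                                scoring, qlen, db_len,
                                names(viral_proteomes)[i], names(frames_v)[j])
      if (hit$pident < thresholds$min_identity ||
          hit$evalue > thresholds$max_evalue ||
          hit$qcovs < thresholds$min_coverage)
        next
      key <- strsplit(names(frames_v)[j], "|", fixed = TRUE)[[1]]
      sc <- key[1]; strand <- key[2]; f <- as.integer(key[3])
      L <- nchar(scaffolds[[sc]])
      # aa span in the frame translation back to plus-strand nucleotides
      a <- f + 3L * (tb$sstart - 1L) + 1L
      b <- f + 3L * tb$send
      if (strand == "-") { tmp <- a; a <- L - b + 1L; b <- L - tmp + 1L }
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = names(viral_proteomes)[i], scaffold_id = sc,
        strand = strand, frame = f, nt_start = a, nt_end = b,
        pident = hit$pident, qcovs = hit$qcovs, evalue = hit$evalue,
        raw_score = hit$raw_score, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(qseqid = character(), scaffold_id = character(),
                      strand = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      pident = numeric(), qcovs = numeric(),
                      evalue = numeric(), raw_score = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$qseqid, out$scaffold_id, out$nt_start), , drop = FALSE]
}

#' Scaffold-context filter
#'
#' A candidate passes iff the count of non-viral-labeled ORFs on its
#' scaffold strictly exceeds the count of virus-labeled ORFs. ORFans count
#' as non-viral; ties fail (conservative strict-majority reading).
#'
#' @param candidates Output of [flag_viral_best_hits()].
#' @param labels Output of [assign_taxonomy()] for every annotated ORF.
#' @param orfs ORF records covering every candidate's scaffold.
#' @return `candidates` with a logical `scaffold_context_pass` column.
#' @export
scaffold_context_filter <- function(candidates, labels, orfs) {
  lab_of <- setNames(labels$category, labels$gene_id)
  candidates$scaffold_context_pass <- vapply(seq_len(nrow(candidates)),
    function(i) {
      sc <- candidates$scaffold_id[i]
      genes <- orfs$gene_id[orfs$scaffold_id == sc]
      if (length(genes) == 0L)
        stop_arg("candidate %s sits on unannotated scaffold %s",
                 candidates$gene_id[i], sc)
      cats <- lab_of[genes]
      n_viral <- sum(cats == "virus", na.rm = TRUE)
      n_nonviral <- sum(cats != "virus" | is.na(cats))
      n_nonviral > n_viral
    }, logical(1))
  candidates
}

#' Merged-database re-screen
#'
#' For each candidate (already length- and context-filtered), hits against
#' an nr-like labeled reference set and against other amoebal proteomes are
#' pooled; hits passing the significance rule (e-value < `max_evalue`,
#' alignment length strictly > `min_aln_len` aa) form a per-candidate merged
#' database. The candidate is re-searched against that database and the
#' pattern is `viral_majority` if > 50% of passing re-search hits are viral,
#' `amoebal_majority` if > 50% are amoebal, otherwise `mixed`. An empty
#' merged database gives `mixed` with a warning.
#'
#' @param candidates Candidate table with `scaffold_context_pass` and
#'   `length_ge_100` TRUE rows (others are returned `untested`).
#' @param candidate_proteins Named character vector covering candidates.
#' @param nr_references Named character vector of nr-like reference
#'   proteins.
#' @param nr_taxonomy taxonomy map for `nr_references` (protein_id,
#'   category, family).
#' @param amoeba_proteomes Named list of named protein vectors from other
#'   amoebal genomes.
#' @param significance list(max_evalue, min_aln_len); defaults 1e-4 and 100
#'   (strict >).
#' @param scoring A [scoring_scheme()].
#' @return `candidates` with a `rescreen_pattern` column in
#'   {viral_majority, amoebal_majority, mixed, untested}.
#' @export
merged_db_rescreen <- function(candidates, candidate_proteins,
                               nr_references, nr_taxonomy,
                               amoeba_proteomes = list(),
                               significance = list(max_evalue = 1e-4,
                                                   min_aln_len = 100),
                               scoring = scoring_scheme()) {
  amoeba_flat <- unlist(unname(amoeba_proteomes))
  if (length(amoeba_flat) && anyDuplicated(names(amoeba_flat)))
    stop_arg("amoebal proteomes carry duplicated gene ids")
  cat_of <- c(setNames(nr_taxonomy$category, nr_taxonomy$protein_id),
              setNames(rep("amoebozoa", length(amoeba_flat)),
                       names(amoeba_flat)))
  pool <- c(nr_references, amoeba_flat)
  pool_len <- sum(nchar(pool))
  candidates$rescreen_pattern <- "untested"
  eligible <- which(candidates$length_ge_100 &
                    candidates$scaffold_context_pass)
  for (i in eligible) {
    gid <- candidates$gene_id[i]
    q <- candidate_proteins[[gid]]
    if (is.null(q)) stop_arg("no protein sequence for candidate %s", gid)
    hits <- all_significant_hits(q, gid, pool, pool_len, significance,
                                 scoring)
    if (nrow(hits) == 0L) {
      warning(sprintf("empty merged database for candidate %s; pattern mixed",
                      gid), call. = FALSE)
      candidates$rescreen_pattern[i] <- "mixed"
      next
    }
    merged <- pool[hits$sseqid]
    re <- all_significant_hits(q, gid, merged, sum(nchar(merged)),
                               significance, scoring)
    if (nrow(re) == 0L) {
      candidates$rescreen_pattern[i] <- "mixed"
      next
    }
    cats <- cat_of[re$sseqid]
    n <- nrow(re)
    n_viral <- sum(cats == "virus", na.rm = TRUE)
    n_amoebal <- sum(cats == "amoebozoa", na.rm = TRUE)
    candidates$rescreen_pattern[i] <-
      if (n_viral > n / 2) "viral_majority"
      else if (n_amoebal > n / 2) "amoebal_majority"
      else "mixed"
  }
  candidates
}

# Every database hit passing the significance rule (not just the best one).
all_significant_hits <- function(query, query_id, database, db_length,
                                 significance, scoring) {
  qenc <- encode_protein(query, scoring)
  denc <- encode_proteome(database, scoring)
  scores <- sw_score_matrix(list(qenc), denc, scoring$submat,
                            scoring$gap_open, scoring$gap_extend)
  smin <- max(scoring$min_score,
              min_passing_score(nchar(query), db_length,
                                significance$max_evalue, scoring))
  rows <- list()
  for (j in which(scores[1, ] >= smin)) {
    tb <- sw_traceback(qenc, denc[[j]], scoring$submat, scoring$gap_open,
                       scoring$gap_extend)
    hit <- hit_from_traceback(tb, query, database[[j]], scoring,
                              nchar(query), db_length, query_id,
                              names(database)[j])
    if (hit$evalue < significance$max_evalue &&
        hit$length > significance$min_aln_len)
      rows[[length(rows) + 1L]] <- hit
  }
  if (length(rows) == 0L) return(empty_hit_row(query_id)[0, ])
  do.call(rbind, rows)
}

#' COG functional summary
#'
#' Each candidate inherits the single-letter COG category of its best hit
#' passing the e-value threshold (no identity/coverage filter, matching the
#' permissive functional-annotation search). Unassigned candidates are
#' excluded from share denominators; shares are reported as integer percent.
#'
#' @param candidate_proteins Named character vector.
#' @param cog_reference Named character vector of COG-labeled proteins.
#' @param cog_categories Named character vector: protein_id -> category
#'   letter.
#' @param evalue_threshold Maximum e-value (default 0.1).
#' @param scoring A [scoring_scheme()].
#' @return data.frame category / n_genes / share_pct (empty when nothing is
#'   assigned).
#' @export
cog_summary <- function(candidate_proteins, cog_reference, cog_categories,
                        evalue_threshold = 0.1,
                        scoring = scoring_scheme()) {
  if (length(cog_reference) == 0L) stop_arg("cog_reference must be non-empty")
  hits <- search_best_hits(candidate_proteins, cog_reference,
                           thresholds = hit_thresholds(
                             min_identity = 0, max_evalue = evalue_threshold,
                             min_coverage = 0),
                           scoring = scoring)
  assigned <- hits[!is.na(hits$sseqid), , drop = FALSE]
  if (nrow(assigned) == 0L)
    return(data.frame(category = character(), n_genes = integer(),
                      share_pct = numeric(), stringsAsFactors = FALSE))
  counts <- table(cog_categories[assigned$sseqid])
  cog_share_table(setNames(as.integer(counts), names(counts)))
}

#' COG category shares from counts
#'
#' @param counts Named integer vector of gene counts per COG category.
#' @return data.frame category / n_genes / share_pct (integer percent over
#'   assigned genes).
#' @export
cog_share_table <- function(counts) {
  total <- sum(counts)
  data.frame(category = names(counts), n_genes = as.integer(counts),
             share_pct = vapply(counts, share_pct, numeric(1),
                                denominator = total, style = "integer"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap between a candidate set and a reference gene set
#'
#' Counts candidates with a reciprocal-best-hit partner in the reference
#' set; the share is reported over the candidate set at one-decimal
#' precision.
#'
#' @param candidate_proteins,reference_proteins Named character vectors.
#' @param thresholds,scoring As in [reciprocal_best_hits()].
#' @return list: shared (count), share_pct (one decimal), pairs (RBH table).
#' @export
overlap_with_gene_set <- function(candidate_proteins, reference_proteins,
                                  thresholds = hit_thresholds(),
                                  scoring = scoring_scheme()) {
  if (length(candidate_proteins) == 0L || length(reference_proteins) == 0L)
    stop_arg("both gene sets must be non-empty")
  pairs <- reciprocal_best_hits(candidate_proteins, reference_proteins,
                                thresholds, scoring)
  list(shared = nrow(pairs),
       share_pct = share_pct(nrow(pairs), length(candidate_proteins),
                             "one_decimal"),
       pairs = pairs)
}

#' Run the best-hit labeling stage of the pipeline on a genome
#'
#' Convenience wrapper: searches every annotated ORF protein against a
#' labeled reference database, labels genes by best hit, and seeds the
#' candidate table.
#'
#' @param orfs ORF records with `protein` column (e.g. from [find_orfs()] or
#'   a `synthetic_genome`).
#' @param reference_db Named character vector of reference proteins.
#' @param taxonomy_map taxonomy map covering the database.
#' @param thresholds,scoring As in [search_best_hits()].
#' @param min_len_aa Candidate length threshold.
#' @return list: best_hits, labels, candidates.
#' @export
hgt_scan <- function(orfs, reference_db, taxonomy_map,
                     thresholds = hit_thresholds(),
                     scoring = scoring_scheme(), min_len_aa = 100) {
  queries <- setNames(orfs$protein, orfs$gene_id)
  best <- search_best_hits(queries, reference_db, thresholds = thresholds,
                           scoring = scoring)
  labels <- assign_taxonomy(best, taxonomy_map)
  cands <- flag_viral_best_hits(labels, orfs, min_len_aa = min_len_aa)
  cands <- scaffold_context_filter(cands, labels, orfs)
  list(best_hits = best, labels = labels, candidates = cands)
}
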