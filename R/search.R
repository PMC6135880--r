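#' Hit-filtering thresholds
#'
#' Default thresholds mirror the viral-homolog screen: amino-acid identity
#' >= 30%, e-value <= 1e-2, query coverage >= 30%.
#'
#' @param min_identity Minimum percent identity over alignment columns.
#' @param max_evalue Maximum Karlin-Altschul e-value.
#' @param min_coverage Minimum percent query coverage.
#' @return A named list of thresholds.
#' @export
hit_thresholds <- function(min_identity = 30, max_evalue = 1e-2,
                           min_coverage = 30) {
  list(min_identity = min_identity, max_evalue = max_evalue,
       min_coverage = min_coverage)
}

empty_hit_row <- function(query_id) {
  data.frame(qseqid = query_id, sseqid = NA_character_, raw_score = NA_integer_,
             bit_score = NA_real_, pident = NA_real_, length = NA_integer_,
             nident = NA_integer_, qcovs = NA_real_, scovs = NA_real_,
             evalue = NA_real_, qstart = NA_integer_, qend = NA_integer_,
             sstart = NA_integer_, send = NA_integer_,
             qaln = NA_character_, saln = NA_character_,
             stringsAsFactors = FALSE)
}

#' Best database hit per query
#'
#' Aligns every query against a labeled protein database and reports, per
#' query, the single hit with the lowest e-value among hits passing all
#' thresholds (ties broken by higher raw score, then lexicographically
#' smallest subject id). Queries with no passing hit get a no-hit row
#' (`sseqid` NA). A score-only pass prunes subjects that cannot reach the
#' e-value threshold before any traceback is computed.
#'
#' @param queries,database Named character vectors of protein sequences.
#' @param db_length Effective database length in residues for e-values
#'   (defaults to the total residues in `database`).
#' @param thresholds A [hit_thresholds()] list.
#' @param scoring A [scoring_scheme()].
#' @return A data.frame with one row per query, in query order.
#' @export
search_best_hits <- function(queries, database,
                             db_length = sum(nchar(database)),
                             thresholds = hit_thresholds(),
                             scoring = scoring_scheme()) {
  if (length(database) == 0L) stop_arg("database must be non-empty")
  if (is.null(names(queries)) || is.null(names(database)))
    stop_arg("queries and database must be named")
  qenc <- encode_proteome(queries, scoring)
  denc <- encode_proteome(database, scoring)
  scores <- sw_score_matrix(qenc, denc, scoring$submat,
                            scoring$gap_open, scoring$gap_extend)
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    qlen <- nchar(queries[[i]])
    smin <- max(scoring$min_score,
                min_passing_score(qlen, db_length, thresholds$max_evalue,
                                  scoring))
    cand <- which(scores[i, ] >= smin)
    best <- NULL
    if (length(cand)) {
      # evalue is monotone in score, so scan candidates by descending score
      cand <- cand[order(-scores[i, cand], names(database)[cand])]
      for (j in cand) {
        if (!is.null(best) && scores[i, j] < best$raw_score) break
        tb <- sw_traceback(qenc[[i]], denc[[j]], scoring$submat,
                           scoring$gap_open, scoring$gap_extend)
        hit <- hit_from_traceback(tb, queries[[i]], database[[j]], scoring,
                                  qlen, db_length,
                                  names(queries)[i], names(database)[j])
        if (hit$pident >= thresholds$min_identity &&
            hit$evalue <= thresholds$max_evalue &&
            hit$qcovs >= thresholds$min_coverage) {
          if (is.null(best)) best <- hit
        }
      }
    }
    rows[[i]] <- if (is.null(best)) empty_hit_row(names(queries)[i]) else best
  }
  do.call(rbind, rows)
}

#' Reciprocal best hits between two proteomes
#'
#' A pair is kept iff each gene is the other's best passing hit under
#' [search_best_hits()] semantics. Symmetric: `reciprocal_best_hits(A, B)`
#' equals `reciprocal_best_hits(B, A)` with the columns swapped.
#'
#' @param proteome_a,proteome_b Named character vectors of proteins.
#' @param thresholds,scoring As in [search_best_hits()].
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 thresholds = hit_thresholds(),
                                 scoring = scoring_scheme()) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L)
    stop_arg("both proteomes must be non-empty")
  ab <- search_best_hits(proteome_a, proteome_b, thresholds = thresholds,
                         scoring = scoring)
  ba <- search_best_hits(proteome_b, proteome_a, thresholds = thresholds,
                         scoring = scoring)
  ab <- ab[!is.na(ab$sseqid), c("qseqid", "sseqid")]
  ba <- ba[!is.na(ba$sseqid), c("qseqid", "sseqid")]
  if (nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  back <- setNames(ba$sseqid, ba$qseqid)
  keep <- !is.na(back[ab$sseqid]) & back[ab$sseqid] == ab$qseqid
  out <- data.frame(gene_a = ab$qseqid[keep], gene_b = ab$sseqid[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Ortholog groups across multiple genomes
#'
#' Genes shorter than `min_len_aa` are dropped, reciprocal best hits are
#' computed for every genome pair, and ortholog groups are the connected
#' components of the union RBH graph. Also reports, per ordered genome pair
#' (G, H), the fraction of groups containing G that also contain H.
#'
#' @param proteomes Named list (genome id -> named character vector of
#'   proteins); at least two genomes.
#' @param min_len_aa Minimum protein length retained before clustering.
#' @param thresholds,scoring As in [search_best_hits()].
#' @return list with `groups` (data.frame group_id / genome_id / gene_id),
#'   `sharing` (genome x genome matrix of sharing fractions) and `rbh`
#'   (per-pair RBH tables).
#' @export
cluster_orthologs <- function(proteomes, min_len_aa = 100,
                              thresholds = hit_thresholds(),
                              scoring = scoring_scheme()) {
  if (!is.list(proteomes) || length(proteomes) < 2L)
    stop_arg("cluster_orthologs() needs at least 2 genomes")
  if (is.null(names(proteomes))) stop_arg("proteomes must be a named list")
  proteomes <- lapply(proteomes, function(p) p[nchar(p) >= min_len_aa])
  gids <- names(proteomes)
  edges <- list(); rbh <- list()
  for (a in seq_along(gids)) {
    for (b in seq_along(gids)) {
      if (a >= b) next
      pr <- reciprocal_best_hits(proteomes[[a]], proteomes[[b]],
                                 thresholds, scoring)
      rbh[[paste(gids[a], gids[b], sep = "|")]] <- pr
      if (nrow(pr))
        edges[[length(edges) + 1L]] <-
          data.frame(from = paste(gids[a], pr$gene_a, sep = "::"),
                     to = paste(gids[b], pr$gene_b, sep = "::"),
                     stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0L) {
    groups <- data.frame(group_id = character(), genome_id = character(),
                         gene_id = character(), stringsAsFactors = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(do.call(rbind, edges), directed = FALSE)
    comp <- igraph::components(g)
    v <- names(comp$membership)
    groups <- data.frame(
      group_id = sprintf("OG%04d", comp$membership),
      genome_id = sub("::.*$", "", v),
      gene_id = sub("^.*?::", "", v),
      stringsAsFactors = FALSE)
    groups <- groups[order(groups$group_id, groups$genome_id,
                           groups$gene_id), , drop = FALSE]
    rownames(groups) <- NULL
  }
  sharing <- matrix(NA_real_, length(gids), length(gids),
                    dimnames = list(gids, gids))
  for (a in gids) {
    in_a <- unique(groups$group_id[groups$genome_id == a])
    for (b in gids) {
      if (a == b) { sharing[a, b] <- 1; next }
      in_b <- unique(groups$group_id[groups$genome_id == b])
      sharing[a, b] <- if (length(in_a)) length(intersect(in_a, in_b)) /
        length(in_a) else NA_real_
    }
  }
  list(groups = groups, sharing = sharing, rbh = rbh)
}
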