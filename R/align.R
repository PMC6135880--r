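#' Scoring scheme for protein alignment
#'
#' Bundles the substitution matrix, affine gap penalties and the fixed
#' Karlin-Altschul parameters used to convert raw Smith-Waterman scores to
#' bit scores and e-values. Defaults correspond to gapped BLOSUM62 with gap
#' open 11 / extend 1 (a gap of length k costs 11 + k), with the published
#' gapped constants lambda = 0.267, K = 0.041.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. "BLOSUM62", "BLOSUM50").
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul parameters for this matrix/gap combination.
#' @param min_score Minimum raw score below which [align_pair()] reports no hit.
#' @return A list of class `sw_scoring` with the resolved matrix and parameters.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, min_score = 1L) {
  submat <- load_submat(matrix)
  structure(list(matrix_name = matrix, submat = submat,
                 alphabet = rownames(submat),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K,
                 min_score = as.integer(min_score)),
            class = "sw_scoring")
}

load_submat <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(err) FALSE)
  if (!ok || !exists(name, envir = e))
    stop_arg("unknown substitution matrix '%s'", name)
  m <- get(name, envir = e)
  storage.mode(m) <- "integer"
  m
}

encode_protein <- function(seq, scoring) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, scoring$alphabet)
  if (anyNA(idx))
    stop_arg("sequence contains letters outside the scoring alphabet: %s",
             paste(unique(chars[is.na(idx)]), collapse = ","))
  idx - 1L
}

encode_proteome <- function(seqs, scoring) {
  lapply(seqs, encode_protein, scoring = scoring)
}

#' Karlin-Altschul e-value for a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' effective database length in residues.
#'
#' @param score Raw Smith-Waterman score(s).
#' @param m Query length (residues).
#' @param n Effective database length (residues).
#' @param scoring A [scoring_scheme()].
#' @return Numeric e-value(s); doubles linearly with `n` at fixed score.
#' @export
karlin_evalue <- function(score, m, n, scoring = scoring_scheme()) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}

#' @rdname karlin_evalue
#' @export
bit_score <- function(score, scoring = scoring_scheme()) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

# Minimum raw score that can reach `max_evalue` for query length m vs db n.
min_passing_score <- function(m, n, max_evalue, scoring) {
  ceiling(log(scoring$K * m * n / max_evalue) / scoring$lambda)
}

aligned_identity <- function(qaln, saln) {
  qc <- strsplit(qaln, "", fixed = TRUE)[[1]]
  sc <- strsplit(saln, "", fixed = TRUE)[[1]]
  # X is an ambiguity placeholder and never counts as an identity
  sum(qc == sc & qc != "-" & qc != "X" & qc != "*")
}

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment with affine gaps, returning score,
#' identity, coverage, spans and a Karlin-Altschul e-value. Identity is
#' `100 * identities / alignment columns` (gap columns included in the
#' denominator); coverage is query-side, `100 * aligned query residues /
#' query length` (subject coverage reported alongside).
#'
#' @param query,subject Protein sequences (single character strings).
#' @param scoring A [scoring_scheme()].
#' @param m,n Query length and effective database length for the e-value;
#'   default to the two sequence lengths.
#' @param query_id,subject_id Labels carried into the hit record.
#' @return A one-row data.frame (an alignment hit) or `NULL` when the best
#'   raw score falls below `scoring$min_score`.
#' @export
align_pair <- function(query, subject, scoring = scoring_scheme(),
                       m = nchar(query), n = nchar(subject),
                       query_id = "query", subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject))
    stop_arg("align_pair() requires non-empty sequences")
  tb <- sw_traceback(encode_protein(query, scoring),
                     encode_protein(subject, scoring),
                     scoring$submat, scoring$gap_open, scoring$gap_extend)
  if (tb$score < scoring$min_score) return(NULL)
  hit_from_traceback(tb, query, subject, scoring, m, n, query_id, subject_id)
}

hit_from_traceback <- function(tb, query, subject, scoring, m, n,
                               query_id, subject_id) {
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1]]
  qaln <- paste(ifelse(tb$qidx > 0, qc[pmax(tb$qidx, 1)], "-"), collapse = "")
  saln <- paste(ifelse(tb$sidx > 0, sc[pmax(tb$sidx, 1)], "-"), collapse = "")
  ncol_aln <- length(tb$qidx)
  nident <- aligned_identity(qaln, saln)
  data.frame(
    qseqid = query_id, sseqid = subject_id,
    raw_score = tb$score,
    bit_score = bit_score(tb$score, scoring),
    pident = 100 * nident / ncol_aln,
    length = ncol_aln, nident = nident,
    qcovs = 100 * (tb$qend - tb$qstart + 1) / nchar(query),
    scovs = 100 * (tb$send - tb$sstart + 1) / nchar(subject),
    evalue = karlin_evalue(tb$score, m, n, scoring),
    qstart = tb$qstart, qend = tb$qend,
    sstart = tb$sstart, send = tb$send,
    qaln = qaln, saln = saln,
    stringsAsFactors = FALSE)
}
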