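#' Percentage with report-style rounding
#'
#' Shares are printed the way the headline statistics are reported: integer
#' percent for values >= 1%, one decimal below 1% ("auto"), or explicitly as
#' integer / one-decimal percent. Rounding uses R's default round-half-even.
#'
#' @param numerator,denominator Counts.
#' @param style "auto", "integer" or "one_decimal".
#' @return Numeric percentage, rounded per `style`.
#' @export
share_pct <- function(numerator, denominator,
                      style = c("auto", "integer", "one_decimal")) {
  style <- match.arg(style)
  if (denominator == 0) return(NA_real_)
  pct <- 100 * numerator / denominator
  switch(style,
         auto = ifelse(pct >= 1, round(pct), round(pct, 1)),
         integer = round(pct),
         one_decimal = round(pct, 1))
}

#' Best-hit taxonomic labeling
#'
#' Each gene inherits the category (and viral family, where applicable) of
#' its single best database hit; genes with no passing hit are ORFans. This
#' is an explicit, deterministic replacement for LCA-style taxonomic
#' binning: every report derived from these labels states the
#' single-best-hit simplification.
#'
#' @param best_hits Output of [search_best_hits()] (one row per gene; no-hit
#'   rows have `sseqid` NA).
#' @param taxonomy_map data.frame with columns protein_id, category, family
#'   covering every subject in the table.
#' @return data.frame: gene_id, category (amoebozoa / other_eukaryote /
#'   bacteria / archaea / virus / ORFan), viral_family, plus the best-hit
#'   columns sseqid, pident, qcovs, evalue, raw_score.
#' @export
assign_taxonomy <- function(best_hits, taxonomy_map) {
  idx <- match(best_hits$sseqid, taxonomy_map$protein_id)
  bad <- !is.na(best_hits$sseqid) & is.na(idx)
  if (any(bad))
    stop_arg("subject(s) missing from the taxonomy map: %s",
             paste(unique(best_hits$sseqid[bad]), collapse = ", "))
  category <- ifelse(is.na(best_hits$sseqid), "ORFan",
                     taxonomy_map$category[idx])
  family <- ifelse(category == "virus", taxonomy_map$family[idx],
                   NA_character_)
  data.frame(gene_id = best_hits$qseqid, category = category,
             viral_family = family, sseqid = best_hits$sseqid,
             pident = best_hits$pident, qcovs = best_hits$qcovs,
             evalue = best_hits$evalue, raw_score = best_hits$raw_score,
             stringsAsFactors = FALSE)
}

#' Taxonomic distribution summary
#'
#' Category proportions over all genes (summing to 1) and, additionally,
#' per-viral-family shares as a fraction of viral-labeled genes, reported
#' both raw and at printed precision (integer percent at >= 1%, one decimal
#' below).
#'
#' @param labels Output of [assign_taxonomy()].
#' @return list: category_counts, category_props, family_counts,
#'   family_share_pct (raw), family_share_printed (rounded).
#' @export
summarize_taxonomic_distribution <- function(labels) {
  if (nrow(labels) == 0L) stop_arg("no labels to summarize")
  cat_counts <- table(labels$category)
  props <- as.numeric(cat_counts) / nrow(labels)
  names(props) <- names(cat_counts)
  viral <- labels[labels$category == "virus", , drop = FALSE]
  fam_counts <- if (nrow(viral)) table(viral$viral_family) else table(character())
  fam_raw <- if (nrow(viral)) 100 * as.numeric(fam_counts) / nrow(viral)
             else numeric(0)
  names(fam_raw) <- names(fam_counts)
  fam_printed <- vapply(names(fam_counts), function(f)
    share_pct(fam_counts[[f]], nrow(viral), "auto"), numeric(1))
  list(category_counts = cat_counts,
       category_props = props,
       family_counts = fam_counts,
       family_share_pct = fam_raw,
       family_share_printed = fam_printed)
}
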