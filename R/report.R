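#' Assemble the run report
#'
#' Collects the stage outputs into one machine-readable structure and
#' (optionally) a human-readable printout: taxonomic category proportions,
#' viral-family shares, ORFan share, the candidate funnel (viral best hit ->
#' length -> scaffold context -> re-screen patterns -> direction calls), COG
#' shares, overlap statistics and synteny conservation totals. Percentages
#' are rounded at printed precision (integer percent at >= 1%, one decimal
#' below); every report carries a metadata block stating the
#' single-best-hit taxonomy simplification and the thresholds used.
#'
#' @param labels Output of [assign_taxonomy()] (required).
#' @param candidates Candidate table after the cascade stages run so far.
#' @param directions Optional character vector of direction calls.
#' @param cog Optional [cog_summary()] table.
#' @param overlap Optional [overlap_with_gene_set()] result.
#' @param conservation Optional [conservation_matrix()] table.
#' @param thresholds The [hit_thresholds()] used.
#' @param path Optional JSON output path.
#' @param verbose Print the human-readable summary.
#' @return The report list, invisibly when written or printed.
#' @export
run_report <- function(labels, candidates = NULL, directions = NULL,
                       cog = NULL, overlap = NULL, conservation = NULL,
                       thresholds = hit_thresholds(), path = NULL,
                       verbose = FALSE) {
  tax <- summarize_taxonomic_distribution(labels)
  n <- nrow(labels)
  funnel <- list(
    n_genes = n,
    n_viral_best_hit = if (!is.null(candidates)) nrow(candidates)
      else sum(labels$category == "virus"),
    n_length_ge_100 = if (!is.null(candidates))
      sum(candidates$length_ge_100) else NA_integer_,
    n_context_pass = if (!is.null(candidates) &&
                         "scaffold_context_pass" %in% names(candidates))
      sum(candidates$length_ge_100 & candidates$scaffold_context_pass)
      else NA_integer_,
    rescreen_patterns = if (!is.null(candidates) &&
                            "rescreen_pattern" %in% names(candidates))
      as.list(table(candidates$rescreen_pattern)) else NULL,
    directions = if (!is.null(directions)) as.list(table(directions))
      else NULL)
  report <- list(
    metadata = list(
      tool = "amoebahgt",
      taxonomy_rule = "single best hit (no lowest-common-ancestor binning)",
      thresholds = thresholds,
      generated = "run_report"),
    taxonomy = list(
      category_counts = as.list(tax$category_counts),
      category_share_pct = lapply(as.list(tax$category_props),
                                  function(p) share_pct(p * n, n, "auto")),
      orfan_share_pct = share_pct(sum(labels$category == "ORFan"), n,
                                  "one_decimal"),
      family_counts = as.list(tax$family_counts),
      family_share_pct = as.list(tax$family_share_printed)),
    funnel = funnel,
    cog = if (!is.null(cog)) cog,
    overlap = if (!is.null(overlap))
      list(shared = overlap$shared, share_pct = overlap$share_pct),
    conservation = conservation)
  if (verbose) {
    cat("amoebahgt run report\n")
    cat(sprintf("  genes: %d; viral best hits: %d; ORFan share: %.1f%%\n",
                n, funnel$n_viral_best_hit,
                report$taxonomy$orfan_share_pct))
    if (length(tax$family_share_printed)) {
      cat("  viral family shares (%):\n")
      for (f in names(tax$family_share_printed))
        cat(sprintf("    %-16s %s\n", f, tax$family_share_printed[[f]]))
    }
    if (!is.na(funnel$n_length_ge_100 %||% NA))
      cat(sprintf("  funnel: %d viral -> %d >=100aa -> %s context-pass\n",
                  funnel$n_viral_best_hit, funnel$n_length_ge_100,
                  ifelse(is.na(funnel$n_context_pass), "NA",
                         funnel$n_context_pass)))
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  invisible(report)
}
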