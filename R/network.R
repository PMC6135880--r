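#' Build a bipartite exchange network
#'
#' Host genes on one side, viral genes (or viral families) on the other;
#' edges carry identity, coverage and e-value. At family resolution viral
#' nodes are merged per family and edge attributes are aggregated by best
#' e-value (highest identity/coverage among the merged hits).
#'
#' @param hits data.frame of hits with columns for the host gene, the viral
#'   subject and pident / qcovs / evalue. Works with
#'   [viral_homolog_scan()] output, candidate tables or best-hit tables.
#' @param resolution "gene" or "family".
#' @param taxonomy_map Needed at family resolution to map subjects to
#'   families (unless the table carries a `viral_family` column).
#' @return An igraph bipartite graph (vertex attribute `type`: FALSE =
#'   host gene, TRUE = viral node).
#' @export
build_exchange_network <- function(hits, resolution = c("gene", "family"),
                                   taxonomy_map = NULL) {
  resolution <- match.arg(resolution)
  host_col <- if ("gene_id" %in% names(hits)) "gene_id" else "qseqid"
  if (nrow(hits) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  viral <- if ("sseqid" %in% names(hits)) hits$sseqid else hits$qseqid
  host <- hits[[host_col]]
  if (resolution == "family") {
    fam <- if ("viral_family" %in% names(hits)) hits$viral_family
    else if (!is.null(taxonomy_map))
      taxonomy_map$family[match(viral, taxonomy_map$protein_id)]
    else stop_arg("family resolution needs viral_family or a taxonomy map")
    viral <- fam
  }
  edges <- data.frame(host = host, viral = viral,
                      pident = hits$pident, qcovs = hits$qcovs,
                      evalue = hits$evalue, stringsAsFactors = FALSE)
  # aggregate parallel edges by best e-value
  key <- paste(edges$host, edges$viral, sep = "\r")
  agg <- do.call(rbind, lapply(split(edges, key), function(e) {
    data.frame(host = e$host[1], viral = e$viral[1],
               pident = max(e$pident), qcovs = max(e$qcovs),
               evalue = min(e$evalue), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  g <- igraph::graph_from_data_frame(
    agg, directed = FALSE,
    vertices = data.frame(name = c(unique(agg$host), unique(agg$viral)),
                          type = rep(c(FALSE, TRUE),
                                     c(length(unique(agg$host)),
                                       length(unique(agg$viral)))),
                          stringsAsFactors = FALSE))
  g
}

#' Export an exchange network
#'
#' SIF lines read `hostGene interactsWith viralNode`; GraphML carries edge
#' attributes and round-trips through [import_network()]; edge TSV is one
#' row per edge with attributes.
#'
#' @param network An igraph graph from [build_exchange_network()].
#' @param path Output file.
#' @param format "sif", "graphml" or "tsv".
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml",
                                                     "tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_arg("unknown format"))
  el <- igraph::as_edgelist(network)
  if (format == "sif") {
    writeLines(if (nrow(el)) paste(el[, 1], "interactsWith", el[, 2])
               else character(0), path)
  } else if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    ea <- igraph::edge_attr(network)
    out <- data.frame(host = el[, 1], viral = el[, 2],
                      stringsAsFactors = FALSE)
    for (a in names(ea)) out[[a]] <- ea[[a]]
    write_tsv(out, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = "graphml") {
  igraph::read_graph(path, format = format)
}
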