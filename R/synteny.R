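#' Select scaffolds rich in viral-best-hit genes
#'
#' One synteny block per scaffold carrying at least `min_viral_genes`
#' virus-labeled genes, with the block's genes ordered by start coordinate.
#'
#' @param orfs ORF records (gene_id, scaffold_id, start).
#' @param labels Output of [assign_taxonomy()].
#' @param min_viral_genes Minimum viral genes per scaffold (default 3).
#' @return list of blocks, each `list(scaffold_id, gene_ids)`.
#' @export
select_viral_scaffolds <- function(orfs, labels, min_viral_genes = 3) {
  viral_ids <- labels$gene_id[labels$category == "virus"]
  v <- orfs[orfs$gene_id %in% viral_ids, , drop = FALSE]
  blocks <- list()
  for (sc in sort(unique(v$scaffold_id))) {
    sub <- v[v$scaffold_id == sc, , drop = FALSE]
    if (nrow(sub) < min_viral_genes) next
    sub <- sub[order(sub$start), , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- list(scaffold_id = sc,
                                          gene_ids = sub$gene_id)
  }
  blocks
}

#' Map a synteny block onto a target genome
#'
#' Gene presence uses reciprocal best hits (avoiding paralog inflation);
#' the order-preservation score is the longest common subsequence of the
#' block's gene order against the partner order along a single target
#' scaffold, divided by the block size, with a fully reversed order counted
#' as collinear (draft scaffolds have arbitrary orientation). Partners
#' scattered over several target scaffolds count toward presence but only
#' the best single-scaffold run contributes to the order score.
#'
#' @param block A block from [select_viral_scaffolds()].
#' @param target_orfs Target ORF records (gene_id, scaffold_id, start).
#' @param rbh RBH pairs between source and target proteomes (data.frame
#'   gene_a = source, gene_b = target).
#' @return list: conserved (count), order_score in `[0, 1]`,
#'   matched_scaffolds (character).
#' @export
map_block <- function(block, target_orfs, rbh) {
  partner <- setNames(rbh$gene_b, rbh$gene_a)[block$gene_ids]
  present <- !is.na(partner)
  conserved <- sum(present)
  if (conserved == 0L)
    return(list(conserved = 0L, order_score = 0,
                matched_scaffolds = character(0)))
  idx <- match(partner[present], target_orfs$gene_id)
  tsc <- target_orfs$scaffold_id[idx]
  tstart <- target_orfs$start[idx]
  src_order <- seq_len(sum(present)) # block genes in source coordinate order
  best <- 0L
  for (sc in unique(tsc)) {
    on_sc <- which(tsc == sc)
    target_rank <- on_sc[order(tstart[on_sc])]
    fwd <- lcs_length_int(as.integer(src_order[src_order %in% on_sc]),
                          as.integer(target_rank))
    rev_ <- lcs_length_int(as.integer(src_order[src_order %in% on_sc]),
                           as.integer(base::rev(target_rank)))
    best <- max(best, fwd, rev_)
  }
  list(conserved = conserved,
       order_score = best / length(block$gene_ids),
       matched_scaffolds = sort(unique(tsc)))
}

#' Scaffold-by-genome conservation matrix
#'
#' @param blocks Blocks from [select_viral_scaffolds()].
#' @param targets Named list; each element `list(orfs = <ORF records>,
#'   rbh = <RBH pairs source->target>)`.
#' @param path Optional TSV output path.
#' @return data.frame: one row per block plus a `total` row, one column per
#'   target genome (conserved gene counts) and a `block_size` column.
#' @export
conservation_matrix <- function(blocks, targets, path = NULL) {
  if (length(blocks) == 0L) stop_arg("no blocks to map")
  m <- matrix(0L, length(blocks), length(targets),
              dimnames = list(vapply(blocks, `[[`, character(1),
                                     "scaffold_id"),
                              names(targets)))
  scores <- m * 0
  for (b in seq_along(blocks)) {
    for (g in names(targets)) {
      res <- map_block(blocks[[b]], targets[[g]]$orfs, targets[[g]]$rbh)
      m[b, g] <- res$conserved
      scores[b, g] <- res$order_score
    }
  }
  out <- data.frame(
    block = c(rownames(m), "total"),
    block_size = c(vapply(blocks, function(b) length(b$gene_ids),
                          integer(1)), NA_integer_),
    rbind(m, colSums(m)), stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "order_scores") <- scores
  if (!is.null(path)) {
    write_tsv(out, path)
    return(invisible(out))
  }
  out
}

#' Genome tree from ortholog-group sharing
#'
#' Pairwise genome distance is 1 minus the Jaccard index of ortholog-group
#' membership (groups from [cluster_orthologs()]); the tree is built by
#' [neighbor_joining()]. Genome pairs sharing no groups get distance 1.
#'
#' @param proteomes Named list of named protein vectors (>= 3 genomes).
#' @param min_len_aa,thresholds,scoring As in [cluster_orthologs()].
#' @return list: tree (`phylo`), distances (matrix), orthologs
#'   (the [cluster_orthologs()] result).
#' @export
genome_tree_from_ortholog_jaccard <- function(proteomes, min_len_aa = 100,
                                              thresholds = hit_thresholds(),
                                              scoring = scoring_scheme()) {
  if (length(proteomes) < 3L) stop_arg("need at least 3 genomes for a tree")
  og <- cluster_orthologs(proteomes, min_len_aa, thresholds, scoring)
  gids <- names(proteomes)
  D <- matrix(0, length(gids), length(gids), dimnames = list(gids, gids))
  member <- lapply(gids, function(g)
    unique(og$groups$group_id[og$groups$genome_id == g]))
  names(member) <- gids
  for (i in seq_along(gids)) {
    for (j in seq_along(gids)) {
      if (i >= j) next
      u <- union(member[[i]], member[[j]])
      jac <- if (length(u)) length(intersect(member[[i]], member[[j]])) /
        length(u) else 0
      D[i, j] <- D[j, i] <- 1 - jac
    }
  }
  list(tree = neighbor_joining(D), distances = D, orthologs = og)
}
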