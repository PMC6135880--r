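#' Poisson-corrected pairwise distances from aligned proteins
#'
#' For each pair, `p` is the mismatch fraction over columns where both
#' sequences are ungapped, and `d = -ln(1 - p)`. `p >= 0.95` is clamped to
#' 0.95 (distance ceiling `-ln(0.05) ~ 3.0`) to keep the matrix finite.
#'
#' @param aligned Named character vector of equal-length aligned proteins
#'   (gaps as `-`).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(aligned) {
  if (length(aligned) < 2L) stop_arg("need at least 2 sequences")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L)
    stop_arg("aligned sequences must have equal length")
  chars <- lapply(aligned, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  n <- length(aligned)
  D <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- chars[[i]]; b <- chars[[j]]
      ok <- a != "-" & b != "-"
      p <- if (any(ok)) mean(a[ok] != b[ok]) else 0
      p <- min(p, 0.95)
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Classical Q-criterion neighbor joining with deterministic tie-breaking:
#' taxa are processed in label order and the first minimal Q pair in that
#' order is joined. Negative branch lengths are clamped to zero with the
#' deficit moved to the sister edge (the path length between the joined
#' taxa is conserved). Returns an unrooted `ape::phylo` tree.
#'
#' @param D Symmetric distance matrix with labeled dimnames (>= 2 taxa;
#'   >= 4 for a non-trivial unrooted topology).
#' @return An `ape` phylo object.
#' @export
neighbor_joining <- function(D) {
  if (is.null(dimnames(D)[[1]])) stop_arg("distance matrix must be labeled")
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop_arg("distance matrix must be symmetric")
  ord <- order(rownames(D))
  Dm <- D[ord, ord, drop = FALSE]
  nw <- rownames(Dm)
  n <- nrow(Dm)
  if (n < 2L) stop_arg("need at least 2 taxa")
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (n > 3L) {
    r <- rowSums(Dm)
    bq <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        q <- (n - 2) * Dm[i, j] - r[i] - r[j]
        if (q < bq - 1e-12) { bq <- q; bi <- i; bj <- j }
      }
    }
    li <- Dm[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (n - 2))
    lj <- Dm[bi, bj] - li
    if (li < 0) { lj <- Dm[bi, bj]; li <- 0 }
    if (lj < 0) { li <- Dm[bi, bj]; lj <- 0 }
    dnew <- (Dm[bi, ] + Dm[bj, ] - Dm[bi, bj]) / 2
    dnew <- dnew[-c(bi, bj)]
    merged <- sprintf("(%s:%s,%s:%s)", nw[bi], fmt(li), nw[bj], fmt(lj))
    keep <- setdiff(seq_len(n), c(bi, bj))
    Dm <- Dm[keep, keep, drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    nw <- c(nw[keep], merged)
    n <- n - 1L
  }
  txt <- if (n == 2L) {
    sprintf("(%s:%s,%s:%s);", nw[1], fmt(Dm[1, 2] / 2), nw[2],
            fmt(Dm[1, 2] / 2))
  } else {
    l1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
    l2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
    l3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);", nw[1], fmt(l1), nw[2], fmt(l2),
            nw[3], fmt(l3))
  }
  ape::read.tree(text = txt)
}

#' A tree with leaf group labels
#'
#' Wraps an `ape` phylo tree with per-leaf groups: exactly one `query` leaf
#' (the host gene under test), plus `amoeba`, `virus` and `other_cellular`
#' homolog leaves.
#'
#' @param tree An `ape` phylo object.
#' @param groups Named character vector (leaf label -> group).
#' @return list of class `labeled_tree`.
#' @export
labeled_tree <- function(tree, groups) {
  if (!inherits(tree, "phylo")) stop_arg("tree must be an ape phylo object")
  if (anyDuplicated(tree$tip.label)) stop_arg("leaf labels must be unique")
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing))
    stop_arg("no group for leaf/leaves: %s", paste(missing, collapse = ", "))
  bad <- setdiff(unique(groups), c("query", "amoeba", "virus",
                                   "other_cellular"))
  if (length(bad))
    stop_arg("unknown group(s): %s", paste(bad, collapse = ", "))
  if (sum(groups[tree$tip.label] == "query") != 1L)
    stop_arg("exactly one leaf must carry group 'query'")
  structure(list(tree = tree, groups = groups[tree$tip.label]),
            class = "labeled_tree")
}

tips_of_node <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

sister_tips <- function(phy, tips) {
  ntip <- length(phy$tip.label)
  node <- if (length(tips) == 1L) match(tips, phy$tip.label)
          else ape::getMRCA(phy, tips)
  parent <- phy$edge[phy$edge[, 2] == node, 1]
  if (length(parent) == 0L) return(character(0))
  sibs <- setdiff(phy$edge[phy$edge[, 1] == parent, 2], node)
  unlist(lapply(sibs, tips_of_node, phy = phy))
}

is_clade <- function(phy, tips) {
  if (length(tips) == 1L) return(TRUE)
  mrca <- ape::getMRCA(phy, tips)
  setequal(tips_of_node(phy, mrca), tips)
}

#' Infer the direction of a putative gene transfer from a labeled tree
#'
#' The tree is rooted at an `other_cellular` leaf if one exists, else at the
#' midpoint. The call is `virus_to_amoeba` iff the amoebal leaves (query
#' included) form a clade whose sister consists only of viral leaves while
#' the viral leaves are paraphyletic with respect to that clade;
#' `amoeba_to_virus` iff the viral leaves form a clade nested inside amoebal
#' paraphyly (sister exclusively amoebal). Every other configuration —
#' including trees with no viral leaf, or reciprocally monophyletic groups —
#' is `inconclusive`.
#'
#' @param lt A [labeled_tree()].
#' @return list of class `direction_call`: direction, rooted_at, clade
#'   (description of the supporting clade, or NA).
#' @export
infer_transfer_direction <- function(lt) {
  if (!inherits(lt, "labeled_tree")) stop_arg("expected a labeled_tree")
  groups <- lt$groups
  A <- names(groups)[groups %in% c("query", "amoeba")]
  V <- names(groups)[groups == "virus"]
  O <- names(groups)[groups == "other_cellular"]
  if (!any(groups == "query")) stop_arg("tree has no query leaf")
  mk <- function(direction, rooted_at, clade = NA_character_)
    structure(list(direction = direction, rooted_at = rooted_at,
                   clade = clade), class = "direction_call")
  if (length(V) == 0L) return(mk("inconclusive", NA_character_))
  if (length(O)) {
    out <- sort(O)[1]
    phy <- ape::root(lt$tree, outgroup = out, resolve.root = TRUE)
    rooted_at <- paste0("outgroup:", out)
  } else {
    phy <- phangorn::midpoint(lt$tree)
    rooted_at <- "midpoint"
  }
  sisterA <- sister_tips(phy, A)
  if (is_clade(phy, A) && length(sisterA) > 0 && all(sisterA %in% V) &&
      !is_clade(phy, V))
    return(mk("virus_to_amoeba", rooted_at,
              sprintf("amoebal clade (%s) with viral sister (%s)",
                      paste(sort(A), collapse = ","),
                      paste(sort(sisterA), collapse = ","))))
  sisterV <- sister_tips(phy, V)
  if (is_clade(phy, V) && length(sisterV) > 0 && all(sisterV %in% A) &&
      !is_clade(phy, A))
    return(mk("amoeba_to_virus", rooted_at,
              sprintf("viral clade (%s) with amoebal sister (%s)",
                      paste(sort(V), collapse = ","),
                      paste(sort(sisterV), collapse = ","))))
  mk("inconclusive", rooted_at)
}

#' Fitch parsimony ancestral sequence at the root
#'
#' Per-column Fitch small parsimony on a rooted binary tree: leaf state sets
#' are singletons, internal sets are the intersection of the children when
#' non-empty else the union (each union event costs one change). Gap/missing
#' leaf characters are excluded from state sets (wildcards). The root state
#' is the alphabetically smallest member of the root set; all-missing
#' columns yield `-`.
#'
#' @param tree Rooted binary `ape` phylo tree.
#' @param sequences Named character vector of equal-length leaf sequences
#'   covering every tip.
#' @return list: sequence (root reconstruction), score (total parsimony
#'   changes).
#' @export
fitch_ancestral <- function(tree, sequences) {
  if (!ape::is.rooted(tree)) stop_arg("fitch_ancestral() needs a rooted tree")
  if (!ape::is.binary(tree)) stop_arg("fitch_ancestral() needs a binary tree")
  missing <- setdiff(tree$tip.label, names(sequences))
  if (length(missing))
    stop_arg("leaf without sequence: %s", paste(missing, collapse = ", "))
  seqs <- sequences[tree$tip.label]
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_arg("leaf sequences must have equal length")
  L <- lens[[1]]
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  root <- setdiff(edge[, 1], edge[, 2])[1]
  children <- split(edge[, 2], edge[, 1])
  out_chars <- character(L)
  total <- 0L
  for (col in seq_len(L)) {
    score <- 0L
    down <- function(node) {
      if (node <= ntip) {
        ch <- chars[[node]][col]
        return(if (ch %in% c("-", ".", "?")) NULL else ch)
      }
      kids <- children[[as.character(node)]]
      s1 <- down(kids[1]); s2 <- down(kids[2])
      if (is.null(s1)) return(s2)
      if (is.null(s2)) return(s1)
      both <- intersect(s1, s2)
      if (length(both)) return(both)
      score <<- score + 1L
      union(s1, s2)
    }
    rs <- down(root)
    out_chars[col] <- if (is.null(rs)) "-" else sort(rs)[1]
    total <- total + score
  }
  list(sequence = paste(out_chars, collapse = ""), score = total)
}
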