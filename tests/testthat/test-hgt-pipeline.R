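test_that("best-hit taxonomy labels genes and flags ORFans", {
  hits <- data.frame(
    qseqid = c("g1", "g2", "g3"),
    sseqid = c("pandoravirus_p001", NA, "bacteria_p002"),
    pident = c(90, NA, 45), qcovs = c(95, NA, 80),
    evalue = c(1e-50, NA, 1e-10), raw_score = c(500L, NA, 120L),
    stringsAsFactors = FALSE)
  tax <- data.frame(
    protein_id = c("pandoravirus_p001", "bacteria_p002"),
    category = c("virus", "bacteria"), family = c("pandoravirus", NA),
    stringsAsFactors = FALSE)
  labels <- assign_taxonomy(hits, tax)
  expect_identical(labels$category, c("virus", "ORFan", "bacteria"))
  expect_identical(labels$viral_family, c("pandoravirus", NA, NA))
  hits$sseqid[2] <- "mystery"
  expect_error(assign_taxonomy(hits, tax), "mystery")
})

family_count_fixture <- function() {
  # 366 virus-labeled genes with the reported per-family best-hit counts
  fams <- c(pandoravirus = 117, mimivirus = 67, mollivirus = 37,
            marseillevirus = 24, pithovirus = 2, phycodnavirus = 119)
  data.frame(gene_id = sprintf("g%03d", seq_len(sum(fams))),
             category = "virus",
             viral_family = rep(names(fams), fams),
             stringsAsFactors = FALSE)
}

test_that("viral family shares print at reported precision", {
  s <- summarize_taxonomic_distribution(family_count_fixture())
  expect_equal(s$family_share_printed[["pandoravirus"]], 32)
  expect_equal(s$family_share_printed[["mimivirus"]], 18)
  expect_equal(s$family_share_printed[["mollivirus"]], 10)
  expect_equal(s$family_share_printed[["marseillevirus"]], 7)
  expect_equal(s$family_share_printed[["pithovirus"]], 0.5)
  expect_equal(sum(s$family_share_pct), 100, tolerance = 1e-9)
  expect_equal(sum(s$category_props), 1, tolerance = 1e-9)
})

test_that("candidate seeding carries the 100-aa length flag", {
  labels <- data.frame(gene_id = c("a", "b"), category = "virus",
                       viral_family = "mimivirus", sseqid = "x",
                       pident = 90, qcovs = 90, evalue = 1e-30,
                       raw_score = 300L, stringsAsFactors = FALSE)
  orfs <- data.frame(gene_id = c("a", "b"), scaffold_id = "s1",
                     length_aa = c(150L, 80L), stringsAsFactors = FALSE)
  cand <- flag_viral_best_hits(labels, orfs)
  expect_identical(cand$length_ge_100, c(TRUE, FALSE))
})

context_fixture <- function(n_viral, n_nonviral) {
  orfs <- data.frame(
    gene_id = sprintf("g%d", seq_len(n_viral + n_nonviral)),
    scaffold_id = "s1", length_aa = 150L, stringsAsFactors = FALSE)
  labels <- data.frame(
    gene_id = orfs$gene_id,
    category = rep(c("virus", "ORFan"), c(n_viral, n_nonviral)),
    stringsAsFactors = FALSE)
  cand <- data.frame(gene_id = "g1", scaffold_id = "s1",
                     length_ge_100 = TRUE, stringsAsFactors = FALSE)
  scaffold_context_filter(cand, labels, orfs)$scaffold_context_pass
}

test_that("scaffold context requires a strict non-viral majority", {
  expect_true(context_fixture(2, 3))   # 3 > 2
  expect_false(context_fixture(3, 0))  # all viral
  expect_false(context_fixture(2, 2))  # tie fails
})

test_that("merged-database re-screen applies majority and strict length rules", {
  withr::with_seed(701, {
    core <- paste0("M", random_aa(149))
  })
  cand <- data.frame(gene_id = "c1", length_ge_100 = TRUE,
                     scaffold_context_pass = TRUE, stringsAsFactors = FALSE)
  prot <- setNames(core, "c1")
  # 4 significant viral subjects, 1 amoebal subject
  nr <- setNames(rep(core, 4), sprintf("vir_%d", 1:4))
  nr_tax <- data.frame(protein_id = names(nr), category = "virus",
                       family = "pandoravirus", stringsAsFactors = FALSE)
  amoeba <- list(acast = setNames(core, "am_1"))
  out <- merged_db_rescreen(cand, prot, nr, nr_tax, amoeba)
  expect_identical(out$rescreen_pattern, "viral_majority")

  # 2 viral vs 2 amoebal -> mixed (tie is not a majority)
  nr2 <- nr[1:2]
  amoeba2 <- list(acast = setNames(rep(core, 2), c("am_1", "am_2")))
  out2 <- merged_db_rescreen(cand, prot, nr2,
                             nr_tax[1:2, , drop = FALSE], amoeba2)
  expect_identical(out2$rescreen_pattern, "mixed")

  # alignment length of exactly 100 aa is excluded (strict >): empty merged
  # database warns and yields mixed
  withr::with_seed(702, { short <- paste0("M", random_aa(99)) })
  cand3 <- data.frame(gene_id = "c2", length_ge_100 = TRUE,
                      scaffold_context_pass = TRUE, stringsAsFactors = FALSE)
  expect_warning(
    out3 <- merged_db_rescreen(cand3, setNames(short, "c2"),
                               setNames(short, "v1"),
                               data.frame(protein_id = "v1",
                                          category = "virus",
                                          family = "mimivirus",
                                          stringsAsFactors = FALSE)),
    "empty merged database")
  expect_identical(out3$rescreen_pattern, "mixed")

  # candidates failing earlier stages stay untested
  cand4 <- data.frame(gene_id = "c1", length_ge_100 = FALSE,
                      scaffold_context_pass = TRUE, stringsAsFactors = FALSE)
  out4 <- merged_db_rescreen(cand4, prot, nr, nr_tax, amoeba)
  expect_identical(out4$rescreen_pattern, "untested")
})

test_that("COG shares reproduce the printed functional distribution", {
  counts <- c(A = 1L, E = 4L, F = 3L, G = 1L, H = 3L, J = 2L, K = 9L,
              L = 19L, M = 1L, O = 13L, P = 7L, R = 16L, S = 5L, T = 17L,
              U = 2L, V = 1L)
  tab <- cog_share_table(counts)
  expect_equal(tab$share_pct[tab$category == "L"], 18)
  expect_equal(tab$share_pct[tab$category == "T"], 16)
  expect_equal(tab$share_pct[tab$category == "R"], 15)
  expect_equal(tab$share_pct[tab$category == "O"], 12)
  expect_equal(tab$share_pct[tab$category == "K"], 9)
  transport <- sum(tab$n_genes[tab$category %in% c("E", "F", "G", "H", "P")])
  expect_equal(share_pct(transport, sum(counts), "integer"), 17)
})

test_that("COG assignment by best hit works end to end", {
  withr::with_seed(703, {
    refs <- setNames(vapply(rep(120, 3), random_aa, character(1)),
                     c("cogL", "cogT", "cogK"))
  })
  cats <- c(cogL = "L", cogT = "T", cogK = "K")
  cands <- setNames(unname(refs[c(1, 1, 2)]), c("c1", "c2", "c3"))
  tab <- cog_summary(cands, refs, cats)
  expect_equal(tab$n_genes[tab$category == "L"], 2)
  expect_equal(tab$n_genes[tab$category == "T"], 1)
  # nothing assignable -> empty table, no division by zero
  withr::with_seed(704, {
    tab0 <- cog_summary(setNames(random_aa(60), "cx"), refs, cats,
                        evalue_threshold = 1e-30)
  })
  expect_equal(nrow(tab0), 0)
})

test_that("overlap share is reported at one decimal", {
  withr::with_seed(705, {
    shared <- setNames(vapply(rep(110, 4), random_aa, character(1)),
                       paste0("s", 1:4))
    only_a <- setNames(vapply(rep(110, 2), random_aa, character(1)),
                       paste0("a", 1:2))
    only_b <- setNames(vapply(rep(110, 3), random_aa, character(1)),
                       paste0("b", 1:3))
  })
  a <- c(shared, only_a)
  b <- c(setNames(shared, paste0("r", 1:4)), only_b)
  ov <- overlap_with_gene_set(a, b)
  expect_equal(ov$shared, 4)
  expect_equal(ov$share_pct, share_pct(4, 6, "one_decimal"))
  disjoint <- overlap_with_gene_set(only_a, only_b)
  expect_equal(disjoint$shared, 0)
  expect_equal(disjoint$share_pct, 0)
  same <- overlap_with_gene_set(shared, setNames(shared, paste0("r", 1:4)))
  expect_equal(same$share_pct, 100)
  expect_equal(share_pct(30, 366, "one_decimal"), 8.2)
})

test_that("the scan labels a synthetic genome consistently with truth", {
  fx <- pipeline_fixture(seed = 41, n_transfers = 12, divergence = 0.1)
  g <- fx$genome
  amo <- make_amoeba_references(setNames(g$orfs$protein, g$orfs$gene_id)[
    g$truth$gene_id[g$truth$source_category == "host"]][1:20],
    divergence = 0.2, seed = 42)
  db <- c(fx$panels$proteins, amo$proteins)
  tax <- rbind(fx$panels$taxonomy,
               amo$taxonomy[, c("protein_id", "category", "family")])
  res <- hgt_scan(g$orfs, db, tax)
  truth_cat <- g$truth$source_category[match(res$labels$gene_id,
                                             g$truth$gene_id)]
  is_implant <- startsWith(truth_cat, "viral:")
  ok_implant <- res$labels$category[is_implant] == "virus"
  ok_host <- res$labels$category[!is_implant] %in% c("amoebozoa", "ORFan")
  expect_gte(mean(c(ok_implant, ok_host)), 0.95)
  # implants recover their family too
  fam_truth <- sub("^viral:", "", truth_cat[is_implant])
  expect_gte(mean(res$labels$viral_family[is_implant] == fam_truth), 0.9)
  # candidates sit on majority-non-viral scaffolds by construction
  expect_true(all(res$candidates$scaffold_context_pass))
})

test_that("tightening any threshold never increases the candidate count", {
  fx <- pipeline_fixture(seed = 51, n_transfers = 8, divergence = 0.25)
  g <- fx$genome
  base_thr <- hit_thresholds()
  n_cand <- function(thr) {
    res <- hgt_scan(g$orfs, fx$panels$proteins, fx$panels$taxonomy,
                    thresholds = thr)
    nrow(res$candidates)
  }
  n0 <- n_cand(base_thr)
  expect_lte(n_cand(hit_thresholds(min_identity = 60)), n0)
  expect_lte(n_cand(hit_thresholds(min_coverage = 70)), n0)
  expect_lte(n_cand(hit_thresholds(max_evalue = 1e-30)), n0)
})

test_that("length and context filters commute", {
  fx <- pipeline_fixture(seed = 61, n_transfers = 10, divergence = 0.1)
  res <- hgt_scan(fx$genome$orfs, fx$panels$proteins, fx$panels$taxonomy)
  cand <- res$candidates
  len_first <- cand[cand$length_ge_100, ]
  len_first <- len_first[len_first$scaffold_context_pass, "gene_id"]
  ctx_first <- cand[cand$scaffold_context_pass, ]
  ctx_first <- ctx_first[ctx_first$length_ge_100, "gene_id"]
  expect_identical(sort(len_first), sort(ctx_first))
})

test_that("the six-frame genome scan finds implants at their true loci", {
  panels <- generate_reference_panels(2, 5, c(150, 10), seed = 91)
  genome <- generate_host_genome(2, 3, seed = 92)
  genome <- implant_transfers(genome, panels, 1, 0, seed = 93)
  tr <- genome$truth[startsWith(genome$truth$source_category, "viral:"), ]
  hits <- viral_homolog_scan(panels$proteins[
    vapply(panels$viral, names, character(5))], genome$scaffolds)
  src <- hits[hits$qseqid == tr$source_protein_id, , drop = FALSE]
  expect_gte(nrow(src), 1)
  best <- src[which.max(src$raw_score), ]
  expect_equal(best$pident, 100)
  expect_identical(best$scaffold_id, tr$scaffold_id)
  expect_identical(best$strand, tr$strand)
  # the reported locus covers the implanted gene body (stop codon excluded)
  expect_lte(abs(best$nt_start - tr$start), 3)
  expect_gte(best$nt_end, tr$end - 3)

  # no-implant genomes stay clean at default thresholds
  for (s in 94:96) {
    g0 <- generate_host_genome(2, 3, seed = s)
    h0 <- viral_homolog_scan(panels$proteins[
      vapply(panels$viral, names, character(5))], g0$scaffolds)
    expect_equal(nrow(h0), 0)
  }
})
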