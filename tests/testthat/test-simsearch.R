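test_that("align_pair matches the brute-force oracle on random short pairs", {
  sc <- scoring_scheme()
  withr::with_seed(101, {
    for (k in 1:120) {
      q <- random_aa(sample(5:30, 1))
      s <- random_aa(sample(5:30, 1))
      oracle <- oracle_sw_score(q, s, sc$submat, sc$gap_open, sc$gap_extend)
      hit <- align_pair(q, s, sc)
      got <- if (is.null(hit)) 0 else hit$raw_score
      if (oracle < sc$min_score) {
        expect_true(is.null(hit) || hit$raw_score == oracle)
      } else {
        expect_equal(got, oracle)
        # reported alignment is a genuinely optimal local alignment
        expect_equal(rescore_alignment(hit$qaln, hit$saln, sc$submat,
                                       sc$gap_open, sc$gap_extend), oracle)
        # spans and identity agree with the reported alignment strings
        expect_identical(gsub("-", "", hit$qaln, fixed = TRUE),
                         substr(q, hit$qstart, hit$qend))
        expect_identical(gsub("-", "", hit$saln, fixed = TRUE),
                         substr(s, hit$sstart, hit$send))
        expect_equal(hit$pident, 100 * hit$nident / hit$length)
      }
    }
  })
})

test_that("align_pair agrees with Biostrings local alignment scores", {
  sc <- scoring_scheme()
  withr::with_seed(202, {
    for (k in 1:40) {
      q <- random_aa(sample(20:60, 1))
      s <- random_aa(sample(20:60, 1))
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = sc$gap_open,
        gapExtension = sc$gap_extend, scoreOnly = TRUE)
      hit <- align_pair(q, s, sc)
      got <- if (is.null(hit)) 0 else hit$raw_score
      expect_equal(got, max(ref, 0))
    }
  })
})

test_that("the textbook HEAGAWGHEE/PAWHEAE alignment is recovered", {
  sc <- scoring_scheme("BLOSUM50", gap_open = 10, gap_extend = 1)
  hit <- align_pair("HEAGAWGHEE", "PAWHEAE", sc)
  oracle <- oracle_sw_score("HEAGAWGHEE", "PAWHEAE", sc$submat, 10, 1)
  expect_equal(hit$raw_score, oracle)
  expect_identical(hit$qaln, "AWGHE")
  expect_identical(hit$saln, "AW-HE")
})

test_that("identical sequences align at 100% identity and coverage", {
  q <- random_aa(100)
  hit <- align_pair(q, q)
  expect_equal(hit$pident, 100)
  expect_equal(hit$qcovs, 100)
  expect_equal(hit$scovs, 100)
  expect_error(align_pair("", "AAA"), "non-empty")
  expect_error(scoring_scheme("NOSUCHMATRIX"), "unknown substitution matrix")
})

test_that("e-values are linear in database length and monotone in score", {
  sc <- scoring_scheme()
  expect_equal(karlin_evalue(60, 100, 2e6, sc),
               2 * karlin_evalue(60, 100, 1e6, sc))
  scores <- seq(10, 200, by = 10)
  ev <- karlin_evalue(scores, 100, 1e6, sc)
  expect_true(all(diff(ev) < 0))
})

test_that("best-hit search picks the true source among decoys", {
  withr::with_seed(303, {
    db <- setNames(vapply(rep(120, 20), random_aa, character(1)),
                   sprintf("decoy_%02d", 1:20))
    target <- random_aa(120)
    db <- c(db, target = target)
    hits <- search_best_hits(c(q1 = target), db)
    expect_identical(hits$sseqid, "target")
    # a diverged copy still wins against unrelated decoys
    q2 <- mutate_protein(paste0("M", target), 0.1)
    hits2 <- search_best_hits(c(q2 = q2), db)
    expect_identical(hits2$sseqid, "target")
    # no-hit behaviour
    none <- search_best_hits(c(q3 = random_aa(80)), db)
    expect_true(is.na(none$sseqid))
  })
})

test_that("identity threshold excludes hits just under the cutoff", {
  withr::with_seed(404, {
    src <- random_aa(150)
    q <- mutate_protein(paste0("M", src), 0.5)
  })
  db <- c(ref = paste0("M", src))
  loose <- search_best_hits(setNames(q, "q"), db,
                            thresholds = hit_thresholds(min_identity = 0,
                                                        max_evalue = 10,
                                                        min_coverage = 0))
  pid <- loose$pident
  expect_false(is.na(pid))
  over <- hit_thresholds(min_identity = pid + 0.1, max_evalue = 10,
                         min_coverage = 0)
  under <- hit_thresholds(min_identity = pid - 0.1, max_evalue = 10,
                          min_coverage = 0)
  expect_true(is.na(search_best_hits(setNames(q, "q"), db,
                                     thresholds = over)$sseqid))
  expect_identical(search_best_hits(setNames(q, "q"), db,
                                    thresholds = under)$sseqid, "ref")
})

test_that("reciprocal best hits are symmetric and require reciprocity", {
  withr::with_seed(505, {
    base <- setNames(vapply(rep(120, 8), random_aa, character(1)),
                     sprintf("g%02d", 1:8))
  })
  a <- base
  b <- setNames(base, sprintf("h%02d", 1:8))
  pr <- reciprocal_best_hits(a, b)
  expect_equal(nrow(pr), 8)
  expect_identical(pr$gene_b, sub("^g", "h", pr$gene_a))
  # symmetry on a noisier fixture
  withr::with_seed(506, {
    a2 <- setNames(vapply(rep(110, 5), random_aa, character(1)),
                   paste0("a", 1:5))
    b2 <- setNames(c(vapply(a2[1:3], function(x)
      mutate_protein(paste0("M", x), 0.15), character(1)),
      random_aa(110), random_aa(110)), paste0("b", 1:5))
  })
  ab <- reciprocal_best_hits(a2, b2)
  ba <- reciprocal_best_hits(b2, a2)
  expect_identical(ab$gene_a, ba$gene_b[match(ab$gene_b, ba$gene_a)])
  expect_error(reciprocal_best_hits(character(0), b2), "non-empty")
})

test_that("one-sided best hits are not reciprocal pairs", {
  withr::with_seed(507, {
    core <- paste0("M", random_aa(149))
    diverged <- mutate_protein(core, 0.1)
  })
  # qa's best hit is b1, but b1's best hit is qa's identical twin 'better'
  a <- c(qa = diverged, better = core)
  b <- c(b1 = core)
  pr <- reciprocal_best_hits(a, b)
  expect_equal(nrow(pr), 1)
  expect_identical(pr$gene_a, "better")
  expect_false(any(pr$gene_a == "qa"))
})

test_that("ortholog clustering partitions genes and chains components", {
  withr::with_seed(606, {
    base <- setNames(vapply(rep(130, 10), random_aa, character(1)),
                     sprintf("p%02d", 1:10))
  })
  two <- list(gA = base, gB = base)
  og <- cluster_orthologs(two, min_len_aa = 100)
  expect_equal(length(unique(og$groups$group_id)), 10)
  expect_equal(og$sharing["gA", "gB"], 1.0)
  # partition: no gene appears in two groups
  key <- paste(og$groups$genome_id, og$groups$gene_id)
  expect_equal(anyDuplicated(key), 0)

  # A~B via left half, B~C via right half, A and C unrelated -> one group of 3
  withr::with_seed(607, {
    x <- random_aa(120); y <- random_aa(120)
    pa <- c(a1 = paste0(x, random_aa(120)))
    pb <- c(b1 = paste0(x, y))
    pc <- c(c1 = paste0(random_aa(120), y))
  })
  og2 <- cluster_orthologs(list(A = pa, B = pb, C = pc), min_len_aa = 100)
  expect_equal(length(unique(og2$groups$group_id)), 1)
  expect_equal(nrow(og2$groups), 3)
  expect_error(cluster_orthologs(list(A = pa)), "at least 2")
})

test_that("universal plus genome-specific genes give designed sharing fractions", {
  withr::with_seed(608, {
    universal <- setNames(vapply(rep(120, 8), random_aa, character(1)),
                          sprintf("u%02d", 1:8))
    mk <- function(tag) c(universal,
                          setNames(vapply(rep(120, 3), random_aa,
                                          character(1)),
                                   sprintf("%s_own%d", tag, 1:3)))
    trio <- list(G1 = mk("G1"), G2 = mk("G2"), G3 = mk("G3"))
  })
  og <- cluster_orthologs(trio, min_len_aa = 100)
  expect_equal(og$sharing["G1", "G2"], 1.0)  # only universal genes group
  expect_equal(length(unique(og$groups$group_id)), 8)
})
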