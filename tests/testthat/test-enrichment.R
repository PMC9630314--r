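ranked_10 <- function() {
  as_ranked_profile(stats::setNames(as.numeric(10:1), letters[1:10]))
}

test_that("rank_profile averages per-cohort correlations and sorts", {
  x1 <- planted_cohort(seed = 51, n_samples = 100)
  x2 <- planted_cohort(seed = 52, n_samples = 100)
  p <- rank_profile(list(x1, x2), "MG01")
  expect_false("MG01" %in% p$gene)
  expect_true(all(diff(p$score) <= 0))
  # independent recomputation for one gene
  per <- vapply(list(x1, x2), function(x) {
    lv <- log2(x$values + 1)
    stats::cor(lv["MG01", ], lv["MG02", ])
  }, numeric(1))
  expect_equal(p$score[p$gene == "MG02"], mean(per), tolerance = 1e-10)
  expect_error(rank_profile(list(x1), "NOPE"), "NOPE")
})

test_that("a gene identical to the query ranks first with score 1", {
  set.seed(5)
  v <- matrix(rexp(5 * 30), 5, 30,
              dimnames = list(c("Q", "COPY", "a", "b", "c"),
                              sprintf("s%02d", 1:30)))
  v["COPY", ] <- v["Q", ]
  p <- rank_profile(make_expr(v), "Q")
  expect_identical(p$gene[1], "COPY")
  expect_equal(p$score[1], 1, tolerance = 1e-12)
})

test_that("planted co-members occupy the top ranks of the profile", {
  top_ok <- vapply(1:10, function(r) {
    x <- planted_cohort(seed = 500 + r)
    p <- rank_profile(list(x), "MG01")
    all(p$gene[1:7] %in% module_genes())
  }, logical(1))
  expect_gte(sum(top_ok), 9L)
})

test_that("mean-expression profile mode ranks by abundance", {
  x <- planted_cohort(seed = 61, n_samples = 50)
  p <- rank_profile(list(x), "MG01", profile_mode = "mean_expression")
  lv <- log2(x$values + 1)
  means <- rowMeans(lv)[p$gene]
  expect_equal(p$score, unname(means), tolerance = 1e-12)
  expect_true(all(diff(p$score) <= 0))
})

test_that("ES matches the step-by-step running-sum oracle", {
  p <- ranked_10()
  # singleton set at the top: full hit weight at position 1
  expect_equal(enrichment_score(p, "a")$es, 1)
  # top block and bottom block
  top <- enrichment_score(p, c("a", "b", "c"))
  expect_equal(top$es, oracle_es(p$score, p$gene, c("a", "b", "c")),
               tolerance = 1e-12)
  bottom <- enrichment_score(p, c("h", "i", "j"))
  expect_lt(bottom$es, 0)
  expect_equal(bottom$es, oracle_es(p$score, p$gene, c("h", "i", "j")),
               tolerance = 1e-12)
  # random profiles, random sets
  set.seed(71)
  for (r in 1:25) {
    N <- sample(10:50, 1)
    pr <- as_ranked_profile(stats::setNames(rnorm(N), sprintf("g%03d", 1:N)))
    gs <- sample(pr$gene, sample(2:8, 1))
    expect_equal(enrichment_score(pr, gs)$es,
                 oracle_es(pr$score, pr$gene, gs), tolerance = 1e-12)
  }
})

test_that("ES agrees with an established implementation", {
  set.seed(73)
  pr <- as_ranked_profile(stats::setNames(rnorm(80), sprintf("g%03d", 1:80)))
  stats_vec <- stats::setNames(pr$score, pr$gene)
  for (r in 1:10) {
    gs <- sample(pr$gene, 8)
    expect_equal(
      enrichment_score(pr, gs)$es,
      fgsea::calcGseaStat(stats_vec, which(names(stats_vec) %in% gs),
                          gseaParam = 1),
      tolerance = 1e-10
    )
  }
})

test_that("ES rejects empty and universe-covering sets, stays in [-1, 1]", {
  p <- ranked_10()
  expect_error(enrichment_score(p, c("zz", "yy")), "no overlap")
  expect_error(enrichment_score(p, p$gene), "entire universe")
  set.seed(79)
  for (r in 1:20) {
    gs <- sample(p$gene, sample(1:9, 1))
    expect_lte(abs(enrichment_score(p, gs)$es), 1)
  }
})

test_that("complement sets have opposite ES sign at weight zero", {
  set.seed(83)
  for (r in 1:10) {
    sc <- sort(rnorm(12), decreasing = TRUE)
    pr <- as_ranked_profile(stats::setNames(sc, sprintf("x%02d", 1:12)))
    gs <- sample(pr$gene, 5)
    e1 <- enrichment_score(pr, gs, weight_p = 0)$es
    e2 <- enrichment_score(pr, setdiff(pr$gene, gs), weight_p = 0)$es
    expect_equal(e1, -e2, tolerance = 1e-12)
  }
})

test_that("promoting a hit never decreases positive unweighted ES", {
  p <- ranked_10()
  combs <- utils::combn(10, 3)
  for (k in seq_len(ncol(combs))) {
    pos <- combs[, k]
    es0 <- enrichment_score(p, p$gene[pos], weight_p = 0)$es
    if (es0 <= 0) next
    for (i in seq_along(pos)) {
      for (newp in setdiff(seq_len(pos[i] - 1L), pos)) {
        pos2 <- sort(c(setdiff(pos, pos[i]), newp))
        es1 <- enrichment_score(p, p$gene[pos2], weight_p = 0)$es
        expect_gte(es1, es0 - 1e-12)
      }
    }
  }
})

test_that("permutation NES/FDR are seeded and identify the planted set", {
  x <- planted_cohort(seed = 91, n_background = 60)
  p <- rank_profile(list(x), "MG01")
  sets <- generate_gene_sets(
    list(module_spec("m1", setdiff(module_genes(), "MG01"), 0.9)),
    n_random_sets = 10, set_size = 7, universe = p$gene, seed = 3
  )
  r1 <- nes_and_fdr(p, sets, n_permutations = 200, seed = 7)
  r2 <- nes_and_fdr(p, sets, n_permutations = 200, seed = 7)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$fdr_q, r2$fdr_q)
  planted <- r1[r1$set == "MODULE_m1", ]
  expect_gte(planted$nes, 1.4)
  expect_lte(planted$fdr_q, 0.05)
  expect_true(all(r1$p_value >= 0 & r1$p_value <= 1))
  expect_true(all(r1$fdr_q >= 0 & r1$fdr_q <= 1, na.rm = TRUE))
  expect_error(nes_and_fdr(p, sets, n_permutations = 50), "100")
})

test_that("filter_results applies both cutoffs with stable |NES| order", {
  res <- tibble::tibble(
    set = c("a", "b", "c", "d"),
    nes = c(2.0, -1.6, 1.2, 1.5),
    fdr_q = c(0.01, 0.02, 0.001, 0.2)
  )
  all_kept <- filter_results(res, nes_cutoff = 0, fdr_cutoff = 1)
  expect_identical(nrow(all_kept), 4L)
  expect_identical(nrow(filter_results(res, nes_cutoff = Inf)), 0L)
  kept <- filter_results(res, nes_cutoff = 1.4, fdr_cutoff = 0.05)
  expect_identical(kept$set, c("a", "b"))  # d fails FDR, c fails NES
})

test_that("GMT and rnk files round-trip", {
  sets <- list(SET_A = c("x", "y", "z"), SET_B = c("p", "q"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_identical(read_gmt(gmt), sets)

  p <- ranked_10()
  rnk <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(p, rnk)
  p2 <- read_rnk(rnk)
  expect_equal(p2$score, p$score, tolerance = 1e-12)
  expect_identical(p2$gene, p$gene)
})
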