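test_that("first-order correlations match a naive double loop", {
  x <- random_expr(6, 10, seed = 31)
  C <- correlation_matrix(x, transform = "log2p1")
  lv <- log2(x$values + 1)
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(C[i, j], stats::cor(lv[i, ], lv[j, ]), tolerance = 1e-10)
    }
  }
  expect_identical(attr(C, "method"), "pearson")
})

test_that("identical and negated genes hit the correlation bounds", {
  v <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                4, 3, 2, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "neg"), sprintf("s%d", 1:4)))
  C <- correlation_matrix(v, transform = "none")
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "neg"], -1)
  expect_error(correlation_matrix(v[, 1:2, drop = FALSE]), "3 samples")
})

test_that("zero-variance genes are flagged NA and excluded downstream", {
  v <- rbind(matrix(rexp(5 * 10), 5, 10), flat = rep(3, 10))
  rownames(v) <- c(sprintf("g%d", 1:5), "flat")
  colnames(v) <- sprintf("s%02d", 1:10)
  expect_message(C <- correlation_matrix(v, transform = "none"),
                 "zero-variance")
  expect_true(all(is.na(C["flat", setdiff(rownames(v), "flat")])))
  expect_message(S <- network_similarity(C), "excluding 1")
  expect_false("flat" %in% rownames(S))
})

test_that("network similarity equals the exhaustive double-loop oracle", {
  for (seed in c(101, 102, 103)) {
    set.seed(seed)
    ng <- sample(5:30, 1)
    ns <- sample(10:50, 1)
    x <- random_expr(ng, ns, seed = seed)
    C <- correlation_matrix(x)
    S <- network_similarity(C)
    expect_lt(max(abs(unclass(S) - oracle_similarity(unclass(C)))), 1e-10)
  }
})

test_that("identical expression rows give unit network similarity", {
  set.seed(7)
  base <- matrix(rexp(6 * 12), 6, 12)
  v <- rbind(base, base[1, , drop = FALSE])
  rownames(v) <- c(sprintf("g%d", 1:6), "twin")
  colnames(v) <- sprintf("s%02d", 1:12)
  S <- network_similarity(correlation_matrix(v, transform = "none"))
  expect_equal(S["g1", "twin"], 1, tolerance = 1e-10)
})

test_that("similarity matrices are bounded, symmetric, unit-diagonal", {
  for (seed in 201:203) {
    x <- random_expr(15, 20, seed = seed)
    S <- network_similarity(correlation_matrix(x))
    expect_true(all(S >= -1 & S <= 1, na.rm = TRUE))
    expect_identical(unclass(S), t(unclass(S)))
    expect_equal(unname(diag(S)), rep(1, 15))
  }
})

test_that("signature extraction respects threshold and tie-stable order", {
  x <- planted_cohort(seed = 11)
  S <- network_similarity(correlation_matrix(x))
  expect_identical(nrow(extract_signature(S, "MG01", threshold = 1.01)), 0L)
  all_sig <- extract_signature(S, "MG01", threshold = -1)
  expect_identical(sort(all_sig$gene), sort(rownames(S)))
  sig <- extract_signature(S, "MG01", threshold = 0.7)
  expect_true(all(sig$score >= 0.7))
  expect_true(all(diff(sig$score) <= 0))
  expect_true("MG01" %in% sig$gene)  # query belongs to its own signature
  expect_error(extract_signature(S, "NOPE"), "NOPE")
})

test_that("planted signatures recover the module and repel background", {
  hits <- 0L
  bg_ok <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    x <- planted_cohort(seed = 300 + r)
    S <- network_similarity(correlation_matrix(x))
    sig <- extract_signature(S, "MG01", threshold = 0.7)
    if (sum(module_genes() %in% sig$gene) >= 7) hits <- hits + 1L
    d <- signature_distribution(S, sig, "BG0001")
    if (d$summary$median < 0.7) bg_ok <- bg_ok + 1L
  }
  expect_gte(hits, n_rep - 1L)
  expect_identical(bg_ok, n_rep)
})

test_that("signature distribution returns one score per member", {
  x <- planted_cohort(seed = 17)
  S <- network_similarity(correlation_matrix(x))
  sig <- extract_signature(S, "MG01")
  self <- signature_distribution(S, sig, "MG01")
  expect_length(self$scores, nrow(sig))
  expect_gte(self$summary$min, 0.7)  # own scores all meet the threshold
  other <- signature_distribution(S, sig, "BG0002")
  expect_length(other$scores, nrow(sig))
  expect_lt(other$summary$median, self$summary$median)
  expect_error(signature_distribution(S, sig, "NOPE"), "NOPE")
})

test_that("signature overlap metrics follow set arithmetic", {
  x <- planted_cohort(seed = 23)
  S <- network_similarity(correlation_matrix(x))
  a <- extract_signature(S, "MG01")
  expect_equal(signature_overlap(a, a)$jaccard, 1)
  # build nested signatures by thresholding the same query
  big <- extract_signature(S, "MG01", threshold = -1)
  ov <- signature_overlap(a, big)
  expect_equal(ov$overlap_coef, 1)
  expect_equal(ov$jaccard, nrow(a) / nrow(big))
  # disjoint member sets -> Jaccard 0
  b <- extract_signature(S, "BG0001", threshold = 2)  # empty
  attr_b <- signature_overlap(a, b)
  expect_equal(attr_b$n_intersect, 0L)
})

test_that("second-order pass concentrates module structure", {
  x <- planted_cohort(seed = 29)
  C <- correlation_matrix(x)
  S <- network_similarity(C)
  mg <- module_genes()
  idx <- upper.tri(diag(length(mg)))
  med_first <- stats::median(C[mg, mg][idx])
  med_second <- stats::median(S[mg, mg][idx])
  expect_gt(med_second, med_first - 0.05)
})

test_that("signature recall is monotone in within-module rho", {
  recall_at <- function(rho) {
    mean(vapply(1:6, function(r) {
      x <- planted_cohort(seed = 400 + r, rho = rho)
      sig <- extract_signature(network_similarity(correlation_matrix(x)),
                               "MG01", 0.7)
      sum(module_genes() %in% sig$gene) / 8
    }, numeric(1)))
  }
  rec <- vapply(c(0.5, 0.7, 0.9), recall_at, numeric(1))
  expect_true(all(diff(rec) >= 0))
})

test_that("UMAP embedding is seeded, complete and clusters the module", {
  x <- planted_cohort(seed = 37, n_background = 30)
  S <- network_similarity(correlation_matrix(x))
  e1 <- embed_networks(S, n_neighbors = 8, seed = 42)
  e2 <- embed_networks(S, n_neighbors = 8, seed = 42)
  expect_identical(e1$x, e2$x)
  expect_identical(nrow(e1), nrow(S))
  expect_error(embed_networks(S, n_neighbors = 100), "n_neighbors")

  coords <- as.matrix(e1[, c("x", "y")])
  rownames(coords) <- e1$gene
  mg <- module_genes()
  d <- as.matrix(stats::dist(coords))
  intra <- mean(d[mg, mg][upper.tri(diag(length(mg)))])
  inter <- mean(d[mg, setdiff(e1$gene, mg)])
  expect_lt(intra, inter)
})

test_that("similarity TSV round-trips with its sidecar", {
  x <- random_expr(10, 15, seed = 41)
  S <- network_similarity(correlation_matrix(x))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(S, path)
  S2 <- read_similarity_tsv(path)
  expect_equal(unclass(S), unclass(S2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(attr(S2, "method"), "pearson")
})
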