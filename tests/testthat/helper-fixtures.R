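# Shared fixtures and independent oracles. Oracles deliberately use naive,
# loop-based code paths so they stay independent of the package internals.

make_expr <- function(values, unit = "TPM", cohort_id = "fix") {
  expression_matrix(values, unit = unit, cohort_id = cohort_id)
}

random_expr <- function(n_genes, n_samples, seed, unit = "TPM") {
  set.seed(seed)
  v <- matrix(rexp(n_genes * n_samples, rate = 1 / 50),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  make_expr(v, unit = unit)
}

module_genes <- function(n = 8) sprintf("MG%02d", seq_len(n))

planted_cohort <- function(seed, rho = 0.9, n_samples = 500,
                           n_module = 8, n_background = 40) {
  generate_cohort(
    cohort_spec("pl", n_samples, unit = "TPM", seed = seed),
    list(module_spec("m1", module_genes(n_module), within_correlation = rho)),
    n_background_genes = n_background
  )
}

# Exhaustive double-loop recomputation of the second-order similarity:
# re-derives each profile pair from scratch with stats::cor.
oracle_similarity <- function(C) {
  G <- nrow(C)
  S <- matrix(NA_real_, G, G, dimnames = dimnames(C))
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (i == j) { S[i, j] <- 1; next }
      keep <- setdiff(seq_len(G), c(i, j))
      S[i, j] <- stats::cor(C[i, keep], C[j, keep])
    }
  }
  S
}

# Step-by-step running-sum recomputation of the weighted KS enrichment
# score: explicit loop over every rank position.
oracle_es <- function(scores, genes_ranked, gene_set, weight_p = 1) {
  N <- length(scores)
  hit <- genes_ranked %in% gene_set
  nh <- sum(hit)
  nr <- sum(abs(scores[hit]) ^ weight_p)
  running <- numeric(N)
  acc <- 0
  for (k in seq_len(N)) {
    acc <- if (hit[k]) {
      acc + abs(scores[k]) ^ weight_p / nr
    } else {
      acc - 1 / (N - nh)
    }
    running[k] <- acc
  }
  running[which.max(abs(running))]
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  as <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(as, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
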