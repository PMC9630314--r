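#' First-order gene-gene correlation matrix
#'
#' Correlates every gene pair across samples, optionally after a
#' `log2(x + 1)` transform (the default, which stabilizes the strong right
#' skew of TPM-scale data). A gene's row of this matrix is its "gene
#' network": the vector of its association scores to all other genes.
#'
#' Genes with zero variance across samples have undefined correlations;
#' their entries are recorded as `NA`, counted, and excluded by downstream
#' steps.
#'
#' @param m An [expression_matrix()] (or plain gene-by-sample matrix).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return A symmetric gene-by-gene matrix of class `gene_cor` with unit
#'   diagonal and attributes `method`, `transform` and `zero_variance`
#'   (flagged gene symbols).
#' @export
correlation_matrix <- function(m, method = c("pearson", "spearman"),
                               transform = c("log2p1", "none")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  vals <- if (inherits(m, "expr_matrix")) m$values else m
  if (ncol(vals) < 3L) {
    stop("need at least 3 samples to correlate genes", call. = FALSE)
  }
  if (transform == "log2p1") vals <- log2(vals + 1)
  zero_var <- rownames(vals)[apply(vals, 1L, stats::var) == 0]
  if (length(zero_var) > 0) {
    message(length(zero_var), " zero-variance gene(s) flagged: entries set NA")
  }
  C <- suppressWarnings(stats::cor(t(vals), method = method))
  C[zero_var, ] <- NA_real_
  C[, zero_var] <- NA_real_
  diag(C) <- 1
  structure(C, class = c("gene_cor", "matrix", "array"),
            method = method, transform = transform, zero_variance = zero_var)
}

#' Second-order gene-network similarity matrix
#'
#' The similarity of two genes' networks is the Pearson correlation of their
#' correlation profiles (their rows of the first-order matrix), computed
#' over all other genes with positions i and j excluded from both profiles.
#' Excluding the pair's own positions matters: the structural 1s on the
#' diagonal would otherwise inflate every pairwise similarity. Scores lie in
#' \[-1, 1\]: -1 for highly discordant networks, 1 for highly similar ones.
#'
#' Genes flagged as zero-variance in the first-order matrix are dropped
#' (with a message) before the second pass. The computation uses a
#' closed-form vectorized identity (a single matrix product plus rank-one
#' corrections for the two excluded positions), algebraically equal to the
#' naive per-pair recomputation.
#'
#' @param c A `gene_cor` from [correlation_matrix()].
#' @return A symmetric matrix of class `network_similarity` with unit
#'   diagonal, attribute `dropped` naming excluded zero-variance genes.
#' @export
#' @examples
#' co <- cohort_spec("d", 30, seed = 1)
#' x <- generate_cohort(co, list(module_spec("m", paste0("G", 1:6), 0.8)),
#'                      n_background_genes = 10)
#' S <- network_similarity(correlation_matrix(x))
#' S["G1", "G2"]
network_similarity <- function(c) {
  if (!inherits(c, "gene_cor")) {
    stop("input must be a correlation matrix from correlation_matrix()",
         call. = FALSE)
  }
  dropped <- attr(c, "zero_variance") %||% character()
  C <- unclass(c)
  if (length(dropped) > 0) {
    keep <- setdiff(rownames(C), dropped)
    C <- C[keep, keep, drop = FALSE]
    message("excluding ", length(dropped),
            " zero-variance gene(s) from network similarity")
  }
  G <- nrow(C)
  if (G < 4L) {
    stop("need at least 4 genes for network similarity", call. = FALSE)
  }
  n <- G - 2  # profile length after excluding positions i and j
  rs <- rowSums(C)
  rq <- rowSums(C * C)
  # Per-pair profile sums with positions i (value 1) and j (value C[i,j])
  # removed; [i, j] entries of these matrices index the pair.
  Sx <- matrix(rs, G, G) - 1 - C
  Sy <- t(Sx)
  Sxx <- matrix(rq, G, G) - 1 - C * C
  Syy <- t(Sxx)
  Sxy <- C %*% C - 2 * C
  num <- n * Sxy - Sx * Sy
  vx <- pmax(n * Sxx - Sx * Sx, 0)
  vy <- pmax(n * Syy - Sy * Sy, 0)
  den <- sqrt(vx * vy)
  S <- num / den
  degenerate <- den <= sqrt(.Machine$double.eps) * n
  if (any(degenerate[upper.tri(degenerate)])) {
    S[degenerate] <- NA_real_
    message(sum(degenerate[upper.tri(degenerate)]),
            " gene pair(s) with a constant profile: similarity set NA")
  }
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  S <- (S + t(S)) / 2  # enforce exact symmetry against float noise
  dimnames(S) <- dimnames(C)
  structure(S, class = c("network_similarity", "matrix", "array"),
            dropped = dropped,
            method = attr(c, "method"), transform = attr(c, "transform"))
}

#' Extract a gene-network signature around a query gene
#'
#' The signature is the set of genes whose network similarity to the query
#' meets the threshold (0.7 by default, the conventional cut for a tight
#' signature). The query itself is a member, with self-similarity 1. Members
#' are ordered by score descending, ties broken by gene symbol.
#'
#' @param s A `network_similarity` matrix.
#' @param query Query gene symbol (e.g. `"CD276"`).
#' @param threshold Minimum similarity score for membership.
#' @return A tibble of class `network_signature` with columns `gene`,
#'   `score`, and attributes `query` and `threshold`.
#' @export
extract_signature <- function(s, query, threshold = 0.7) {
  stopifnot(inherits(s, "network_similarity"))
  if (!query %in% rownames(s)) {
    stop("query gene '", query, "' not in the similarity matrix", call. = FALSE)
  }
  scores <- s[query, ]
  keep <- !is.na(scores) & scores >= threshold
  out <- tibble::tibble(gene = names(scores)[keep], score = unname(scores[keep]))
  out <- out[order(-out$score, out$gene), ]
  structure(out, class = c("network_signature", class(tibble::tibble())),
            query = query, threshold = threshold)
}

#' @export
print.network_signature <- function(x, ...) {
  cat(sprintf("<network_signature> query %s, threshold %.3g, %d member(s)\n",
              attr(x, "query"), attr(x, "threshold"), nrow(x)))
  NextMethod()
}

#' Distribution of a test gene's similarities to a signature
#'
#' Returns the similarity of `test_gene` to every member of a reference
#' signature, plus the five-number style summary used to draw the violin
#' comparison (median, quartiles, range). When `test_gene` is the
#' signature's own query, the distribution is the signature's own scores,
#' all at or above the threshold; an unrelated gene's distribution sits
#' near zero.
#'
#' @param s A `network_similarity` matrix.
#' @param sig A [extract_signature()] result (from the same matrix).
#' @param test_gene Gene whose similarity distribution is assessed.
#' @return List of class `signature_distribution` with elements
#'   `test_gene`, `query`, `scores` (named numeric, one per member) and
#'   `summary` (one-row tibble: median, q1, q3, min, max, n).
#' @export
signature_distribution <- function(s, sig, test_gene) {
  stopifnot(inherits(s, "network_similarity"), inherits(sig, "network_signature"))
  if (!test_gene %in% rownames(s)) {
    stop("test gene '", test_gene, "' not in the similarity matrix",
         call. = FALSE)
  }
  missing_members <- setdiff(sig$gene, rownames(s))
  if (length(missing_members) > 0) {
    stop("signature members absent from the similarity matrix: ",
         paste(utils::head(missing_members, 3L), collapse = ", "),
         call. = FALSE)
  }
  scores <- s[test_gene, sig$gene]
  structure(
    list(
      test_gene = test_gene,
      query = attr(sig, "query"),
      scores = scores,
      summary = tibble::tibble(
        test_gene = test_gene,
        median = stats::median(scores, na.rm = TRUE),
        q1 = stats::quantile(scores, 0.25, names = FALSE, na.rm = TRUE),
        q3 = stats::quantile(scores, 0.75, names = FALSE, na.rm = TRUE),
        min = min(scores, na.rm = TRUE),
        max = max(scores, na.rm = TRUE),
        n = length(scores)
      )
    ),
    class = "signature_distribution"
  )
}

#' @export
print.signature_distribution <- function(x, ...) {
  cat(sprintf(
    "<signature_distribution> %s vs signature of %s (n = %d): median %.3f [Q1 %.3f, Q3 %.3f]\n",
    x$test_gene, x$query, length(x$scores),
    x$summary$median, x$summary$q1, x$summary$q3
  ))
  invisible(x)
}

#' @export
#' @method tidy signature_distribution
tidy.signature_distribution <- function(x, ...) {
  tibble::tibble(test_gene = x$test_gene, member = names(x$scores),
                 score = unname(x$scores))
}

#' Overlap metrics between two signatures
#'
#' Quantifies what the violin comparison shows visually: the Jaccard index
#' and the overlap coefficient (intersection over the smaller set) of the
#' two member sets. Both signatures should come from the same similarity
#' matrix.
#'
#' @param a,b [extract_signature()] results.
#' @return One-row tibble: `query_a`, `query_b`, `n_a`, `n_b`,
#'   `n_intersect`, `jaccard`, `overlap_coef`.
#' @export
signature_overlap <- function(a, b) {
  stopifnot(inherits(a, "network_signature"), inherits(b, "network_signature"))
  ga <- a$gene
  gb <- b$gene
  ni <- length(intersect(ga, gb))
  nu <- length(union(ga, gb))
  tibble::tibble(
    query_a = attr(a, "query"), query_b = attr(b, "query"),
    n_a = length(ga), n_b = length(gb), n_intersect = ni,
    jaccard = if (nu == 0) NA_real_ else ni / nu,
    overlap_coef = if (min(length(ga), length(gb)) == 0) NA_real_
                   else ni / min(length(ga), length(gb))
  )
}

#' Embed gene networks in two dimensions with UMAP
#'
#' Each gene's feature vector is its full row of the similarity matrix; UMAP
#' places genes with similar networks close together, so the distance of any
#' gene to the query reflects relative network similarity.
#'
#' @param s A `network_similarity` matrix.
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1).
#' @param seed RNG seed; coordinates are reproducible given the seed.
#' @return Tibble of class `network_embedding` with columns `gene`, `x`,
#'   `y`; UMAP parameters are recorded in the `parameters` attribute.
#' @export
embed_networks <- function(s, n_neighbors = 15, min_dist = 0.1, seed = 42L) {
  stopifnot(inherits(s, "network_similarity"))
  G <- nrow(s)
  if (G < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1,
         " genes; have ", G, call. = FALSE)
  }
  X <- unclass(s)
  if (anyNA(X)) {
    message("replacing ", sum(is.na(X)), " missing similarity value(s) with 0 ",
            "for embedding")
    X[is.na(X)] <- 0
  }
  coords <- with_seed(seed, {
    uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
               metric = "euclidean", n_threads = 1, n_sgd_threads = 0)
  })
  out <- tibble::tibble(gene = rownames(s), x = coords[, 1], y = coords[, 2])
  structure(out, class = c("network_embedding", class(tibble::tibble())),
            parameters = list(n_neighbors = n_neighbors, min_dist = min_dist,
                              metric = "euclidean", seed = seed))
}

#' Write a similarity matrix as TSV with a JSON sidecar
#' @param s A `network_similarity` matrix.
#' @param path Output TSV path (gene-by-gene, first column `gene`).
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(s, path) {
  stopifnot(inherits(s, "network_similarity"))
  tbl <- tibble::as_tibble(unclass(s), rownames = "gene")
  readr::write_tsv(tbl, path, progress = FALSE)
  jsonlite::write_json(
    list(method = attr(s, "method"), transform = attr(s, "transform"),
         n_genes = nrow(s), dropped = attr(s, "dropped")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_tsv()]
#' @param path TSV path.
#' @return A `network_similarity` matrix.
#' @export
read_similarity_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  S <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(S) <- tbl$gene
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(S, class = c("network_similarity", "matrix", "array"),
            dropped = as.character(unlist(meta$dropped)),
            method = meta$method %||% NA_character_,
            transform = meta$transform %||% NA_character_)
}
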