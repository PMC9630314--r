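#' Ranked association profile of a query gene
#'
#' Builds the input to preranked enrichment: for each cohort, the
#' correlation of the query gene with every other gene (over samples, after
#' the chosen transform), averaged across cohorts per gene and sorted
#' descending. Genes are restricted to the symbols common to all cohorts.
#' Ties are broken by gene symbol so the ranking is deterministic.
#'
#' The alternative reading — ranking genes by their mean expression across
#' cohorts rather than by association with the query — is available as
#' `profile_mode = "mean_expression"`.
#'
#' @param cohorts List of [expression_matrix()] objects (or a single one).
#' @param query Query gene symbol; must be present in every cohort.
#' @param method,transform Passed to the per-cohort correlation (see
#'   [correlation_matrix()]).
#' @param profile_mode `"correlation"` (default) or `"mean_expression"`.
#' @return Tibble of class `ranked_profile` with columns `gene`, `score`,
#'   sorted descending; the query itself is excluded. Attribute `query`
#'   records the gene.
#' @export
rank_profile <- function(cohorts, query,
                         method = c("pearson", "spearman"),
                         transform = c("log2p1", "none"),
                         profile_mode = c("correlation", "mean_expression")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  profile_mode <- match.arg(profile_mode)
  if (inherits(cohorts, "expr_matrix")) cohorts <- list(cohorts)
  stopifnot(length(cohorts) >= 1L)
  for (co in cohorts) {
    stopifnot(inherits(co, "expr_matrix"))
    if (!query %in% genes(co)) {
      stop("query gene '", query, "' missing from cohort '", co$cohort_id, "'",
           call. = FALSE)
    }
  }
  common <- Reduce(intersect, lapply(cohorts, genes))
  others <- setdiff(common, query)
  if (length(others) == 0L) {
    stop("no genes besides the query are common to all cohorts", call. = FALSE)
  }
  per_cohort <- vapply(cohorts, function(co) {
    vals <- co$values[common, , drop = FALSE]
    if (transform == "log2p1") vals <- log2(vals + 1)
    if (profile_mode == "mean_expression") {
      rowMeans(vals)[others]
    } else {
      q <- vals[query, ]
      suppressWarnings(
        drop(stats::cor(q, t(vals[others, , drop = FALSE]), method = method))
      )
    }
  }, numeric(length(others)))
  per_cohort <- matrix(per_cohort, nrow = length(others),
                       dimnames = list(others, NULL))
  score <- rowMeans(per_cohort, na.rm = TRUE)
  undefined <- names(score)[is.nan(score)]
  if (length(undefined) > 0) {
    message("dropping ", length(undefined),
            " gene(s) with undefined score in every cohort")
    score <- score[!names(score) %in% undefined]
  }
  out <- tibble::tibble(gene = names(score), score = unname(score))
  out <- out[order(-out$score, out$gene), ]
  structure(out, class = c("ranked_profile", class(tibble::tibble())),
            query = query, method = method, transform = transform,
            profile_mode = profile_mode)
}

#' Construct a ranked profile from a gene/score table
#'
#' @param tbl Data frame with columns `gene` and `score` (or a named
#'   numeric vector).
#' @param query Optional query gene label; removed from the profile if
#'   present.
#' @return A `ranked_profile` tibble sorted descending, ties by symbol.
#' @export
as_ranked_profile <- function(tbl, query = NA_character_) {
  if (is.numeric(tbl) && !is.null(names(tbl))) {
    tbl <- tibble::tibble(gene = names(tbl), score = unname(tbl))
  }
  stopifnot(all(c("gene", "score") %in% names(tbl)))
  if (anyDuplicated(tbl$gene)) stop("genes must be unique", call. = FALSE)
  tbl <- tibble::as_tibble(tbl[, c("gene", "score")])
  if (!is.na(query)) tbl <- tbl[tbl$gene != query, ]
  tbl <- tbl[order(-tbl$score, tbl$gene), ]
  structure(tbl, class = c("ranked_profile", class(tibble::tibble())),
            query = query)
}

# Weighted Kolmogorov-Smirnov enrichment statistic from sorted hit
# positions. `absw` is |score|^p over the whole ranked list. Evaluates the
# running sum only at its candidate extrema (just before and at each hit),
# which is what makes permutation nulls cheap.
es_from_positions <- function(pos, absw, N) {
  m <- length(pos)
  w <- absw[pos]
  NR <- sum(w)
  cumw <- if (NR == 0) seq_len(m) / m else cumsum(w) / NR
  miss_step <- 1 / (N - m)
  i <- seq_len(m)
  at_hit <- cumw - (pos - i) * miss_step
  before_hit <- c(0, cumw[-m]) - (pos - 1 - (i - 1)) * miss_step
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Enrichment score of a gene set on a ranked profile
#'
#' The weighted Kolmogorov-Smirnov running-sum statistic of preranked GSEA:
#' walking down the ranked list, hits add `|score|^weight_p` (normalized by
#' the set's total weight) and misses subtract `1/(N - Nh)`; the ES is the
#' running sum's maximum-magnitude deviation from zero. The leading edge is
#' the set members at or before the extremum (for positive ES; at or after
#' it for negative ES). If every hit has score zero, hits fall back to equal
#' weights (a message is emitted).
#'
#' @param profile A `ranked_profile`.
#' @param gene_set Character vector of gene symbols.
#' @param weight_p Hit-weight exponent (default 1, the standard choice;
#'   0 gives the unweighted KS statistic).
#' @return List of class `enrichment_score`: `es` in \[-1, 1\],
#'   `running_sum` (tibble with `rank`, `gene`, `score`, `hit`, `running`),
#'   `leading_edge` (character).
#' @export
enrichment_score <- function(profile, gene_set, weight_p = 1) {
  stopifnot(inherits(profile, "ranked_profile"))
  N <- nrow(profile)
  hit <- profile$gene %in% gene_set
  Nh <- sum(hit)
  if (Nh == 0L) {
    stop("gene set has no overlap with the ranked profile", call. = FALSE)
  }
  if (Nh == N) {
    stop("gene set covers the entire universe; miss penalty undefined",
         call. = FALSE)
  }
  absw <- abs(profile$score) ^ weight_p
  NR <- sum(absw[hit])
  if (NR == 0) {
    message("all hit scores are zero; using equal hit weights")
    inc_hit <- rep(1 / Nh, Nh)
  } else {
    inc_hit <- absw[hit] / NR
  }
  inc <- rep(-1 / (N - Nh), N)
  inc[hit] <- inc_hit
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  es <- running[peak]
  leading <- if (es >= 0) {
    profile$gene[hit & seq_len(N) <= peak]
  } else {
    profile$gene[hit & seq_len(N) >= peak]
  }
  structure(
    list(
      es = es,
      running_sum = tibble::tibble(rank = seq_len(N), gene = profile$gene,
                                   score = profile$score, hit = hit,
                                   running = running),
      leading_edge = leading
    ),
    class = "enrichment_score"
  )
}

#' @export
print.enrichment_score <- function(x, ...) {
  cat(sprintf("<enrichment_score> ES = %.4f, leading edge %d gene(s)\n",
              x$es, length(x$leading_edge)))
  invisible(x)
}

#' Preranked enrichment with permutation NES and FDR
#'
#' For every gene set, computes the observed ES, then a gene-label
#' permutation null: random sets of the same size drawn from the profile's
#' universe. NES is ES divided by the mean magnitude of same-sign null ES
#' (per set size); nominal p is the fraction of same-sign null ES at least
#' as extreme; FDR q follows the GSEA convention — the ratio of the null
#' NES tail fraction to the observed NES tail fraction, clipped to
#' \[0, 1\]. Deterministic given `seed`.
#'
#' @param profile A `ranked_profile`.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param n_permutations Number of permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutations.
#' @param weight_p Hit-weight exponent passed to the ES.
#' @return Tibble of class `gsea_result`, one row per set: `set`,
#'   `n_hits_in_universe`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `leading_edge` (list column), sorted by `nes` descending.
#' @export
nes_and_fdr <- function(profile, collection, n_permutations = 1000L,
                        seed = 1L, weight_p = 1) {
  stopifnot(inherits(profile, "ranked_profile"))
  if (n_permutations < 100L) {
    stop("need at least 100 permutations", call. = FALSE)
  }
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stop("collection must be a uniquely named list of gene sets", call. = FALSE)
  }
  N <- nrow(profile)
  absw <- abs(profile$score) ^ weight_p
  obs <- lapply(collection, function(gs) enrichment_score(profile, gs, weight_p))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- vapply(collection, function(gs) sum(profile$gene %in% gs), integer(1))

  null_by_size <- with_seed(seed, {
    lapply(stats::setNames(nm = sort(unique(sizes))), function(m) {
      vapply(seq_len(n_permutations), function(i) {
        es_from_positions(sort.int(sample.int(N, m)), absw, N)
      }, numeric(1))
    })
  })

  norm_null <- function(null_es) {
    mp <- mean(null_es[null_es >= 0])
    mn <- mean(abs(null_es[null_es < 0]))
    ifelse(null_es >= 0, null_es / mp, null_es / mn)
  }
  nes <- p <- numeric(length(collection))
  for (k in seq_along(collection)) {
    null_es <- null_by_size[[as.character(sizes[k])]]
    e <- es_obs[k]
    if (e >= 0) {
      same <- null_es[null_es >= 0]
      nes[k] <- e / mean(same)
      p[k] <- if (length(same)) mean(same >= e) else 0
    } else {
      same <- null_es[null_es < 0]
      nes[k] <- e / mean(abs(same))
      p[k] <- if (length(same)) mean(abs(same) >= abs(e)) else 0
    }
  }
  null_nes <- unlist(lapply(null_by_size, norm_null), use.names = FALSE)
  fdr <- vapply(seq_along(collection), function(k) {
    v <- nes[k]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num_den <- sum(null_nes >= 0)
      num <- if (num_den == 0) 0 else sum(null_nes >= v) / num_den
      obs_den <- sum(nes >= 0)
      den <- if (obs_den == 0) 1 else sum(nes >= v) / obs_den
    } else {
      num_den <- sum(null_nes < 0)
      num <- if (num_den == 0) 0 else sum(null_nes <= v) / num_den
      obs_den <- sum(nes < 0)
      den <- if (obs_den == 0) 1 else sum(nes <= v) / obs_den
    }
    min(1, max(0, num / den))
  }, numeric(1))

  out <- tibble::tibble(
    set = names(collection),
    n_hits_in_universe = unname(sizes),
    es = unname(es_obs),
    nes = nes,
    p_value = p,
    fdr_q = fdr,
    leading_edge = unname(lapply(obs, `[[`, "leading_edge"))
  )
  out <- out[order(-out$nes), ]
  structure(out, class = c("gsea_result", class(tibble::tibble())),
            n_permutations = as.integer(n_permutations), seed = seed,
            weight_p = weight_p, query = attr(profile, "query"))
}

#' Filter enrichment results by NES and FDR cutoffs
#'
#' @param results A `gsea_result` tibble.
#' @param nes_cutoff Minimum `|NES|` (default 1.4, a conventional cutoff
#'   for tabulating enriched oncogenic signatures).
#' @param fdr_cutoff Maximum FDR q (default 0.05).
#' @return The surviving rows, stably sorted by `|NES|` descending.
#' @export
filter_results <- function(results, nes_cutoff = 1.4, fdr_cutoff = 0.05) {
  stopifnot(is.data.frame(results))
  keep <- !is.na(results$nes) & abs(results$nes) >= nes_cutoff &
    !is.na(results$fdr_q) & results$fdr_q <= fdr_cutoff
  out <- results[keep, , drop = FALSE]
  out[order(-abs(out$nes)), , drop = FALSE]
}

#' @export
#' @method glance gsea_result
glance.gsea_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_permutations = attr(x, "n_permutations"),
    seed = attr(x, "seed"),
    n_nes_ge_1.4 = sum(abs(x$nes) >= 1.4, na.rm = TRUE),
    n_fdr_le_0.05 = sum(x$fdr_q <= 0.05, na.rm = TRUE)
  )
}

#' @export
#' @method tidy gsea_result
tidy.gsea_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$leading_edge <- vapply(out$leading_edge, paste, "", collapse = ",")
  out
}

#' Read gene sets from a GMT file
#' @param path GMT file (tab-separated: name, description, genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled; defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = names(sets)) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked profile from a 2-column `.rnk` file (gene, score; no header)
#' @param path File path.
#' @return A `ranked_profile`.
#' @export
read_rnk <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("gene", "score"),
                         col_types = "cd", progress = FALSE)
  as_ranked_profile(tbl)
}

#' Write a ranked profile in the `.rnk` convention
#' @param profile A `ranked_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(profile, path) {
  stopifnot(inherits(profile, "ranked_profile"))
  readr::write_tsv(profile[, c("gene", "score")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}
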