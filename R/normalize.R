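#' Convert FPKM to TPM
#'
#' Rescales each sample (column) by a constant so the column sums to one
#' million, which turns FPKM into TPM while preserving within-sample
#' proportions.
#'
#' @param m An [expression_matrix()] in FPKM.
#' @return An `expr_matrix` in TPM.
#' @export
#' @examples
#' v <- matrix(c(3, 1), 2, 1, dimnames = list(c("A", "B"), "s1"))
#' fpkm_to_tpm(expression_matrix(v, "FPKM"))$values
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "FPKM") {
    stop("fpkm_to_tpm expects FPKM input, got ", m$unit, call. = FALSE)
  }
  expression_matrix(rescale_columns(m$values, 1e6), unit = "TPM",
                    cohort_id = m$cohort_id)
}

#' Convert RSEM estimated transcript fractions to TPM
#'
#' Transcript fractions sum to 1 per sample; multiplying every value by one
#' million gives TPM directly.
#'
#' @param m An [expression_matrix()] in RSEM_FRACTION with values in \[0, 1\].
#' @return An `expr_matrix` in TPM.
#' @export
rsem_fraction_to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "RSEM_FRACTION") {
    stop("rsem_fraction_to_tpm expects RSEM_FRACTION input, got ", m$unit,
         call. = FALSE)
  }
  if (any(m$values > 1)) {
    stop("values above 1 are not transcript fractions", call. = FALSE)
  }
  expression_matrix(m$values * 1e6, unit = "TPM", cohort_id = m$cohort_id)
}

#' Convert any supported unit to TPM
#'
#' Dispatches on the declared unit; TPM input is returned unchanged.
#'
#' @param m An [expression_matrix()].
#' @return An `expr_matrix` in TPM.
#' @export
to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  switch(m$unit,
    TPM = m,
    FPKM = fpkm_to_tpm(m),
    RSEM_FRACTION = rsem_fraction_to_tpm(m),
    stop("no TPM conversion defined for unit ", m$unit, call. = FALSE)
  )
}

#' Merge cohorts on shared gene symbols into pseudo-TPM
#'
#' Rows are restricted to the exact (case-sensitive) intersection of gene
#' symbols, columns concatenated, and every sample rescaled so its total is
#' again one million ("pseudo-TPM"): the expression mass of genes dropped in
#' the merge is redistributed, which is the only reading under which
#' post-merge per-sample sums can equal 1e6.
#'
#' @param cohorts List of [expression_matrix()] objects, all in TPM.
#' @return An `expr_matrix` of class `merged_expr` (unit PSEUDO_TPM) with
#'   elements `sample_provenance` (named cohort label per sample) and
#'   `n_common_genes`.
#' @export
#' @examples
#' specs <- list(cohort_spec("a", 5, seed = 1), cohort_spec("b", 5, seed = 2))
#' xs <- generate_multicohort(specs, n_shared_background_genes = 10,
#'                            per_cohort_extra_genes = 3)
#' merged <- merge_cohorts(xs)
#' merged$n_common_genes
merge_cohorts <- function(cohorts) {
  if (length(cohorts) < 2L) {
    stop("need at least two cohorts to merge", call. = FALSE)
  }
  for (co in cohorts) {
    stopifnot(inherits(co, "expr_matrix"))
    if (co$unit != "TPM") {
      stop("cohort '", co$cohort_id, "' is in ", co$unit,
           "; convert to TPM first (see to_tpm())", call. = FALSE)
    }
  }
  common <- Reduce(intersect, lapply(cohorts, genes))
  if (length(common) == 0L) {
    stop("gene-symbol intersection across cohorts is empty", call. = FALSE)
  }
  all_samples <- unlist(lapply(cohorts, samples))
  if (anyDuplicated(all_samples)) {
    cohorts <- lapply(cohorts, function(co) {
      colnames(co$values) <- paste(co$cohort_id, colnames(co$values), sep = ".")
      co
    })
  }
  values <- do.call(cbind, lapply(cohorts, function(co) {
    co$values[common, , drop = FALSE]
  }))
  values <- rescale_columns(values, 1e6)
  provenance <- unlist(lapply(cohorts, function(co) {
    stats::setNames(rep(co$cohort_id, ncol(co$values)), colnames(co$values))
  }))
  out <- expression_matrix(values, unit = "PSEUDO_TPM", cohort_id = "merged")
  out$sample_provenance <- provenance
  out$n_common_genes <- length(common)
  class(out) <- c("merged_expr", class(out))
  out
}

#' @export
print.merged_expr <- function(x, ...) {
  cat(sprintf(
    "<merged_expr> %d common genes x %d samples from %d cohorts [PSEUDO_TPM]\n",
    nrow(x$values), ncol(x$values), length(unique(x$sample_provenance))
  ))
  invisible(x)
}

#' Per-cohort summary of a single gene
#'
#' Reports, per cohort, the sample size, median, quartiles and a percentile
#' bootstrap 95% CI of the median (2000 resamples, seeded), matching the
#' "median with 95% CI" display convention for cross-cohort expression
#' comparisons.
#'
#' @param merged A `merged_expr` from [merge_cohorts()].
#' @param gene Gene symbol.
#' @param n_boot Bootstrap resamples for the median CI.
#' @param seed RNG seed for the bootstrap.
#' @return A tibble with one row per cohort: `cohort`, `n`, `median`, `q1`,
#'   `q3`, `ci_lo`, `ci_hi`.
#' @export
summarize_gene <- function(merged, gene, n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(merged, "merged_expr"))
  if (!gene %in% genes(merged)) {
    near <- utils::head(genes(merged)[order(utils::adist(gene, genes(merged)))], 3L)
    stop("gene '", gene, "' not in merged matrix; nearest symbols: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  vals <- merged$values[gene, ]
  cohort <- merged$sample_provenance[names(vals)]
  with_seed(seed, {
    purrr::map_dfr(unique(cohort), function(co) {
      x <- vals[cohort == co]
      boots <- vapply(seq_len(n_boot), function(i) {
        stats::median(sample(x, replace = TRUE))
      }, numeric(1))
      ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
      tibble::tibble(
        cohort = co, n = length(x),
        median = stats::median(x),
        q1 = stats::quantile(x, 0.25, names = FALSE),
        q3 = stats::quantile(x, 0.75, names = FALSE),
        ci_lo = ci[1], ci_hi = ci[2]
      )
    })
  })
}
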