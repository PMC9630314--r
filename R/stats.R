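#' Pearson correlation with significance
#'
#' Two-sided p-value from the t transform `t = r * sqrt((n - 2) / (1 - r^2))`
#' on n - 2 degrees of freedom (the classical test, as computed by
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `p_value`,
#'   `n`, `method`.
#' @export
#' @examples
#' pearson_r(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate), statistic = unname(ct$statistic),
    p_value = ct$p.value, n = length(x), method = "pearson"
  )
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects F test: `F = (SSB / dfB) / (SSW / dfW)` with the
#' p-value from the F distribution (equal-variance form, via
#' [stats::oneway.test()]).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return One-row tibble: `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, `method`.
#' @export
#' @examples
#' one_way_anova(list(c(0, 1), c(2, 3)))
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0) {
    stop("zero within-group variance: F undefined", call. = FALSE)
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ft$statistic), p_value = ft$p.value,
    df_between = unname(ft$parameter[1]), df_within = unname(ft$parameter[2]),
    method = "one-way ANOVA"
  )
}

#' Two-sample t test (pooled or Welch)
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param welch Use the Welch unequal-variance statistic (default `FALSE`,
#'   i.e. the pooled Student form).
#' @return One-row tibble: `statistic` (t), `p_value`, `df`,
#'   `mean_x`, `mean_y`, `method`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (!welch && stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  tibble::tibble(
    statistic = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter), mean_x = mean(x), mean_y = mean(y),
    method = if (welch) "Welch t" else "Student t (pooled)"
  )
}

#' 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer counts, laid out as
#'   `rbind(c(a, b), c(c, d))`.
#' @param row_labels,col_labels Optional dimension labels (e.g. marker
#'   high/low by alteration present/absent).
#' @return A labelled 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d,
                            row_labels = c("row1", "row2"),
                            col_labels = c("col1", "col2")) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  m <- matrix(as.integer(counts), 2, 2, byrow = TRUE,
              dimnames = list(row_labels, col_labels))
  structure(m, class = c("contingency_2x2", "matrix", "array"))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing the probabilities of all tables (under the fixed
#' margins) no more probable than the observed one — the standard
#' hypergeometric definition, as computed by [stats::fisher.test()]. The
#' reported odds ratio is the sample odds ratio `(a * d) / (b * c)` (not the
#' conditional MLE), which is the convention quoted alongside the exact p.
#'
#' @param t A [contingency_2x2()].
#' @return One-row tibble: `odds_ratio`, `p_value`, `n`, `method`.
#' @export
#' @examples
#' fisher_exact_2x2(contingency_2x2(2, 0, 0, 2))
fisher_exact_2x2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("zero margin: exact test undefined", call. = FALSE)
  }
  ft <- stats::fisher.test(unclass(t))
  or <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  tibble::tibble(
    odds_ratio = or, p_value = ft$p.value, n = sum(t),
    method = "Fisher exact (two-sided)"
  )
}

#' Chi-square test for a 2x2 table
#'
#' @param t A [contingency_2x2()].
#' @param yates Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic` (chi-square, 1 df), `p_value`, `n`,
#'   `method`.
#' @export
chi_square_2x2 <- function(t, yates = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(expected == 0)) {
    stop("zero expected count: chi-square undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(unclass(t), correct = yates))
  tibble::tibble(
    statistic = unname(ct$statistic), p_value = ct$p.value, n = sum(t),
    method = if (yates) "chi-square (Yates)" else "chi-square"
  )
}

#' Dichotomize samples at an expression quantile
#'
#' Default split at the cohort median of pseudo-TPM, the usual cut for
#' "high/low" marker groups when no clinical threshold exists; the quantile
#' is configurable and recorded in the output.
#'
#' @param merged A `merged_expr` (or any `expr_matrix`).
#' @param gene Gene symbol.
#' @param quantile Split point in (0, 1); default 0.5.
#' @return Tibble with `sample`, `value`, `group` (`"high"`/`"low"`) and
#'   attribute `cut_value`.
#' @export
dichotomize_expression <- function(merged, gene, quantile = 0.5) {
  stopifnot(inherits(merged, "expr_matrix"))
  if (!gene %in% genes(merged)) {
    stop("gene '", gene, "' not in the matrix", call. = FALSE)
  }
  v <- merged$values[gene, ]
  cut <- stats::quantile(v, quantile, names = FALSE)
  out <- tibble::tibble(
    sample = names(v), value = unname(v),
    group = ifelse(v > cut, "high", "low")
  )
  attr(out, "cut_value") <- cut
  attr(out, "quantile") <- quantile
  out
}

#' Benjamini-Hochberg adjustment helper
#'
#' Off by default everywhere in this package (the headline comparisons are
#' reported as raw p-values); provided for users who want set-level
#' correction of a results table.
#'
#' @param tbl Data frame with a p-value column.
#' @param p_col Name of the p-value column (default `"p_value"`).
#' @return `tbl` with an added `p_adjusted` column (BH).
#' @export
adjust_p_bh <- function(tbl, p_col = "p_value") {
  stopifnot(p_col %in% names(tbl))
  tbl$p_adjusted <- stats::p.adjust(tbl[[p_col]], method = "BH")
  tbl
}
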