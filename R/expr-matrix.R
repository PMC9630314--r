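#' Expression matrix container
#'
#' A light wrapper around a gene-by-sample numeric matrix that carries the
#' expression unit and a cohort label. Units are tracked explicitly because
#' public cohorts ship in different units (FPKM, TPM, RSEM transcript
#' fraction) and the downstream merge requires everything in TPM.
#'
#' @param values Numeric gene-by-sample matrix with unique rownames (gene
#'   symbols) and unique colnames (sample IDs). No negative entries.
#' @param unit One of `"FPKM"`, `"TPM"`, `"RSEM_FRACTION"`, `"PSEUDO_TPM"`,
#'   `"COUNTS"`.
#' @param cohort_id Cohort label, a single string.
#' @return An object of class `expr_matrix`.
#' @export
#' @examples
#' m <- matrix(c(3, 1, 2, 2), 2, 2,
#'             dimnames = list(c("CD276", "FOLH1"), c("s1", "s2")))
#' expression_matrix(m, unit = "TPM", cohort_id = "demo")
expression_matrix <- function(values, unit, cohort_id = "cohort") {
  unit <- match.arg(unit, expr_units())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene symbol: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("sample IDs must be unique", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  structure(
    list(values = values, unit = unit, cohort_id = as.character(cohort_id)),
    class = "expr_matrix"
  )
}

expr_units <- function() c("FPKM", "TPM", "RSEM_FRACTION", "PSEUDO_TPM", "COUNTS")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> cohort '%s': %d genes x %d samples [%s]\n",
    x$cohort_id, nrow(x$values), ncol(x$values), x$unit
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene symbols of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene symbols.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.expr_matrix <- function(x) rownames(x$values)

#' @export
genes.default <- function(x) rownames(x)

#' Sample IDs of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample IDs.
#' @export
samples <- function(x) UseMethod("samples")

#' @export
samples.expr_matrix <- function(x) colnames(x$values)

#' @describeIn expression_matrix Long-format view: one row per
#'   gene-sample pair with columns `gene`, `sample`, `value`, `unit`,
#'   `cohort`.
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @export
#' @method tidy expr_matrix
tidy.expr_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    unit = x$unit,
    cohort = x$cohort_id
  )
}

#' Read an expression matrix from TSV
#'
#' Expects genes as rows with the first column named `gene` and the remaining
#' columns holding one sample each.
#'
#' @param path TSV file path.
#' @param unit Expression unit of the stored values.
#' @param cohort_id Cohort label (defaults to the file name sans extension).
#' @return An [expression_matrix()].
#' @export
read_expr_tsv <- function(path, unit, cohort_id = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "gene") {
    stop("first column of an expression TSV must be named 'gene'", call. = FALSE)
  }
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(vals) <- tbl$gene
  if (is.null(cohort_id)) {
    cohort_id <- sub("\\.[^.]*$", "", basename(path))
  }
  expression_matrix(vals, unit = unit, cohort_id = cohort_id)
}

#' Write an expression matrix to TSV (+ JSON sidecar)
#'
#' Writes genes as rows (first column `gene`) and a `<path>.json` sidecar
#' recording unit and cohort so a round-trip preserves metadata.
#'
#' @param x An `expr_matrix`.
#' @param path Output TSV path.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  tbl <- tibble::as_tibble(x$values, rownames = "gene")
  readr::write_tsv(tbl, path, progress = FALSE)
  if (sidecar) {
    meta <- list(unit = x$unit, cohort_id = x$cohort_id,
                 n_genes = nrow(x$values), n_samples = ncol(x$values))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
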