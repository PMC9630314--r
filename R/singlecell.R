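#' Call per-cell marker positivity from raw counts
#'
#' A cell is positive when its absolute count for the gene reaches
#' `min_count` (default 1, i.e. any detected transcript). Raising the floor
#' can only shrink the positive set.
#'
#' @param counts An [sc_counts()] object.
#' @param gene Marker gene symbol.
#' @param min_count Minimum count to call a cell positive (default 1).
#' @return Named logical vector, one element per cell.
#' @export
call_positive <- function(counts, gene, min_count = 1L) {
  stopifnot(inherits(counts, "sc_counts"))
  if (!gene %in% rownames(counts$counts)) {
    stop("gene '", gene, "' not in the count matrix", call. = FALSE)
  }
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  v <- as.numeric(counts$counts[gene, ])
  stats::setNames(v >= min_count, colnames(counts$counts))
}

#' Fraction of cells positive for a marker
#'
#' Integer-count arithmetic throughout: the only floating operation is the
#' final division. Reports the fraction and the percent rounded to one
#' decimal, the resolution positivity percentages are usually quoted at.
#'
#' @param counts An [sc_counts()] object.
#' @param gene Marker gene symbol.
#' @param by_condition Split by the per-cell condition labels (default
#'   `TRUE` when labels are present).
#' @param min_count Positivity floor passed to [call_positive()].
#' @return Tibble with one row per condition (or a single `all` row):
#'   `condition`, `n_cells`, `n_positive`, `fraction`, `percent_1dp`.
#' @export
#' @examples
#' sp <- single_cell_spec(112, c(CD276 = 0.179), n_genes = 3, seed = 11)
#' positivity_fraction(generate_single_cell(sp, condition = "pre"), "CD276")
positivity_fraction <- function(counts, gene,
                                by_condition = !is.null(counts$conditions),
                                min_count = 1L) {
  pos <- call_positive(counts, gene, min_count = min_count)
  grp <- if (by_condition) {
    if (is.null(counts$conditions)) {
      stop("no condition labels attached to the counts", call. = FALSE)
    }
    counts$conditions
  } else {
    rep("all", length(pos))
  }
  if (any(is.na(grp)) || any(grp == "")) {
    bad <- unique(names(pos)[is.na(grp) | grp == ""])[1L]
    stop("cell '", bad, "' has an empty condition label", call. = FALSE)
  }
  purrr::map_dfr(unique(grp), function(g) {
    n <- sum(grp == g)
    np <- sum(pos[grp == g])
    tibble::tibble(
      condition = g, n_cells = n, n_positive = np,
      fraction = np / n, percent_1dp = round(100 * np / n, 1)
    )
  })
}

#' Write single-cell counts as MTX with gene/barcode sidecars
#'
#' Produces `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and, when condition
#' labels are present, `conditions.tsv` (cell, condition) in `dir`.
#'
#' @param x An [sc_counts()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sc_mtx <- function(x, dir) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(x$counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(x$conditions)) {
    readr::write_tsv(
      tibble::tibble(cell = colnames(x$counts),
                     condition = unname(x$conditions)),
      file.path(dir, "conditions.tsv"), col_names = FALSE, progress = FALSE
    )
  }
  invisible(dir)
}

#' Read single-cell counts from an MTX directory
#'
#' Expects the layout written by [write_sc_mtx()]; `conditions.tsv` is
#' optional.
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return An [sc_counts()] object.
#' @export
read_sc_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  cond_path <- file.path(dir, "conditions.tsv")
  conditions <- NULL
  if (file.exists(cond_path)) {
    tbl <- readr::read_tsv(cond_path, col_names = c("cell", "condition"),
                           col_types = "cc", progress = FALSE)
    conditions <- stats::setNames(tbl$condition, tbl$cell)[colnames(m)]
  }
  sc_counts(m, conditions = conditions)
}
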