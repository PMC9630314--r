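#' Specify a planted co-expression module
#'
#' A module is a block of genes that share a latent factor so that every
#' within-module gene pair has (approximately) the same pairwise correlation
#' `rho` on the log scale. This is the statistical skeleton of a coherent
#' transcriptional program (such as an AR/FOXA1/HOXB13-like axis) that the
#' network-similarity stage is expected to recover.
#'
#' @param module_id Module label.
#' @param genes Character vector of member gene symbols (non-empty, unique).
#' @param within_correlation Target pairwise latent correlation, in \[0, 1\].
#' @param mean_log_expression Mean of log2 expression for member genes.
#' @param module_signal_sd Standard deviation of log2 expression. Kept modest
#'   (default 0.5) so that exponentiation barely attenuates the Pearson
#'   correlation of the heavy-tailed values.
#' @return A `module_spec` list.
#' @export
module_spec <- function(module_id, genes, within_correlation,
                        mean_log_expression = 5, module_signal_sd = 0.5) {
  if (length(genes) == 0L) {
    stop("module '", module_id, "' has no genes", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("module '", module_id, "' has duplicate gene symbols", call. = FALSE)
  }
  if (!is.numeric(within_correlation) || length(within_correlation) != 1L ||
      is.na(within_correlation) ||
      within_correlation < 0 || within_correlation > 1) {
    stop("within_correlation of module '", module_id,
         "' must lie in [0, 1]", call. = FALSE)
  }
  assert_scalar_number(module_signal_sd, "module_signal_sd", lower = 0)
  structure(
    list(module_id = as.character(module_id), genes = as.character(genes),
         within_correlation = within_correlation,
         mean_log_expression = mean_log_expression,
         module_signal_sd = module_signal_sd),
    class = "module_spec"
  )
}

#' Specify a synthetic bulk cohort
#'
#' @param cohort_id Cohort label.
#' @param n_samples Number of samples (>= 2).
#' @param unit Unit the cohort is expressed in: `"FPKM"`, `"TPM"` or
#'   `"RSEM_FRACTION"`. Emulates public cohorts mapped on different
#'   platforms with different units.
#' @param noise_sd Standard deviation of log2 expression for background
#'   (independent) genes.
#' @param seed RNG seed; recorded so generation is reproducible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(cohort_id, n_samples, unit = "TPM",
                        noise_sd = 0.5, seed = 1L) {
  unit <- match.arg(unit, c("FPKM", "TPM", "RSEM_FRACTION"))
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be >= 2", call. = FALSE)
  }
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(cohort_id = as.character(cohort_id),
         n_samples = as.integer(n_samples), unit = unit,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Latent-factor Gaussian copula for one module: z = sqrt(rho) f + sqrt(1-rho) e
# gives every within-module pair latent correlation rho; expression is
# 2^(mu + sd * z), i.e. log-normal marginals with controlled correlation.
simulate_module_block <- function(module, n_samples) {
  rho <- module$within_correlation
  g <- length(module$genes)
  f <- stats::rnorm(n_samples)
  e <- matrix(stats::rnorm(g * n_samples), nrow = g)
  z <- sqrt(rho) * matrix(f, nrow = g, ncol = n_samples, byrow = TRUE) +
    sqrt(1 - rho) * e
  vals <- 2 ^ (module$mean_log_expression + module$module_signal_sd * z)
  rownames(vals) <- module$genes
  vals
}

#' Generate a synthetic bulk expression cohort with planted modules
#'
#' Module genes share a latent Gaussian factor (copula) so their pairwise
#' log-scale correlation is `within_correlation`; exponentiation then yields
#' heavy-tailed, TPM-like positive marginals. Background genes are mutually
#' independent log-normals whose log2 means are spread uniformly, mimicking
#' the dynamic range of bulk RNA-seq. The matrix is finally expressed in the
#' cohort's declared unit: TPM columns sum to 1e6, RSEM transcript-fraction
#' columns sum to 1, FPKM columns keep arbitrary per-sample depths.
#'
#' @param cohort A [cohort_spec()].
#' @param modules List of [module_spec()]s; gene symbols must be disjoint
#'   across modules.
#' @param n_background_genes Number of independent background genes.
#' @param background_names Optional explicit background gene symbols
#'   (length `n_background_genes`); used by [generate_multicohort()] to give
#'   cohorts shared and private backgrounds.
#' @return An [expression_matrix()] in the cohort's unit.
#' @export
#' @examples
#' mod <- module_spec("m1", paste0("MG", 1:8), within_correlation = 0.9)
#' co <- cohort_spec("demo", n_samples = 50, unit = "TPM", seed = 7)
#' x <- generate_cohort(co, list(mod), n_background_genes = 20)
#' x
generate_cohort <- function(cohort, modules = list(),
                            n_background_genes = 0L,
                            background_names = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "module_spec")) {
      do.call(module_spec, m)
    } else {
      m
    }
  })
  module_genes <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(module_genes)) {
    dup <- module_genes[duplicated(module_genes)][1L]
    stop("gene '", dup, "' appears in more than one module", call. = FALSE)
  }
  if (is.null(background_names) && n_background_genes > 0) {
    background_names <- sprintf("BG%04d", seq_len(n_background_genes))
  }
  all_genes <- c(module_genes, background_names)
  if (anyDuplicated(all_genes)) {
    dup <- all_genes[duplicated(all_genes)][1L]
    stop("duplicate gene symbol: ", dup, call. = FALSE)
  }
  n <- cohort$n_samples
  vals <- with_seed(cohort$seed, {
    blocks <- lapply(modules, simulate_module_block, n_samples = n)
    if (length(background_names) > 0) {
      nb <- length(background_names)
      mu <- stats::runif(nb, min = 1, max = 7)  # log2 TPM dynamic range
      z <- matrix(stats::rnorm(nb * n), nrow = nb)
      bg <- 2 ^ (mu + cohort$noise_sd * z)
      rownames(bg) <- background_names
      blocks <- c(blocks, list(bg))
    }
    v <- do.call(rbind, blocks)
    colnames(v) <- sprintf("%s_S%03d", cohort$cohort_id, seq_len(n))
    if (cohort$unit == "TPM") {
      v <- rescale_columns(v, 1e6)
    } else if (cohort$unit == "RSEM_FRACTION") {
      v <- rescale_columns(v, 1)
    } else {
      # FPKM: arbitrary per-sample sequencing depths
      v <- sweep(v, 2L, stats::rlnorm(n, meanlog = 0, sdlog = 0.3), `*`)
    }
    v
  })
  expression_matrix(vals, unit = cohort$unit, cohort_id = cohort$cohort_id)
}

#' Generate several cohorts sharing planted modules
#'
#' All cohorts contain the shared module genes (plus an optional shared
#' background); each cohort additionally carries private genes absent from
#' every other cohort, so the size of the gene-symbol intersection is known
#' by construction — the property the cross-cohort merge step is tested
#' against.
#'
#' @param cohorts List of [cohort_spec()]s (>= 2).
#' @param shared_modules Modules planted identically in every cohort.
#' @param per_cohort_extra_genes Number of private background genes per
#'   cohort.
#' @param n_shared_background_genes Number of background genes shared by all
#'   cohorts (default 0).
#' @return List of [expression_matrix()], one per cohort.
#' @export
generate_multicohort <- function(cohorts, shared_modules = list(),
                                 per_cohort_extra_genes = 0L,
                                 n_shared_background_genes = 0L) {
  if (length(cohorts) < 2L) {
    stop("need at least two cohorts", call. = FALSE)
  }
  shared_bg <- if (n_shared_background_genes > 0) {
    sprintf("SBG%04d", seq_len(n_shared_background_genes))
  } else {
    character()
  }
  lapply(cohorts, function(co) {
    priv <- if (per_cohort_extra_genes > 0) {
      sprintf("%s_PRIV%03d", co$cohort_id, seq_len(per_cohort_extra_genes))
    } else {
      character()
    }
    generate_cohort(
      co, shared_modules,
      n_background_genes = length(shared_bg) + length(priv),
      background_names = c(shared_bg, priv)
    )
  })
}

#' Specify a synthetic single-cell experiment
#'
#' @param n_cells Number of cells.
#' @param detection_fraction Named numeric vector mapping gene symbol to the
#'   probability that a cell has a nonzero count for that gene.
#' @param n_genes Total genes; genes beyond `names(detection_fraction)` are
#'   filler genes with detection `default_detection`.
#' @param mean_count_when_detected Mean count among detected (positive)
#'   cells; must be >= 1.
#' @param default_detection Detection fraction for filler genes.
#' @param seed RNG seed.
#' @return A `single_cell_spec` list.
#' @export
single_cell_spec <- function(n_cells, detection_fraction,
                             n_genes = length(detection_fraction),
                             mean_count_when_detected = 2,
                             default_detection = 0.1, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (is.null(names(detection_fraction)) || any(names(detection_fraction) == "")) {
    stop("detection_fraction must be a named vector (gene -> fraction)",
         call. = FALSE)
  }
  if (any(detection_fraction < 0 | detection_fraction > 1)) {
    stop("detection fractions must lie in [0, 1]", call. = FALSE)
  }
  if (mean_count_when_detected < 1) {
    stop("mean_count_when_detected must be >= 1", call. = FALSE)
  }
  if (n_genes < length(detection_fraction)) {
    stop("n_genes is smaller than the number of named genes", call. = FALSE)
  }
  structure(
    list(n_cells = as.integer(n_cells),
         detection_fraction = detection_fraction,
         n_genes = as.integer(n_genes),
         mean_count_when_detected = mean_count_when_detected,
         default_detection = default_detection,
         seed = as.integer(seed)),
    class = "single_cell_spec"
  )
}

#' Single-cell count container
#'
#' @param counts Gene-by-cell matrix of non-negative integer counts (dense
#'   or `Matrix` sparse), with gene rownames and cell colnames.
#' @param conditions Optional character vector of per-cell condition labels
#'   (e.g. pre/post treatment), length `ncol(counts)`.
#' @return An `sc_counts` object.
#' @export
sc_counts <- function(counts, conditions = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) stop("cell IDs must be unique", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("gene symbols must be unique", call. = FALSE)
  v <- as.vector(as.matrix(counts))
  if (any(v < 0) || any(v != floor(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!is.null(conditions)) {
    if (length(conditions) != ncol(counts)) {
      stop("conditions must have one label per cell", call. = FALSE)
    }
    conditions <- as.character(conditions)
    names(conditions) <- colnames(counts)
  }
  structure(list(counts = counts, conditions = conditions),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d genes x %d cells", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$conditions)) {
    cat(sprintf(" (%d conditions)", length(unique(x$conditions))))
  }
  cat("\n")
  invisible(x)
}

#' Generate sparse single-cell counts with known detection fractions
#'
#' Each cell-gene entry is zero with probability `1 - detection_fraction` and
#' otherwise `1 + Poisson(mean_count_when_detected - 1)`, so "detected"
#' means exactly count > 0 and the expected per-gene positive fraction equals
#' the specified detection fraction.
#'
#' @param spec A [single_cell_spec()].
#' @param condition Optional single condition label for all generated cells.
#' @param cell_prefix Prefix for cell barcodes.
#' @return An [sc_counts()] with a sparse `Matrix` inside.
#' @export
#' @examples
#' sp <- single_cell_spec(200, c(CD276 = 0.3), n_genes = 5, seed = 3)
#' generate_single_cell(sp, condition = "pre")
generate_single_cell <- function(spec, condition = NULL, cell_prefix = "cell") {
  stopifnot(inherits(spec, "single_cell_spec"))
  det <- spec$detection_fraction
  n_fill <- spec$n_genes - length(det)
  if (n_fill > 0) {
    fill <- rep(spec$default_detection, n_fill)
    names(fill) <- sprintf("SCG%04d", seq_len(n_fill))
    det <- c(det, fill)
  }
  g <- length(det)
  n <- spec$n_cells
  counts <- with_seed(spec$seed, {
    detected <- matrix(stats::runif(g * n) < det, nrow = g)  # recycles by gene
    k <- sum(detected)
    pos <- 1L + stats::rpois(k, lambda = spec$mean_count_when_detected - 1)
    m <- matrix(0L, nrow = g, ncol = n)
    m[detected] <- pos
    m
  })
  rownames(counts) <- names(det)
  colnames(counts) <- sprintf("%s_%05d", cell_prefix, seq_len(n))
  cond <- if (!is.null(condition)) rep(as.character(condition), n)
  sc_counts(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
            conditions = cond)
}

#' Combine single-cell count objects (same gene panel)
#'
#' @param ... `sc_counts` objects sharing identical gene rownames.
#' @return A combined `sc_counts`.
#' @export
bind_cells <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "sc_counts")))
  gs <- rownames(xs[[1]]$counts)
  for (x in xs) {
    if (!identical(rownames(x$counts), gs)) {
      stop("all objects must share the same gene panel", call. = FALSE)
    }
  }
  counts <- do.call(cbind, lapply(xs, `[[`, "counts"))
  conds <- lapply(xs, `[[`, "conditions")
  conditions <- if (all(vapply(conds, is.null, TRUE))) NULL else {
    unlist(lapply(seq_along(xs), function(i) {
      conds[[i]] %||% rep(NA_character_, ncol(xs[[i]]$counts))
    }))
  }
  if (anyDuplicated(colnames(counts))) {
    colnames(counts) <- make.unique(colnames(counts), sep = "_")
  }
  sc_counts(counts, conditions = conditions)
}

#' Generate gene-set collections with the planted modules as truth
#'
#' One set per planted module (its exact gene list) plus `n_random_sets`
#' uniform draws from the universe — a stand-in for an oncogenic-signature
#' collection in which the module sets are the true positives.
#'
#' @param modules List of [module_spec()]s.
#' @param n_random_sets Number of random decoy sets.
#' @param set_size Size of each random set.
#' @param universe Character vector of gene symbols to draw decoys from.
#' @param seed RNG seed.
#' @return Named list of character vectors (GMT-serializable).
#' @export
generate_gene_sets <- function(modules, n_random_sets, set_size, universe,
                               seed = 1L) {
  if (set_size > length(universe)) {
    stop("set_size exceeds the universe size", call. = FALSE)
  }
  sets <- lapply(modules, `[[`, "genes")
  names(sets) <- paste0("MODULE_", vapply(modules, `[[`, "", "module_id"))
  rand <- with_seed(seed, {
    lapply(seq_len(n_random_sets), function(i) sort(sample(universe, set_size)))
  })
  names(rand) <- sprintf("RANDOM_%03d", seq_len(n_random_sets))
  c(sets, rand)
}
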