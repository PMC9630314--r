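#' @importFrom rlang %||%
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Scale each column of a non-negative matrix to sum to `total`.
# Zero-sum columns are hard errors: silently dropping them would change n.
rescale_columns <- function(values, total = 1e6) {
  cs <- colSums(values)
  if (any(cs <= 0)) {
    bad <- colnames(values)[cs <= 0][1L]
    stop("sample '", bad, "' has zero total expression; rescale undefined",
         call. = FALSE)
  }
  sweep(values, 2L, total / cs, `*`)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop("`", name, "` must be a single number in [", lower, ", ", upper, "]",
         call. = FALSE)
  }
  invisible(x)
}
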