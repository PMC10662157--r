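#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so library functions stay reproducible without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Fisher z transform with clipping
#'
#' `atanh` of a correlation, with `r` clipped to `1 - eps` in absolute value
#' so numerically perfect correlations stay finite.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @param eps clipping margin (default `1e-12`).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r, eps = 1e-12) {
  atanh(pmin(pmax(r, -(1 - eps)), 1 - eps))
}

#' Cosine similarity matrix of row vectors
#'
#' @param embeddings numeric matrix, one row per word (rownames are word ids).
#' @return square symmetric matrix of cosine similarities.
#' @export
cosine_similarity <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(nrm == 0)) stop("zero-norm embedding vector")
  s <- tcrossprod(embeddings / nrm)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# Values of the strict upper triangle, column-major.
upper_vals <- function(m) m[upper.tri(m)]

# Derive a child seed (< 2^31) from a base seed and stream index.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483647)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
}
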