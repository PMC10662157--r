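#' K-nearest-neighbor imputation of structurally missing dissimilarities
#'
#' Pairs of to-be-learned words are never co-presented on an arrangement
#' trial, so their dissimilarity is never measured directly. Each word's full
#' row of the dissimilarity matrix is treated as a sample over n features;
#' a missing cell (i, j) is filled with the inverse-distance-weighted mean of
#' column j over the k rows nearest to row i under the nan-aware Euclidean
#' distance (squared differences summed over mutually observed features and
#' rescaled by the fraction observed). The filled matrix is then symmetrized
#' by averaging with its transpose, since row-wise imputation is not
#' guaranteed symmetric. The diagonal is excluded as a feature.
#'
#' @param combined a `combined_rsm` with missing cells.
#' @param k number of neighbor rows (default 40, the pipeline's standard).
#' @return the `combined_rsm` with `delta` complete and `imputed_mask`
#'   marking the filled cells.
#' @export
knn_impute <- function(combined, k = 40L) {
  x <- combined$delta
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of words")
  miss <- is.na(x)
  diag(miss) <- FALSE
  if (!any(miss)) {
    combined$imputed_mask <- miss
    return(combined)
  }

  # feature matrix: rows of delta with the diagonal masked out
  feat <- x
  diag(feat) <- NA
  if (any(rowSums(!is.na(feat)) < 2L)) stop("a row has fewer than 2 observed features")
  d <- nan_euclidean(feat)

  filled <- x
  has_val <- !is.na(x)
  for (i in seq_len(n)) {
    cols <- which(miss[i, ])
    if (!length(cols)) next
    ord <- order(d[i, ], seq_len(n))        # all rows, nearest first
    ord <- ord[ord != i & is.finite(d[i, ord])]
    for (j in cols) {
      dn <- ord[has_val[ord, j]]
      if (!length(dn)) next
      dn <- dn[seq_len(min(k, length(dn)))]
      dist_sel <- d[i, dn]
      vals <- x[dn, j]
      if (any(dist_sel == 0)) {
        filled[i, j] <- mean(vals[dist_sel == 0])
      } else {
        w <- 1 / dist_sel
        filled[i, j] <- sum(w * vals) / sum(w)
      }
    }
  }
  if (any(is.na(filled) & !diag(n))) stop("imputation failed: cell with no donors")
  filled <- (filled + t(filled)) / 2
  diag(filled) <- 0
  combined$delta <- filled
  combined$imputed_mask <- miss | t(miss)
  combined
}

#' Nan-aware Euclidean distances between matrix rows
#'
#' Squared differences are summed over features observed in both rows and
#' rescaled by `n_features / n_shared` (so rows with little overlap are not
#' spuriously close). Rows sharing no feature get distance `Inf`.
#'
#' @param x numeric matrix, `NA` for missing entries.
#' @return symmetric matrix of distances.
#' @export
nan_euclidean <- function(x) {
  m <- !is.na(x)
  x0 <- x
  x0[!m] <- 0
  p <- ncol(x)
  sq <- x0^2
  shared <- tcrossprod(m * 1)
  ss <- tcrossprod(sq, m) + tcrossprod(m, sq) - 2 * tcrossprod(x0)
  ss[ss < 0] <- 0
  d2 <- ifelse(shared > 0, (p / shared) * ss, Inf)
  d <- sqrt(d2)
  diag(d) <- 0
  d
}
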