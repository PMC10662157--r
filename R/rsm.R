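#' Per-trial dissimilarity matrix from canvas placements
#'
#' Converts one arrangement trial into a partial representational
#' dissimilarity matrix over the full word index: Euclidean distance in
#' pixels between word centers for co-presented words, missing elsewhere.
#' Evidence weights are the squared on-screen distances — larger separations
#' are more reliably intended placements — so a trial contributes most where
#' the participant spread words out.
#'
#' @param layout list with `trial_index`, `positions` (data frame `word_id`,
#'   `x`, `y`, or 2-column matrix with word-id rownames) and `canvas`
#'   (`c(width, height)` in pixels).
#' @param word_ids full word index the matrix is defined over (defaults to
#'   the words on the trial).
#' @return object of class `partial_rdm`: list with `d` (distances, `NA`
#'   where not co-presented), `w` (evidence weights, zero where missing) and
#'   `trial_index`.
#' @export
trial_distance_matrix <- function(layout, word_ids = NULL) {
  pos <- layout$positions
  if (is.matrix(pos)) {
    pos <- data.frame(word_id = rownames(pos), x = pos[, 1], y = pos[, 2])
  }
  stopifnot_cols(pos, c("word_id", "x", "y"), "positions")
  if (anyDuplicated(pos$word_id)) stop("duplicate word on trial")
  if (anyNA(pos$x) || anyNA(pos$y)) stop("missing coordinates")
  if (!is.null(layout$canvas)) {
    cv <- layout$canvas
    if (any(pos$x < 0 | pos$x > cv[1] | pos$y < 0 | pos$y > cv[2])) {
      warning("coordinates outside canvas bounds")
    }
  }
  if (is.null(word_ids)) word_ids <- sort(pos$word_id)
  if (!all(pos$word_id %in% word_ids)) stop("trial word not in word index")

  n <- length(word_ids)
  d <- matrix(NA_real_, n, n, dimnames = list(word_ids, word_ids))
  idx <- match(pos$word_id, word_ids)
  dd <- as.matrix(stats::dist(cbind(pos$x, pos$y)))
  d[idx, idx] <- dd
  w <- d^2
  w[is.na(w)] <- 0
  structure(list(d = d, w = w, trial_index = layout$trial_index),
            class = "partial_rdm")
}

#' Combine partial trial matrices by scaled-to-match evidence-weighted
#' averaging
#'
#' Arrangement trials use the canvas at arbitrary, trial-specific scales, so
#' their distance matrices must be brought to a common scale before
#' averaging. Iteratively: (1) initialize the estimate as the evidence-
#' weighted mean of trials each scaled to unit RMS over its observed cells;
#' (2) rescale each trial by the least-squares factor matching the current
#' estimate on its cells; (3) recompute the evidence-weighted cell-wise mean;
#' repeat to convergence. The result is scaled so the completed upper
#' triangle has unit Frobenius norm (observed-cell RMS equals
#' `1/sqrt(n(n-1)/2)`), which for a fully observed matrix is exactly the unit
#' Frobenius norm of the upper triangle. Cells observed on no trial (the
#' structurally never-co-presented pairs) remain missing; cells only ever
#' observed at zero distance carry zero evidence and are treated as missing.
#'
#' @param partials list of `partial_rdm` over a common word index.
#' @param tol convergence tolerance on the max cell change (default `1e-8`).
#' @param max_iter iteration cap (default 100).
#' @param session optional label (`"pre"`/`"post"`) carried on the result.
#' @return object of class `combined_rsm`: `delta` (dissimilarities, `NA`
#'   where unobserved), `s` (`NA` until [to_similarity()]), `imputed_mask`
#'   (`TRUE` on cells with no direct measurement), `session`, `words`.
#' @export
combine_trials <- function(partials, tol = 1e-8, max_iter = 100L,
                           session = NA_character_) {
  if (length(partials) < 1L) stop("need at least one trial")
  words <- rownames(partials[[1L]]$d)
  n <- length(words)
  for (p in partials) {
    if (!identical(rownames(p$d), words)) stop("trials must share a word index")
  }

  # sparse upper-triangle representation: per trial, cell indices + values
  ut <- upper.tri(matrix(0, n, n))
  trials <- lapply(partials, function(p) {
    keep <- !is.na(p$d) & p$w > 0 & ut
    idx <- which(keep)
    if (!length(idx)) stop("trial has no informative (nonzero) distances")
    list(idx = idx, d = p$d[idx], w = p$w[idx])
  })
  if (length(trials) > 1L) .check_connected(lapply(trials, `[[`, "idx"))

  n_cells <- sum(ut)
  wsum <- numeric(n_cells)
  cell_of <- match(seq_len(n * n), which(ut))
  tcells <- lapply(trials, function(t) cell_of[t$idx])
  for (i in seq_along(trials)) wsum[tcells[[i]]] <- wsum[tcells[[i]]] + trials[[i]]$w
  observed <- wsum > 0

  avg <- function(sc) {
    num <- numeric(n_cells)
    for (i in seq_along(trials)) {
      num[tcells[[i]]] <- num[tcells[[i]]] + trials[[i]]$w * (sc[i] * trials[[i]]$d)
    }
    e <- num / wsum
    e[!observed] <- NA
    e
  }
  rms_obs <- function(v) sqrt(mean(v[observed]^2))

  scales <- vapply(trials, function(t) 1 / sqrt(mean(t$d^2)), numeric(1))
  est <- avg(scales)
  est <- est / rms_obs(est)
  for (it in seq_len(max_iter)) {
    sc <- vapply(seq_along(trials), function(i) {
      e <- est[tcells[[i]]]
      sum(trials[[i]]$d * e) / sum(trials[[i]]$d^2)
    }, numeric(1))
    new <- avg(sc)
    new <- new / rms_obs(new)
    delta_max <- max(abs(new - est), na.rm = TRUE)
    est <- new
    if (delta_max < tol) break
  }

  n_full <- n * (n - 1) / 2
  est <- est * (1 / sqrt(n_full)) / rms_obs(est)

  full <- matrix(NA_real_, n, n, dimnames = list(words, words))
  full[ut] <- est
  full <- pmin(full, t(full), na.rm = TRUE)  # mirror upper triangle down
  diag(full) <- 0
  est <- full
  mask <- is.na(est)
  diag(mask) <- FALSE
  structure(
    list(delta = est, s = NULL, imputed_mask = mask, session = session,
         words = words),
    class = "combined_rsm"
  )
}

# Trials must overlap so a common scale is identifiable.
.check_connected <- function(idx_sets) {
  k <- length(idx_sets)
  linked <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    i == j || length(intersect(idx_sets[[i]], idx_sets[[j]])) > 0
  }))
  reach <- linked
  for (s in seq_len(k)) reach <- (reach %*% linked) > 0
  if (!all(reach)) stop("disconnected trials: no shared cells to match scales")
}

#' @export
print.combined_rsm <- function(x, ...) {
  cat(sprintf(
    "<combined_rsm> %d words, session=%s, %d imputed cells (%s)\n",
    length(x$words), x$session, sum(x$imputed_mask),
    if (anyNA(x$delta)) "incomplete" else "complete"
  ))
  invisible(x)
}

#' Convert a completed dissimilarity matrix to similarities
#'
#' `s = 1 - delta` elementwise, on the normalized scale where all
#' off-diagonal dissimilarities are small positive numbers (for the 120-word
#' design, mean similarity around 0.989). A dissimilarity above 1 signals a
#' broken normalization and is an error.
#'
#' @param combined a complete `combined_rsm` (no missing cells).
#' @return the `combined_rsm` with `s` filled.
#' @export
to_similarity <- function(combined) {
  if (anyNA(combined$delta)) stop("dissimilarity matrix still has missing cells")
  if (any(combined$delta > 1)) stop("dissimilarity > 1: normalization is broken")
  combined$s <- 1 - combined$delta
  combined
}

#' Within-pair similarity before and after learning
#'
#' One row per learned pair with its pre- and post-session similarity and
#' whether the cell was imputed (for learned pairs this is true by design:
#' the pair members were never co-presented).
#'
#' @param rsm_pre,rsm_post complete `combined_rsm` objects with `s` filled.
#' @param pairs pair table with `pair_id`, `cue_id`, `target_id`.
#' @return data frame `pair_id`, `cue_id`, `target_id`, `s_pre`, `s_post`,
#'   `imputed`.
#' @export
pair_similarity_table <- function(rsm_pre, rsm_post, pairs) {
  stopifnot_cols(pairs, c("pair_id", "cue_id", "target_id"), "pairs")
  for (rsm in list(rsm_pre, rsm_post)) {
    if (is.null(rsm$s)) stop("run to_similarity() first")
  }
  ci <- match(as.character(pairs$cue_id), rsm_pre$words)
  ti <- match(as.character(pairs$target_id), rsm_pre$words)
  if (anyNA(ci) || anyNA(ti)) stop("pair references a word missing from the RSM")
  cells <- cbind(ci, ti)
  data.frame(
    pair_id = pairs$pair_id, cue_id = pairs$cue_id, target_id = pairs$target_id,
    s_pre = rsm_pre$s[cells], s_post = rsm_post$s[cells],
    imputed = rsm_pre$imputed_mask[cells] | rsm_post$imputed_mask[cells]
  )
}
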