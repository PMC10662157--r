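#' Pairwise similarity change for learned pairs and random controls
#'
#' Computes the change in within-pair similarity across learning,
#' `delta = s_post - s_pre`, for every learned pair (classed by final recall
#' as `learned-recalled` or `learned-forgotten`) and for `n_random` random
#' never-learned word pairings sampled by `seed` as a baseline. A positive
#' value means the words became more similar over learning.
#'
#' @param rsm_pre,rsm_post complete similarity matrices ([to_similarity()]).
#' @param pairs pair table with `pair_id`, `cue_id`, `target_id` and,
#'   optionally, `recalled_day2` (logical) for classing.
#' @param n_random number of random control pairings (default 60).
#' @param seed seed for the control sampling.
#' @return data frame `pair_id`, `word_i`, `word_j`, `class`, `s_pre`,
#'   `s_post`, `delta`.
#' @export
pair_change <- function(rsm_pre, rsm_post, pairs, n_random = 60L, seed = 1L) {
  tab <- pair_similarity_table(rsm_pre, rsm_post, pairs)
  cls <- if ("recalled_day2" %in% names(pairs)) {
    ifelse(pairs$recalled_day2[match(tab$pair_id, pairs$pair_id)],
           "learned-recalled", "learned-forgotten")
  } else {
    rep("learned", nrow(tab))
  }
  learned <- data.frame(
    pair_id = tab$pair_id, word_i = as.character(tab$cue_id),
    word_j = as.character(tab$target_id), class = cls,
    s_pre = tab$s_pre, s_post = tab$s_post, stringsAsFactors = FALSE
  )

  words <- rsm_pre$words
  n <- length(words)
  learned_key <- c(paste(learned$word_i, learned$word_j),
                   paste(learned$word_j, learned$word_i))
  rand <- with_seed(seed, {
    got <- character(0)
    out <- matrix(character(0), 0, 2)
    guard <- 0L
    while (nrow(out) < n_random && guard < 50L * n_random) {
      guard <- guard + 1L
      ij <- sample.int(n, 2L)
      key <- paste(words[ij[1]], words[ij[2]])
      if (key %in% learned_key || key %in% got) next
      got <- c(got, key, paste(words[ij[2]], words[ij[1]]))
      out <- rbind(out, words[ij])
    }
    out
  })
  if (nrow(rand) < n_random) stop("could not sample enough distinct control pairs")
  ri <- match(rand[, 1], words)
  rj <- match(rand[, 2], words)
  random <- data.frame(
    pair_id = NA_integer_, word_i = rand[, 1], word_j = rand[, 2],
    class = "random-control",
    s_pre = rsm_pre$s[cbind(ri, rj)], s_post = rsm_post$s[cbind(ri, rj)],
    stringsAsFactors = FALSE
  )
  out <- rbind(learned, random)
  out$delta <- out$s_post - out$s_pre
  out
}

#' Top-k nearest neighbors by normative cosine similarity
#'
#' Neighbors of a word under the normative embedding space, in descending
#' cosine similarity, after removing the exclusions (always including the
#' word itself); exclusions are applied before truncation to `k`. Ties are
#' broken by word id.
#'
#' @param embeddings numeric matrix with word-id rownames, or a precomputed
#'   square cosine-similarity matrix (detected by symmetry with unit
#'   diagonal).
#' @param word_id the word whose neighbors are sought.
#' @param k number of neighbors (default 20).
#' @param exclusions word ids to drop (e.g. the learned partner, words whose
#'   similarity cell is imputed).
#' @return character vector of neighbor word ids, length `k`.
#' @export
nearest_neighbors <- function(embeddings, word_id, k = 20L, exclusions = NULL) {
  word_id <- as.character(word_id)
  sim <- if (is.matrix(embeddings) && nrow(embeddings) == ncol(embeddings) &&
             identical(rownames(embeddings), colnames(embeddings)) &&
             all(abs(diag(embeddings) - 1) < 1e-8)) {
    embeddings
  } else {
    cosine_similarity(embeddings)
  }
  if (!word_id %in% rownames(sim)) stop("unknown word_id: ", word_id)
  v <- sim[word_id, ]
  drop <- unique(c(word_id, as.character(exclusions)))
  v <- v[setdiff(names(v), drop)]
  if (k > length(v)) stop("k exceeds the number of available candidate words")
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(k)]
}

#' Word-level representational vector over fixed neighbor columns
#'
#' The behavioral representation of a word in one session: its measured
#' (non-imputed) similarity values to a fixed set of neighbor columns.
#'
#' @param rsm a complete `combined_rsm` with `s` filled.
#' @param word_id the word.
#' @param neighbor_ids columns of the vector.
#' @return named numeric vector.
#' @export
word_vector <- function(rsm, word_id, neighbor_ids) {
  i <- match(as.character(word_id), rsm$words)
  j <- match(as.character(neighbor_ids), rsm$words)
  if (is.na(i) || anyNA(j)) stop("unknown word id")
  stats::setNames(rsm$s[i, j], as.character(neighbor_ids))
}

#' Neighbor column set for a word's representational vectors
#'
#' The top-`k` normative neighbors of a word, excluding the word itself, its
#' learned partner, and any word whose similarity cell with it is imputed in
#' either session.
#'
#' @param embeddings normative embeddings or cosine matrix.
#' @param word_id the word.
#' @param partner_id its learned partner.
#' @param rsm_pre,rsm_post the two sessions' matrices (for imputation masks).
#' @param k number of neighbors (default 20).
#' @return character vector of neighbor ids.
#' @export
neighbor_columns <- function(embeddings, word_id, partner_id,
                             rsm_pre, rsm_post, k = 20L) {
  i <- match(as.character(word_id), rsm_pre$words)
  imp <- rsm_pre$imputed_mask[i, ] | rsm_post$imputed_mask[i, ]
  nearest_neighbors(
    embeddings, word_id, k = k,
    exclusions = c(as.character(partner_id), rsm_pre$words[imp])
  )
}

#' Within-word representational change across learning
#'
#' Fisher z-transformed Pearson correlation between a word's pre- and
#' post-learning representational vectors over the same neighbor columns.
#' Lower z means more representational change.
#'
#' @param v_pre,v_post numeric vectors over identical neighbor columns.
#' @return Fisher z value (`NA` with a warning for constant vectors).
#' @export
word_change <- function(v_pre, v_post) {
  if (!is.null(names(v_pre)) && !is.null(names(v_post)) &&
      !identical(names(v_pre), names(v_post))) {
    stop("pre and post vectors must share the same neighbor columns")
  }
  if (length(v_pre) != length(v_post) || length(v_pre) < 3L) {
    stop("need >= 3 shared columns")
  }
  if (stats::sd(v_pre) == 0 || stats::sd(v_post) == 0) {
    warning("constant representational vector; change undefined")
    return(NA_real_)
  }
  fisher_z(stats::cor(v_pre, v_post))
}

#' Directional (cue vs target) representational change asymmetry
#'
#' `A = z(r(cue_pre, target_post)) - z(r(cue_post, target_pre))`, the
#' difference of Fisher z-transformed cross-session correlations computed
#' over a shared column set. Positive A: the target was drawn toward the
#' cue's position; negative A: the cue was drawn toward the target; zero:
#' symmetric (or no) change. Swapping the cue and target roles negates A.
#'
#' @param cue_pre,cue_post,target_pre,target_post numeric vectors over the
#'   same columns.
#' @param columns optional column names (recorded on the result).
#' @return list of class `asymmetry_record`: `r_c1t2`, `r_c2t1`, `A`,
#'   `columns`.
#' @export
asymmetry <- function(cue_pre, cue_post, target_pre, target_post,
                      columns = names(cue_pre)) {
  lens <- lengths(list(cue_pre, cue_post, target_pre, target_post))
  if (length(unique(lens)) != 1L) stop("vectors must share the same columns")
  if (lens[1] < 3L) stop("need >= 3 shared columns")
  sds <- vapply(list(cue_pre, cue_post, target_pre, target_post), stats::sd, numeric(1))
  if (any(sds == 0)) stop("constant vector; asymmetry undefined")
  r_c1t2 <- stats::cor(cue_pre, target_post)
  r_c2t1 <- stats::cor(cue_post, target_pre)
  structure(
    list(r_c1t2 = r_c1t2, r_c2t1 = r_c2t1,
         A = fisher_z(r_c1t2) - fisher_z(r_c2t1), columns = columns),
    class = "asymmetry_record"
  )
}

#' Asymmetry for every learned pair of a participant
#'
#' For each pair, builds the shared column set (by default the union of the
#' cue's and the target's top-`k` normative neighbors, minus the pair members
#' and any column imputed for either word in either session; `mode =
#' "all-words"` uses all other words instead as a sensitivity analysis) and
#' computes the asymmetry statistic.
#'
#' @param rsm_pre,rsm_post complete similarity matrices.
#' @param pairs pair table (`pair_id`, `cue_id`, `target_id`).
#' @param embeddings normative embeddings or cosine matrix.
#' @param k neighbors per word for the union column set (default 20).
#' @param mode `"union-NN"` (default) or `"all-words"`.
#' @return data frame `pair_id`, `r_c1t2`, `r_c2t1`, `A`, `n_columns`.
#' @export
pair_asymmetry <- function(rsm_pre, rsm_post, pairs, embeddings, k = 20L,
                           mode = c("union-NN", "all-words")) {
  mode <- match.arg(mode)
  words <- rsm_pre$words
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    cid <- as.character(pairs$cue_id[r])
    tid <- as.character(pairs$target_id[r])
    ci <- match(cid, words)
    ti <- match(tid, words)
    imp <- rsm_pre$imputed_mask[ci, ] | rsm_post$imputed_mask[ci, ] |
      rsm_pre$imputed_mask[ti, ] | rsm_post$imputed_mask[ti, ]
    cols <- if (mode == "union-NN") {
      nn_c <- nearest_neighbors(embeddings, cid, k, exclusions = c(tid, words[imp]))
      nn_t <- nearest_neighbors(embeddings, tid, k, exclusions = c(cid, words[imp]))
      union(nn_c, nn_t)
    } else {
      setdiff(words[!imp], c(cid, tid))
    }
    cols <- setdiff(cols, c(cid, tid))
    a <- asymmetry(
      word_vector(rsm_pre, cid, cols), word_vector(rsm_post, cid, cols),
      word_vector(rsm_pre, tid, cols), word_vector(rsm_post, tid, cols)
    )
    data.frame(pair_id = pairs$pair_id[r], r_c1t2 = a$r_c1t2,
               r_c2t1 = a$r_c2t1, A = a$A, n_columns = length(cols))
  })
  do.call(rbind, rows)
}

#' Bin a normative cosine similarity into lure strength classes
#'
#' Weak/non-lure below 0.2, moderate in `[0.2, 0.4)`, strong in `[0.4, 0.6)`,
#' very strong at 0.6 and above (half-open bins, left edge included).
#'
#' @param lsa_cos numeric vector of cosine similarities.
#' @param edges bin edges (default `c(0.2, 0.4, 0.6)`).
#' @return factor with levels `weak/non`, `moderate`, `strong`,
#'   `very strong`.
#' @export
lure_bin <- function(lsa_cos, edges = c(0.2, 0.4, 0.6)) {
  cut(lsa_cos, breaks = c(-Inf, edges, Inf), right = FALSE,
      labels = c("weak/non", "moderate", "strong", "very strong"))
}

#' Semantic lure table: cue-to-lure similarity change by lure strength
#'
#' For each retained cue (its pair correctly recalled at the final test, and
#' not a tested pair that failed at initial learning), every other corpus
#' word except the paired target is a potential lure: 118 records per cue on
#' the 120-word design. Each record carries the lure's normative similarity
#' bin and the change in measured cue-lure similarity across learning.
#'
#' @param pairs pair table with `pair_id`, `cue_id`, `target_id`,
#'   `relatedness`, `condition`, `recalled_day2` (logical) and
#'   `day1_outcome`.
#' @param lsa square normative cosine matrix (word-id dimnames).
#' @param rsm_pre,rsm_post complete similarity matrices.
#' @param edges lure bin edges.
#' @return data frame `cue_id`, `lure_id`, `lsa_cos`, `bin`, `s_pre`,
#'   `s_post`, `delta`, `condition`, `relatedness`.
#' @export
lure_table <- function(pairs, lsa, rsm_pre, rsm_post, edges = c(0.2, 0.4, 0.6)) {
  stopifnot_cols(pairs, c("pair_id", "cue_id", "target_id", "relatedness",
                          "condition", "recalled_day2", "day1_outcome"), "pairs")
  keep <- pairs$recalled_day2 &
    !(pairs$condition == "tested" & pairs$day1_outcome == "incorrect")
  kept <- pairs[keep, , drop = FALSE]
  words <- rsm_pre$words
  rows <- lapply(seq_len(nrow(kept)), function(r) {
    cid <- as.character(kept$cue_id[r])
    tid <- as.character(kept$target_id[r])
    lures <- setdiff(words, c(cid, tid))
    lv <- lsa[cid, lures]
    if (anyNA(lv)) stop("missing normative similarity value for a lure of ", cid)
    ci <- match(cid, words)
    lj <- match(lures, words)
    sp <- rsm_pre$s[ci, lj]
    so <- rsm_post$s[ci, lj]
    data.frame(
      cue_id = cid, lure_id = lures, lsa_cos = as.numeric(lv),
      bin = lure_bin(as.numeric(lv), edges),
      s_pre = sp, s_post = so, delta = so - sp,
      condition = kept$condition[r], relatedness = kept$relatedness[r],
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(cue_id = character(0), lure_id = character(0),
                      lsa_cos = numeric(0), bin = lure_bin(numeric(0), edges),
                      s_pre = numeric(0), s_post = numeric(0), delta = numeric(0),
                      condition = character(0), relatedness = character(0)))
  }
  do.call(rbind, rows)
}

#' Change in a word's alignment with normative semantic structure
#'
#' Correlates a word's measured similarity vector (over non-imputed columns)
#' with its normative cosine vector, in each session, and returns the change
#' in Fisher z. Positive: the word's measured representation moved toward the
#' normative structure over learning.
#'
#' @param word_id the word.
#' @param rsm_pre,rsm_post complete similarity matrices.
#' @param lsa square normative cosine matrix.
#' @param partner_id learned partner to exclude from the columns.
#' @return list `z_pre`, `z_post`, `delta_z`.
#' @export
normative_alignment_change <- function(word_id, rsm_pre, rsm_post, lsa,
                                       partner_id = NULL) {
  wid <- as.character(word_id)
  i <- match(wid, rsm_pre$words)
  if (is.na(i)) stop("unknown word id")
  imp <- rsm_pre$imputed_mask[i, ] | rsm_post$imputed_mask[i, ]
  cols <- setdiff(rsm_pre$words[!imp], c(wid, as.character(partner_id)))
  if (length(cols) < 3L) stop("fewer than 3 non-imputed columns")
  norm_v <- lsa[wid, cols]
  zp <- word_change_z(word_vector(rsm_pre, wid, cols), norm_v)
  zq <- word_change_z(word_vector(rsm_post, wid, cols), norm_v)
  list(z_pre = zp, z_post = zq, delta_z = zq - zp)
}

# Fisher-z correlation of two vectors, NA (with warning) if either constant.
word_change_z <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector; correlation undefined")
    return(NA_real_)
  }
  fisher_z(stats::cor(as.numeric(a), as.numeric(b)))
}

#' Word-level change table for every pair member of a participant
#'
#' For each learned pair, computes the cue's and target's 20-nearest-neighbor
#' representational change ([word_change()]) across sessions.
#'
#' @param rsm_pre,rsm_post complete similarity matrices.
#' @param pairs pair table.
#' @param embeddings normative embeddings or cosine matrix.
#' @param k neighbors (default 20).
#' @return data frame `pair_id`, `word_id`, `position` (cue/target), `z`.
#' @export
word_change_table <- function(rsm_pre, rsm_post, pairs, embeddings, k = 20L) {
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    out <- lapply(c(cue = "cue_id", target = "target_id"), function(col) {
      wid <- as.character(pairs[[col]][r])
      partner <- as.character(pairs[[setdiff(c("cue_id", "target_id"), col)]][r])
      cols <- neighbor_columns(embeddings, wid, partner, rsm_pre, rsm_post, k)
      word_change(word_vector(rsm_pre, wid, cols), word_vector(rsm_post, wid, cols))
    })
    data.frame(
      pair_id = rep(pairs$pair_id[r], 2L),
      word_id = c(as.character(pairs$cue_id[r]), as.character(pairs$target_id[r])),
      position = c("cue", "target"), z = c(out$cue, out$target),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
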