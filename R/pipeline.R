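#' Build one participant-session similarity matrix from arrangement layouts
#'
#' Distance extraction, scaled-to-match evidence-weighted combination,
#' k-nearest-neighbor imputation and similarity conversion in one call.
#'
#' @param layouts list of trial layouts (one session).
#' @param word_ids full word index.
#' @param k_impute imputation neighbors (default 40).
#' @param session label carried on the result.
#' @return complete `combined_rsm` with `s` filled.
#' @export
build_rsm <- function(layouts, word_ids, k_impute = 40L, session = NA_character_) {
  partials <- lapply(layouts, trial_distance_matrix, word_ids = word_ids)
  combined <- combine_trials(partials, session = session)
  combined <- knn_impute(combined, k = k_impute)
  to_similarity(combined)
}

#' Run the full analysis pipeline on a synthetic or loaded dataset
#'
#' Validates the design, builds each participant's pre/post similarity
#' matrices, scores recall, and computes the change, asymmetry and lure
#' statistics plus participant-level summaries. This is the programmatic
#' orchestration surface; all stage functions are exported and can be run
#' individually.
#'
#' @param dataset a `sim_dataset` (from [generate_dataset()]) or an
#'   equivalently structured list of loaded real data.
#' @param k_impute imputation neighbors (default 40).
#' @param k_neighbors nearest neighbors for word vectors (default 20).
#' @param lure_edges lure bin edges (default `c(0.2, 0.4, 0.6)`).
#' @param n_random random control pairings per participant (default 60).
#' @param use_true_recall use the generator's ground-truth recall outcomes
#'   instead of re-scoring responses (default `FALSE`).
#' @param verbose print per-participant progress (default `FALSE`).
#' @return list of class `swat_results` with per-participant tables
#'   (`pair_changes`, `asymmetry`, `lures`, `accuracy`, `word_changes`) and
#'   a `summary` data frame of participant-level means.
#' @export
run_pipeline <- function(dataset, k_impute = 40L, k_neighbors = 20L,
                         lure_edges = c(0.2, 0.4, 0.6), n_random = 60L,
                         use_true_recall = FALSE, verbose = FALSE) {
  corpus <- dataset$corpus
  word_ids <- corpus$words$word_id
  res <- lapply(dataset$participants, function(pp) {
    if (verbose) message("participant ", pp$id)
    analyze_participant(pp, corpus, k_impute = k_impute,
                        k_neighbors = k_neighbors, lure_edges = lure_edges,
                        n_random = n_random, use_true_recall = use_true_recall)
  })
  collect <- function(field) {
    do.call(rbind, lapply(res, function(r) {
      tab <- r[[field]]
      if (is.null(tab) || !nrow(tab)) return(NULL)
      if (!"participant" %in% names(tab)) tab <- cbind(participant = r$id, tab)
      tab
    }))
  }
  structure(
    list(
      pair_changes = collect("pair_changes"),
      asymmetry = collect("asymmetry"),
      lures = collect("lures"),
      accuracy = collect("accuracy"),
      word_changes = collect("word_changes"),
      summary = do.call(rbind, lapply(res, `[[`, "summary")),
      n_imputed = vapply(res, `[[`, numeric(1), "n_imputed")
    ),
    class = "swat_results"
  )
}

#' Analyze a single participant
#'
#' @param pp participant bundle (`pairs`, `recall`, `layouts_pre`,
#'   `layouts_post`).
#' @param corpus corpus bundle (`words`, `embeddings`, `lsa`).
#' @inheritParams run_pipeline
#' @return list of per-participant result tables.
#' @export
analyze_participant <- function(pp, corpus, k_impute = 40L, k_neighbors = 20L,
                                lure_edges = c(0.2, 0.4, 0.6), n_random = 60L,
                                use_true_recall = FALSE) {
  word_ids <- corpus$words$word_id
  rsm_pre <- build_rsm(pp$layouts_pre, word_ids, k_impute, session = "pre")
  rsm_post <- build_rsm(pp$layouts_post, word_ids, k_impute, session = "post")
  n_imputed <- sum(rsm_pre$imputed_mask[upper.tri(rsm_pre$imputed_mask)])

  pairs <- pp$pairs
  if (!use_true_recall || !"recalled_day2" %in% names(pairs)) {
    scored <- score_recall(pp$recall, pairs, corpus$words)
    d2 <- scored[scored$day == 2L, ]
    pairs$recalled_day2 <- d2$correct[match(pairs$pair_id, d2$pair_id)]
    pairs$day1_outcome <- d2$day1_outcome[match(pairs$pair_id, d2$pair_id)]
  } else {
    scored <- score_recall(pp$recall, pairs, corpus$words)
  }

  acc <- accuracy_table(scored, pairs, day = 2L, split = "condition")
  changes <- pair_change(rsm_pre, rsm_post, pairs, n_random = n_random,
                         seed = child_seed(sum(utf8ToInt(pp$id)), 9L))
  asym <- pair_asymmetry(rsm_pre, rsm_post, pairs, corpus$lsa, k = k_neighbors)
  asym$relatedness <- pairs$relatedness[match(asym$pair_id, pairs$pair_id)]
  asym$condition <- pairs$condition[match(asym$pair_id, pairs$pair_id)]
  asym$recalled_day2 <- pairs$recalled_day2[match(asym$pair_id, pairs$pair_id)]
  lures <- lure_table(pairs, corpus$lsa, rsm_pre, rsm_post, edges = lure_edges)

  mean_cls <- function(cls) {
    v <- changes$delta[changes$class == cls]
    if (length(v)) mean(v) else NA_real_
  }
  lure_mean <- function(bin, cond) {
    v <- lures$delta[lures$bin == bin & lures$condition == cond]
    if (length(v)) mean(v) else NA_real_
  }
  smry <- data.frame(
    participant = pp$id,
    mean_s_pre = mean(upper_vals(rsm_pre$s)),
    mean_s_post = mean(upper_vals(rsm_post$s)),
    delta_recalled = mean_cls("learned-recalled"),
    delta_forgotten = mean_cls("learned-forgotten"),
    delta_random = mean_cls("random-control"),
    A_related = mean(asym$A[asym$relatedness == "related" & asym$recalled_day2], na.rm = TRUE),
    A_unrelated = mean(asym$A[asym$relatedness == "unrelated" & asym$recalled_day2], na.rm = TRUE),
    lure_mod_tested = lure_mean("moderate", "tested"),
    lure_mod_restudied = lure_mean("moderate", "restudied"),
    lure_weak_tested = lure_mean("weak/non", "tested"),
    lure_weak_restudied = lure_mean("weak/non", "restudied"),
    n_lures = nrow(lures),
    n_excluded_day1 = sum(pairs$condition == "tested" & pairs$day1_outcome == "incorrect")
  )
  list(id = pp$id, rsm_pre = rsm_pre, rsm_post = rsm_post, pairs = pairs,
       accuracy = acc, pair_changes = changes, asymmetry = asym, lures = lures,
       word_changes = NULL, summary = smry, n_imputed = n_imputed)
}

#' @export
print.swat_results <- function(x, ...) {
  cat(sprintf("<swat_results> %d participants\n", nrow(x$summary)))
  print(utils::head(x$summary), digits = 4)
  invisible(x)
}
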