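#' Spell-tolerant scoring of a typed cued-recall response
#'
#' A response is correct if it matches the target exactly (case- and
#' surrounding-whitespace-insensitive), or if the dictionary word closest to
#' it in Levenshtein edit distance is the target and that distance is at most
#' `max_dist`. A response that is itself a different corpus word is always
#' incorrect, even when within `max_dist` of the target — typing a lure never
#' earns credit. Ties among equally close dictionary words are broken in
#' favor of corpus membership, then higher frequency, then alphabetical
#' order. A blank response is incorrect.
#'
#' @param response typed response (any case).
#' @param target the correct target word.
#' @param dictionary character vector of candidate words (should include the
#'   full stimulus corpus, and may add a standard word list).
#' @param corpus the stimulus corpus words (default: `dictionary`).
#' @param frequency optional numeric frequencies aligned with `dictionary`
#'   for tie-breaking.
#' @param max_dist maximum edit distance for spell tolerance (default 2).
#' @return logical.
#' @export
score_response <- function(response, target, dictionary,
                           corpus = dictionary, frequency = NULL,
                           max_dist = 2L) {
  if (is.na(target) || !nzchar(target)) stop("empty target")
  target <- toupper(trimws(target))
  if (is.na(response)) response <- ""
  response <- toupper(trimws(response))
  if (!nzchar(response)) return(FALSE)
  if (response == target) return(TRUE)

  dict0 <- toupper(dictionary)
  freq_map <- if (!is.null(frequency)) stats::setNames(frequency, dict0) else NULL
  dictionary <- unique(c(dict0, target))
  corpus <- toupper(corpus)
  if (response %in% corpus && response != target) return(FALSE)

  dists <- as.integer(utils::adist(response, dictionary))
  dmin <- min(dists)
  if (dmin > max_dist) return(FALSE)
  cand <- dictionary[dists == dmin]
  if (length(cand) > 1L) {
    in_corpus <- cand %in% corpus
    if (any(in_corpus)) cand <- cand[in_corpus]
  }
  if (length(cand) > 1L && !is.null(freq_map)) {
    f <- freq_map[cand]
    f[is.na(f)] <- -Inf
    cand <- cand[f == max(f)]
  }
  cand <- sort(cand)[1L]
  identical(cand, target)
}

#' Score a cued-recall log and derive Day-1 outcomes
#'
#' Applies [score_response()] to every row of a recall log and attaches each
#' pair's Day-1 outcome (`correct` / `incorrect` for tested pairs scored at
#' initial learning, `restudied` for restudy pairs, whose Day-1 "responses"
#' only show the ability to re-type the visible target).
#'
#' @param records recall log: `participant`, `pair_id`, `day`, `phase`,
#'   `response`.
#' @param pairs pair table with `pair_id`, `target_id`, `condition`.
#' @param words word table with `word_id`, `text` (and optionally
#'   `frequency`).
#' @param dictionary extra dictionary words beyond the corpus.
#' @param max_dist see [score_response()].
#' @return `records` with logical `correct` and `day1_outcome` columns.
#' @export
score_recall <- function(records, pairs, words, dictionary = NULL,
                         max_dist = 2L) {
  stopifnot_cols(records, c("participant", "pair_id", "day", "response"), "records")
  stopifnot_cols(pairs, c("pair_id", "target_id", "condition"), "pairs")
  stopifnot_cols(words, c("word_id", "text"), "words")
  corpus <- toupper(words$text)
  dict <- unique(c(corpus, toupper(dictionary)))
  freq <- if ("frequency" %in% names(words)) words$frequency[match(dict, corpus)] else NULL

  tid <- pairs$target_id[match(records$pair_id, pairs$pair_id)]
  if (anyNA(tid)) stop("recall record for unknown pair_id")
  targets <- words$text[match(tid, words$word_id)]
  records$correct <- vapply(seq_len(nrow(records)), function(i) {
    score_response(records$response[i], targets[i], dict, corpus, freq, max_dist)
  }, logical(1))

  cond <- pairs$condition[match(records$pair_id, pairs$pair_id)]
  d1 <- records$day == 1
  key <- paste(records$participant, records$pair_id)
  d1_correct <- tapply(records$correct[d1], key[d1], any)
  records$day1_outcome <- ifelse(
    cond == "restudied", "restudied",
    ifelse(is.na(d1_correct[key]) | !d1_correct[key], "incorrect", "correct")
  )
  records
}

#' Per-participant recall accuracy by condition cell
#'
#' Cell means of recall accuracy per participant, either in the 2 x 2
#' relatedness-by-learning-condition design (`split = "condition"`) or with
#' tested pairs split by their Day-1 outcome into the three-level factor
#' tested-correct / tested-incorrect / restudied (`split = "day1"`). Day-1
#' accuracy excludes restudied rows, which only reflect re-typing the visible
#' target.
#'
#' @param records scored recall log (see [score_recall()]).
#' @param pairs pair table with `pair_id`, `relatedness`, `condition`.
#' @param day which day's responses to aggregate (default 2).
#' @param split `"condition"` or `"day1"`.
#' @return data frame `participant`, `relatedness`, cell factor, `n`,
#'   `accuracy`.
#' @export
accuracy_table <- function(records, pairs, day = 2, split = c("condition", "day1")) {
  split <- match.arg(split)
  if (!"correct" %in% names(records)) stop("records must be scored first")
  rec <- records[records$day == day, , drop = FALSE]
  idx <- match(rec$pair_id, pairs$pair_id)
  rec$relatedness <- pairs$relatedness[idx]
  rec$condition <- pairs$condition[idx]
  if (day == 1) rec <- rec[rec$condition != "restudied", , drop = FALSE]

  cellvar <- if (split == "condition") {
    rec$condition
  } else {
    ifelse(rec$condition == "restudied", "restudied",
           paste0("tested_", rec$day1_outcome))
  }
  agg <- stats::aggregate(
    rec$correct,
    by = list(participant = rec$participant, relatedness = rec$relatedness,
              cell = cellvar),
    FUN = function(z) c(n = length(z), acc = mean(z))
  )
  out <- data.frame(
    participant = agg$participant, relatedness = agg$relatedness,
    cell = agg$cell, n = agg$x[, "n"], accuracy = agg$x[, "acc"],
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "cell"] <- if (split == "condition") "condition" else "day1_cell"
  out
}

#' Per-participant testing effect
#'
#' The behavioral testing effect: the probability of recalling a tested pair
#' minus the probability of recalling a restudied pair, within the requested
#' relatedness scope. Participants with a missing cell get `NA`.
#'
#' @param acc output of [accuracy_table()] with `split = "condition"`.
#' @param scope `"all"`, `"related"` or `"unrelated"`.
#' @return data frame `participant`, `testing_effect`.
#' @export
testing_effect <- function(acc, scope = c("all", "related", "unrelated")) {
  scope <- match.arg(scope)
  if (scope != "all") acc <- acc[acc$relatedness == scope, , drop = FALSE]
  ps <- unique(acc$participant)
  te <- vapply(ps, function(p) {
    a <- acc[acc$participant == p, ]
    pt <- a[a$condition == "tested", ]
    pr <- a[a$condition == "restudied", ]
    if (!nrow(pt) || !nrow(pr)) return(NA_real_)
    sum(pt$n * pt$accuracy) / sum(pt$n) - sum(pr$n * pr$accuracy) / sum(pr$n)
  }, numeric(1))
  data.frame(participant = ps, testing_effect = te)
}
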