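#' Split cue and target words into the four arrangement lists
#'
#' The arrangement task requires that the two members of a to-be-learned pair
#' never appear on the same trial. This is achieved by splitting the cue list
#' and the target list in half: C1/T1 hold the cues/targets of one half of
#' the pairs, C2/T2 the other half. Trials are then built from list unions
#' that never combine a half's cue list with its own target list.
#'
#' @param pairs data frame with columns `pair_id`, `cue_id`, `target_id` and
#'   optionally `half` (1 or 2). Without `half`, the first half of the pairs
#'   in sorted `pair_id` order forms half 1 (deterministic).
#' @return data frame with columns `word_id` and `list`
#'   (one of `"C1"`, `"C2"`, `"T1"`, `"T2"`).
#' @export
build_lists <- function(pairs) {
  stopifnot_cols(pairs, c("pair_id", "cue_id", "target_id"), "pairs")
  if (nrow(pairs) < 2L || nrow(pairs) %% 2L != 0L) {
    stop("need an even number of pairs (>= 2) to split into halves")
  }
  if (anyDuplicated(pairs$pair_id)) stop("duplicated pair_id")
  if (any(pairs$cue_id == pairs$target_id)) stop("pair with cue_id == target_id")
  ids <- c(pairs$cue_id, pairs$target_id)
  if (anyDuplicated(ids)) stop("a word appears in more than one role/pair")

  pairs <- pairs[order(pairs$pair_id), , drop = FALSE]
  half <- if ("half" %in% names(pairs)) {
    if (!all(pairs$half %in% c(1L, 2L))) stop("`half` must be 1 or 2")
    if (sum(pairs$half == 1L) != nrow(pairs) / 2L) {
      stop("`half` must split the pairs evenly")
    }
    pairs$half
  } else {
    rep(c(1L, 2L), each = nrow(pairs) / 2L)
  }
  data.frame(
    word_id = c(pairs$cue_id, pairs$target_id),
    list = c(ifelse(half == 1L, "C1", "C2"), ifelse(half == 1L, "T1", "T2")),
    stringsAsFactors = FALSE
  )
}

#' Build the four arrangement trials from the list split
#'
#' Each list is paired with every other list except the one holding its own
#' pairs' partners, giving the trial rosters C1+C2, C1+T2, C2+T1, T1+T2.
#' Every word is arranged exactly twice and no trial contains both members of
#' a to-be-learned pair. Trial order and within-trial word order are
#' randomized by `seed`.
#'
#' @param list_map output of [build_lists()].
#' @param seed integer seed for the randomization.
#' @return object of class `trial_assignment`: a list with `trials` (list of
#'   4 word-id vectors) and `list_map`.
#' @export
build_trial_assignment <- function(list_map, seed = 1L) {
  stopifnot_cols(list_map, c("word_id", "list"), "list_map")
  lists <- split(list_map$word_id, list_map$list)
  need <- c("C1", "C2", "T1", "T2")
  if (!all(need %in% names(lists))) stop("list_map must contain lists C1, C2, T1, T2")
  rosters <- list(
    c(lists$C1, lists$C2), c(lists$C1, lists$T2),
    c(lists$C2, lists$T1), c(lists$T1, lists$T2)
  )
  trials <- with_seed(seed, {
    rosters <- rosters[sample.int(4L)]
    lapply(rosters, sample)
  })
  structure(list(trials = trials, list_map = list_map), class = "trial_assignment")
}

#' @export
print.trial_assignment <- function(x, ...) {
  cat(sprintf(
    "<trial_assignment> 4 trials of %s words (%d words total)\n",
    paste(lengths(x$trials), collapse = "/"), length(unique(x$list_map$word_id))
  ))
  invisible(x)
}

#' Count pair co-occurrence across arrangement trials
#'
#' Brute-force enumeration of all word pairs against the trial rosters:
#' how many are presented together on at least one trial (directly measured),
#' never (structurally missing, to be imputed), and on exactly two trials
#' (doubly measured). For the 120-word design the counts are 5340 / 1800 /
#' 1740.
#'
#' @param assignment a `trial_assignment`.
#' @return list with `n_pairs`, `measured`, `never`, `twice`.
#' @export
cooccurrence_counts <- function(assignment) {
  words <- sort(unique(assignment$list_map$word_id))
  n <- length(words)
  counts <- matrix(0L, n, n, dimnames = list(words, words))
  for (tr in assignment$trials) {
    idx <- match(tr, words)
    counts[idx, idx] <- counts[idx, idx] + 1L
  }
  diag(counts) <- 0L
  up <- upper_vals(counts)
  list(
    n_pairs = length(up),
    measured = sum(up >= 1L),
    never = sum(up == 0L),
    twice = sum(up == 2L)
  )
}

#' Randomly assign the matched sets to learning conditions
#'
#' One matched set of pairs is assigned to the tested (retrieval-practice)
#' condition and the other to restudy, uniformly at random per participant
#' seed.
#'
#' @param pairs data frame with a `set_label` column (values `"A"`/`"B"`).
#' @param seed participant-level seed.
#' @return `pairs` with a `condition` column (`"tested"`/`"restudied"`).
#' @export
assign_conditions <- function(pairs, seed) {
  stopifnot_cols(pairs, "set_label", "pairs")
  if (anyNA(pairs$set_label)) stop("missing set_label")
  labs <- sort(unique(pairs$set_label))
  if (length(labs) != 2L) stop("expected exactly two set labels")
  tested <- with_seed(seed, sample(labs, 1L))
  pairs$condition <- ifelse(pairs$set_label == tested, "tested", "restudied")
  pairs
}

#' Check that the two counterbalanced sets are matched on stimulus measures
#'
#' Welch two-sample t tests compare sets A and B on each pair-level measure
#' (LSA cosine, word2vec cosine, forward association strength where normed)
#' and, if a word table is supplied, on cue/target concreteness, frequency
#' and length. Measures whose test rejects at `alpha` are flagged.
#'
#' @param pairs data frame with `set_label` and measure columns among
#'   `lsa_cos`, `w2v_cos`, `fsa`.
#' @param words optional word table with `word_id`, `concreteness`,
#'   `frequency`, `length`.
#' @param alpha flagging level (default 0.05).
#' @return data frame: `measure`, `mean_A`, `mean_B`, `t`, `df`, `p`,
#'   `flagged`.
#' @export
validate_matched_sets <- function(pairs, words = NULL, alpha = 0.05) {
  stopifnot_cols(pairs, "set_label", "pairs")
  labs <- sort(unique(pairs$set_label))
  if (length(labs) != 2L) stop("expected exactly two set labels")
  if (any(table(pairs$set_label) == 0L)) stop("empty set")

  measures <- list()
  for (m in intersect(c("lsa_cos", "w2v_cos", "fsa"), names(pairs))) {
    measures[[m]] <- pairs[[m]]
  }
  if (!is.null(words)) {
    stopifnot_cols(words, c("word_id", "concreteness", "frequency", "length"), "words")
    for (role in c("cue", "target")) {
      idx <- match(pairs[[paste0(role, "_id")]], words$word_id)
      for (nm in c("concreteness", "frequency", "length")) {
        measures[[paste(role, nm, sep = "_")]] <- words[[nm]][idx]
      }
    }
  }
  is_a <- pairs$set_label == labs[1L]
  rows <- lapply(names(measures), function(m) {
    x <- measures[[m]][is_a]
    y <- measures[[m]][!is_a]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(measure = m, mean_A = mean(x), mean_B = mean(y),
                        t = NA_real_, df = NA_real_, p = NA_real_, flagged = FALSE))
    }
    if (stats::sd(c(x, y)) == 0) {
      return(data.frame(measure = m, mean_A = mean(x), mean_B = mean(y),
                        t = 0, df = length(x) + length(y) - 2, p = 1, flagged = FALSE))
    }
    tt <- stats::t.test(x, y)
    data.frame(measure = m, mean_A = mean(x), mean_B = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, flagged = tt$p.value < alpha)
  })
  do.call(rbind, rows)
}
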