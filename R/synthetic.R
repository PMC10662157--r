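#' Configuration of the synthetic study generator
#'
#' Collects the generative parameters of a simulated word-arrangement /
#' paired-associate study. Defaults emulate the design the package targets:
#' 120 words forming 60 cue-target pairs (30 semantically related, 30
#' unrelated) split into two matched sets, four 60-word arrangement trials
#' per session under the no-co-occurrence constraint, and recall governed by
#' a logistic model whose default coefficients reproduce recall marginals in
#' the empirically typical range (unrelated-restudied near 0.28, a
#' relatedness effect of about 0.35 and a testing effect near 0.08 on the
#' probability scale).
#'
#' @param n_participants number of simulated participants (default 20).
#' @param n_pairs number of word pairs (default 60; words = 2 * pairs).
#' @param latent_dim dimension of the latent semantic space (default 8).
#' @param related_cos range of cosine similarity for related pairs (default
#'   `c(0.75, 0.92)`).
#' @param margin minimum gap between the smallest related and largest
#'   unrelated pair cosine (default 0.2).
#' @param sigma placement noise, SD of the per-word pixel jitter applied to
#'   arranged positions (default 20).
#' @param canvas canvas size in pixels (default `c(1280, 800)`).
#' @param alpha pair attraction in `[0, 1]`: fraction of the cue-target
#'   separation removed for correctly recalled pairs (default 0.3).
#' @param gamma_related,gamma_unrelated asymmetry share in `[0, 1]`: the
#'   fraction of the attraction carried by the cue, per relatedness.
#'   Values above 0.5 move the cue more than the target and push the
#'   asymmetry statistic negative. Default 0.5 (symmetric).
#' @param rho lure repulsion (latent units) applied to moderate-bin lures of
#'   tested, recalled cues (default 0.1).
#' @param strong_pull small attraction (latent units) of very-strong-bin
#'   lures toward recalled cues (default 0.03).
#' @param beta0,beta_related,beta_tested,beta_interaction recall logistic
#'   coefficients (defaults -0.95, 1.5, 0.35, 0).
#' @param day2_penalty logit shift for Day-2 recall of tested pairs missed at
#'   Day 1 (default -2).
#' @param day2_boost logit shift for Day-2 recall of tested pairs correctly
#'   recalled at Day 1 — the retrieval-practice strengthening that makes the
#'   marginal testing effect positive despite the penalty (default 1.5,
#'   calibrated so the emulated marginals show a testing effect near +0.08).
#' @param typo_prob probability that a correct response carries one random
#'   character edit (default 0.08).
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20L, n_pairs = 60L, latent_dim = 8L,
                       related_cos = c(0.75, 0.92), margin = 0.2,
                       sigma = 20, canvas = c(1280, 800),
                       alpha = 0.3, gamma_related = 0.5, gamma_unrelated = 0.5,
                       rho = 0.1, strong_pull = 0.03,
                       beta0 = -0.95, beta_related = 1.5, beta_tested = 0.35,
                       beta_interaction = 0, day2_penalty = -2,
                       day2_boost = 1.5, typo_prob = 0.08, seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_pairs = as.integer(n_pairs),
    latent_dim = as.integer(latent_dim), related_cos = related_cos,
    margin = margin, sigma = sigma, canvas = canvas, alpha = alpha,
    gamma_related = gamma_related, gamma_unrelated = gamma_unrelated,
    rho = rho, strong_pull = strong_pull, beta0 = beta0,
    beta_related = beta_related, beta_tested = beta_tested,
    beta_interaction = beta_interaction, day2_penalty = day2_penalty,
    day2_boost = day2_boost, typo_prob = typo_prob, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_pairs >= 2L, cfg$n_pairs %% 2L == 0L, cfg$latent_dim >= 2L,
    cfg$alpha >= 0, cfg$alpha <= 1,
    cfg$gamma_related >= 0, cfg$gamma_related <= 1,
    cfg$gamma_unrelated >= 0, cfg$gamma_unrelated <= 1,
    cfg$rho >= 0, cfg$sigma >= 0
  )
  structure(cfg, class = "sim_config")
}

# Unique pronounceable-ish uppercase pseudo-words.
make_words <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    len <- sample(4:8, n, replace = TRUE)
    w <- vapply(len, function(l) {
      paste(sample(LETTERS, l, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

rand_unit <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# Unit vector at a given cosine to u.
at_cosine <- function(u, cos_target) {
  d <- length(u)
  r <- stats::rnorm(d)
  r <- r - sum(r * u) * u
  r <- r / sqrt(sum(r^2))
  cos_target * u + sqrt(1 - cos_target^2) * r
}

#' Generate the synthetic stimulus corpus
#'
#' Builds words, latent embedding vectors and the pair table. Related pairs
#' are tight two-word clusters: the target direction is placed at a sampled
#' cosine within `related_cos` of its cue. Unrelated targets are drawn
#' independently and re-drawn until their cosine to the cue sits below the
#' related minimum by at least `margin`, so every normative measure separates
#' the two relatedness levels strictly. Norms (concreteness, frequency) are
#' drawn independently; counterbalanced sets A/B alternate within
#' relatedness, giving matched sets by construction.
#'
#' @param config a [sim_config()].
#' @return list `words` (word table), `embeddings` (matrix, word-id
#'   rownames), `lsa` (cosine matrix standing in for the normative
#'   similarity source), `pairs` (pair table with `half`, `set_label`,
#'   normative measures).
#' @export
generate_corpus <- function(config) {
  with_seed(child_seed(config$seed, 1L), {
    np <- config$n_pairs
    nw <- 2L * np
    d <- config$latent_dim
    texts <- make_words(nw)
    relatedness <- rep(c("related", "unrelated"), each = np / 2L)

    emb <- matrix(NA_real_, nw, d)
    unrel_max <- config$related_cos[1] - config$margin
    for (p in seq_len(np)) {
      cue <- rand_unit(d)
      tgt <- if (relatedness[p] == "related") {
        at_cosine(cue, stats::runif(1, config$related_cos[1], config$related_cos[2]))
      } else {
        repeat {
          cand <- rand_unit(d)
          if (sum(cand * cue) < unrel_max) break
        }
        cand
      }
      emb[p, ] <- cue
      emb[np + p, ] <- tgt
    }
    word_id <- sprintf("w%03d", seq_len(nw))
    rownames(emb) <- word_id

    words <- data.frame(
      word_id = word_id, text = texts,
      role = rep(c("cue", "target"), each = np),
      pair_id = rep(seq_len(np), 2L),
      concreteness = stats::runif(nw, 3.5, 5),
      frequency = exp(stats::rnorm(nw, 3, 1)),
      length = nchar(texts),
      stringsAsFactors = FALSE
    )

    cs <- cosine_similarity(emb)
    half <- integer(np)
    set_label <- character(np)
    for (lv in unique(relatedness)) {
      idx <- which(relatedness == lv)
      half[idx] <- rep(c(1L, 2L), length.out = length(idx))
      set_label[idx] <- rep(c("A", "B", "B", "A"), length.out = length(idx))
    }
    pair_cos <- cs[cbind(seq_len(np), np + seq_len(np))]
    pairs <- data.frame(
      pair_id = seq_len(np),
      cue_id = word_id[seq_len(np)], target_id = word_id[np + seq_len(np)],
      relatedness = relatedness, half = half, set_label = set_label,
      lsa_cos = pair_cos, w2v_cos = pair_cos,
      fsa = ifelse(relatedness == "related", stats::runif(np, 0.05, 0.45),
                   ifelse(stats::runif(np) < 0.2, stats::runif(np, 0, 0.05), NA_real_)),
      stringsAsFactors = FALSE
    )
    words$half <- half[words$pair_id]
    list(words = words, embeddings = emb, lsa = cs, pairs = pairs)
  })
}

logistic <- function(x) 1 / (1 + exp(-x))

# One random character edit (substitute / insert / delete).
inject_typo <- function(word) {
  chars <- strsplit(word, "")[[1L]]
  op <- sample(c("sub", "ins", "del"), 1L)
  pos <- sample(length(chars), 1L)
  chars <- switch(op,
    sub = { chars[pos] <- sample(LETTERS, 1L); chars },
    ins = append(chars, sample(LETTERS, 1L), after = pos),
    del = if (length(chars) > 1L) chars[-pos] else chars
  )
  paste(chars, collapse = "")
}

#' Simulate cued-recall logs for one participant
#'
#' Day-1 (round 3) retrieval attempts for tested pairs and Day-2 final-test
#' attempts for all pairs are drawn from the logistic model
#' `P(correct) = logistic(b0 + b_rel * related + b_test * tested +
#' b_int * related * tested)`; the Day-2 logit is shifted by `day2_penalty`
#' for tested pairs missed at Day 1 and by `day2_boost` for tested pairs
#' recalled at Day 1 (retrieval-practice strengthening). Correct responses
#' are the target text, with probability `typo_prob` carrying one random
#' character edit; incorrect responses are blank or another corpus word.
#' Restudied pairs get Day-1 copy-typing rows (the visible target).
#'
#' @param config a [sim_config()].
#' @param pairs pair table with `condition` assigned.
#' @param words word table.
#' @param seed participant-level seed.
#' @param participant participant id recorded in the log.
#' @return data frame `participant`, `pair_id`, `day`, `phase`, `response`,
#'   plus hidden truth columns `true_day1`, `true_day2`.
#' @export
simulate_recall <- function(config, pairs, words, seed, participant = "p1") {
  with_seed(seed, {
    rel <- as.numeric(pairs$relatedness == "related")
    tst <- as.numeric(pairs$condition == "tested")
    eta <- config$beta0 + config$beta_related * rel + config$beta_tested * tst +
      config$beta_interaction * rel * tst
    p1 <- logistic(eta)
    day1 <- stats::runif(nrow(pairs)) < p1
    day1[pairs$condition == "restudied"] <- NA

    d1ok <- tst == 1 & !is.na(day1) & day1
    d1miss <- tst == 1 & !is.na(day1) & !day1
    eta2 <- eta + ifelse(d1miss, config$day2_penalty, 0) +
      ifelse(d1ok, config$day2_boost, 0)
    day2 <- stats::runif(nrow(pairs)) < logistic(eta2)

    targets <- words$text[match(pairs$target_id, words$word_id)]
    others <- words$text
    make_resp <- function(correct, target) {
      if (is.na(correct)) return(target)          # restudy copy-typing
      if (correct) {
        if (stats::runif(1) < config$typo_prob) inject_typo(target) else target
      } else {
        if (stats::runif(1) < 0.6) "" else sample(setdiff(others, target), 1L)
      }
    }
    resp1 <- vapply(seq_len(nrow(pairs)), function(i) make_resp(day1[i], targets[i]), character(1))
    resp2 <- vapply(seq_len(nrow(pairs)), function(i) make_resp(day2[i], targets[i]), character(1))

    rbind(
      data.frame(participant = participant, pair_id = pairs$pair_id, day = 1L,
                 phase = "round3", response = resp1,
                 true_day1 = day1, true_day2 = day2, stringsAsFactors = FALSE),
      data.frame(participant = participant, pair_id = pairs$pair_id, day = 2L,
                 phase = "final", response = resp2,
                 true_day1 = day1, true_day2 = day2, stringsAsFactors = FALSE)
    )
  })
}

#' Apply learning-induced distortion to the latent space
#'
#' Encodes the studied effects in latent coordinates, so that measurement
#' noise, the trial structure and imputation are exercised exactly as in a
#' real pipeline. For each correctly recalled pair the members are pulled
#' together: the cue moves `alpha * gamma` of the separation toward the
#' target and the target `alpha * (1 - gamma)` toward the cue (`gamma` per
#' the pair's relatedness). Moderate-bin lures of tested, recalled cues are
#' pushed directly away from the cue by `rho`; very-strong lures are pulled
#' toward it by `strong_pull`. All shifts are computed from the pre-learning
#' positions and summed. Forgotten pairs and untouched words do not move.
#'
#' @param latent_pre matrix of pre-learning latent positions (word-id
#'   rownames).
#' @param pairs pair table with `condition`, `relatedness` and
#'   `recalled_day2`.
#' @param lsa normative cosine matrix used to bin the lures.
#' @param config a [sim_config()].
#' @return matrix of post-learning latent positions.
#' @export
distort_space <- function(latent_pre, pairs, lsa, config) {
  post <- latent_pre
  shift <- matrix(0, nrow(latent_pre), ncol(latent_pre),
                  dimnames = dimnames(latent_pre))
  for (r in seq_len(nrow(pairs))) {
    if (!isTRUE(pairs$recalled_day2[r])) next
    cid <- as.character(pairs$cue_id[r])
    tid <- as.character(pairs$target_id[r])
    gamma <- if (pairs$relatedness[r] == "related") config$gamma_related else config$gamma_unrelated
    cue <- latent_pre[cid, ]
    tgt <- latent_pre[tid, ]
    shift[cid, ] <- shift[cid, ] + config$alpha * gamma * (tgt - cue)
    shift[tid, ] <- shift[tid, ] + config$alpha * (1 - gamma) * (cue - tgt)

    if (pairs$condition[r] == "tested" && (config$rho > 0 || config$strong_pull > 0)) {
      lures <- setdiff(rownames(latent_pre), c(cid, tid))
      bins <- lure_bin(lsa[cid, lures])
      for (b in c("moderate", "very strong")) {
        mag <- if (b == "moderate") config$rho else -config$strong_pull
        if (mag == 0) next
        for (lid in lures[bins == b]) {
          dvec <- latent_pre[lid, ] - cue
          nrm <- sqrt(sum(dvec^2))
          if (nrm < 1e-12) {
            warning("coincident cue/lure points; skipping repulsion")
            next
          }
          shift[lid, ] <- shift[lid, ] + mag * dvec / nrm
        }
      }
    }
  }
  post + shift
}

#' Simulate the arrangement trials of one session
#'
#' For each trial, the 60 on-trial words' latent distances are embedded in
#' 2D by classical multidimensional scaling (exact when the latent space is
#' 2D), scaled and centered into the canvas with a 5% margin, jittered with
#' per-word Gaussian pixel noise `sigma`, and clamped to the canvas.
#'
#' @param latent latent position matrix for the session.
#' @param assignment a `trial_assignment`.
#' @param config a [sim_config()].
#' @param seed session-level seed.
#' @return list of 4 layouts (`trial_index`, `positions`, `canvas`).
#' @export
simulate_arrangements <- function(latent, assignment, config, seed) {
  with_seed(seed, {
    lapply(seq_along(assignment$trials), function(t) {
      ids <- as.character(assignment$trials[[t]])
      sub <- latent[ids, , drop = FALSE]
      dm <- as.matrix(stats::dist(sub))
      xy <- suppressWarnings(stats::cmdscale(dm, k = 2L))
      if (ncol(xy) < 2L) xy <- cbind(xy, 0)
      if (ncol(sub) > 2L) {
        # latent space deeper than the canvas: polish the classical solution
        # by Sammon stress minimization
        xy <- suppressWarnings(
          MASS::sammon(stats::as.dist(dm), y = xy, trace = FALSE)$points
        )
      }
      # fit into the canvas with a 5% margin
      cv <- config$canvas
      xy <- sweep(xy, 2L, colMeans(xy))
      ext <- max(abs(xy))
      scale <- 0.45 * min(cv) / max(ext, 1e-9)
      xy <- xy * scale
      xy[, 1] <- xy[, 1] + cv[1] / 2
      xy[, 2] <- xy[, 2] + cv[2] / 2
      xy <- xy + matrix(stats::rnorm(length(xy), 0, config$sigma), nrow(xy))
      xy[, 1] <- pmin(pmax(xy[, 1], 0), cv[1])
      xy[, 2] <- pmin(pmax(xy[, 2], 0), cv[2])
      list(
        trial_index = t - 1L,
        positions = data.frame(word_id = ids, x = xy[, 1], y = xy[, 2],
                               stringsAsFactors = FALSE),
        canvas = cv
      )
    })
  })
}

#' Generate a complete synthetic study dataset
#'
#' One corpus is shared by all participants (as in a real stimulus set);
#' per participant, conditions are assigned at random, recall is simulated,
#' the latent space is distorted according to the recall outcomes, and both
#' sessions' four arrangement trials are simulated. Ground-truth outcomes
#' and latent positions are stored for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset`: `config`, `corpus`, `assignment`
#'   and `participants` (list with `id`, `pairs`, `recall`, `layouts_pre`,
#'   `layouts_post`, `truth`).
#' @export
generate_dataset <- function(config) {
  corpus <- generate_corpus(config)
  list_map <- build_lists(corpus$pairs)
  participants <- lapply(seq_len(config$n_participants), function(p) {
    sp <- child_seed(config$seed, 100L + p)
    id <- sprintf("p%03d", p)
    assignment <- build_trial_assignment(list_map, seed = child_seed(sp, 1L))
    pairs <- assign_conditions(corpus$pairs, seed = child_seed(sp, 2L))
    recall <- simulate_recall(config, pairs, corpus$words,
                              seed = child_seed(sp, 3L), participant = id)
    d2 <- recall[recall$day == 2L, ]
    pairs$recalled_day2 <- d2$true_day2[match(pairs$pair_id, d2$pair_id)]
    d1 <- recall[recall$day == 1L, ]
    t1 <- d1$true_day1[match(pairs$pair_id, d1$pair_id)]
    pairs$day1_outcome <- ifelse(pairs$condition == "restudied", "restudied",
                                 ifelse(t1, "correct", "incorrect"))

    latent_pre <- corpus$embeddings
    latent_post <- distort_space(latent_pre, pairs, corpus$lsa, config)
    layouts_pre <- simulate_arrangements(latent_pre, assignment, config,
                                         seed = child_seed(sp, 4L))
    layouts_post <- simulate_arrangements(latent_post, assignment, config,
                                          seed = child_seed(sp, 5L))
    list(id = id, pairs = pairs, assignment = assignment, recall = recall,
         layouts_pre = layouts_pre, layouts_post = layouts_post,
         truth = list(latent_pre = latent_pre, latent_post = latent_post,
                      day1 = t1, day2 = pairs$recalled_day2))
  })
  structure(list(config = config, corpus = corpus, participants = participants),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d participants, %d words, seed %d\n",
              length(x$participants), nrow(x$corpus$words), x$config$seed))
  invisible(x)
}
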