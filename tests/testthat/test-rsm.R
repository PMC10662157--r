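simple_layout <- function(xy, ids = NULL, canvas = c(100, 100), trial = 0L) {
  if (is.null(ids)) ids <- paste0("w", seq_len(nrow(xy)))
  list(trial_index = trial,
       positions = data.frame(word_id = ids, x = xy[, 1], y = xy[, 2]),
       canvas = canvas)
}

test_that("trial distances are pixel Euclidean with squared-distance weights", {
  lay <- simple_layout(rbind(c(0, 0), c(3, 4)))
  pr <- trial_distance_matrix(lay)
  expect_equal(pr$d["w1", "w2"], 5)
  expect_equal(pr$w["w1", "w2"], 25)

  lay3 <- simple_layout(rbind(c(0, 0), c(1, 0), c(0, 1)))
  pr3 <- trial_distance_matrix(lay3)
  expect_equal(pr3$d["w1", "w2"], 1)
  expect_equal(pr3$d["w1", "w3"], 1)
  expect_equal(pr3$d["w2", "w3"], sqrt(2))

  # identical positions: observed but carrying zero evidence
  lay0 <- simple_layout(rbind(c(5, 5), c(5, 5)))
  pr0 <- trial_distance_matrix(lay0)
  expect_equal(pr0$d["w1", "w2"], 0)
  expect_equal(pr0$w["w1", "w2"], 0)
})

test_that("trial layout validation catches duplicates and stray coordinates", {
  bad <- simple_layout(rbind(c(0, 0), c(1, 1)), ids = c("a", "a"))
  expect_error(trial_distance_matrix(bad), "duplicate")
  out <- simple_layout(rbind(c(0, 0), c(500, 1)), canvas = c(100, 100))
  expect_warning(trial_distance_matrix(out), "canvas")
  # words absent from the trial stay missing in the full-index matrix
  pr <- trial_distance_matrix(simple_layout(rbind(c(0, 0), c(3, 4))),
                              word_ids = c("w1", "w2", "w3"))
  expect_true(is.na(pr$d["w1", "w3"]))
  expect_equal(pr$w["w1", "w3"], 0)
})

test_that("single-trial combination is the trial scaled to unit Frobenius norm", {
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  comb <- combine_trials(list(make_partial(d)))
  expect_equal(upper_vals(comb$delta), c(1, 2, 2) / 3, tolerance = 1e-10)
  expect_equal(comb$delta, t(comb$delta))
  expect_equal(diag(comb$delta), setNames(rep(0, 3), letters[1:3]))
})

test_that("two proportional trials combine to the common shape", {
  d1 <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  d2 <- 2 * d1
  comb <- combine_trials(list(make_partial(d1), make_partial(d2, 1L)))
  expect_equal(upper_vals(comb$delta), c(1, 2, 2) / 3, tolerance = 1e-8)
  # identical trials: same answer as the single-trial case
  comb_same <- combine_trials(list(make_partial(d1), make_partial(d1, 1L)))
  expect_equal(comb_same$delta, comb$delta, tolerance = 1e-8)
})

test_that("combination is invariant to global coordinate rescaling", {
  cfg <- sim_config(n_participants = 1, seed = 21)
  ds <- generate_dataset(cfg)
  lays <- ds$participants[[1]]$layouts_pre
  ids <- ds$corpus$words$word_id
  scale_layout <- function(l, f) {
    l$positions$x <- l$positions$x * f
    l$positions$y <- l$positions$y * f
    l$canvas <- l$canvas * f
    l
  }
  c1 <- combine_trials(lapply(lays, trial_distance_matrix, word_ids = ids))
  c2 <- combine_trials(lapply(lapply(lays, scale_layout, f = 3.7),
                              trial_distance_matrix, word_ids = ids))
  expect_lt(max(abs(c1$delta - c2$delta), na.rm = TRUE), 1e-10)
})

test_that("noise-free 2D layouts recover the latent geometry", {
  cfg <- sim_config(n_participants = 1, latent_dim = 2, sigma = 0, seed = 5)
  ds <- generate_dataset(cfg)
  pp <- ds$participants[[1]]
  ids <- ds$corpus$words$word_id
  comb <- combine_trials(lapply(pp$layouts_pre, trial_distance_matrix,
                                word_ids = ids))
  truth <- as.matrix(dist(pp$truth$latent_pre))[ids, ids]
  obs <- !is.na(comb$delta) & upper.tri(comb$delta)
  expect_gte(cor(comb$delta[obs], truth[obs]), 0.999)
})

test_that("disconnected trials are rejected", {
  d1 <- matrix(NA_real_, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d2 <- d1
  d1["a", "b"] <- d1["b", "a"] <- 1
  d2["c", "d"] <- d2["d", "c"] <- 2
  expect_error(combine_trials(list(make_partial(d1), make_partial(d2, 1L))),
               "disconnected")
})

test_that("similarity conversion is 1 - dissimilarity with range checks", {
  d <- matrix(c(0, 0.011, 0.011, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  rsm <- structure(list(delta = d, imputed_mask = matrix(FALSE, 2, 2),
                        session = "pre", words = c("a", "b")),
                   class = "combined_rsm")
  out <- to_similarity(rsm)
  expect_equal(out$s["a", "b"], 0.989)
  expect_equal(diag(out$s), setNames(c(1, 1), c("a", "b")))
  rsm$delta["a", "b"] <- 1.5
  expect_error(to_similarity(rsm), "normalization")
  rsm$delta["a", "b"] <- NA
  expect_error(to_similarity(rsm), "missing")
})

test_that("the 120-word pipeline lands on the published similarity scale", {
  # near-uniform dissimilarities on a unit-Frobenius-norm triangle average
  # about 1/sqrt(7140), so mean similarity should be close to 0.988-0.989
  cfg <- sim_config(n_participants = 1, seed = 33)
  ds <- generate_dataset(cfg)
  pp <- ds$participants[[1]]
  rsm <- build_rsm(pp$layouts_pre, ds$corpus$words$word_id, session = "pre")
  m <- mean(upper_vals(rsm$s))
  expect_gt(m, 0.983)
  expect_lt(m, 0.995)
})

test_that("pair similarity table flags learned pairs as imputed by design", {
  cfg <- sim_config(n_participants = 1, seed = 13)
  ds <- generate_dataset(cfg)
  pp <- ds$participants[[1]]
  ids <- ds$corpus$words$word_id
  pre <- build_rsm(pp$layouts_pre, ids, session = "pre")
  tab <- pair_similarity_table(pre, pre, pp$pairs)
  expect_equal(nrow(tab), 60L)
  expect_true(all(tab$imputed))
  expect_equal(tab$s_pre, tab$s_post)
  bad <- pp$pairs
  bad$cue_id[1] <- "nope"
  expect_error(pair_similarity_table(pre, pre, bad), "missing from the RSM")
})
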