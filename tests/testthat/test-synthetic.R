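test_that("corpus generation separates relatedness levels with the set margin", {
  for (s in c(1, 9, 23)) {
    cfg <- sim_config(seed = s)
    corp <- generate_corpus(cfg)
    rel <- corp$pairs$lsa_cos[corp$pairs$relatedness == "related"]
    unr <- corp$pairs$lsa_cos[corp$pairs$relatedness == "unrelated"]
    expect_gte(min(rel) - max(unr), cfg$margin)
  }
  cfg <- sim_config(seed = 4)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  # structure: 120 unique words, 30/30 relatedness, matched 15/15 sets
  expect_equal(nrow(c1$words), 120L)
  expect_false(anyDuplicated(c1$words$text) > 0)
  expect_equal(unname(table(c1$pairs$relatedness)), c(30L, 30L), ignore_attr = TRUE)
  expect_equal(unname(table(c1$pairs$set_label, c1$pairs$relatedness)),
               matrix(15L, 2, 2), ignore_attr = TRUE)
  expect_true(all(c1$pairs$fsa[c1$pairs$relatedness == "related"] < 0.5,
                  na.rm = TRUE))
})

test_that("recall simulation follows its logistic model", {
  cfg0 <- sim_config(beta0 = 6, seed = 2)
  corp <- generate_corpus(cfg0)
  pairs <- assign_conditions(corp$pairs, seed = 1)
  rec <- simulate_recall(cfg0, pairs, corp$words, seed = 10)
  expect_gt(mean(rec$true_day2), 0.99)

  # relatedness effect matches the closed-form probability gap
  cfgr <- sim_config(beta0 = 0, beta_related = 1.5, beta_tested = 0,
                     day2_penalty = 0, day2_boost = 0, seed = 2)
  d2 <- do.call(rbind, lapply(1:200, function(p) {
    r <- simulate_recall(cfgr, pairs, corp$words, seed = 5000 + p)
    r[r$day == 2, ]
  }))
  rel <- pairs$relatedness[match(d2$pair_id, pairs$pair_id)] == "related"
  gap <- mean(d2$true_day2[rel]) - mean(d2$true_day2[!rel])
  expect_equal(gap, plogis(1.5) - plogis(0), tolerance = 0.02)
})

test_that("latent distortion endpoints and symmetry are exact", {
  cfg <- sim_config(seed = 3)
  corp <- generate_corpus(cfg)
  pairs <- assign_conditions(corp$pairs, seed = 2)
  pairs$recalled_day2 <- TRUE
  id <- function(a) corp$embeddings[a, ]

  cfg0 <- sim_config(alpha = 0, rho = 0, strong_pull = 0, seed = 3)
  expect_identical(distort_space(corp$embeddings, pairs, corp$lsa, cfg0),
                   corp$embeddings)

  cfg1 <- sim_config(alpha = 1, gamma_related = 1, gamma_unrelated = 1,
                     rho = 0, strong_pull = 0, seed = 3)
  post <- distort_space(corp$embeddings, pairs, corp$lsa, cfg1)
  p1 <- pairs[pairs$relatedness == "related", ][1, ]
  expect_equal(post[p1$cue_id, ], id(p1$target_id))
  expect_equal(post[p1$target_id, ], id(p1$target_id))

  cfg5 <- sim_config(alpha = 0.4, gamma_related = 0.5, gamma_unrelated = 0.5,
                     rho = 0, strong_pull = 0, seed = 3)
  post5 <- distort_space(corp$embeddings, pairs, corp$lsa, cfg5)
  mv <- function(a) sqrt(sum((post5[a, ] - id(a))^2))
  expect_equal(mv(p1$cue_id), mv(p1$target_id), tolerance = 1e-12)
})

test_that("arrangements embed latent geometry into the canvas", {
  cfg <- sim_config(n_participants = 1, latent_dim = 2, sigma = 0, seed = 6)
  corp <- generate_corpus(cfg)
  ta <- build_trial_assignment(build_lists(corp$pairs), seed = 2)
  lays <- simulate_arrangements(corp$embeddings, ta, cfg, seed = 4)
  expect_length(lays, 4L)
  for (l in lays) {
    expect_true(all(l$positions$x >= 0 & l$positions$x <= cfg$canvas[1]))
    expect_true(all(l$positions$y >= 0 & l$positions$y <= cfg$canvas[2]))
    ids <- l$positions$word_id
    pix <- as.matrix(dist(l$positions[, c("x", "y")]))
    lat <- as.matrix(dist(corp$embeddings[ids, ]))
    expect_gte(cor(pix[upper.tri(pix)], lat[upper.tri(lat)]), 0.999)
  }

  # mild extra dimensionality (weak third axis): monotone agreement survives
  # the 2D projection
  cfg3 <- sim_config(latent_dim = 3, sigma = 0, seed = 6)
  lat3 <- withr::with_seed(7, cbind(rnorm(120), rnorm(120), 0.35 * rnorm(120)))
  rownames(lat3) <- corp$words$word_id
  lays3 <- simulate_arrangements(lat3, ta, cfg3, seed = 4)
  ids <- lays3[[1]]$positions$word_id
  pix <- as.matrix(dist(lays3[[1]]$positions[, c("x", "y")]))
  lat <- as.matrix(dist(lat3[ids, ]))
  expect_gte(cor(pix[upper.tri(pix)], lat[upper.tri(lat)], method = "spearman"),
             0.9)
})

test_that("full datasets have the right shape and are seed-reproducible", {
  cfg <- sim_config(n_participants = 3, seed = 12)
  ds <- generate_dataset(cfg)
  expect_length(ds$participants, 3L)
  for (pp in ds$participants) {
    expect_length(pp$layouts_pre, 4L)
    expect_length(pp$layouts_post, 4L)
    expect_equal(nrow(pp$recall), 120L)  # 60 pairs x 2 days
    expect_setequal(unique(pp$pairs$condition), c("tested", "restudied"))
  }
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$participants[[2]]$recall, ds2$participants[[2]]$recall)
  expect_identical(ds$participants[[3]]$layouts_post[[2]]$positions,
                   ds2$participants[[3]]$layouts_post[[2]]$positions)
})

test_that("attraction strength moves recalled-pair similarity monotonically", {
  grid <- c(0, 0.1, 0.2, 0.4)
  means <- vapply(grid, function(a) {
    cfg <- sim_config(n_participants = 4, alpha = a, rho = 0,
                      strong_pull = 0, seed = 71)
    ds <- generate_dataset(cfg)
    mean(vapply(ds$participants, function(pp) {
      pre <- build_rsm(pp$layouts_pre, ds$corpus$words$word_id, session = "pre")
      post <- build_rsm(pp$layouts_post, ds$corpus$words$word_id, session = "post")
      ch <- pair_change(pre, post, pp$pairs, n_random = 10, seed = 3)
      mean(ch$delta[ch$class == "learned-recalled"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the asymmetry share controls the sign of the asymmetry statistic", {
  run_gamma <- function(g) {
    cfg <- sim_config(n_participants = 6, alpha = 0.35, gamma_related = g,
                      gamma_unrelated = g, rho = 0, strong_pull = 0, seed = 55)
    ds <- generate_dataset(cfg)
    mean(vapply(ds$participants, function(pp) {
      pre <- build_rsm(pp$layouts_pre, ds$corpus$words$word_id, session = "pre")
      post <- build_rsm(pp$layouts_post, ds$corpus$words$word_id, session = "post")
      asym <- pair_asymmetry(pre, post, pp$pairs[pp$pairs$recalled_day2, ],
                             ds$corpus$lsa)
      mean(asym$A, na.rm = TRUE)
    }, numeric(1)))
  }
  a_high <- run_gamma(0.8)
  a_low <- run_gamma(0.2)
  a_mid <- run_gamma(0.5)
  expect_lt(a_high, 0)
  expect_gt(a_low, 0)
  expect_lt(abs(a_mid), abs(a_high))
})
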