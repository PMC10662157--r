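# a small complete similarity structure for direct metric tests
toy_rsms <- function(n = 10, seed = 4, post_shift = NULL) {
  withr::with_seed(seed, {
    words <- sprintf("w%02d", 1:n)
    xy <- matrix(rnorm(2 * n), n, dimnames = list(words, NULL))
    mk <- function(pts) {
      d <- as.matrix(dist(pts))
      d <- d / sqrt(sum(d[upper.tri(d)]^2))
      structure(list(delta = d, s = 1 - d,
                     imputed_mask = matrix(FALSE, n, n, dimnames = dimnames(d)),
                     session = "pre", words = words),
                class = "combined_rsm")
    }
    post <- if (is.null(post_shift)) xy else xy + post_shift
    list(pre = mk(xy), post = mk(post), xy = xy)
  })
}

test_that("pair change is plain cell arithmetic with recall classes", {
  rs <- toy_rsms()
  pairs <- data.frame(pair_id = 1:2, cue_id = c("w01", "w03"),
                      target_id = c("w02", "w04"),
                      recalled_day2 = c(TRUE, FALSE))
  ch <- pair_change(rs$pre, rs$pre, pairs, n_random = 5, seed = 2)
  expect_true(all(ch$delta == 0))
  expect_setequal(unique(ch$class),
                  c("learned-recalled", "learned-forgotten", "random-control"))
  expect_equal(sum(ch$class == "random-control"), 5L)
  # controls never coincide with learned pairs
  learned_keys <- c("w01 w02", "w02 w01", "w03 w04", "w04 w03")
  rc <- ch[ch$class == "random-control", ]
  expect_false(any(paste(rc$word_i, rc$word_j) %in% learned_keys))

  post <- rs$pre
  post$s["w01", "w02"] <- post$s["w01", "w02"] + 0.003
  post$s["w02", "w01"] <- post$s["w01", "w02"]
  ch2 <- pair_change(rs$pre, post, pairs, n_random = 3, seed = 2)
  expect_equal(ch2$delta[ch2$pair_id == 1][1], 0.003)
})

test_that("nearest neighbors follow cosine order with exclusions before truncation", {
  e <- rbind(A = c(1, 0), B = c(0.9, 0.1), C = c(0, 1))
  expect_equal(nearest_neighbors(e, "A", k = 1), "B")
  expect_equal(nearest_neighbors(e, "A", k = 1, exclusions = "B"), "C")
  expect_error(nearest_neighbors(e, "A", k = 3), "exceeds")

  emb <- withr::with_seed(8, matrix(rnorm(120 * 50), 120))
  rownames(emb) <- sprintf("w%03d", 1:120)
  cs <- cosine_similarity(emb)
  for (w in rownames(emb)[c(1, 57, 120)]) {
    nn <- nearest_neighbors(emb, w, k = 20)
    brute <- names(sort(cs[w, setdiff(rownames(emb), w)], decreasing = TRUE))[1:20]
    expect_identical(nn, brute)
    expect_false(w %in% nn)
  }
})

test_that("word change is the Fisher-z pre/post correlation with clipping", {
  v <- withr::with_seed(3, rnorm(20))
  names(v) <- sprintf("n%02d", 1:20)
  expect_equal(word_change(v, v), fisher_z(1))
  expect_equal(word_change(v, -v + 2 * mean(v)), fisher_z(-1))
  ortho <- withr::with_seed(4, {
    u <- rnorm(20)
    resid <- residuals(lm(u ~ v))
    setNames(resid, names(v))
  })
  expect_equal(word_change(v, ortho), 0, tolerance = 1e-10)
  expect_warning(z <- word_change(v, setNames(rep(1, 20), names(v))), "constant")
  expect_true(is.na(z))
  expect_error(word_change(v[1:2], v[1:2]), ">= 3")
  expect_error(word_change(v, setNames(v, rev(names(v)))), "same neighbor")
})

test_that("asymmetry is zero without change, negates under role swap, and
           goes positive when the target assimilates to the cue", {
  set.seed(9)
  cue <- rnorm(25); tgt <- rnorm(25)
  a0 <- asymmetry(cue, cue, tgt, tgt)
  expect_equal(a0$A, 0)
  cue2 <- cue + rnorm(25, 0, 0.3); tgt2 <- tgt + rnorm(25, 0, 0.3)
  a <- asymmetry(cue, cue2, tgt, tgt2)
  aswap <- asymmetry(tgt, tgt2, cue, cue2)
  expect_equal(a$A + aswap$A, 0, tolerance = 1e-12)
  # target fully assimilated to the cue's old position, cue unchanged
  ap <- asymmetry(cue, cue, tgt, cue)
  expect_gt(ap$A, 0)
  expect_error(asymmetry(cue[1:2], cue[1:2], tgt[1:2], tgt[1:2]), ">= 3")
  expect_error(asymmetry(cue, cue, rep(1, 25), tgt), "constant")
})

test_that("lure bins partition the cosine range with half-open edges", {
  x <- c(-0.5, 0.19, 0.2, 0.35, 0.39, 0.4, 0.59, 0.6, 0.95)
  b <- lure_bin(x)
  expect_equal(as.character(b),
               c("weak/non", "weak/non", "moderate", "moderate", "moderate",
                 "strong", "strong", "very strong", "very strong"))
  expect_false(anyNA(lure_bin(seq(-1, 1, by = 0.01))))
})

test_that("each retained cue contributes exactly 118 lure records", {
  cfg <- sim_config(n_participants = 1, seed = 17)
  ds <- generate_dataset(cfg)
  pp <- ds$participants[[1]]
  ids <- ds$corpus$words$word_id
  pre <- build_rsm(pp$layouts_pre, ids, session = "pre")
  post <- build_rsm(pp$layouts_post, ids, session = "post")
  lt <- lure_table(pp$pairs, ds$corpus$lsa, pre, post)
  keep <- pp$pairs$recalled_day2 &
    !(pp$pairs$condition == "tested" & pp$pairs$day1_outcome == "incorrect")
  expect_equal(nrow(lt), 118L * sum(keep))
  expect_true(all(table(lt$cue_id) == 118L))
  # neither the cue itself nor the paired target ever appears as a lure
  for (r in which(keep)) {
    lures <- lt$lure_id[lt$cue_id == pp$pairs$cue_id[r]]
    expect_false(pp$pairs$cue_id[r] %in% lures)
    expect_false(pp$pairs$target_id[r] %in% lures)
  }
  expect_equal(lt$delta, lt$s_post - lt$s_pre)
})

test_that("normative alignment change responds to movement toward the norms", {
  rs <- toy_rsms(n = 12, seed = 6)
  lsa <- 1 - as.matrix(dist(rs$xy)) / max(dist(rs$xy))  # norms match geometry
  dimnames(lsa) <- list(rs$pre$words, rs$pre$words)
  # both sessions proportional to the norms: no change
  nc <- normative_alignment_change("w01", rs$pre, rs$pre, lsa)
  expect_equal(nc$delta_z, 0)
  # post vector replaced by the normative vector itself: forced increase
  post <- rs$pre
  noisy_pre <- rs$pre
  noisy_cols <- setdiff(rs$pre$words, "w01")
  noisy_pre$s["w01", noisy_cols] <- withr::with_seed(2, {
    rs$pre$s["w01", noisy_cols] + rnorm(11, 0, 0.3)
  })
  post$s["w01", noisy_cols] <- lsa["w01", noisy_cols]
  nc2 <- normative_alignment_change("w01", noisy_pre, post, lsa)
  expect_gt(nc2$delta_z, 0)
})
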