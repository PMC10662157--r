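# Independent oracles and small fixtures, written naively on purpose:
# they validate the optimized implementations by brute force.

# Brute-force sklearn-style KNN imputation on a symmetric matrix with NAs.
# Plain double loops, no shared code with knn_impute().
oracle_knn_impute <- function(x, k) {
  n <- nrow(x)
  feat <- x
  diag(feat) <- NA
  # nan-aware euclidean row distances
  dmat <- matrix(Inf, n, n)
  for (a in 1:n) {
    for (b in 1:n) {
      shared <- which(!is.na(feat[a, ]) & !is.na(feat[b, ]))
      if (length(shared) > 0) {
        ss <- sum((feat[a, shared] - feat[b, shared])^2)
        dmat[a, b] <- sqrt(ncol(feat) / length(shared) * ss)
      }
    }
  }
  filled <- x
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j || !is.na(x[i, j])) next
      cand <- data.frame(row = integer(0), d = numeric(0))
      for (h in 1:n) {
        if (h != i && !is.na(x[h, j]) && is.finite(dmat[i, h])) {
          cand <- rbind(cand, data.frame(row = h, d = dmat[i, h]))
        }
      }
      cand <- cand[order(cand$d, cand$row), ]
      cand <- cand[seq_len(min(k, nrow(cand))), ]
      if (!nrow(cand)) next
      if (any(cand$d == 0)) {
        filled[i, j] <- mean(x[cand$row[cand$d == 0], j])
      } else {
        w <- 1 / cand$d
        filled[i, j] <- sum(w * x[cand$row, j]) / sum(w)
      }
    }
  }
  out <- (filled + t(filled)) / 2
  diag(out) <- 0
  out
}

# Step-down Holm adjustment by direct enumeration.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# Sums-of-squares decomposition for a fully within-subject 2x2 design,
# straight from the definitions.
oracle_rm_anova_2x2 <- function(df) {
  # df: participant, a, b (factors), y; one row per cell
  gm <- mean(df$y)
  subj <- unique(df$participant)
  al <- unique(df$a); bl <- unique(df$b)
  n <- length(subj)
  cellmean <- function(aa, bb) mean(df$y[df$a == aa & df$b == bb])
  amean <- function(aa) mean(df$y[df$a == aa])
  bmean <- function(bb) mean(df$y[df$b == bb])
  smean <- function(s) mean(df$y[df$participant == s])
  samean <- function(s, aa) mean(df$y[df$participant == s & df$a == aa])
  sbmean <- function(s, bb) mean(df$y[df$participant == s & df$b == bb])

  ss_a <- length(bl) * n * sum((vapply(al, amean, 1) - gm)^2)
  ss_b <- length(al) * n * sum((vapply(bl, bmean, 1) - gm)^2)
  ss_s <- length(al) * length(bl) * sum((vapply(subj, smean, 1) - gm)^2)
  ss_ab <- n * sum(vapply(al, function(aa) sum(vapply(bl, function(bb) {
    (cellmean(aa, bb) - amean(aa) - bmean(bb) + gm)^2
  }, 1)), 1))
  ss_as <- length(bl) * sum(vapply(subj, function(s) sum(vapply(al, function(aa) {
    (samean(s, aa) - smean(s) - amean(aa) + gm)^2
  }, 1)), 1))
  ss_bs <- length(al) * sum(vapply(subj, function(s) sum(vapply(bl, function(bb) {
    (sbmean(s, bb) - smean(s) - bmean(bb) + gm)^2
  }, 1)), 1))
  ss_tot <- sum((df$y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  df_a <- length(al) - 1; df_b <- length(bl) - 1; df_ab <- df_a * df_b
  df_as <- df_a * (n - 1); df_bs <- df_b * (n - 1); df_abs <- df_ab * (n - 1)
  err <- ss_as + ss_bs + ss_abs
  list(
    F_a = (ss_a / df_a) / (ss_as / df_as),
    F_b = (ss_b / df_b) / (ss_bs / df_bs),
    F_ab = (ss_ab / df_ab) / (ss_abs / df_abs),
    eta_a = ss_a / (ss_a + ss_s + err),
    eta_b = ss_b / (ss_b + ss_s + err),
    eta_ab = ss_ab / (ss_ab + ss_s + err),
    ss_total = ss_tot,
    ss_sum = ss_a + ss_b + ss_ab + ss_s + ss_as + ss_bs + ss_abs
  )
}

# Construct a partial_rdm directly from a distance matrix (NA = unobserved).
make_partial <- function(d, trial_index = 0L) {
  w <- d^2
  w[is.na(w)] <- 0
  structure(list(d = d, w = w, trial_index = trial_index), class = "partial_rdm")
}

# A minimal valid pair table.
tiny_pairs <- function(n = 2L) {
  data.frame(
    pair_id = seq_len(n),
    cue_id = sprintf("c%d", seq_len(n)),
    target_id = sprintf("t%d", seq_len(n)),
    relatedness = rep(c("related", "unrelated"), length.out = n),
    stringsAsFactors = FALSE
  )
}

# Dissimilarity matrix from 2D latent points, with the structural missing
# pattern of a trial assignment applied.
latent_delta <- function(xy) {
  d <- as.matrix(dist(xy))
  d / sqrt(sum(d[upper.tri(d)]^2))
}

# all permutations of 1..m, tiny recursive enumeration
combinat_perms <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(m - 1)) {
    for (pos in 0:(m - 1)) {
      out[[length(out) + 1L]] <- append(sub, m, after = pos)
    }
  }
  out
}
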