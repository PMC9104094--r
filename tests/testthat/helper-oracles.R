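# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

# direct per-cell kernel summation (same truncated-Gaussian kernel definition)
oracle_kde <- function(scores, grid, hx, hy) {
  out <- matrix(0, grid$R, grid$R)
  for (r in seq_len(grid$R)) for (s in seq_len(grid$R)) {
    acc <- 0
    for (i in seq_len(nrow(scores))) {
      ux <- (grid$x[r] - scores[i, 1]) / hx
      uy <- (grid$y[s] - scores[i, 2]) / hy
      if (abs(ux) <= 3 && abs(uy) <= 3)
        acc <- acc + exp(-ux^2 / 2) * exp(-uy^2 / 2)
    }
    out[r, s] <- acc / (nrow(scores) * hx * hy * 2 * pi)
  }
  out
}

oracle_schoener_d <- function(z1, z2) {
  p1 <- z1 / sum(z1)
  p2 <- z2 / sum(z2)
  total <- 0
  for (i in seq_along(p1)) total <- total + abs(p1[i] - p2[i])
  1 - total / 2
}

# pairwise Mann-Whitney counting, ties worth one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (a in neg)
    wins <- wins + if (p > a) 1 else if (p == a) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# scan all score midpoints for the best sensitivity + specificity
oracle_max_sss <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; best_t <- NA_real_
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec > best) { best <- sens + spec; best_t <- t }
  }
  list(threshold = best_t, sss = best)
}

sss_at <- function(scores, labels, t) {
  mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t)
}
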