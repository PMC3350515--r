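# Straight-line scalar reference implementations, kept deliberately naive
# and independent of the package internals, for cross-checking the
# vectorized engine on small fixtures.

oracle_independent <- function(x, g, gamma = 0.5, weight = 1) {
  ok <- !is.na(x)
  xv <- x[ok]
  gv <- droplevels(as.factor(g[ok]))
  N <- length(xv)
  r <- rank(xv)
  u <- (r - 0.5) / N
  u1 <- u[gv == levels(gv)[1]]
  u2 <- u[gv == levels(gv)[2]]
  n1 <- length(u1)
  n2 <- length(u2)
  B <- mean(u1) - mean(u2)
  popvar <- function(z) mean((z - mean(z))^2)
  S <- sqrt(((n1 - 1) * popvar(u1) + (n2 - 1) * popvar(u2)) / (N - 2))
  q <- sort(u)[ceiling(gamma * N)]
  p1 <- mean(u1 > q)
  p2 <- mean(u2 > q)
  pbar <- (n1 * p1 + n2 * p2) / N
  O <- if (pbar <= 0 || pbar >= 1) {
    0
  } else {
    (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  }
  list(B = B, S = S, O = O, pbar = pbar, p1 = p1, p2 = p2,
       mor = if (S > 0) weight * B * abs(O) / S else 0)
}

oracle_dependent <- function(x1, x2, weight = 1) {
  n <- length(x1)
  r <- rank(c(x1, x2))
  u <- (r - 0.5) / (2 * n)
  u1 <- u[1:n]
  u2 <- u[(n + 1):(2 * n)]
  d <- u1 - u2
  B <- mean(d)
  S <- sqrt(mean((d - mean(d))^2))
  pos <- sum(d > 0)
  neg <- sum(d < 0)
  np <- pos + neg
  O <- if (np == 0) 0 else (pos / np - neg / np) / sqrt(0.5 / np)
  list(B = B, S = S, O = O, mor = if (S > 0) weight * B * abs(O) / S else 0)
}

# all group-1 index sets of size n1 out of n1 + n2 samples
all_splits <- function(n1, n2) {
  utils::combn(n1 + n2, n1, simplify = FALSE)
}

# two-group tibble with one completely separated feature and noise
separated_tbl <- function(n = 10, p_noise = 1, seed = 42) {
  set.seed(seed)
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = n),
    sep = c(seq_len(n) + n, seq_len(n))
  )
  for (j in seq_len(p_noise)) d[[paste0("noise", j)]] <- stats::rnorm(2 * n)
  d
}
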