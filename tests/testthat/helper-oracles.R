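# Independent brute-force oracles used to validate the vectorized
# implementations. Deliberately slow and literal.

# double-loop evaluation of I = n^-1 sum_i n_i^2 (Ybar_i - Ybar)^2
naive_i_score <- function(y, cell, standardize = FALSE) {
  if (standardize) y <- (y - mean(y)) / stats::sd(y)
  n <- length(y)
  ybar <- mean(y)
  tot <- 0
  for (cl in unique(cell)) {
    yi <- y[cell == cl]
    tot <- tot + length(yi)^2 * (mean(yi) - ybar)^2
  }
  tot / n
}

# exhaustive 1-D 2-means: try every breakpoint between consecutive order
# statistics, return the split with minimal within-cluster sum of squares
brute_two_means <- function(v) {
  s <- sort(v)
  n <- length(s)
  best <- Inf
  bestk <- NA_integer_
  for (k in seq_len(n - 1L)) {
    if (s[k] == s[k + 1L]) next
    lo <- s[1:k]
    hi <- s[(k + 1L):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best) {
      best <- w
      bestk <- k
    }
  }
  list(cutoff = s[bestk], wss = best)
}

# exhaustive hypergeometric zero-overlap: enumerate all C(T, t2) draws
brute_p_zero_overlap <- function(T_true, t1, t2) {
  draws <- utils::combn(T_true, t2)
  mean(apply(draws, 2, function(d) all(d > t1)))
}

# projection pursuit by grid search: directions on the unit circle,
# running-mean smoother on the sorted projection
grid_ppr_resvar <- function(x, y, n_angles = 180L, span = 21L) {
  best <- Inf
  n <- length(y)
  for (th in seq(0, pi, length.out = n_angles)) {
    a <- c(cos(th), sin(th))
    proj <- as.numeric(x %*% a)
    o <- order(proj)
    sm <- stats::filter(y[o], rep(1 / span, span), sides = 2)
    ok <- !is.na(sm)                     # drop window-truncated edges
    rss <- sum((y[o][ok] - sm[ok])^2) / sum(ok)
    if (rss < best) best <- rss
  }
  best
}

# small deterministic cohort fixture used across I/O tests
toy_fixture <- function(seed = 42L, n = 12L, p = 6L) {
  cfg <- sim_config(n_samples = n, n_snps = p, seed = seed)
  simulate_cohort(cfg)
}

run_cli <- function(args) {
  script <- system.file("cli", "puregxe", package = "puregxe")
  out <- suppressWarnings(system2(
    "Rscript", c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
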