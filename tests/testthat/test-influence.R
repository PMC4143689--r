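test_that("joint level combinations define the partition cells", {
  # two binary factors with all four combinations -> four singleton cells
  p <- build_partition(list(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1)))
  expect_equal(p$n_cells, 4L)
  expect_equal(p$sizes, rep(1L, 4))

  p2 <- build_partition(rep(1, 7))
  expect_equal(p2$n_cells, 1L)
  expect_equal(p2$sizes, 7L)

  # genotype x binary environment sizes match a cross-tabulation
  set.seed(21)
  g <- rbinom(80, 2, 0.35)
  z <- rbinom(80, 1, 0.4)
  p3 <- build_partition(list(genotype = g, env = z))
  expect_equal(sort(p3$sizes), sort(as.integer(table(g, z)[table(g, z) > 0])))
  expect_equal(sum(p3$sizes), 80L)

  expect_error(build_partition(rnorm(50)), "discretize")
})

test_that("the I-score matches hand evaluation and degenerates to zero", {
  # two cells of means +1/-1 around a zero grand mean: I = (4+4)/4 = 2
  p <- build_partition(c("a", "a", "b", "b"))
  expect_equal(i_score(c(1, 1, -1, -1), p, standardize = FALSE), 2)

  expect_equal(i_score(rnorm(7) * 0 + 5, build_partition(rep(1, 7)),
                       standardize = FALSE), 0)
  p1 <- build_partition(rep(1, 10))
  expect_equal(i_score(rnorm(10), p1, standardize = FALSE), 0)
  expect_warning(s <- i_score(rep(2, 6), build_partition(c(1, 1, 1, 2, 2, 2))),
                 "zero-variance")
  expect_equal(s, 0)
})

test_that("vectorized I-score equals the naive double-loop on random instances", {
  set.seed(22)
  for (rep in 1:100) {
    n <- sample(8:50, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    z <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rnorm(n)
    p <- build_partition(list(g = g, z = z))
    cell <- paste(g, z)
    expect_equal(i_score(y, p, standardize = FALSE),
                 naive_i_score(y, cell), tolerance = 1e-12)
    if (stats::sd(y) > 0)
      expect_equal(i_score(y, p, standardize = TRUE),
                   naive_i_score(y, cell, standardize = TRUE),
                   tolerance = 1e-12)
  }
})

test_that("the I-score is invariant to cell relabeling and quadratic in response scale", {
  set.seed(23)
  n <- 60
  g <- rbinom(n, 2, 0.3)
  z <- rbinom(n, 1, 0.5)
  y <- rnorm(n)
  p <- build_partition(list(g, z))
  p_relab <- build_partition(list(2 - g, 1 - z))
  expect_equal(i_score(y, p_relab), i_score(y, p))

  ord <- sample(n)
  p_perm <- build_partition(list(g[ord], z[ord]))
  expect_equal(i_score(y[ord], p_perm), i_score(y, p))

  expect_equal(i_score(3 * y, p, standardize = FALSE),
               9 * i_score(y, p, standardize = FALSE))
  expect_equal(i_score(3 * y, p, standardize = TRUE),
               i_score(y, p, standardize = TRUE))
})

test_that("permutation p-values attain the add-one floor for extreme scores", {
  set.seed(24)
  g <- rep(0:1, each = 30)
  y <- c(rnorm(30, -3), rnorm(30, 3))   # association far beyond any shuffle
  p <- build_partition(g)
  r <- permutation_p(y, p, n_perm = 200, seed = 5)
  expect_equal(r$p_value, 1 / 201)
  expect_gte(r$p_value, 1 / (r$n_perm + 1))
  expect_s3_class(r, "iscore_result")
})

test_that("permutation p-values are uniform under independence", {
  set.seed(25)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  z <- rbinom(n, 1, 0.4)
  p <- build_partition(list(g, z))
  B <- 2000L
  reps <- 500L
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    y <- rnorm(n)
    pvals[r] <- permutation_p(y, p, n_perm = B, seed = 7000 + r)$p_value
  }
  frac <- mean(pvals <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  # wider-band sanity at 0.5
  expect_lt(abs(mean(pvals <= 0.5) - 0.5), 0.06)
})

test_that("permutation results are reproducible for a fixed seed", {
  set.seed(26)
  y <- rnorm(100)
  p <- build_partition(rbinom(100, 2, 0.4))
  r1 <- permutation_p(y, p, n_perm = 300, seed = 99)
  r2 <- permutation_p(y, p, n_perm = 300, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
  # chunked accumulation does not change the answer
  r3 <- permutation_p(y, p, n_perm = 300, seed = 99, chunk = 64)
  expect_identical(r3$p_value, r1$p_value)
})
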