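test_that("the BH inversion reproduces the genome-wide FDR arithmetic", {
  # 18 SNPs at p <= 1e-4 among 62,915 tests -> FDR 0.35; 64 SNPs -> 0.098
  expect_lt(abs(bh_fdr_at_k(1e-4, 18, 62915) - 0.35), 0.005)
  expect_lt(abs(bh_fdr_at_k(1e-4, 64, 62915) - 0.098), 0.0005)
  # boundary of the BH inequality: p_k = k/m gives FDR 1
  expect_equal(bh_fdr_at_k(18 / 62915, 18, 62915), 1)
  expect_error(bh_fdr_at_k(1e-4, 0, 100), "at least 1")
  expect_error(bh_fdr_at_k(c(2e-4, 1e-4), 2, 100), "sorted")
})

test_that("expected true positives round half away from zero", {
  expect_identical(expected_tp(18, 0.35), 12L)
  expect_identical(expected_tp(64, 0.098), 58L)
  expect_identical(expected_tp(10, 0), 10L)
  expect_identical(expected_tp(5, 0.5), 3L)   # 2.5 rounds up, not to even
})

test_that("zero-overlap probability matches closed form, enumeration, and exact rationals", {
  expect_lt(abs(p_zero_overlap(200, 12, 58) - 0.014), 5e-4)
  expect_equal(p_zero_overlap(50, 0, 20), 1)
  expect_equal(p_zero_overlap(30, 10, 25), 0)
  expect_equal(p_zero_overlap(20, 3, 5), brute_p_zero_overlap(20, 3, 5),
               tolerance = 1e-12)
  # log-gamma path agrees with exact rational arithmetic for all T <= 30
  for (T_true in c(8, 15, 30)) {
    for (t1 in c(1, 3)) {
      for (t2 in c(2, 4)) {
        exact <- choose(T_true - t1, t2) / choose(T_true, t2)
        expect_equal(p_zero_overlap(T_true, t1, t2), exact,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("zero-overlap probability is symmetric and monotone", {
  for (T_true in c(40, 100)) {
    expect_equal(p_zero_overlap(T_true, 7, 13), p_zero_overlap(T_true, 13, 7),
                 tolerance = 1e-12)
  }
  p_t1 <- sapply(1:10, function(t1) p_zero_overlap(100, t1, 20))
  expect_true(all(diff(p_t1) < 0))
  p_T <- sapply(c(50, 80, 120, 200), function(T_) p_zero_overlap(T_, 10, 20))
  expect_true(all(diff(p_T) > 0))
})

test_that("first-overlap rank scanning follows the joint frontier", {
  mk <- function(ids, scores, p = NA_real_) {
    structure(data.frame(rank = rank(-scores), snp_id = ids, chrom = "3",
                         pos = seq_along(ids), n_used = 100L,
                         i_score = scores, p_perm = p, n_perm = NA_integer_,
                         flags = ""),
              class = c("scan_table", "data.frame"), mode = "G-only",
              env_name = NA_character_, env_cutoff = NA_real_, seed = 1L)
  }
  ids <- c("a", "b", "c")
  identical_rank <- mk(ids, c(3, 2, 1))
  ov <- compare_subgroups(identical_rank, mk(ids, c(30, 20, 10)), top_k = 2)
  expect_equal(ov$first_overlap, c(1L, 1L))

  # reversed rankings of three SNPs: frontier meets at rank 2 on both sides
  rev_rank <- mk(ids, c(1, 2, 3))
  ov2 <- compare_subgroups(identical_rank, rev_rank, top_k = 1)
  expect_equal(max(ov2$first_overlap), 2L)
  expect_equal(ov2$top_overlap_count, 0L)
})

test_that("the full overlap analysis wires FDR, TP and the hypergeometric together", {
  set.seed(41)
  m <- 400
  ids <- sprintf("s%03d", 1:m)
  p1 <- sort(c(runif(12, 1e-6, 1e-4), runif(m - 12, 1e-3, 1)))
  p2 <- sort(c(runif(20, 1e-6, 1e-4), runif(m - 20, 1e-3, 1)))
  mk <- function(p, flip) {
    sc <- rev(seq_along(p))
    structure(data.frame(rank = seq_along(p),
                         snp_id = if (flip) rev(ids) else ids, chrom = "3",
                         pos = 1:m, n_used = 100L, i_score = sc,
                         p_perm = p, n_perm = 10000L, flags = ""),
              class = c("scan_table", "data.frame"), mode = "G-only",
              env_name = NA_character_, env_cutoff = NA_real_, seed = 1L)
  }
  ov <- compare_subgroups(mk(p1, FALSE), mk(p2, TRUE), top_k = 10,
                          T_true = 100, alpha = 1e-4)
  expect_equal(ov$k1, 12L)
  expect_equal(ov$k2, 20L)
  expect_equal(ov$fdr1, bh_fdr_at_k(sort(p1), 12, m))
  expect_equal(ov$tp1, expected_tp(12, ov$fdr1))
  expect_equal(ov$p_no_overlap, p_zero_overlap(100, ov$tp1, ov$tp2))
})
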