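#' Implied FDR at the k-th smallest permutation p-value
#'
#' Inverts the Benjamini-Hochberg inequality \eqn{p_k \le (k/m) q^*}: the
#' smallest target FDR \eqn{q^*} under which the k-th ranked p-value would
#' still be declared is \eqn{\hat q = p_k m / k}, capped at 1. With m tests
#' genome-wide and k SNPs at or below a permutation p-value threshold, this
#' estimates the false discovery rate within those k SNPs.
#'
#' @param pvalues P-values sorted ascending (or a single value, taken as
#'   \eqn{p_k} directly).
#' @param k Rank of interest (1-based); must not exceed `length(pvalues)`
#'   when a full vector is given.
#' @param m Total number of tests.
#' @return The implied FDR estimate in `[0, 1]`.
#' @export
bh_fdr_at_k <- function(pvalues, k, m) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (m < k) stop("m must be at least k", call. = FALSE)
  if (length(pvalues) > 1L) {
    if (is.unsorted(pvalues))
      stop("pvalues must be sorted ascending", call. = FALSE)
    if (k > length(pvalues))
      stop("k exceeds the number of p-values", call. = FALSE)
    pk <- pvalues[k]
  } else {
    pk <- pvalues
  }
  min(1, pk * m / k)
}

#' Expected number of true positives among k selections
#'
#' \eqn{(1 - \widehat{FDR}) \times k}, rounded half away from zero, read as
#' the expected count of truly associated SNPs among the k selected.
#'
#' @param k Number of selected SNPs.
#' @param fdr Estimated FDR in `[0, 1]`.
#' @return Integer expected true-positive count.
#' @export
expected_tp <- function(k, fdr) {
  if (fdr < 0 || fdr > 1) stop("fdr must be in [0, 1]", call. = FALSE)
  x <- (1 - fdr) * k
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Probability that two true-positive sets share no SNP
#'
#' Under the null that both subgroups draw their true positives from the
#' same pool of `T` truly associated SNPs, the chance that `t2` draws avoid
#' all `t1` SNPs found by the other subgroup is the hypergeometric
#' \deqn{P = \binom{T - t_1}{t_2} / \binom{T}{t_2},}
#' evaluated through log-gamma so large T cannot overflow. Returns 0 when
#' `t1 + t2 > T` (overlap is then forced by pigeonhole).
#'
#' @param T_true Assumed number of truly associated SNPs.
#' @param t1,t2 Expected true positives in each subgroup.
#' @return Probability in `[0, 1]`.
#' @export
p_zero_overlap <- function(T_true, t1, t2) {
  if (t1 < 0 || t2 < 0 || T_true < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (t1 > T_true || t2 > T_true)
    stop("t1 and t2 cannot exceed T_true", call. = FALSE)
  if (t1 + t2 > T_true) return(0)
  if (t1 == 0 || t2 == 0) return(1)
  exp(lchoose(T_true - t1, t2) - lchoose(T_true, t2))
}

#' Compare top-SNP lists between two subgroups
#'
#' Given two genotype-only scan tables over the same SNP universe (e.g. a
#' younger and an older age stratum), finds where their rankings first share
#' a SNP, estimates each subgroup's FDR and expected true positives at a
#' p-value threshold, and computes the hypergeometric probability of zero
#' overlap between those true-positive sets.
#'
#' The "first overlap" convention scans the joint rank frontier: the
#' smallest r such that the top-r lists of both groups intersect, reported
#' as the shared SNP's rank pair (r1, r2) with max(r1, r2) = r.
#'
#' @param tab1,tab2 `scan_table`s over identical SNP ids.
#' @param top_k Depth for the disjointness summary of the two top lists.
#' @param T_true Assumed number of truly associated SNPs shared by the two
#'   groups.
#' @param alpha P-value threshold defining each group's selection (counts
#'   all SNPs with `p_perm` at or below it); ignored if either table lacks
#'   permutation p-values, in which case `k1`/`k2` fall back to `top_k`
#'   with FDR treated as unknown (`NA`).
#' @param m Total number of tests for the BH inversion; defaults to the
#'   number of scanned SNPs.
#' @return An `overlap_analysis` list: `first_overlap` (ranks, or `NA` if
#'   the rankings never intersect), `top_k`, `top_overlap_count`, `k1`,
#'   `k2`, `fdr1`, `fdr2`, `tp1`, `tp2`, `T_true`, `p_no_overlap`.
#' @export
compare_subgroups <- function(tab1, tab2, top_k = 10L, T_true = 200L,
                              alpha = 1e-4, m = NULL) {
  id1 <- tab1$snp_id[order(tab1$rank, na.last = NA)]
  id2 <- tab2$snp_id[order(tab2$rank, na.last = NA)]
  if (!setequal(tab1$snp_id, tab2$snp_id))
    stop("the two scans cover different SNP universes", call. = FALSE)
  if (is.null(m)) m <- sum(!is.na(tab1$i_score))

  # first overlap along the joint rank frontier
  first <- c(NA_integer_, NA_integer_)
  seen1 <- seen2 <- character()
  for (r in seq_len(max(length(id1), length(id2)))) {
    if (r <= length(id1)) seen1 <- c(seen1, id1[r])
    if (r <= length(id2)) seen2 <- c(seen2, id2[r])
    shared <- intersect(seen1, seen2)
    if (length(shared)) {
      s <- shared[1L]
      first <- c(match(s, id1), match(s, id2))
      break
    }
  }

  have_p <- !all(is.na(tab1$p_perm)) && !all(is.na(tab2$p_perm))
  if (have_p) {
    k1 <- sum(tab1$p_perm <= alpha, na.rm = TRUE)
    k2 <- sum(tab2$p_perm <= alpha, na.rm = TRUE)
    p1 <- sort(tab1$p_perm[!is.na(tab1$p_perm)])
    p2 <- sort(tab2$p_perm[!is.na(tab2$p_perm)])
    fdr1 <- if (k1 > 0) bh_fdr_at_k(p1, k1, m) else NA_real_
    fdr2 <- if (k2 > 0) bh_fdr_at_k(p2, k2, m) else NA_real_
  } else {
    k1 <- k2 <- as.integer(top_k)
    fdr1 <- fdr2 <- NA_real_
  }
  tp1 <- if (!is.na(fdr1)) expected_tp(k1, fdr1) else NA_integer_
  tp2 <- if (!is.na(fdr2)) expected_tp(k2, fdr2) else NA_integer_
  pno <- if (!is.na(tp1) && !is.na(tp2) && tp1 <= T_true && tp2 <= T_true)
    p_zero_overlap(T_true, tp1, tp2) else NA_real_

  structure(list(first_overlap = first,
                 top_k = as.integer(top_k),
                 top_overlap_count = length(intersect(
                   utils::head(id1, top_k), utils::head(id2, top_k))),
                 k1 = k1, k2 = k2, fdr1 = fdr1, fdr2 = fdr2,
                 tp1 = tp1, tp2 = tp2,
                 T_true = as.integer(T_true), alpha = alpha, m = m,
                 p_no_overlap = pno),
            class = "overlap_analysis")
}

#' @exportS3Method base::print
print.overlap_analysis <- function(x, ...) {
  cat("overlap_analysis:\n")
  if (all(is.na(x$first_overlap)))
    cat("  first overlap: none\n")
  else
    cat("  first overlap at ranks (", x$first_overlap[1], ", ",
        x$first_overlap[2], ")\n", sep = "")
  cat("  top-", x$top_k, " overlap: ", x$top_overlap_count, " SNPs\n",
      sep = "")
  cat("  group 1: k =", x$k1, "FDR =", signif(x$fdr1, 3),
      "expected TP =", x$tp1, "\n")
  cat("  group 2: k =", x$k2, "FDR =", signif(x$fdr2, 3),
      "expected TP =", x$tp2, "\n")
  cat("  P(zero overlap | T =", x$T_true, ") =",
      signif(x$p_no_overlap, 3), "\n")
  invisible(x)
}
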