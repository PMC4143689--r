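#' Dichotomize a continuous covariate by exact two-means clustering
#'
#' One-dimensional k-means with k = 2 has an exact solution: the optimal
#' clustering is a split of the sorted values, so the within-cluster sum of
#' squares is evaluated at every breakpoint between consecutive distinct
#' values and the minimizer taken. The reported cutoff is the largest value
#' in the lower cluster, so the labelling rule is `value > cutoff -> 1`
#' (the convention under which an age cutoff of 55 codes ages over 55 as 1).
#' Deterministic; no random initialization.
#'
#' @param v Numeric vector with at least two distinct values.
#' @return An object of class `dichotomy`: `cutoff`, `labels` (0/1 per
#'   sample), `rule`, and `wss` (the achieved within-cluster sum of squares).
#' @export
two_means_dichotomize <- function(v) {
  v <- as.numeric(v)
  if (anyNA(v)) stop("missing values not allowed", call. = FALSE)
  s <- sort(v)
  n <- length(s)
  if (n < 2L || s[1L] == s[n])
    stop("degenerate-environment: need at least two distinct values",
         call. = FALSE)
  # prefix sums give each split's WSS in O(1):
  # WSS = sum(x^2) - L1^2/k - (S1-L1)^2/(n-k) for lower block of size k
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)
  wss <- (cs2[n]) - cs[k]^2 / k - (cs[n] - cs[k])^2 / (n - k)
  valid <- s[k] != s[k + 1L]               # split only between distinct values
  wss[!valid] <- Inf
  kbest <- which.min(wss)                  # ties: lowest cutoff, deterministic
  cutoff <- s[kbest]
  structure(list(cutoff = cutoff,
                 labels = as.integer(v > cutoff),
                 rule = "value > cutoff -> 1",
                 wss = wss[kbest]),
            class = "dichotomy")
}

#' @exportS3Method base::print
print.dichotomy <- function(x, ...) {
  cat("dichotomy: cutoff =", x$cutoff, "(", x$rule, ");",
      sum(x$labels == 0L), "low /", sum(x$labels == 1L), "high\n")
  invisible(x)
}
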