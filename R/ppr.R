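#' Fit a projection pursuit regression main-effect model
#'
#' Fits the additive ridge-function model
#' \deqn{y = \sum_{m=1}^{M} S_{\alpha_m}(\alpha_m \cdot x) + \epsilon}
#' used to remove (possibly nonlinear) main effects before interaction
#' scoring. Continuous smoothers are fitted by Friedman--Stuetzle alternating
#' optimization via [stats::ppr()] (supersmoother or GCV smoothing spline).
#' For a discrete predictor with at most `max_levels` distinct values and
#' `smoother = "level-means"`, the ridge function is the per-level response
#' mean, which removes the predictor's main effect exactly and
#' deterministically.
#'
#' @param x Numeric predictor matrix (or vector, treated as one column).
#' @param y Numeric response vector.
#' @param M Number of ridge terms (ignored for level-means, which uses one).
#' @param smoother One of `"supersmoother"`, `"loess-like"` (GCV smoothing
#'   spline), `"level-means"`.
#' @param max_levels Maximum distinct values for a level-means fit.
#' @return An object of class `ppr_model` with elements `directions` (unit
#'   vectors, one per ridge term), `smoothers` (fitted 1-D functions, where
#'   extractable), `fitted_values`, `residuals`, `residual_variance`, `M`,
#'   `smoother`, and `converged`.
#' @export
fit_ppr <- function(x, y, M = 1L,
                    smoother = c("supersmoother", "loess-like", "level-means"),
                    max_levels = 10L) {
  smoother <- match.arg(smoother)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y))
    stop("x and y lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("fit_ppr requires complete data (apply pairwise deletion first)",
         call. = FALSE)

  ybar <- mean(y)
  if (stats::var(y) == 0) {                 # degenerate response: S == mean(y)
    return(new_ppr_model(directions = list(rep(1, ncol(x)) /
                                             sqrt(ncol(x))),
                         smoothers = list(function(z) rep(ybar, length(z))),
                         fitted = rep(ybar, length(y)), y = y,
                         M = 1L, smoother = smoother, converged = TRUE))
  }

  if (smoother == "level-means") {
    if (ncol(x) != 1L)
      stop("level-means smoothing expects a single predictor column",
           call. = FALSE)
    v <- x[, 1L]
    lev <- sort(unique(v))
    if (length(lev) > max_levels)
      stop("predictor has ", length(lev), " levels; > max_levels (",
           max_levels, ") — use a continuous smoother", call. = FALSE)
    mu <- vapply(lev, function(l) mean(y[v == l]), numeric(1))
    fitted <- mu[match(v, lev)]
    fn <- function(z) mu[match(z, lev)]
    return(new_ppr_model(directions = list(1), smoothers = list(fn),
                         fitted = fitted, y = y, M = 1L,
                         smoother = smoother, converged = TRUE))
  }

  if (length(y) < 8L)
    stop("continuous PPR smoothing needs at least 8 samples", call. = FALSE)
  sm <- if (smoother == "supersmoother") "supsmu" else "gcvspline"
  fit <- stats::ppr(x = x, y = y, nterms = M, sm.method = sm)
  dirs <- fit$alpha
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = M)
  dirs <- lapply(seq_len(ncol(dirs)), function(m) {
    a <- dirs[, m]
    n2 <- sqrt(sum(a^2))
    if (n2 > 0) a / n2 else a
  })
  fitted <- as.numeric(fit$fitted.values)
  smoothers <- NULL
  if (M == 1L) {
    proj <- as.numeric(x %*% dirs[[1L]])
    o <- order(proj)
    smoothers <- list(stats::approxfun(proj[o], fitted[o],
                                       ties = mean, rule = 2))
  }
  new_ppr_model(directions = dirs, smoothers = smoothers, fitted = fitted,
                y = y, M = M, smoother = smoother, converged = TRUE,
                engine = fit)
}

new_ppr_model <- function(directions, smoothers, fitted, y, M, smoother,
                          converged, engine = NULL) {
  res <- y - fitted
  structure(list(directions = directions, smoothers = smoothers,
                 fitted_values = fitted, residuals = res,
                 residual_variance = mean(res^2), M = M,
                 smoother = smoother, converged = converged,
                 engine = engine),
            class = "ppr_model")
}

#' @exportS3Method base::print
print.ppr_model <- function(x, ...) {
  cat("ppr_model:", x$M, "ridge term(s),", x$smoother,
      "smoother; residual variance", signif(x$residual_variance, 4), "\n")
  invisible(x)
}

#' @export
residuals.ppr_model <- function(object, ...) object$residuals

#' @export
fitted.ppr_model <- function(object, ...) object$fitted_values

#' Stepwise removal of environment then genotype main effects
#'
#' Step 1 of the pure interaction scan: residualize the trait on the
#' environmental covariate first, then on the genotype, without ever
#' modelling their joint effect; the two single-predictor fits are then
#' backfitted (alternating re-fits on the partial residuals) until the
#' additive main-effect surface converges. For discrete predictors the
#' per-level-means smoother makes the annihilation exact: the converged
#' residual has zero mean within every environment level and every genotype
#' level, so only interaction structure and noise survive. Binary
#' environments and 0/1/2 genotypes use level means; a continuous
#' environment uses the continuous smoother.
#'
#' @param y Numeric trait vector (complete).
#' @param e Environment vector (complete), binary or continuous.
#' @param g Genotype vector (complete), additive codes 0/1/2.
#' @param smoother Continuous smoother for a non-discrete environment.
#' @param discrete_max_levels An environment with at most this many distinct
#'   values is residualized by level means.
#' @param tol Convergence tolerance: maximum absolute within-level residual
#'   mean (discrete) or relative change in residual sum of squares
#'   (continuous environment).
#' @param max_iter Backfitting iteration cap.
#' @return An object of class `residual_vector`: `values`, `removed`
#'   (ordered predictors residualized out), `flags`.
#' @export
residualize_stepwise <- function(y, e, g,
                                 smoother = c("supersmoother", "loess-like"),
                                 discrete_max_levels = 3L,
                                 tol = 1e-12, max_iter = 100L) {
  smoother <- match.arg(smoother)
  y <- as.numeric(y); e <- as.numeric(e); g <- as.numeric(g)
  n <- length(y)
  if (length(e) != n || length(g) != n)
    stop("y, e, g must be aligned vectors of equal length", call. = FALSE)
  if (anyNA(y) || anyNA(e) || anyNA(g))
    stop("residualize_stepwise requires complete vectors", call. = FALSE)
  flags <- character()

  if (stats::var(y) == 0) {
    return(structure(list(values = rep(0, n), removed = c("env", "snp"),
                          flags = "constant-response"),
                     class = "residual_vector"))
  }

  e_discrete <- length(unique(e)) <= discrete_max_levels
  g_poly <- length(unique(g)) >= 2L
  if (!g_poly) flags <- c(flags, "no-genotype-variation")
  if (!e_discrete) max_iter <- min(max_iter, 10L)  # smoother refits are costly

  fit_env <- function(target) {
    if (stats::var(target) == 0) return(rep(mean(target), n))
    if (e_discrete)
      fit_ppr(e, target, smoother = "level-means",
              max_levels = discrete_max_levels)$fitted_values
    else fit_ppr(e, target, M = 1L, smoother = smoother)$fitted_values
  }
  fit_snp <- function(target) {
    if (!g_poly || stats::var(target) == 0) return(rep(mean(target), n))
    fit_ppr(g, target, smoother = "level-means")$fitted_values
  }

  # env first (the stepwise order), then alternate to convergence
  fe <- fit_env(y)
  fg <- fit_snp(y - fe)
  res <- y - fe - fg
  for (it in seq_len(max_iter)) {
    fe <- fit_env(y - fg)
    fg <- fit_snp(y - fe)
    new_res <- y - fe - fg
    if (e_discrete) {
      drift <- max(abs(vapply(split(new_res, e), mean, numeric(1))),
                   abs(vapply(split(new_res, g), mean, numeric(1))))
      res <- new_res
      if (drift < tol) break
    } else {
      delta <- abs(sum(new_res^2) - sum(res^2)) / max(sum(res^2), 1e-300)
      res <- new_res
      if (delta < 1e-8) break
    }
  }
  res <- res - mean(res)
  structure(list(values = res, removed = c("env", "snp"), flags = flags),
            class = "residual_vector")
}

#' @exportS3Method base::print
print.residual_vector <- function(x, ...) {
  cat("residual_vector: n =", length(x$values), "; removed:",
      paste(x$removed, collapse = " -> "),
      if (length(x$flags)) paste("; flags:", paste(x$flags, collapse = ",")),
      "\n")
  invisible(x)
}
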