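#' Genome-wide pure gene-environment interaction scan
#'
#' Runs the two-step procedure over every SNP: per SNP, samples with a
#' missing genotype are deleted pairwise, the trait is residualized on the
#' environment and then on the genotype ([residualize_stepwise()]), the
#' residual is scored on the joint genotype-by-environment partition
#' ([i_score()]), and significance is assessed by permutation
#' ([permutation_p()]). A continuous environment (more than two distinct
#' values) is residualized as-is in Step 1 and dichotomized by exact
#' two-means clustering ([two_means_dichotomize()]) for the Step-2 partition.
#'
#' @param g A [genotype_matrix()].
#' @param cohort A [cohort_table()].
#' @param trait Trait name to scan.
#' @param env Environment name.
#' @param n_perm Permutations per SNP; `0` skips permutation p-values
#'   (I-scores only, `p_perm` = `NA`).
#' @param seed Integer seed; each SNP gets a deterministic sub-seed so
#'   results do not depend on scan order.
#' @param min_cell_total Minimum usable samples for a SNP to be tested;
#'   below this the row is flagged `"skipped:insufficient-samples"`.
#' @param smoother Continuous smoother for Step 1 (see [fit_ppr()]).
#' @param standardize Standardize the residual before scoring (default).
#' @param refit_permutations Re-run Step 1 on every permuted phenotype
#'   instead of permuting the fixed residual. Exact but roughly `n_perm`
#'   times slower; the default holds the Step-1 fits fixed, the standard
#'   conditional approximation.
#' @return A `scan_table`: a data frame with one row per SNP in input order
#'   (columns `rank`, `snp_id`, `chrom`, `pos`, `n_used`, `i_score`,
#'   `p_perm`, `n_perm`, `flags`) carrying attributes `mode`, `env_name`,
#'   `env_cutoff` (if dichotomized), and `seed`.
#' @export
scan_pure_gxe <- function(g, cohort, trait, env, n_perm = 1000L, seed = 1L,
                          min_cell_total = 20L,
                          smoother = c("supersmoother", "loess-like"),
                          standardize = TRUE, refit_permutations = FALSE) {
  smoother <- match.arg(smoother)
  al <- align_and_drop_missing(g, cohort, trait, envs = env)
  g <- al$genotypes
  y <- al$cohort$traits[[trait]]
  e <- al$cohort$environments[[env]]

  cutoff <- NA_real_
  if (length(unique(e)) > 2L) {
    dich <- two_means_dichotomize(e)
    ebin <- dich$labels
    cutoff <- dich$cutoff
  } else {
    # binary environment: map its two levels onto 0/1
    ebin <- as.integer(e == max(e))
    if (length(unique(e)) < 2L)
      stop("environment '", env, "' is constant in the aligned cohort",
           call. = FALSE)
  }

  p <- ncol(g$codes)
  score <- pval <- rep(NA_real_, p)
  n_used <- integer(p)
  flags <- character(p)
  for (j in seq_len(p)) {
    gj <- g$codes[, j]
    ok <- !is.na(gj)
    n_used[j] <- sum(ok)
    if (n_used[j] < min_cell_total) {
      flags[j] <- "skipped:insufficient-samples"
      next
    }
    if (length(unique(gj[ok])) < 2L) {
      flags[j] <- "skipped:monomorphic"
      next
    }
    res <- residualize_stepwise(y[ok], e[ok], gj[ok], smoother = smoother)
    part <- build_partition(list(genotype = gj[ok], env = ebin[ok]))
    if (n_perm > 0L) {
      if (refit_permutations) {
        r <- refit_permutation_p(y[ok], e[ok], gj[ok], part, n_perm,
                                 snp_seed(seed, j), smoother, standardize)
      } else {
        r <- permutation_p_centered(res$values, gj[ok], ebin[ok], part,
                                    n_perm = n_perm,
                                    seed = snp_seed(seed, j),
                                    standardize = standardize)
      }
      score[j] <- r$score
      pval[j] <- r$p_value
    } else {
      score[j] <- i_score(res$values, part, standardize = standardize)
    }
    if (length(res$flags)) flags[j] <- paste(res$flags, collapse = ";")
  }
  new_scan_table(g$snps, score, pval, n_used, flags,
                 mode = "pure-GxE", env_name = env, env_cutoff = cutoff,
                 n_perm = n_perm, seed = seed)
}

# permute the raw phenotype and redo Step 1 each time (exact, slow)
refit_permutation_p <- function(y, e, gj, part, n_perm, seed, smoother,
                                standardize) {
  res_obs <- residualize_stepwise(y, e, gj, smoother = smoother)$values
  obs <- i_score(res_obs, part, standardize = standardize)
  n <- length(y)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    rp <- residualize_stepwise(yp, e, gj, smoother = smoother)$values
    if (i_score(rp, part, standardize = standardize) >= obs - 1e-12)
      exceed <- exceed + 1L
  }
  list(score = obs, p_value = (1 + exceed) / (1 + n_perm))
}

# deterministic per-SNP sub-seed below 2^31, independent of scan order
snp_seed <- function(seed, j) {
  as.integer((as.numeric(seed) %% 2147483647 + j * 48271) %% 2147483647)
}

#' Genotype-only I-score scan, optionally within a subgroup
#'
#' Scores each SNP by the I-score of the (standardized) trait on the
#' three-cell genotype partition, within an optional sample subgroup (for
#' example an age stratum), and reports the all-sample ("overall") I-score
#' side by side, the layout used to compare age-stratified and whole-cohort
#' genetic association.
#'
#' @inheritParams scan_pure_gxe
#' @param subgroup Optional subgroup selector: a logical vector over the
#'   aligned samples or a character vector of sample ids. `NULL` scans all
#'   samples (then `i_score` equals `overall_i_score`).
#' @param min_subgroup_n Minimum subgroup size.
#' @return A `scan_table` with additional column `overall_i_score`;
#'   attribute `mode` is `"G-only"`.
#' @export
scan_g_only <- function(g, cohort, trait, subgroup = NULL, n_perm = 0L,
                        seed = 1L, min_cell_total = 20L,
                        min_subgroup_n = 20L, standardize = TRUE) {
  al <- align_and_drop_missing(g, cohort, trait)
  g <- al$genotypes
  y <- al$cohort$traits[[trait]]
  n <- length(y)

  if (is.null(subgroup)) {
    mask <- rep(TRUE, n)
  } else if (is.character(subgroup)) {
    mask <- g$samples %in% subgroup
  } else {
    if (length(subgroup) != n)
      stop("logical subgroup must match the aligned sample count (", n, ")",
           call. = FALSE)
    mask <- as.logical(subgroup)
  }
  if (sum(mask) < min_subgroup_n)
    stop("subgroup has ", sum(mask), " samples; need at least ",
         min_subgroup_n, call. = FALSE)

  p <- ncol(g$codes)
  score <- overall <- pval <- rep(NA_real_, p)
  n_used <- integer(p)
  flags <- character(p)
  for (j in seq_len(p)) {
    gj <- g$codes[, j]
    ok_sub <- mask & !is.na(gj)
    ok_all <- !is.na(gj)
    n_used[j] <- sum(ok_sub)
    if (n_used[j] < min_cell_total) {
      flags[j] <- "skipped:insufficient-samples"
      next
    }
    if (length(unique(gj[ok_sub])) < 2L) {
      flags[j] <- "skipped:monomorphic"
      next
    }
    part <- build_partition(list(genotype = gj[ok_sub]))
    score[j] <- i_score(y[ok_sub], part, standardize = standardize)
    if (length(unique(gj[ok_all])) >= 2L) {
      overall[j] <- i_score(y[ok_all],
                            build_partition(list(genotype = gj[ok_all])),
                            standardize = standardize)
    }
    if (n_perm > 0L) {
      r <- permutation_p(y[ok_sub], part, n_perm = n_perm,
                         seed = snp_seed(seed, j),
                         standardize = standardize, response_kind = "raw")
      pval[j] <- r$p_value
    }
  }
  tab <- new_scan_table(g$snps, score, pval, n_used, flags,
                        mode = "G-only", env_name = NA_character_,
                        env_cutoff = NA_real_, n_perm = n_perm, seed = seed)
  tab$overall_i_score <- overall
  tab
}

new_scan_table <- function(snps, score, pval, n_used, flags, mode, env_name,
                           env_cutoff, n_perm, seed) {
  rk <- rep(NA_integer_, length(score))
  tested <- !is.na(score)
  rk[tested] <- rank(-score[tested], ties.method = "first")
  tab <- data.frame(rank = rk,
                    snp_id = snps$id,
                    chrom = snps$chrom,
                    pos = snps$pos,
                    n_used = n_used,
                    i_score = score,
                    p_perm = pval,
                    n_perm = ifelse(is.na(pval), NA_integer_,
                                    as.integer(n_perm)),
                    flags = flags,
                    stringsAsFactors = FALSE)
  structure(tab, class = c("scan_table", "data.frame"),
            mode = mode, env_name = env_name, env_cutoff = env_cutoff,
            seed = seed)
}

#' @exportS3Method base::print
print.scan_table <- function(x, ...) {
  cat("scan_table (", attr(x, "mode"), "): ", nrow(x), " SNPs, ",
      sum(!is.na(x$i_score)), " tested",
      if (!is.na(attr(x, "env_name"))) paste0("; env = ",
                                              attr(x, "env_name")),
      if (!is.na(attr(x, "env_cutoff"))) paste0(" (cutoff ",
                                                attr(x, "env_cutoff"), ")"),
      "\n", sep = "")
  utils::head(as.data.frame(x)[order(x$rank), ], 5) |> print()
  invisible(x)
}

#' Tally SNPs reaching significance thresholds
#'
#' Counts scanned SNPs with permutation p strictly below each threshold,
#' the summary used to compare the yield of pure interaction scans against
#' genotype-only scans at nested significance levels.
#'
#' @param tab A `scan_table` with permutation p-values.
#' @param thresholds Decreasing p-value cutpoints.
#' @return A `significance_tally`: data frame of `threshold`, `count`,
#'   `fraction` (of SNPs tested).
#' @export
tally_significance <- function(tab, thresholds = c(1e-3, 1e-4, 1e-5)) {
  stopifnot(inherits(tab, "scan_table"))
  p <- tab$p_perm[!is.na(tab$p_perm)]
  total <- sum(!is.na(tab$i_score))
  counts <- vapply(thresholds, function(t) sum(p < t), integer(1))
  structure(data.frame(threshold = thresholds, count = counts,
                       fraction = if (total > 0) counts / total else 0),
            class = c("significance_tally", "data.frame"), n_tested = total)
}

#' Write a scan table as TSV with a provenance header
#'
#' @param tab A `scan_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(tab, path) {
  hdr <- sprintf("# puregxe %s; mode=%s; env=%s; seed=%s",
                 as.character(utils::packageVersion("puregxe")),
                 attr(tab, "mode"), attr(tab, "env_name"),
                 attr(tab, "seed"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a scan table written by [write_scan_table()]
#'
#' @param path Path to the TSV.
#' @return A `scan_table` data frame (provenance attributes not restored).
#' @export
read_scan_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  structure(d, class = c("scan_table", "data.frame"),
            mode = NA_character_, env_name = NA_character_,
            env_cutoff = NA_real_, seed = NA_integer_)
}
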