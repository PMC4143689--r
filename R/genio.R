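#' Construct a genotype matrix
#'
#' Container for additive-coded biallelic genotypes: a samples x SNPs integer
#' matrix of alt-allele counts (0/1/2, `NA` for missing) plus per-SNP metadata.
#'
#' @param codes Integer matrix, samples in rows, SNPs in columns. Values must
#'   be 0, 1, 2 or `NA`.
#' @param samples Character vector of sample ids (row order of `codes`).
#' @param snps Data frame with one row per SNP: columns `id`, `chrom`, `pos`
#'   (1-based), and optionally `ref`, `alt`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, samples, snps) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  samples <- as.character(samples)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(snps$ref)) snps$ref <- "A"
  if (is.null(snps$alt)) snps$alt <- "G"
  if (nrow(codes) != length(samples))
    stop("genotype matrix has ", nrow(codes), " rows but ", length(samples),
         " sample ids", call. = FALSE)
  if (ncol(codes) != nrow(snps))
    stop("genotype matrix has ", ncol(codes), " columns but ", nrow(snps),
         " SNP records", call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample ids in genotype matrix", call. = FALSE)
  if (anyDuplicated(snps$id))
    stop("duplicate SNP ids", call. = FALSE)
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or missing; found ",
         paste(unique(codes[bad]), collapse = ", "), call. = FALSE)
  dimnames(codes) <- list(samples, snps$id)
  structure(list(samples = samples, snps = snps, codes = codes),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$snps),
      "SNPs;", sum(is.na(x$codes)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Construct a cohort table
#'
#' Per-sample quantitative traits (e.g. SBP, DBP in mmHg) and environmental
#' covariates (age in years, binary smoking / medication indicators).
#'
#' @param samples Character vector of sample ids.
#' @param traits Data frame (or named list) of numeric trait vectors.
#' @param environments Data frame (or named list) of covariate vectors;
#'   binary covariates are conventionally coded 0/1.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(samples, traits, environments) {
  samples <- as.character(samples)
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  environments <- as.data.frame(environments, stringsAsFactors = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample ids in cohort table", call. = FALSE)
  for (d in list(traits, environments)) {
    if (ncol(d) > 0L && nrow(d) != length(samples))
      stop("trait/environment columns must have one value per sample",
           call. = FALSE)
  }
  rownames(traits) <- samples
  rownames(environments) <- samples
  structure(list(samples = samples, traits = traits,
                 environments = environments),
            class = "cohort_table")
}

#' @exportS3Method base::print
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", length(x$samples), "samples; traits:",
      paste(names(x$traits), collapse = ", "), "; environments:",
      paste(names(x$environments), collapse = ", "), "\n")
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file and converts diploid GT fields to additive
#' alt-allele counts (0/1/2). Missing genotypes (`./.` or `.`) become `NA`.
#' Multi-allelic records are rejected unless `drop_multiallelic = TRUE`, in
#' which case they are dropped with a warning; the I-score partition assumes
#' at most three genotype levels per SNP.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param drop_multiallelic Drop multi-allelic records instead of erroring.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, drop_multiallelic = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path,
                            call. = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    if (!drop_multiallelic)
      stop("multi-allelic records not supported (set drop_multiallelic=TRUE ",
           "to drop them): ", paste(utils::head(fix$ID[multi], 5),
                                    collapse = ", "), call. = FALSE)
    warning(sum(multi), " multi-allelic records dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")          # SNPs x samples
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  codes <- gt_to_additive(gt)
  genotype_matrix(t(codes),
                  samples = colnames(gt),
                  snps = data.frame(id = ids, chrom = fix$CHROM,
                                    pos = as.integer(fix$POS),
                                    ref = fix$REF, alt = fix$ALT,
                                    stringsAsFactors = FALSE))
}

# GT strings -> alt-allele counts; errors on non-diploid calls
gt_to_additive <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(s) {
    if (s %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2L)
      stop("non-diploid genotype '", s, "' encountered", call. = FALSE)
    if (any(al == ".")) return(NA_integer_)
    ac <- suppressWarnings(as.integer(al))
    if (anyNA(ac) || any(ac > 1L))
      stop("unsupported allele code in genotype '", s, "'", call. = FALSE)
    sum(ac)
  }, integer(1))
  out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (i in seq_along(u)) out[gt == u[i]] <- map[i]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a genotype or cohort table from delimited text
#'
#' Tab- or comma-delimited text with a header row; the first column holds
#' sample ids. For `kind = "genotypes"` all remaining columns are SNPs coded
#' 0/1/2 (anything else is an error). For `kind = "cohort"`, columns named in
#' `traits` become quantitative traits and the rest environments; unparseable
#' numeric cells become `NA` with a warning.
#'
#' @param path Path to the delimited file.
#' @param kind `"genotypes"` or `"cohort"`.
#' @param traits For `kind = "cohort"`, names of the trait columns; all other
#'   columns are treated as environments.
#' @param snp_meta Optional data frame of SNP metadata (`id`, `chrom`, `pos`)
#'   to attach when `kind = "genotypes"`; defaults to placeholder positions.
#' @return A [genotype_matrix()] or [cohort_table()].
#' @export
read_table <- function(path, kind = c("genotypes", "cohort"),
                       traits = NULL, snp_meta = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "#")
  if (nrow(d) == 0L) stop("no data rows in ", path, call. = FALSE)
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", path, call. = FALSE)
  d <- d[-1L]
  num <- lapply(d, function(col) {
    v <- suppressWarnings(as.numeric(col))
    bad <- is.na(v) & !is.na(col) & trimws(as.character(col)) != "" &
      !(col %in% c("NA", "."))
    if (any(bad))
      warning(sum(bad), " unparseable numeric cells set to NA")
    v
  })
  if (kind == "genotypes") {
    codes <- do.call(cbind, num)
    bad <- !is.na(codes) & !(codes %in% 0:2)
    if (any(bad))
      stop("genotype value out of {0,1,2}: ",
           paste(utils::head(unique(codes[bad]), 5), collapse = ", "),
           call. = FALSE)
    if (is.null(snp_meta))
      snp_meta <- data.frame(id = names(d), chrom = "NA",
                             pos = seq_along(d), stringsAsFactors = FALSE)
    genotype_matrix(codes, samples = ids, snps = snp_meta)
  } else {
    num <- as.data.frame(num, check.names = FALSE)
    if (is.null(traits)) traits <- intersect(c("SBP", "DBP", "y"), names(num))
    miss <- setdiff(traits, names(num))
    if (length(miss))
      stop("trait columns not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    cohort_table(ids,
                 traits = num[, traits, drop = FALSE],
                 environments = num[, setdiff(names(num), traits),
                                    drop = FALSE])
  }
}

#' Write a genotype matrix or cohort table as TSV
#'
#' Inverse of [read_table()]: a header row, sample ids in the first column.
#'
#' @param x A `genotype_matrix` or `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "genotype_matrix")) {
    d <- data.frame(sample_id = x$samples, x$codes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  } else if (inherits(x, "cohort_table")) {
    d <- data.frame(sample_id = x$samples, x$traits, x$environments,
                    check.names = FALSE, stringsAsFactors = FALSE)
  } else stop("x must be a genotype_matrix or cohort_table", call. = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotypes and cohort and drop incomplete samples
#'
#' Restricts both containers to the samples present in each that have a
#' non-missing value for the requested trait and for every requested
#' environment, in a common order. Per-SNP missing genotypes are left in
#' place; single-SNP tests delete them pairwise.
#'
#' @param g A [genotype_matrix()].
#' @param cohort A [cohort_table()].
#' @param trait Trait name that must be complete.
#' @param envs Character vector of environment names that must be complete.
#' @return List with elements `genotypes` and `cohort`, sample-aligned.
#' @export
align_and_drop_missing <- function(g, cohort, trait, envs = character()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cohort, "cohort_table"))
  if (!trait %in% names(cohort$traits))
    stop("trait '", trait, "' not in cohort", call. = FALSE)
  miss <- setdiff(envs, names(cohort$environments))
  if (length(miss))
    stop("environments not in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  common <- intersect(g$samples, cohort$samples)
  if (length(common) == 0L)
    stop("no overlapping sample ids between genotypes and cohort",
         call. = FALSE)
  idx <- match(common, cohort$samples)
  keep <- !is.na(cohort$traits[[trait]][idx])
  for (e in envs) keep <- keep & !is.na(cohort$environments[[e]][idx])
  common <- common[keep]
  if (length(common) == 0L)
    stop("no samples remain after dropping missing values", call. = FALSE)
  gi <- match(common, g$samples)
  ci <- match(common, cohort$samples)
  list(genotypes = genotype_matrix(g$codes[gi, , drop = FALSE],
                                   samples = common, snps = g$snps),
       cohort = cohort_table(common,
                             traits = cohort$traits[ci, , drop = FALSE],
                             environments = cohort$environments[ci, ,
                                                                drop = FALSE]))
}
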