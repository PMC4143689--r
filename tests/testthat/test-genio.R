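test_that("VCF genotypes map to additive codes with missing convention", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1|1\t./."
  ), vcf)
  g <- read_vcf(vcf)
  expect_equal(g$samples, c("A", "B"))
  expect_equal(unname(g$codes[, "rs1"]), c(0L, 1L))
  expect_equal(unname(g$codes[, "rs2"]), c(2L, NA_integer_))
  expect_equal(g$snps$pos, c(100L, 200L))
})

test_that("multi-allelic records are rejected unless dropped explicitly", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
    "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1"
  ), vcf)
  expect_error(read_vcf(vcf), "multi-allelic")
  g <- suppressWarnings(read_vcf(vcf, drop_multiallelic = TRUE))
  expect_equal(g$snps$id, "rs2")
})

test_that("simulated fixtures round-trip through VCF and TSV unchanged", {
  sim <- toy_fixture(seed = 7L, n = 10L, p = 20L)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim$genotypes, sim$cohort, dir)
  g2 <- read_vcf(paths[["vcf"]])
  expect_equal(unname(g2$codes), unname(sim$genotypes$codes))
  expect_equal(g2$samples, sim$genotypes$samples)
  expect_equal(g2$snps$id, sim$genotypes$snps$id)

  c2 <- read_table(paths[["cohort"]], kind = "cohort", traits = "SBP")
  expect_equal(c2$samples, sim$cohort$samples)
  expect_equal(c2$traits$SBP, sim$cohort$traits$SBP)
  expect_equal(c2$environments$age, sim$cohort$environments$age)

  # VCF format sanity: header then one row per SNP, constant column count
  lines <- readLines(paths[["vcf"]])
  body <- lines[!startsWith(lines, "##")]
  ncols <- lengths(strsplit(body, "\t"))
  expect_true(all(ncols == ncols[1]))
  expect_equal(length(body) - 1L, nrow(sim$genotypes$snps))
})

test_that("genotype tables round-trip and invalid codes are rejected", {
  sim <- toy_fixture(seed = 3L)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "g.tsv")
  write_table(sim$genotypes, path)
  g2 <- read_table(path, kind = "genotypes")
  expect_equal(unname(g2$codes), unname(sim$genotypes$codes))

  writeLines(c("sample_id\tsnp1", "S1\t3", "S2\t1"), path)
  expect_error(read_table(path, kind = "genotypes"), "out of \\{0,1,2\\}")

  writeLines(c("sample_id\tsnp1", "S1\t1", "S1\t2"), path)
  expect_error(read_table(path, kind = "genotypes"), "duplicate")

  writeLines("sample_id\tsnp1", path)
  expect_error(read_table(path, kind = "genotypes"), "no data rows")
})

test_that("cohort tables type their columns and flag unparseable cells", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "c.tsv")
  writeLines(c("sample_id\tSBP\tage\tsmoke",
               "S1\t120\t40\t0",
               "S2\t135\t60\t1"), path)
  ct <- read_table(path, kind = "cohort", traits = "SBP")
  expect_equal(ct$environments$age, c(40, 60))
  expect_equal(ct$traits$SBP, c(120, 135))

  writeLines(c("sample_id\tSBP\tage", "S1\t120\tforty", "S2\t130\t61"), path)
  expect_warning(ct <- read_table(path, kind = "cohort", traits = "SBP"),
                 "unparseable")
  expect_true(is.na(ct$environments$age[1]))
})

test_that("alignment keeps only samples complete in trait and chosen envs", {
  # 142 enrolled, 12 with a missing phenotype or environment -> 130 usable
  n <- 142L
  ids <- sprintf("S%03d", 1:n)
  set.seed(9)
  g <- genotype_matrix(matrix(rbinom(n * 3, 2, 0.3), n, 3),
                       samples = ids,
                       snps = data.frame(id = paste0("s", 1:3), chrom = "3",
                                         pos = 1:3))
  sbp <- rnorm(n, 125, 12)
  age <- rnorm(n, 50, 10)
  smoke <- rbinom(n, 1, 0.3)
  sbp[1:5] <- NA
  age[6:10] <- NA
  smoke[11:12] <- NA
  ct <- cohort_table(ids, traits = data.frame(SBP = sbp),
                     environments = data.frame(age = age, smoke = smoke))
  al <- align_and_drop_missing(g, ct, "SBP", envs = c("age", "smoke"))
  expect_equal(length(al$cohort$samples), 130L)
  expect_identical(al$genotypes$samples, al$cohort$samples)

  # a sample missing only age survives when only smoke is requested
  al2 <- align_and_drop_missing(g, ct, "SBP", envs = "smoke")
  expect_true("S006" %in% al2$cohort$samples)
  expect_equal(length(al2$cohort$samples), 135L)

  # no missing anywhere -> identity
  ct3 <- cohort_table(ids, traits = data.frame(SBP = rnorm(n)),
                      environments = data.frame(age = rnorm(n, 50, 8)))
  al3 <- align_and_drop_missing(g, ct3, "SBP", envs = "age")
  expect_equal(al3$cohort$samples, ids)

  expect_error(align_and_drop_missing(
    g, cohort_table("X1", data.frame(SBP = 1), data.frame(age = 2)),
    "SBP"), "no overlapping")
})
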