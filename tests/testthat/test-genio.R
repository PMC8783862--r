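# format I/O: VCF dosage extraction, allele orientation, TSV round trips

make_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    lines), path)
  path
}

test_that("VCF dosages count the named effect allele in either orientation", {
  path <- make_vcf(c(
    paste(c("1", "100", "rsA", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "1/1", "0/0"), collapse = "\t"),
    # insertion allele: effect allele is the multi-base ALT
    paste(c("9", "200", "rsIns", "T", "TG", ".", "PASS", ".", "GT",
            "1/1", "0|1", "./."), collapse = "\t"),
    # effect allele is REF: homozygous reference carries two copies
    paste(c("2", "300", "rsRef", "G", "A", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    # multi-allelic: only the named allele counts
    paste(c("3", "400", "rsMulti", "A", "G,T", ".", "PASS", ".", "GT",
            "1/2", "2/2", "0/1"), collapse = "\t")))
  g <- read_vcf(path, c(rsA = "G", rsIns = "TG", rsRef = "G", rsMulti = "G"))
  expect_equal(unname(g$dosages[, "rsA"]), c(1L, 2L, 0L))
  expect_equal(unname(g$dosages[, "rsIns"]), c(2L, 1L, NA_integer_))
  expect_equal(unname(g$dosages[, "rsRef"]), c(2L, 1L, 0L))
  expect_equal(unname(g$dosages[, "rsMulti"]), c(1L, 0L, 1L))
})

test_that("VCF reader reports absent variants and rejects non-diploid GT", {
  path <- make_vcf(paste(c("1", "100", "rsA", "A", "G", ".", "PASS", ".",
                           "GT", "0/1", "1/1", "0/0"), collapse = "\t"))
  expect_warning(read_vcf(path, c(rsA = "G", rsGone = "T")), "rsGone")

  bad <- make_vcf(paste(c("1", "100", "rsA", "A", "G", ".", "PASS", ".",
                          "GT", "0", "1/1", "0/0"), collapse = "\t"))
  expect_error(suppressWarnings(read_vcf(bad, c(rsA = "G"))), "non-diploid")
})

test_that("simulate -> write VCF -> read VCF reproduces dosages exactly", {
  spec <- cohort_spec(40, study_panel("athletes"), seed = 7)
  g <- simulate_genotypes(spec)
  g$dosages[3, 2] <- NA_integer_  # inject a missing call
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, path)
  ea <- stats::setNames(g$panel$effect_allele, g$panel$rsid)
  back <- read_vcf(path, ea)
  idx <- match(g$panel$rsid, back$panel$rsid)
  expect_identical(unname(back$dosages[, idx]), unname(g$dosages))
  expect_identical(back$individual_ids, g$individual_ids)
})

test_that("flipping allele orientation maps every dosage d to 2 - d", {
  spec <- cohort_spec(30, tiny_panel(4), seed = 9)
  g <- simulate_genotypes(spec)
  g$dosages[1, 1] <- NA_integer_
  fl <- flip_effect_alleles(g)
  expect_identical(unname(fl$dosages), unname(2L - g$dosages))
  expect_identical(fl$panel$effect_allele, g$panel$other_allele)
  expect_equal(fl$panel$maf, 1 - g$panel$maf)
  expect_identical(flip_effect_alleles(fl)$dosages, g$dosages)
})

test_that("dosage TSV round-trips including missing values", {
  spec <- cohort_spec(15, tiny_panel(3), seed = 13)
  g <- simulate_genotypes(spec)
  g$dosages[2, 3] <- NA_integer_
  path <- tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  back <- read_dosage_tsv(path, panel = g$panel)
  expect_identical(back$dosages, g$dosages)
})

test_that("summary-statistics reader types, filters and reports rows", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(study_associations(), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st <- read_summary_stats(path)
  expect_equal(nrow(st), 20)  # 5 variants x 4 traits
  expect_type(st$beta, "double")
  expect_equal(st$p[st$rsid == "rs190930099" &
                      st$trait == "testosterone"], 8.1e-11)

  # p = 0 and unparseable rows are rejected with line numbers
  df <- study_associations()
  df$p[2] <- 0
  df$beta[5] <- "not_a_number"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(st2 <- read_summary_stats(path), "line")
  expect_equal(nrow(st2), 18)

  # a missing required column is named
  df2 <- study_associations()
  names(df2)[names(df2) == "beta"] <- "effect"
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "beta")
})

test_that("phenotype reader enforces unique ids and category vocabularies", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(id = c("a", "b", "c"), csa = c(5000, NA, 6100),
                   sex = c("male", "female", "male"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- read_phenotypes(path, categories = list(sex = c("female", "male")))
  expect_true(is.na(ph$csa[2]))  # missing kept as NA, excluded listwise later
  expect_s3_class(ph$sex, "factor")

  df$id[2] <- "a"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(path), "duplicate")

  df$id[2] <- "b"; df$sex[1] <- "unknown"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(path,
                               categories = list(sex = c("female", "male"))),
               "female, male")
})

test_that("result writing is deterministic and handles empty tables", {
  dir1 <- tempfile(); dir2 <- tempfile()
  tabs <- list(res = data.frame(rsid = c("rs1", "rs2"), p = c(0.01, 0.2)),
               empty = data.frame(rsid = character(), p = numeric()))
  suppressMessages(write_results(tabs, dir1))
  suppressMessages(write_results(tabs, dir2))
  expect_identical(readLines(file.path(dir1, "res.tsv")),
                   readLines(file.path(dir2, "res.tsv")))
  expect_equal(readLines(file.path(dir1, "empty.tsv")), "rsid\tp")
})
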