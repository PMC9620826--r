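test_that("write-then-read round trip is identity and order-invariant", {
  demos <- toy_demos(5L)
  icd <- as_icd(person_id = c("P01", "P01", "P02"),
                icd = c("571.5", "571.5", "E84.9"),
                flag = c(9L, 9L, 10L),
                occurrence_date = as.Date(c("2011-03-01", "2012-04-02",
                                            "2011-05-05")))
  gt <- validate_cohort_table(
    data.table(person_id = c("P01", "P02", "P03"),
               variant_id = "rs1", allele_count = c(0L, NA_integer_, 2L)),
    "genotype")

  for (tbl in list(list(demos, "demographics"), list(icd, "icd_occurrence"),
                   list(gt, "genotype"))) {
    path <- file.path(tempdir(), "roundtrip.tsv")
    write_cohort_table(tbl[[1]], path)
    back <- read_cohort_table(path, tbl[[2]], verbose = FALSE)
    expect_equal(as.data.frame(back), as.data.frame(tbl[[1]]))
  }

  ## missingness flag survives the round trip distinctly from zero
  path <- file.path(tempdir(), "gt.tsv")
  write_cohort_table(gt, path)
  back <- read_cohort_table(path, "genotype", verbose = FALSE)
  expect_identical(back$allele_count, c(0L, NA_integer_, 2L))

  ## shuffled input rows yield the identical canonical table
  path2 <- file.path(tempdir(), "shuffled.tsv")
  shuffled <- icd[c(3, 1, 2)]
  write_cohort_table(shuffled, path2)
  expect_equal(as.data.frame(read_cohort_table(path2, "icd_occurrence",
                                               verbose = FALSE)),
               as.data.frame(icd))
})

test_that("exact duplicate ICD rows are collapsed on load", {
  path <- file.path(tempdir(), "dup.tsv")
  writeLines(c("person_id\ticd\tflag\toccurrence_date",
               "P01\t571.5\t9\t2011-03-01",
               "P01\t571.5\t9\t2011-03-01",
               "P02\tE84.9\t10\t2011-05-05"), path)
  icd <- read_cohort_table(path, "icd_occurrence", verbose = FALSE)
  expect_equal(nrow(icd), 2L)
})

test_that("schema and invariant violations raise informative errors", {
  d <- data.table(person_id = sprintf("P%02d", 1:5),
                  sex = "female",
                  first_visit_date = as.Date("2012-01-01"),
                  last_visit_date = as.Date("2013-01-01"))
  d$last_visit_date[5] <- as.Date("2011-01-01")
  path <- file.path(tempdir(), "demo_bad.tsv")
  fwrite(d, path, sep = "\t")
  expect_error(read_cohort_table(path, "demographics", verbose = FALSE),
               "row\\(s\\) 5")

  path2 <- file.path(tempdir(), "demo_nocol.tsv")
  fwrite(d[, !"sex"], path2, sep = "\t")
  expect_error(read_cohort_table(path2, "demographics", verbose = FALSE),
               "sex")

  expect_error(as_icd(person_id = "P01", icd = "571.5", flag = 11L,
                      occurrence_date = as.Date("2011-01-01")),
               "flag must be 9 or 10")
  expect_error(validate_cohort_table(
    data.table(person_id = "P01", variant_id = "rs1", allele_count = 3L),
    "genotype"), "allele_count")
  expect_error(validate_cohort_table(
    transform(as.data.frame(toy_demos(2L)), sex = "unknown"),
    "demographics"), "male/female")

  path3 <- file.path(tempdir(), "baddate.tsv")
  writeLines(c("person_id\ticd\tflag\toccurrence_date",
               "P01\t571.5\t9\tnot-a-date"), path3)
  expect_error(read_cohort_table(path3, "icd_occurrence", verbose = FALSE),
               "unparseable date")
})

test_that("timestamps are truncated to calendar dates on load", {
  path <- file.path(tempdir(), "ts.tsv")
  writeLines(c("person_id\ticd\tflag\toccurrence_date",
               "P01\t571.5\t9\t2011-03-01 13:45:00"), path)
  icd <- read_cohort_table(path, "icd_occurrence", verbose = FALSE)
  expect_equal(as.Date(icd$occurrence_date), as.Date("2011-03-01"))
})

test_that("validate_cohort flags orphans hard and warns on empty ICD", {
  demos <- toy_demos(3L)
  ok <- as_icd(person_id = "P01", icd = "571.5", flag = 9L,
               occurrence_date = as.Date("2011-01-01"))
  rep <- validate_cohort(demos, ok)
  expect_length(rep$orphans, 0L)

  orphan <- as_icd(person_id = c("P01", "X9"), icd = "571.5", flag = 9L,
                   occurrence_date = as.Date("2011-01-01"))
  expect_error(validate_cohort(demos, orphan), "X9")

  empty <- ok[0]
  expect_warning(validate_cohort(demos, empty), "empty")
})

test_that("VCF genotypes map GT fields to allele counts", {
  path <- file.path(tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T,G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "300", ".", "G", "A", ".", "PASS", ".", "GT",
          "./.", "1|0", "0|0", sep = "\t")), path)
  gt <- read_genotypes_vcf(path, verbose = FALSE)
  ## multiallelic rs2 dropped; 2 variants x 3 samples remain
  expect_equal(sort(unique(gt$variant_id)), c("1:300", "rs1"))
  expect_equal(gt[variant_id == "rs1"][order(person_id), allele_count],
               c(0L, 1L, 2L))
  expect_equal(gt[variant_id == "1:300"][order(person_id), allele_count],
               c(NA_integer_, 1L, 0L))
})
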