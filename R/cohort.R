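## Schemas for the cohort input tables. Each table is a keyed data.table;
## loading sorts on the key so row order of the input file never matters.
.cohort_schemas <- list(
  demographics = list(
    required = c("person_id", "sex", "first_visit_date", "last_visit_date"),
    optional = c("birth_date", "age_first_visit"),
    dates = c("first_visit_date", "last_visit_date", "birth_date"),
    key = "person_id"
  ),
  icd_occurrence = list(
    required = c("person_id", "icd", "flag", "occurrence_date"),
    optional = character(0),
    dates = "occurrence_date",
    key = c("person_id", "icd", "flag", "occurrence_date")
  ),
  phecode_occurrence = list(
    required = c("person_id", "phecode", "occurrence_date"),
    optional = character(0),
    dates = "occurrence_date",
    key = c("person_id", "phecode", "occurrence_date")
  ),
  genotype = list(
    required = c("person_id", "variant_id", "allele_count"),
    optional = character(0),
    dates = character(0),
    key = c("person_id", "variant_id")
  )
)

#' Read and validate a cohort input table
#'
#' Reads a delimited file (delimiter sniffed from the extension: `.csv` is
#' comma, anything else tab, overridable via `delim`), checks the header
#' against the schema, parses ISO-8601 dates (timestamps are truncated to
#' day resolution), enforces the schema's invariants, and removes duplicate
#' rows according to the type's rule. The result is sorted on the schema
#' key, so shuffled input yields an identical canonical table.
#'
#' Schema-specific validation:
#' \describe{
#'   \item{demographics}{`person_id` unique; `last_visit_date >=
#'     first_visit_date`; `sex` in \{male, female\} (case-insensitive,
#'     stored lower-case); no missing fields.}
#'   \item{icd_occurrence}{`flag` in \{9, 10\}; exact duplicate rows
#'     collapsed (repeat same-day postings carry no information under the
#'     binary phecode-indicator model).}
#'   \item{phecode_occurrence}{unique on (person, phecode, date).}
#'   \item{genotype}{`allele_count` in \{0, 1, 2\} or missing (`NA`);
#'     conflicting duplicate (person, variant) rows are an error.}
#' }
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of `"demographics"`, `"icd_occurrence"`,
#'   `"phecode_occurrence"`, `"genotype"`.
#' @param delim Optional delimiter override.
#' @param verbose Log row counts with `message()`.
#' @return A validated, keyed `data.table`.
#' @export
read_cohort_table <- function(path, schema, delim = NULL, verbose = TRUE) {
  schema <- match.arg(schema, names(.cohort_schemas))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sc <- .cohort_schemas[[schema]]
  dt <- data.table::fread(path, sep = .sniff_delim(path, delim),
                          colClasses = "character", na.strings = "NA",
                          showProgress = FALSE)
  .require_cols(dt, sc$required, sprintf("%s file '%s'", schema, path))
  dt <- dt[, intersect(c(sc$required, sc$optional), names(dt)), with = FALSE]
  for (dc in intersect(sc$dates, names(dt))) {
    data.table::set(dt, j = dc,
                    value = .parse_dates(dt[[dc]], dc,
                                         allow_na = dc == "birth_date"))
  }
  dt <- validate_cohort_table(dt, schema, verbose = verbose)
  .msg(verbose, "%s: read %d row(s) from %s", schema, nrow(dt), path)
  dt
}

#' Validate an in-memory cohort table
#'
#' Applies the same invariants and deduplication as [read_cohort_table()]
#' to a table constructed in code.
#'
#' @param dt A `data.frame` or `data.table` with the schema's columns.
#' @inheritParams read_cohort_table
#' @return A validated, keyed `data.table` (a copy).
#' @export
validate_cohort_table <- function(dt, schema, verbose = FALSE) {
  schema <- match.arg(schema, names(.cohort_schemas))
  sc <- .cohort_schemas[[schema]]
  dt <- data.table::as.data.table(dt)
  .require_cols(dt, sc$required, schema)

  if (schema == "demographics") {
    if (anyNA(dt[, sc$required, with = FALSE])) {
      stop("demographics: missing values in required fields", call. = FALSE)
    }
    dt[, sex := tolower(trimws(sex))]
    bad_sex <- setdiff(unique(dt$sex), c("male", "female"))
    if (length(bad_sex) > 0L) {
      stop(sprintf("demographics: sex must be male/female, found: %s",
                   paste(bad_sex, collapse = ", ")), call. = FALSE)
    }
    bad <- which(dt$last_visit_date < dt$first_visit_date)
    if (length(bad) > 0L) {
      stop(sprintf("demographics: last_visit_date < first_visit_date on data row(s) %s",
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
    dt <- unique(dt)
    if (anyDuplicated(dt$person_id) > 0L) {
      dup <- unique(dt$person_id[duplicated(dt$person_id)])
      stop(sprintf("demographics: duplicated person_id(s) with conflicting rows: %s",
                   paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
    }
    if ("age_first_visit" %in% names(dt)) {
      dt[, age_first_visit := as.numeric(age_first_visit)]
    }
  } else if (schema == "icd_occurrence") {
    dt[, flag := as.integer(flag)]
    bad <- which(!dt$flag %in% c(9L, 10L))
    if (length(bad) > 0L) {
      stop(sprintf("icd_occurrence: flag must be 9 or 10, violated on data row(s) %s",
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
    if (anyNA(dt[, sc$required, with = FALSE])) {
      stop("icd_occurrence: missing values", call. = FALSE)
    }
    dt[, icd := trimws(icd)]
    n0 <- nrow(dt)
    dt <- unique(dt)
    if (nrow(dt) < n0) {
      .msg(verbose, "icd_occurrence: collapsed %d duplicate row(s)",
           n0 - nrow(dt))
    }
  } else if (schema == "phecode_occurrence") {
    if (anyNA(dt[, sc$required, with = FALSE])) {
      stop("phecode_occurrence: missing values", call. = FALSE)
    }
    dt <- unique(dt)
  } else if (schema == "genotype") {
    dt[, allele_count := as.integer(allele_count)]
    bad <- which(!(is.na(dt$allele_count) | dt$allele_count %in% 0:2))
    if (length(bad) > 0L) {
      stop(sprintf("genotype: allele_count must be 0, 1, 2 or NA; violated on data row(s) %s",
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
    dt <- unique(dt)
    if (anyDuplicated(dt, by = c("person_id", "variant_id")) > 0L) {
      stop("genotype: conflicting duplicate (person_id, variant_id) rows",
           call. = FALSE)
    }
  }
  data.table::setkeyv(dt, sc$key)
  dt[]
}

#' Write a cohort or result table to a delimited file
#'
#' Dates are written as ISO-8601 and missing values as the literal `NA`, so
#' a write-then-read round trip through [read_cohort_table()] is identity.
#'
#' @param x A `data.table`/`data.frame`.
#' @param path Output path; delimiter sniffed from extension unless `delim`
#'   is given.
#' @param delim Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path, delim = NULL) {
  data.table::fwrite(x, path, sep = .sniff_delim(path, delim), na = "NA",
                     quote = FALSE, dateTimeAs = "ISO", logical01 = FALSE)
  invisible(path)
}

#' Cross-check ICD occurrences against demographics
#'
#' Every person with an ICD occurrence must be present in demographics:
#' silently dropping orphans would invisibly change the cohort size N that
#' enters the weight formula, so orphans are a hard error.
#'
#' @param demos Validated demographics table.
#' @param icd Validated ICD occurrence table.
#' @return Invisibly, a report list with `n_persons`, `n_icd_occurrences`,
#'   and `orphans` (empty on success). An empty ICD table is allowed but
#'   warned about.
#' @export
validate_cohort <- function(demos, icd) {
  orphans <- setdiff(unique(icd$person_id), demos$person_id)
  if (length(orphans) > 0L) {
    stop(sprintf("ICD occurrences reference person_id(s) absent from demographics: %s",
                 paste(head(orphans, 10L), collapse = ", ")), call. = FALSE)
  }
  if (nrow(icd) == 0L) {
    warning("ICD occurrence table is empty (zero occurrences)", call. = FALSE)
  }
  invisible(list(n_persons = nrow(demos), n_icd_occurrences = nrow(icd),
                 orphans = character(0)))
}

#' Read genotypes from a VCF file
#'
#' Reads biallelic sites from a VCF (sites with multiple ALT alleles are
#' dropped with a message) and converts the GT field to alternate-allele
#' counts: `0/0` is 0, `0/1` or `1/0` is 1, `1/1` is 2, and `./.` or `.` is
#' missing. Phased separators (`|`) are treated like `/`. Sample names
#' become `person_id`s; the VCF ID column (or `CHROM:POS` when ID is `.`)
#' becomes `variant_id`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param verbose Log counts.
#' @return A validated genotype `data.table`.
#' @export
read_genotypes_vcf <- function(path, verbose = TRUE) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!biallelic)) {
    .msg(verbose, "dropped %d multiallelic site(s)", sum(!biallelic))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  vid <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  gtn <- gsub("|", "/", gt, fixed = TRUE)
  counts <- matrix(NA_integer_, nrow = nrow(gtn), ncol = ncol(gtn))
  counts[gtn == "0/0"] <- 0L
  counts[gtn %in% c("0/1", "1/0")] <- 1L
  counts[gtn == "1/1"] <- 2L
  out <- data.table(
    person_id = rep(colnames(gt), each = nrow(gtn)),
    variant_id = rep(vid, times = ncol(gtn)),
    allele_count = as.integer(counts)
  )
  validate_cohort_table(out, "genotype", verbose = verbose)
}
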