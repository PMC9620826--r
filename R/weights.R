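#' Compute inverse-log-prevalence phecode weights
#'
#' Assigns phecode j the weight `w_j = log10(N / n_j)`, where N is the
#' total number of individuals in the cohort (all demographics rows, not
#' just persons with at least one phecode) and n_j is the number of
#' individuals with at least one occurrence of phecode j. Rare phecodes
#' thus carry more weight; a phecode present in everyone carries weight 0.
#'
#' Phecodes never observed in the cohort have no defined weight
#' (`log10(N/0)` is undefined) and are simply absent from the returned
#' table; downstream scoring treats them as contributing 0.
#'
#' @param demos Validated demographics table (defines N).
#' @param phe Phecode occurrence table; every person in it must appear in
#'   `demos`, otherwise the denominator N would be silently wrong and an
#'   error is raised.
#' @param exclude_persons Optional character vector of person_ids to drop
#'   from both N and the n_j counts — e.g. diagnosed cases, when weights
#'   are intended for analyses of undiagnosed individuals. Default: none.
#' @return A `WeightTable` `data.table` with columns `phecode`,
#'   `n_persons`, `cohort_size`, `weight`, keyed on phecode.
#' @export
calc_weights <- function(demos, phe, exclude_persons = NULL) {
  .require_cols(phe, c("person_id", "phecode"), "phecode occurrences")
  if (nrow(demos) == 0L) stop("demographics table is empty", call. = FALSE)
  demos_use <- demos
  phe_use <- phe
  if (!is.null(exclude_persons) && length(exclude_persons) > 0L) {
    demos_use <- demos[!person_id %in% exclude_persons]
    phe_use <- phe[!person_id %in% exclude_persons]
    if (nrow(demos_use) == 0L) {
      stop("all persons excluded from weight calculation", call. = FALSE)
    }
  }
  orphans <- setdiff(unique(phe_use$person_id), demos_use$person_id)
  if (length(orphans) > 0L) {
    stop(sprintf("phecode occurrences reference person_id(s) absent from demographics: %s",
                 paste(head(orphans, 10L), collapse = ", ")), call. = FALSE)
  }
  Ntot <- nrow(demos_use)
  wt <- phe_use[, .(n_persons = data.table::uniqueN(person_id)), by = phecode]
  wt[, cohort_size := Ntot]
  wt[, weight := log10(Ntot / n_persons)]
  data.table::setkeyv(wt, "phecode")
  wt[]
}

#' Load a pre-calculated weight table
#'
#' Supports externally supplied weights (e.g. derived from a large
#' reference EHR cohort whose phecode prevalences better reflect the
#' population of interest than a small user cohort would). The file needs
#' `phecode` and `weight` columns; `n_persons` and `cohort_size` are
#' optional and recorded as missing when absent.
#'
#' @param path Path to a delimited file.
#' @param delim Optional delimiter override.
#' @param verbose Log row count.
#' @return A `WeightTable` `data.table`. Duplicate phecodes and negative
#'   weights are errors.
#' @export
load_weights <- function(path, delim = NULL, verbose = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  dt <- data.table::fread(path, sep = .sniff_delim(path, delim),
                          colClasses = "character", na.strings = "NA",
                          showProgress = FALSE)
  .require_cols(dt, c("phecode", "weight"), sprintf("weight file '%s'", path))
  wt <- data.table(
    phecode = dt$phecode,
    n_persons = if ("n_persons" %in% names(dt)) as.integer(dt$n_persons)
                else NA_integer_,
    cohort_size = if ("cohort_size" %in% names(dt))
                    as.integer(dt$cohort_size) else NA_integer_,
    weight = as.numeric(dt$weight)
  )
  if (anyDuplicated(wt$phecode) > 0L) {
    dup <- unique(wt$phecode[duplicated(wt$phecode)])
    stop(sprintf("weight file: duplicated phecode(s): %s",
                 paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(wt$weight)) stop("weight file: missing weight values",
                             call. = FALSE)
  if (any(wt$weight < 0)) {
    stop(sprintf("weight file: negative weight(s) for phecode(s): %s",
                 paste(head(wt$phecode[wt$weight < 0], 5L), collapse = ", ")),
         call. = FALSE)
  }
  data.table::setkeyv(wt, "phecode")
  .msg(verbose, "weights: %d phecode(s) loaded from %s", nrow(wt), path)
  wt[]
}
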