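#' Map ICD occurrences to phecode occurrences
#'
#' Joins ICD occurrences to the ICD-to-phecode map on the exact
#' (code, version flag) pair; codes are whitespace-trimmed and upper-cased
#' on both sides before the join, and no prefix/rollup matching is
#' attempted (phecode maps enumerate codes at full code level). One ICD
#' occurrence can yield several phecode occurrences when the code maps to
#' multiple phecodes. The result is deduplicated on
#' (person, phecode, date).
#'
#' When `exclude_dx_icd` is supplied, occurrences of those diagnostic ICD
#' codes are removed *before* the join. This excludes codes that denote a
#' genetic diagnosis itself, so that scores of diagnosed and undiagnosed
#' individuals can be compared without the diagnosis code trivially
#' inflating the cases' scores. Exclusion is global across diseases by
#' default; pass a subset of the diagnostic map to exclude per-disease.
#'
#' Unmapped ICD codes are expected in real feeds and are not an error;
#' their count and the ten most frequent offenders are logged.
#'
#' @param icd Validated ICD occurrence table.
#' @param map `icd_phecode` map (see [load_map()]).
#' @param exclude_dx_icd Optional `disease_dx_icd` map of diagnostic codes
#'   to drop before mapping; `NULL` or empty disables exclusion.
#' @param verbose Log mapping statistics.
#' @return A phecode occurrence `data.table`, keyed on
#'   (person_id, phecode, occurrence_date). Empty with a warning if nothing
#'   maps.
#' @export
map_icd_to_phecodes <- function(icd, map, exclude_dx_icd = NULL,
                                verbose = TRUE) {
  map <- data.table::as.data.table(map)
  .require_cols(map, c("icd", "flag", "phecode"), "icd_phecode map")
  if (nrow(map) == 0L) stop("ICD-phecode map is empty", call. = FALSE)
  .require_cols(icd, c("person_id", "icd", "flag", "occurrence_date"),
                "icd occurrences")

  icd2 <- data.table::copy(icd)[, icd := .norm_icd(icd)]
  map2 <- unique(data.table::copy(map)[, icd := .norm_icd(icd)])

  if (!is.null(exclude_dx_icd) && nrow(exclude_dx_icd) > 0L) {
    dx <- unique(data.table::as.data.table(exclude_dx_icd)[
      , .(icd = .norm_icd(icd), flag = as.integer(flag))])
    n0 <- nrow(icd2)
    icd2 <- icd2[!dx, on = c("icd", "flag")]
    .msg(verbose, "excluded %d occurrence(s) of %d diagnostic ICD code(s)",
         n0 - nrow(icd2), nrow(dx))
  }

  joined <- merge(icd2, map2[, .(icd, flag, phecode)], by = c("icd", "flag"),
                  allow.cartesian = TRUE)

  if (isTRUE(verbose)) {
    unmapped <- icd2[!unique(map2[, .(icd, flag)]), on = c("icd", "flag")]
    if (nrow(unmapped) > 0L) {
      top <- unmapped[, .N, by = .(icd, flag)][order(-N)][seq_len(min(10L, .N))]
      .msg(verbose, "%d ICD occurrence(s) of %d code(s) had no phecode mapping; most frequent: %s",
           nrow(unmapped), data.table::uniqueN(unmapped[, .(icd, flag)]),
           paste(sprintf("%s(%d) x%d", top$icd, top$flag, top$N),
                 collapse = ", "))
    }
  }

  out <- unique(joined[, .(person_id, phecode, occurrence_date)])
  if (nrow(out) == 0L) {
    warning("no ICD occurrences mapped to any phecode", call. = FALSE)
  }
  data.table::setkeyv(out, c("person_id", "phecode", "occurrence_date"))
  .msg(verbose, "mapped %d ICD occurrence(s) to %d phecode occurrence(s)",
       nrow(icd2), nrow(out))
  out[]
}
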