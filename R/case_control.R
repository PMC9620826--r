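#' Assign case/control status from diagnostic ICD codes
#'
#' For each disease in the diagnostic map and each person in the cohort,
#' counts the number of distinct calendar dates on which the person has
#' *any* of the disease's diagnostic ICD codes (codes are pooled: code A on
#' Monday and code B on Tuesday make two distinct dates). A person is a
#' `case` with at least `case_min_dates` distinct dates (default 2 —
#' requiring two distinct dates rather than one improves positive
#' predictive value of billing-code diagnoses), a `control` with zero, and
#' `neither` otherwise. Multiple postings on one date count once: "distinct
#' dates" is a calendar-day concept.
#'
#' @param icd Validated ICD occurrence table.
#' @param demos Validated demographics table; every person appears in the
#'   output for every mapped disease.
#' @param dx_map `disease_dx_icd` map; must be nonempty.
#' @param case_min_dates Minimum distinct diagnostic dates for case status
#'   (>= 1). With 1, the `neither` category is empty.
#' @return A `DxStatusTable` `data.table` with columns `person_id`,
#'   `disease_id`, `status`, `n_dx_dates`, keyed on (person_id,
#'   disease_id).
#' @export
assign_dx_status <- function(icd, demos, dx_map, case_min_dates = 2L) {
  dx_map <- data.table::as.data.table(dx_map)
  .require_cols(dx_map, c("disease_id", "icd", "flag"), "diagnostic ICD map")
  if (nrow(dx_map) == 0L) stop("diagnostic ICD map is empty", call. = FALSE)
  stopifnot(case_min_dates >= 1L)
  .require_cols(icd, c("person_id", "icd", "flag", "occurrence_date"),
                "icd occurrences")

  icd2 <- data.table::copy(icd)[, icd := .norm_icd(icd)]
  dxm <- unique(data.table::copy(dx_map)[, icd := .norm_icd(icd)])
  hits <- merge(icd2, dxm, by = c("icd", "flag"), allow.cartesian = TRUE)
  cnt <- hits[, .(n_dx_dates = data.table::uniqueN(occurrence_date)),
              by = .(person_id, disease_id)]

  grid <- data.table::CJ(person_id = demos$person_id,
                         disease_id = unique(dxm$disease_id), unique = TRUE)
  out <- cnt[grid, on = c("person_id", "disease_id")]
  out[is.na(n_dx_dates), n_dx_dates := 0L]
  out[, status := data.table::fifelse(
    n_dx_dates >= case_min_dates, "case",
    data.table::fifelse(n_dx_dates == 0L, "control", "neither"))]
  data.table::setcolorder(out, c("person_id", "disease_id", "status",
                                 "n_dx_dates"))
  data.table::setkeyv(out, c("person_id", "disease_id"))
  out[]
}

#' Compare scores between cases and controls
#'
#' Validation step: diagnosed individuals should score higher for their
#' disease than undiagnosed ones. Per disease, persons with `neither`
#' status are excluded and the chosen score column is regressed (OLS) on a
#' case indicator plus the covariates; the case-indicator coefficient, its
#' standard error, t statistic and two-sided p-value are returned together
#' with group counts.
#'
#' Diseases with fewer than `min_cases` cases (default 50, a reporting
#' screen that keeps estimates stable — it never affects status
#' assignment) or fewer than `min_controls` controls are skipped with a
#' warning.
#'
#' @param scores `ScoreTable`, optionally with `residual_score`.
#' @param status `DxStatusTable` from [assign_dx_status()].
#' @param demos Validated demographics table.
#' @param covariates Covariate names (see [derive_covariates()]); empty for
#'   an unadjusted comparison.
#' @param score_column `"residual_score"` (default when present) or
#'   `"score"`.
#' @param min_cases,min_controls Minimum group sizes for a disease to be
#'   tested.
#' @param verbose Log skipped diseases.
#' @return A `data.table` with one row per tested disease: `disease_id`,
#'   `coef`, `se`, `t`, `p`, `n_case`, `n_control`.
#' @export
compare_scores_by_status <- function(scores, status, demos,
                                     covariates = c("sex", "age_first_visit",
                                                    "visit_span"),
                                     score_column = NULL, min_cases = 50L,
                                     min_controls = 2L, verbose = TRUE) {
  score_column <- score_column %||%
    (if ("residual_score" %in% names(scores)) "residual_score" else "score")
  .require_cols(scores, c("person_id", "disease_id", score_column), "scores")
  .require_cols(status, c("person_id", "disease_id", "status"), "status")

  X <- .covariate_matrix(demos, covariates)
  rownames(X) <- demos$person_id
  dat <- merge(data.table::as.data.table(scores),
               data.table::as.data.table(status)[, .(person_id, disease_id,
                                                     status)],
               by = c("person_id", "disease_id"))
  dat <- dat[status != "neither"]

  res <- list()
  for (dis in unique(dat$disease_id)) {
    d <- dat[disease_id == dis]
    nca <- sum(d$status == "case")
    nco <- sum(d$status == "control")
    if (nca < min_cases || nco < min_controls) {
      .msg(verbose, "disease %s skipped: %d case(s), %d control(s)",
           dis, nca, nco)
      next
    }
    Xd <- cbind(X[d$person_id, , drop = FALSE],
                case = as.numeric(d$status == "case"))
    fit <- .ols(d[[score_column]], Xd)
    res[[dis]] <- data.table(
      disease_id = dis, coef = unname(fit$coef["case"]),
      se = unname(fit$se["case"]), t = unname(fit$t["case"]),
      p = unname(fit$p["case"]), n_case = nca, n_control = nco
    )
  }
  if (length(res) == 0L) {
    warning("no disease met the case/control size thresholds", call. = FALSE)
    return(data.table(disease_id = character(0), coef = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0),
                      n_case = integer(0), n_control = integer(0)))
  }
  data.table::rbindlist(res)[]
}
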