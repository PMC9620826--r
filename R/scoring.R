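#' Calculate phenotype risk scores
#'
#' For person i and disease k the raw score is
#' `s_ik = sum over phecodes j in P_k of w_j * x_ij`, where `P_k` is the
#' disease's phecode set, `w_j` the phecode's weight, and `x_ij` 1 if
#' person i has at least one occurrence of phecode j and 0 otherwise.
#' The full person-by-disease grid is materialized: persons with no
#' qualifying occurrences get explicit zero scores, so that downstream
#' residualization sees the whole cohort including its zero-inflation.
#'
#' Disease-map phecodes absent from the weight table contribute 0 to every
#' score and are warned about once (such phecodes were never observed in
#' the weighting cohort, so their weight is undefined).
#'
#' @param weights `WeightTable` from [calc_weights()] or [load_weights()].
#' @param phe Phecode occurrence table.
#' @param disease_map `disease_phecode` map.
#' @param demos Validated demographics table; defines the person set.
#' @return A `ScoreTable` `data.table` with columns `person_id`,
#'   `disease_id`, `score`, keyed on (person_id, disease_id).
#' @export
calc_scores <- function(weights, phe, disease_map, demos) {
  .require_cols(weights, c("phecode", "weight"), "weights")
  .require_cols(disease_map, c("disease_id", "phecode"), "disease map")
  .require_cols(phe, c("person_id", "phecode"), "phecode occurrences")
  orphans <- setdiff(unique(phe$person_id), demos$person_id)
  if (length(orphans) > 0L) {
    stop(sprintf("phecode occurrences reference person_id(s) absent from demographics: %s",
                 paste(head(orphans, 10L), collapse = ", ")), call. = FALSE)
  }
  unweighted <- setdiff(unique(disease_map$phecode), weights$phecode)
  if (length(unweighted) > 0L) {
    warning(sprintf("%d disease-map phecode(s) have no weight and contribute 0: %s",
                    length(unweighted),
                    paste(head(unweighted, 10L), collapse = ", ")),
            call. = FALSE)
  }
  dm <- merge(unique(data.table::as.data.table(disease_map)[
                , .(disease_id, phecode)]),
              weights[, .(phecode, weight)], by = "phecode")
  x <- unique(data.table::as.data.table(phe)[, .(person_id, phecode)])
  hits <- merge(x, dm, by = "phecode",
                allow.cartesian = TRUE)[, .(score = sum(weight)),
                                        by = .(person_id, disease_id)]
  grid <- data.table::CJ(person_id = demos$person_id,
                         disease_id = unique(disease_map$disease_id),
                         unique = TRUE)
  out <- hits[grid, on = c("person_id", "disease_id")]
  out[is.na(score), score := 0]
  data.table::setkeyv(out, c("person_id", "disease_id"))
  out[]
}

#' Residualize and standardize phenotype risk scores
#'
#' Per disease, fits an ordinary-least-squares model of the raw score on an
#' intercept plus the requested covariates (default: biological sex, age at
#' first visit, and elapsed time between first and last visits) and returns
#' the residuals rescaled to unit variance. The residual standard deviation
#' uses denominator `n - p` with `p` the number of fitted parameters, so
#' per-disease residual scores have mean 0 (exactly, via the intercept) and
#' unit variance under that convention, making scores comparable from one
#' disease to another.
#'
#' Covariates with zero variance are dropped with a warning. A disease with
#' zero residual variance (scores exactly linear in the covariates), or a
#' fit with `n <= p`, is an error.
#'
#' @param demos Validated demographics table. Age at first visit is taken
#'   from an `age_first_visit` column or derived from `birth_date` (see
#'   [derive_covariates()]).
#' @param scores `ScoreTable` from [calc_scores()].
#' @param covariates Character vector of covariate names; the empty vector
#'   reduces residualization to per-disease z-scoring.
#' @return The score table with a `residual_score` column added.
#' @export
calc_residual_scores <- function(demos, scores,
                                 covariates = c("sex", "age_first_visit",
                                                "visit_span")) {
  .require_cols(scores, c("person_id", "disease_id", "score"), "scores")
  sc <- data.table::as.data.table(scores)
  if (!setequal(unique(sc$person_id), demos$person_id)) {
    stop("score table persons do not match demographics", call. = FALSE)
  }
  X <- .covariate_matrix(demos, covariates)
  wide <- data.table::dcast(sc, person_id ~ disease_id, value.var = "score")
  wide <- wide[match(demos$person_id, wide$person_id)]
  diseases <- setdiff(names(wide), "person_id")
  Y <- as.matrix(wide[, diseases, with = FALSE])

  n <- nrow(X)
  qx <- qr(X)
  r <- qx$rank
  if (n <= r) {
    stop(sprintf("cannot residualize: n = %d persons <= p = %d parameters",
                 n, r), call. = FALSE)
  }
  res <- qr.resid(qx, Y)
  sdv <- sqrt(colSums(res^2) / (n - r))
  degenerate <- diseases[sdv < .Machine$double.eps^0.5 * pmax(1, apply(abs(Y), 2, max))]
  if (length(degenerate) > 0L) {
    stop(sprintf("zero residual variance for disease(s): %s",
                 paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  rs <- sweep(res, 2L, sdv, "/")

  long <- data.table(
    person_id = rep(demos$person_id, times = length(diseases)),
    disease_id = rep(diseases, each = n),
    residual_score = as.numeric(rs)
  )
  out <- merge(sc[, .(person_id, disease_id, score)], long,
               by = c("person_id", "disease_id"))
  data.table::setkeyv(out, c("person_id", "disease_id"))
  out[]
}
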