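#' Encode genotypes under an inheritance model
#'
#' Converts alternate-allele counts (0/1/2) into regression predictors:
#' \describe{
#'   \item{additive}{one column, the allele count itself;}
#'   \item{dominant}{one indicator, 1 for carriers (count >= 1);}
#'   \item{recessive}{one indicator, 1 only for homozygous-alternate
#'     (count = 2);}
#'   \item{genotypic}{two indicators, `het` (count = 1) and `hom_alt`
#'     (count = 2), against a homozygous-reference baseline.}
#' }
#'
#' @param allele_count Integer vector with values in \{0, 1, 2\}; missing
#'   values are not allowed here (exclude them before encoding).
#' @param model Model name.
#' @return A numeric matrix with one row per input value and named
#'   column(s) (`additive`, `dominant`, `recessive`, or `het`/`hom_alt`).
#' @export
encode_genotype <- function(allele_count,
                            model = c("additive", "dominant", "recessive",
                                      "genotypic")) {
  model <- match.arg(model)
  if (anyNA(allele_count) || !all(allele_count %in% 0:2)) {
    stop("allele_count must be 0, 1 or 2 with no missing values",
         call. = FALSE)
  }
  ac <- as.numeric(allele_count)
  switch(model,
    additive = cbind(additive = ac),
    dominant = cbind(dominant = as.numeric(ac >= 1)),
    recessive = cbind(recessive = as.numeric(ac == 2)),
    genotypic = cbind(het = as.numeric(ac == 1),
                      hom_alt = as.numeric(ac == 2))
  )
}

#' Test score-genotype associations
#'
#' For each requested disease-variant pair, regresses the score on the
#' encoded genotype term(s) plus an intercept and covariates by OLS, and
#' reports per genetic term the coefficient, standard error, t statistic
#' and two-sided p-value (t distribution with `n_used - p` degrees of
#' freedom), together with genotype counts over the *full* cohort
#' (including missing genotypes — counts are model-independent). Persons
#' with a missing genotype, or with no genotype record for the variant,
#' are excluded pairwise per variant, so each pair uses the maximal
#' available sample.
#'
#' A rank-deficient design (e.g. the recessive encoding when the cohort
#' has no homozygous-alternate carriers) yields a row flagged
#' `estimable = FALSE` with NA statistics rather than an error.
#'
#' @param scores `ScoreTable`, optionally with `residual_score`.
#' @param genotypes Validated genotype table.
#' @param demos Validated demographics table; defines the cohort over which
#'   genotype counts are reported.
#' @param pairs `data.table`/`data.frame` with columns `disease_id`,
#'   `variant_id` naming which variants to test against which diseases.
#' @param model Inheritance encoding (see [encode_genotype()]).
#' @param covariates Covariate names; empty for an unadjusted test.
#' @param score_column `"residual_score"` (default when present — residual
#'   scores are comparable across diseases) or `"score"`.
#' @param adjust `"none"` (default) or `"bonferroni"`, which adds a
#'   `p_adjusted` column multiplying p by the number of tested pairs.
#' @param exclude_persons Optional person_ids to drop from the analysis
#'   (e.g. diagnosed cases), applied before pairwise missing-genotype
#'   exclusion; genotype counts are still reported over the full cohort.
#' @param verbose Log per-pair notes.
#' @return An `AssociationResult` `data.table`, one row per pair x genetic
#'   term: `disease_id`, `variant_id`, `model`, `term`, `coef`, `se`, `t`,
#'   `p`, `n_hom_ref`, `n_het`, `n_hom_alt`, `n_missing`, `n_used`,
#'   `estimable` (and `p_adjusted` if requested).
#' @export
run_associations <- function(scores, genotypes, demos, pairs,
                             model = c("additive", "dominant", "recessive",
                                       "genotypic"),
                             covariates = c("sex", "age_first_visit",
                                            "visit_span"),
                             score_column = NULL,
                             adjust = c("none", "bonferroni"),
                             exclude_persons = NULL, verbose = TRUE) {
  model <- match.arg(model)
  adjust <- match.arg(adjust)
  score_column <- score_column %||%
    (if ("residual_score" %in% names(scores)) "residual_score" else "score")
  pairs <- unique(data.table::as.data.table(pairs)[, .(disease_id,
                                                       variant_id)])
  .require_cols(scores, c("person_id", "disease_id", score_column), "scores")
  .require_cols(genotypes, c("person_id", "variant_id", "allele_count"),
                "genotypes")
  missing_dis <- setdiff(pairs$disease_id, unique(scores$disease_id))
  if (length(missing_dis) > 0L) {
    stop(sprintf("pair disease_id(s) absent from score table: %s",
                 paste(missing_dis, collapse = ", ")), call. = FALSE)
  }
  missing_var <- setdiff(pairs$variant_id, unique(genotypes$variant_id))
  if (length(missing_var) > 0L) {
    stop(sprintf("pair variant_id(s) absent from genotype table: %s",
                 paste(missing_var, collapse = ", ")), call. = FALSE)
  }

  X <- .covariate_matrix(demos, covariates)
  rownames(X) <- demos$person_id
  sc <- data.table::as.data.table(scores)
  gt <- data.table::as.data.table(genotypes)
  analysed <- demos$person_id
  if (!is.null(exclude_persons)) {
    analysed <- setdiff(analysed, exclude_persons)
  }

  out <- list()
  for (i in seq_len(nrow(pairs))) {
    dis <- pairs$disease_id[i]
    var <- pairs$variant_id[i]
    g_full <- gt[variant_id == var][match(demos$person_id, person_id),
                                    allele_count]
    counts <- c(n_hom_ref = sum(g_full == 0L, na.rm = TRUE),
                n_het = sum(g_full == 1L, na.rm = TRUE),
                n_hom_alt = sum(g_full == 2L, na.rm = TRUE),
                n_missing = sum(is.na(g_full)))
    y_all <- sc[disease_id == dis][match(demos$person_id, person_id)]
    use <- !is.na(g_full) & demos$person_id %in% analysed &
      !is.na(y_all[[score_column]])
    n_used <- sum(use)

    base <- data.table(disease_id = dis, variant_id = var, model = model)
    if (n_used == 0L) {
      .msg(verbose, "pair %s / %s: no usable genotypes", dis, var)
      terms <- colnames(encode_genotype(0L, model))
      out[[i]] <- cbind(base[rep(1L, length(terms))],
                        data.table(term = terms, coef = NA_real_,
                                   se = NA_real_, t = NA_real_, p = NA_real_,
                                   t(counts), n_used = 0L,
                                   estimable = FALSE))
      next
    }
    G <- encode_genotype(g_full[use], model)
    Xd <- cbind(X[which(use), , drop = FALSE], G)
    fit <- .ols(y_all[[score_column]][use], Xd)
    terms <- colnames(G)
    est <- !fit$aliased[terms]
    out[[i]] <- cbind(base[rep(1L, length(terms))],
                      data.table(term = terms,
                                 coef = unname(fit$coef[terms]),
                                 se = unname(fit$se[terms]),
                                 t = unname(fit$t[terms]),
                                 p = unname(fit$p[terms]),
                                 t(counts), n_used = n_used,
                                 estimable = unname(est)))
  }
  res <- data.table::rbindlist(out)
  if (adjust == "bonferroni") {
    res[, p_adjusted := pmin(1, p * nrow(pairs))]
  }
  res[]
}
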