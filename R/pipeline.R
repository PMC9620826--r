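#' Run the full PheRS pipeline
#'
#' Chains the pipeline stages in dependency order — simulate (or load) the
#' cohort, map ICD occurrences to phecodes, compute weights, compute raw
#' and residual scores, assign case/control status, validate scores by
#' case/control comparison, and run genetic association tests — writing
#' every intermediate artifact as a delimited file so any stage can be
#' inspected or resumed independently. Running twice with the same config
#' and seed produces byte-identical outputs.
#'
#' The config is a named list (or path to a YAML file with the same
#' structure) with elements:
#' \describe{
#'   \item{out_dir}{output directory (required; created if absent).}
#'   \item{seed}{integer seed, default 1.}
#'   \item{simulate}{list of [simulation_config()] arguments; used when no
#'     `inputs` are given.}
#'   \item{inputs}{optional list of paths `demographics`, `icd`,
#'     `genotypes` to load instead of simulating.}
#'   \item{maps}{optional list of paths `icd_phecode`, `disease_phecode`,
#'     `disease_dx_icd`; defaults to the bundled toy fixtures.}
#'   \item{weights}{optional path to pre-calculated weights (see
#'     [load_weights()]); default computes weights from the cohort.}
#'   \item{covariates}{default `c("sex", "age_first_visit",
#'     "visit_span")`.}
#'   \item{case_min_dates}{default 2.}
#'   \item{model}{association model, default `"genotypic"`.}
#'   \item{residual}{compute residual scores, default `TRUE`.}
#'   \item{min_cases}{case/control reporting screen, default 50.}
#'   \item{adjust}{`"none"` or `"bonferroni"`.}
#'   \item{exclude_dx_icd}{drop diagnostic ICD codes before phecode
#'     mapping, default `FALSE`.}
#'   \item{exclude_cases}{drop case-status persons from the association
#'     analysis, default `FALSE`.}
#'   \item{pairs}{`data.frame` or path with `disease_id`, `variant_id`;
#'     defaults to the simulated variants and their linked diseases.}
#' }
#'
#' On a stage failure a `<stage>.partial` marker file is left in `out_dir`
#' and the error names the stage.
#'
#' @param config Named list or path to a YAML config file.
#' @param verbose Log per-stage row counts.
#' @return Invisibly, a list with the written file paths and the in-memory
#'   tables.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package",
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  covariates <- config$covariates %||% c("sex", "age_first_visit",
                                         "visit_span")
  residual <- isTRUE(config$residual %||% TRUE)

  paths <- character(0)
  stage <- function(name, fun) {
    .msg(verbose, "[stage %s]", name)
    tryCatch(fun(), error = function(e) {
      file.create(file.path(out_dir, paste0(name, ".partial")))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write_cohort_table(x, p)
    paths[[name]] <<- p
    .msg(verbose, "  wrote %s (%d rows)", p, nrow(x))
  }

  maps <- stage("maps", function() {
    mp <- config$maps %||% list()
    list(
      icd_phecode = if (!is.null(mp$icd_phecode))
        load_map(mp$icd_phecode, "icd_phecode", verbose = verbose)
        else example_map("icd_phecode"),
      disease_phecode = if (!is.null(mp$disease_phecode))
        load_map(mp$disease_phecode, "disease_phecode", verbose = verbose)
        else example_map("disease_phecode"),
      disease_dx_icd = if (!is.null(mp$disease_dx_icd))
        load_map(mp$disease_dx_icd, "disease_dx_icd", verbose = verbose)
        else example_map("disease_dx_icd")
    )
  })

  truth <- NULL
  cohort <- stage("cohort", function() {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      demos <- read_cohort_table(inp$demographics, "demographics",
                                 verbose = verbose)
      icd <- read_cohort_table(inp$icd, "icd_occurrence", verbose = verbose)
      gt <- if (!is.null(inp$genotypes)) {
        read_cohort_table(inp$genotypes, "genotype", verbose = verbose)
      } else NULL
      validate_cohort(demos, icd)
      list(demographics = demos, icd_occurrences = icd, genotypes = gt,
           truth = NULL)
    } else {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% seed
      sim <- simulate_cohort(do.call(simulation_config, sim_args), maps)
      sim
    }
  })
  truth <- cohort$truth
  emit(cohort$demographics, "demographics")
  emit(cohort$icd_occurrences, "icd_occurrences")
  if (!is.null(cohort$genotypes)) emit(cohort$genotypes, "genotypes")
  if (!is.null(truth) && requireNamespace("jsonlite", quietly = TRUE)) {
    tp <- file.path(out_dir, "truth.json")
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                null = "null"), tp)
    paths[["truth"]] <- tp
  }

  phe <- stage("phecode", function() {
    map_icd_to_phecodes(
      cohort$icd_occurrences, maps$icd_phecode,
      exclude_dx_icd = if (isTRUE(config$exclude_dx_icd))
        maps$disease_dx_icd else NULL,
      verbose = verbose)
  })
  emit(phe, "phecode_occurrences")

  wt <- stage("weights", function() {
    if (!is.null(config$weights)) {
      load_weights(config$weights, verbose = verbose)
    } else {
      calc_weights(cohort$demographics, phe)
    }
  })
  emit(wt, "weights")

  scores <- stage("score", function() {
    s <- calc_scores(wt, phe, maps$disease_phecode, cohort$demographics)
    if (residual) {
      s <- calc_residual_scores(cohort$demographics, s, covariates)
    }
    s
  })
  emit(scores, "scores")

  status <- stage("dx-status", function() {
    assign_dx_status(cohort$icd_occurrences, cohort$demographics,
                     maps$disease_dx_icd,
                     case_min_dates = config$case_min_dates %||% 2L)
  })
  emit(status, "dx_status")

  validation <- stage("validate", function() {
    compare_scores_by_status(scores, status, cohort$demographics,
                             covariates = covariates,
                             min_cases = config$min_cases %||% 50L,
                             verbose = verbose)
  })
  emit(validation, "validation")

  assoc <- NULL
  if (!is.null(cohort$genotypes)) {
    assoc <- stage("assoc", function() {
      pairs <- config$pairs
      if (is.character(pairs)) {
        pairs <- data.table::fread(pairs, colClasses = "character",
                                   showProgress = FALSE)
      }
      if (is.null(pairs) && !is.null(truth)) {
        pairs <- unique(truth$variant_spec[, .(disease_id, variant_id)])
      }
      if (is.null(pairs)) {
        .msg(verbose, "  no disease-variant pairs configured; skipping")
        return(NULL)
      }
      excl <- NULL
      if (isTRUE(config$exclude_cases)) {
        excl <- unique(status[status == "case", person_id])
      }
      run_associations(scores, cohort$genotypes, cohort$demographics,
                       pairs, model = config$model %||% "genotypic",
                       covariates = covariates,
                       adjust = config$adjust %||% "none",
                       exclude_persons = excl, verbose = verbose)
    })
    if (!is.null(assoc)) emit(assoc, "associations")
  }

  invisible(list(paths = paths, maps = maps,
                 demographics = cohort$demographics,
                 icd_occurrences = cohort$icd_occurrences,
                 genotypes = cohort$genotypes, truth = truth,
                 phecode_occurrences = phe, weights = wt, scores = scores,
                 dx_status = status, validation = validation,
                 associations = assoc))
}
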