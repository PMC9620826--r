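#' Configure a synthetic cohort simulation
#'
#' Collects and validates the parameters of the synthetic-cohort generator
#' (see [simulate_cohort()]). The defaults define a desk-scale cohort with
#' a modest background code burden, one planted Mendelian-disease signal,
#' and one pathogenic (recessive-acting) plus one benign variant.
#'
#' @param n_persons Cohort size.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @param background_code_rate Mean number of distinct background ICD codes
#'   per person (diagnostic codes are never emitted as background).
#' @param disease_signal `data.frame` with columns `disease_id`, `n_cases`,
#'   `emission_prob`: for each planted case, each of the disease's phecodes
#'   is expressed (via one of its source ICD codes) with probability
#'   `emission_prob`, and a diagnostic ICD code is posted on two distinct
#'   dates. Default: 1% of the cohort (at least 10) as cases of the first
#'   bundled diagnosable disease, emission probability 0.8.
#' @param variant_spec `data.frame` with columns `variant_id`,
#'   `alt_allele_freq`, `effect_hom`, `effect_het`, `disease_id`. Genotypes
#'   are drawn at Hardy-Weinberg equilibrium; carriers receive additional
#'   disease-phecode emissions calibrated so the expected raw-score shift
#'   equals `effect_hom` (homozygous-alternate) or `effect_het`
#'   (heterozygous). Default: a pathogenic variant (allele frequency 0.10,
#'   homozygous effect 2.0 on the raw-score scale, no heterozygous effect)
#'   and a benign variant (frequency 0.20, no effect), both linked to the
#'   planted disease.
#' @param covariate_effects Named numeric vector (`sex`, `age`, `span`):
#'   log-scale multipliers of the background code burden, so that
#'   residualization has real covariate signal to remove.
#' @param geno_missing_rate Fraction of genotype records set to missing.
#' @param age_range First-visit age range (years), uniform.
#' @param mean_span_years Mean of the exponential visit-span distribution;
#'   a 30-day floor guarantees room for two distinct diagnostic dates.
#' @return A `phescore_sim_config` list.
#' @export
simulation_config <- function(n_persons = 1000L, seed = 1L,
                              background_code_rate = 2,
                              disease_signal = NULL, variant_spec = NULL,
                              covariate_effects = c(sex = 0.2, age = 0.3,
                                                    span = 0.3),
                              geno_missing_rate = 0.01,
                              age_range = c(0, 90), mean_span_years = 8) {
  if (is.null(disease_signal)) {
    disease_signal <- data.table(
      disease_id = "OMIM:219700",
      n_cases = max(10L, as.integer(round(0.01 * n_persons))),
      emission_prob = 0.8
    )
  }
  if (is.null(variant_spec)) {
    variant_spec <- data.table(
      variant_id = c("var_pathogenic", "var_benign"),
      alt_allele_freq = c(0.10, 0.20),
      effect_hom = c(2.0, 0.0),
      effect_het = c(0.0, 0.0),
      disease_id = c("OMIM:219700", "OMIM:219700")
    )
  }
  disease_signal <- data.table::as.data.table(disease_signal)
  variant_spec <- data.table::as.data.table(variant_spec)
  .require_cols(disease_signal, c("disease_id", "n_cases", "emission_prob"),
                "disease_signal")
  .require_cols(variant_spec, c("variant_id", "alt_allele_freq",
                                "effect_hom", "effect_het", "disease_id"),
                "variant_spec")
  stopifnot(n_persons >= 1L, background_code_rate > 0,
            mean_span_years > 0, length(age_range) == 2L,
            geno_missing_rate >= 0, geno_missing_rate < 1)
  if (any(disease_signal$n_cases > n_persons)) {
    stop("infeasible config: n_cases > n_persons", call. = FALSE)
  }
  if (any(disease_signal$emission_prob < 0 | disease_signal$emission_prob > 1)) {
    stop("emission_prob must be in [0, 1]", call. = FALSE)
  }
  if (any(variant_spec$alt_allele_freq <= 0 | variant_spec$alt_allele_freq >= 1)) {
    stop("alt_allele_freq must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    background_code_rate = background_code_rate,
    disease_signal = disease_signal, variant_spec = variant_spec,
    covariate_effects = covariate_effects,
    geno_missing_rate = geno_missing_rate,
    age_range = as.numeric(age_range),
    mean_span_years = mean_span_years
  ), class = "phescore_sim_config")
}

## genotype classes at Hardy-Weinberg equilibrium for allele frequency q
.simulate_hwe_genotypes <- function(n, q) {
  sample.int(3L, n, replace = TRUE,
             prob = c((1 - q)^2, 2 * q * (1 - q), q^2)) - 1L
}

#' Simulate a complete synthetic cohort
#'
#' Generates demographics, ICD occurrences, and genotypes with known
#' planted structure, fully reproducible from the config seed:
#' \itemize{
#'   \item demographics: sex Bernoulli(0.5); age at first visit uniform on
#'     `age_range`; visit span exponential with mean `mean_span_years`
#'     plus a 30-day floor; `birth_date` included so age derivation is
#'     exercised.
#'   \item background ICD occurrences: each non-diagnostic code of the
#'     ICD-phecode map is present in a person with a code-specific base
#'     probability (log-uniform across codes, scaled so the expected
#'     number of distinct codes per person equals
#'     `background_code_rate`), multiplied by a per-person covariate
#'     factor `exp(b_sex z_sex + b_age z_age + b_span z_span)` normalized
#'     to mean 1; present codes get one or two occurrence dates uniform in
#'     the person's visit window.
#'   \item planted cases: for each disease signal, `n_cases` persons are
#'     sampled; each disease phecode is emitted (through a randomly chosen
#'     source ICD code) with the signal's emission probability, and a
#'     diagnostic ICD code is posted on exactly two distinct dates.
#'   \item genotypes: Hardy-Weinberg draws per variant; carriers of an
#'     effect variant receive extra disease-phecode emissions planted
#'     conditionally on the features they already express — phecodes the
#'     carrier lacks are taken in random order and emitted until the
#'     expected-weight sum reaches the target, the boundary phecode being
#'     emitted with the fractional probability that makes the conditional
#'     expected raw-score shift equal `effect_hom` / `effect_het` exactly
#'     (randomized rounding, with a two-pass adjustment of expected
#'     weights for the carriers' own contribution to prevalence); a
#'     fraction `geno_missing_rate` of genotype records is then masked to
#'     missing.
#' }
#'
#' @param config A [simulation_config()] object.
#' @param maps Optional list with elements `icd_phecode`,
#'   `disease_phecode`, `disease_dx_icd`; defaults to the bundled toy
#'   fixtures.
#' @return A list with `demographics`, `icd_occurrences`, `genotypes`
#'   (validated tables) and `truth`, a record of every planted quantity
#'   (case ids, carrier ids, calibrated emission probabilities, expected
#'   weights and score shifts).
#' @export
simulate_cohort <- function(config = simulation_config(), maps = NULL) {
  stopifnot(inherits(config, "phescore_sim_config"))
  if (is.null(maps)) {
    maps <- list(icd_phecode = example_map("icd_phecode"),
                 disease_phecode = example_map("disease_phecode"),
                 disease_dx_icd = example_map("disease_dx_icd"))
  }
  set.seed(config$seed)
  n <- config$n_persons

  ## --- demographics -------------------------------------------------
  pid <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- runif(n, config$age_range[1], config$age_range[2])
  first <- data.table::as.IDate("2005-01-01") +
    sample.int(3653L, n, replace = TRUE) - 1L
  span_days <- 30L + as.integer(round(rexp(n, 1 / (config$mean_span_years * 365.25))))
  demos <- data.table(
    person_id = pid, sex = sex,
    first_visit_date = first,
    last_visit_date = first + span_days,
    birth_date = first - as.integer(round(age * 365.25))
  )
  demos <- validate_cohort_table(demos, "demographics")
  ## validation sorts on person_id; pid was generated sorted, so row i is
  ## person i throughout
  stopifnot(identical(demos$person_id, pid))

  ## --- background code-presence probabilities -----------------------
  dx_codes <- unique(data.table::as.data.table(maps$disease_dx_icd)[
    , .(icd = .norm_icd(icd), flag)])
  codes <- unique(data.table::as.data.table(maps$icd_phecode)[
    , .(icd = .norm_icd(icd), flag)])
  codes <- codes[!dx_codes, on = c("icd", "flag")]
  M <- nrow(codes)
  if (M == 0L) stop("no non-diagnostic codes in the ICD-phecode map",
                    call. = FALSE)
  base <- exp(runif(M, log(0.002), log(0.25)))
  base <- base * config$background_code_rate / sum(base)
  base <- pmin(base, 0.9)

  ce <- config$covariate_effects
  z_sex <- (sex == "male") - 0.5
  z_age <- (age - mean(config$age_range)) / (diff(config$age_range) / sqrt(12))
  span_yr <- span_days / 365.25
  z_span <- (span_yr - config$mean_span_years) / config$mean_span_years
  mult <- exp(ce[["sex"]] * z_sex + ce[["age"]] * z_age +
              ce[["span"]] * z_span)
  mult <- mult / mean(mult)
  P <- pmin(outer(mult, base), 0.95)

  present <- matrix(runif(n * M) < P, n, M)
  idx <- which(present, arr.ind = TRUE)
  n_occ <- 1L + rbinom(nrow(idx), 1L, 0.3)
  rows <- rep.int(seq_len(nrow(idx)), n_occ)
  pi_row <- idx[rows, 1L]
  bg <- data.table(
    person_id = pid[pi_row],
    icd = codes$icd[idx[rows, 2L]],
    flag = codes$flag[idx[rows, 2L]],
    occurrence_date = first[pi_row] +
      as.integer(floor(runif(length(rows)) * (span_days[pi_row] + 1L)))
  )

  ## expected background probability of having each phecode
  dpm <- data.table::as.data.table(maps$disease_phecode)
  map_rows <- data.table::as.data.table(maps$icd_phecode)[
    , .(icd = .norm_icd(icd), flag, phecode)]
  map_rows <- map_rows[codes, on = c("icd", "flag"), nomatch = NULL]
  phe_cols <- lapply(split(map_rows, by = "phecode"), function(m) {
    unique(codes[m, on = c("icd", "flag"), which = TRUE])
  })
  p_bg <- vapply(phe_cols, function(cols) {
    mean(1 - exp(rowSums(log1p(-P[, cols, drop = FALSE]))))
  }, numeric(1))

  ## emit one occurrence of phecode `ph` for each person index in `who`
  emit_phecode <- function(who, ph) {
    src <- map_rows[phecode == ph]
    if (nrow(src) == 0L) return(NULL)
    pick <- src[sample.int(nrow(src), length(who), replace = TRUE)]
    data.table(
      person_id = pid[who], icd = pick$icd, flag = pick$flag,
      occurrence_date = first[who] +
        as.integer(floor(runif(length(who)) * (span_days[who] + 1L)))
    )
  }

  ## --- planted disease cases ----------------------------------------
  extra <- list(bg)
  case_ids <- list()
  case_emits <- list()  # phecode -> person indices, for presence tracking
  for (k in seq_len(nrow(config$disease_signal))) {
    dis <- config$disease_signal$disease_id[k]
    nk <- config$disease_signal$n_cases[k]
    e <- config$disease_signal$emission_prob[k]
    pk <- dpm[disease_id == dis, phecode]
    if (length(pk) == 0L) {
      stop(sprintf("disease %s not in the disease-phecode map", dis),
           call. = FALSE)
    }
    who <- sort(sample.int(n, nk))
    case_ids[[dis]] <- pid[who]
    for (ph in pk) {
      hit <- who[runif(nk) < e]
      if (length(hit) > 0L) {
        extra[[length(extra) + 1L]] <- emit_phecode(hit, ph)
        case_emits[[ph]] <- c(case_emits[[ph]], hit)
      }
    }
    dxk <- dx_codes[data.table::as.data.table(maps$disease_dx_icd)[
      disease_id == dis, .(icd = .norm_icd(icd), flag)],
      on = c("icd", "flag"), nomatch = NULL]
    if (nrow(dxk) == 0L) {
      stop(sprintf("disease %s has no diagnostic ICD codes", dis),
           call. = FALSE)
    }
    for (ci in who) {
      offs <- sample.int(span_days[ci] + 1L, 2L) - 1L
      pick <- dxk[sample.int(nrow(dxk), 2L, replace = TRUE)]
      extra[[length(extra) + 1L]] <- data.table(
        person_id = pid[ci], icd = pick$icd, flag = pick$flag,
        occurrence_date = first[ci] + offs
      )
    }
  }

  ## --- genotypes and calibrated variant effects ---------------------
  ## Carrier phenotypes are planted conditionally on what a carrier
  ## already expresses: for each carrier, disease phecodes the person does
  ## not yet have are taken in random order and emitted until the planned
  ## expected-weight sum reaches the target effect, the last phecode being
  ## included with the fractional probability that makes the conditional
  ## expected raw-score shift equal the target exactly (randomized
  ## rounding). This keeps the planted shift nearly homogeneous across
  ## carriers, so a linear model's standard errors remain meaningful.
  eff_dis <- unique(config$variant_spec[
    effect_hom != 0 | effect_het != 0, disease_id])
  pk_all <- intersect(sort(unique(dpm[disease_id %in% eff_dis, phecode])),
                      names(p_bg))
  present_phe <- NULL
  if (length(pk_all) > 0L) {
    present_phe <- vapply(pk_all, function(ph) {
      has <- rowSums(present[, phe_cols[[ph]], drop = FALSE]) > 0
      if (!is.null(case_emits[[ph]])) has[case_emits[[ph]]] <- TRUE
      has
    }, logical(n))
    colnames(present_phe) <- pk_all
  }

  ## greedy randomized-rounding plan for one carrier group
  plan_carriers <- function(carriers, target, pk, w) {
    plans <- vector("list", length(carriers))
    for (ii in seq_along(carriers)) {
      absent <- pk[!present_phe[carriers[ii], pk]]
      if (length(absent) == 0L || target <= 0) {
        plans[[ii]] <- character(0)
        next
      }
      ord <- sample(absent)
      acc <- 0
      sel <- character(0)
      for (ph in ord) {
        wj <- w[[ph]]
        if (acc + wj <= target) {
          sel <- c(sel, ph)
          acc <- acc + wj
        } else {
          if (runif(1) < (target - acc) / wj) sel <- c(sel, ph)
          acc <- target
          break
        }
      }
      plans[[ii]] <- sel
    }
    plans
  }

  geno <- list()
  truth_var <- list()
  for (v in seq_len(nrow(config$variant_spec))) {
    vs <- config$variant_spec[v]
    ac <- .simulate_hwe_genotypes(n, vs$alt_allele_freq)
    pk <- intersect(dpm[disease_id == vs$disease_id, phecode], names(p_bg))
    w_exp <- NULL
    planned_shift <- c(hom = 0, het = 0)
    if (vs$effect_hom != 0 || vs$effect_het != 0) {
      if (length(pk) == 0L) {
        stop(sprintf("effect variant %s: linked disease %s has no phecodes",
                     vs$variant_id, vs$disease_id), call. = FALSE)
      }
      sig <- config$disease_signal[disease_id == vs$disease_id]
      f_case <- if (nrow(sig) > 0L) sig$n_cases[1] / n else 0
      e_case <- if (nrow(sig) > 0L) sig$emission_prob[1] else 0
      ## expected prevalence before carrier emissions: background plus
      ## planted-case contribution
      p_pre <- p_bg[pk] + f_case * e_case * (1 - p_bg[pk])
      if (vs$effect_hom > sum(-log10(p_pre)) ||
          vs$effect_het > sum(-log10(p_pre))) {
        stop(sprintf("variant %s: planted effect exceeds the maximum score of disease %s",
                     vs$variant_id, vs$disease_id), call. = FALSE)
      }
      hom_idx <- which(ac == 2L)
      het_idx <- which(ac == 1L)
      ## two passes: carrier emissions raise phecode prevalence and hence
      ## lower realized weights, so re-plan once with adjusted weights
      w_exp <- -log10(p_pre)
      for (pass in 1:2) {
        plans_hom <- plan_carriers(hom_idx, vs$effect_hom, pk, w_exp)
        plans_het <- plan_carriers(het_idx, vs$effect_het, pk, w_exp)
        cnt <- table(factor(unlist(c(plans_hom, plans_het)), levels = pk))
        w_exp <- -log10(pmin(p_pre + as.numeric(cnt) / n, 1 - 1e-12))
        names(w_exp) <- pk
      }
      for (grp in list(list(idx = hom_idx, plans = plans_hom, lab = "hom"),
                       list(idx = het_idx, plans = plans_het,
                            lab = "het"))) {
        if (length(grp$idx) == 0L) next
        for (ph in pk) {
          hit <- grp$idx[vapply(grp$plans, function(s) ph %in% s,
                                logical(1))]
          if (length(hit) > 0L) {
            extra[[length(extra) + 1L]] <- emit_phecode(hit, ph)
            present_phe[hit, ph] <- TRUE
          }
        }
        planned_shift[[grp$lab]] <- mean(vapply(grp$plans, function(s) {
          sum(w_exp[s])
        }, numeric(1)))
      }
    }
    ac_obs <- ac
    if (config$geno_missing_rate > 0) {
      ac_obs[runif(n) < config$geno_missing_rate] <- NA_integer_
    }
    geno[[v]] <- data.table(person_id = pid, variant_id = vs$variant_id,
                            allele_count = ac_obs)
    truth_var[[vs$variant_id]] <- list(
      alt_allele_freq = vs$alt_allele_freq,
      effect_hom = vs$effect_hom, effect_het = vs$effect_het,
      disease_id = vs$disease_id,
      hom_ids = pid[ac == 2L], het_ids = pid[ac == 1L],
      planned_shift_hom = planned_shift[["hom"]],
      planned_shift_het = planned_shift[["het"]],
      expected_weights = w_exp
    )
  }

  icd <- validate_cohort_table(data.table::rbindlist(extra), "icd_occurrence")
  genotypes <- validate_cohort_table(data.table::rbindlist(geno), "genotype")

  truth <- list(
    seed = config$seed, n_persons = n,
    background_code_base_prob = stats::setNames(base, paste0(codes$icd, "_",
                                                             codes$flag)),
    background_phecode_prob = p_bg,
    case_ids = case_ids,
    variants = truth_var,
    disease_signal = config$disease_signal,
    variant_spec = config$variant_spec
  )
  list(demographics = demos, icd_occurrences = icd, genotypes = genotypes,
       truth = truth)
}
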