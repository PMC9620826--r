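library(data.table)

## small cohort builders ------------------------------------------------

toy_demos <- function(n = 6L) {
  validate_cohort_table(data.table(
    person_id = sprintf("P%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    first_visit_date = as.Date("2010-01-01") + seq_len(n),
    last_visit_date = as.Date("2016-01-01") + 3L * seq_len(n),
    birth_date = as.Date("1960-01-01") + 700L * seq_len(n)
  ), "demographics")
}

as_icd <- function(...) {
  validate_cohort_table(data.table(...), "icd_occurrence")
}

as_phe <- function(...) {
  validate_cohort_table(data.table(...), "phecode_occurrence")
}

weight_table <- function(phecode, weight, N = 100L) {
  data.table(phecode = phecode,
             n_persons = as.integer(round(N / 10^weight)),
             cohort_size = N, weight = weight, key = "phecode")
}

## independent oracles --------------------------------------------------

## brute-force double loop over persons x diseases
brute_scores <- function(weights, phe, disease_map, demos) {
  out <- list()
  for (p in demos$person_id) {
    has <- unique(phe$phecode[phe$person_id == p])
    for (d in sort(unique(disease_map$disease_id))) {
      pk <- disease_map$phecode[disease_map$disease_id == d]
      s <- 0
      for (j in pk) {
        if (j %in% has) {
          w <- weights$weight[weights$phecode == j]
          if (length(w) == 1L) s <- s + w
        }
      }
      out[[paste(p, d)]] <- data.table(person_id = p, disease_id = d,
                                       score = s)
    }
  }
  setkeyv(rbindlist(out), c("person_id", "disease_id"))[]
}

## closed-form OLS: (X'X)^-1 X'y, classical standard errors
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- drop(y - X %*% b)
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  list(coef = drop(b), se = sqrt(diag(solve(XtX)) * s2), resid = res,
       df = df, sigma2 = s2)
}

## covariate design matrix built independently of the package internals
oracle_design <- function(demos) {
  age <- as.numeric(demos$first_visit_date - demos$birth_date) / 365.25
  span <- as.numeric(demos$last_visit_date - demos$first_visit_date) / 365.25
  cbind(intercept = 1, male = as.numeric(demos$sex == "male"),
        age = age, span = span)
}

## standard end-to-end helper: simulate and score a cohort
sim_scored <- function(n = 1000L, seed = 1L, ...) {
  sim <- simulate_cohort(simulation_config(n_persons = n, seed = seed, ...))
  phe <- map_icd_to_phecodes(sim$icd_occurrences, example_map("icd_phecode"),
                             verbose = FALSE)
  wt <- calc_weights(sim$demographics, phe)
  ## at small n some disease phecodes may be unobserved; that path is
  ## tested explicitly elsewhere
  scores <- suppressWarnings(
    calc_scores(wt, phe, example_map("disease_phecode"),
                sim$demographics))
  c(sim, list(phecode_occurrences = phe, weights = wt, scores = scores))
}
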