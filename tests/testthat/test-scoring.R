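test_that("raw scores are the weighted sum of present disease phecodes", {
  demos <- toy_demos(3L)
  wt <- weight_table(c("a", "b"), c(2, 1))
  dm <- data.table(disease_id = "D1", phecode = c("a", "b"))
  ## person has phecode a only -> score w_a = 2
  phe <- as_phe(person_id = "P01", phecode = "a",
                occurrence_date = as.Date("2011-01-01"))
  sc <- calc_scores(wt, phe, dm, demos)
  expect_equal(sc[person_id == "P01", score], 2)
  ## persons with zero phecodes get explicit zero for every disease
  expect_equal(sc[person_id %in% c("P02", "P03"), score], c(0, 0))
  expect_equal(nrow(sc), 3L)
})

test_that("scores match a brute-force double-loop oracle element-wise", {
  set.seed(5)
  n <- 20L
  demos <- toy_demos(n)
  phecodes <- sprintf("ph%02d", 1:12)
  wt <- data.table(phecode = phecodes, n_persons = 1L, cohort_size = 100L,
                   weight = round(runif(12, 0.2, 3), 3))
  dm <- rbindlist(lapply(1:5, function(k) {
    data.table(disease_id = sprintf("D%d", k),
               phecode = sample(phecodes, sample(3:6, 1)))
  }))
  phe <- as_phe(person_id = sample(demos$person_id, 80L, replace = TRUE),
                phecode = sample(phecodes, 80L, TRUE),
                occurrence_date = as.Date("2012-01-01") +
                  sample(0:200, 80L, TRUE))
  sc <- calc_scores(wt, phe, dm, demos)
  oracle <- brute_scores(wt, phe, dm, demos)
  ## identical up to floating-point summation order
  expect_identical(sc[, .(person_id, disease_id)],
                   oracle[, .(person_id, disease_id)])
  expect_equal(sc$score, oracle$score, tolerance = 1e-12)
})

test_that("score additivity and monotonicity hold", {
  set.seed(9)
  demos <- toy_demos(10L)
  phecodes <- sprintf("ph%02d", 1:8)
  wt <- data.table(phecode = phecodes, n_persons = 1L, cohort_size = 10L,
                   weight = runif(8, 0.1, 2))
  phe <- as_phe(person_id = sample(demos$person_id, 30L, TRUE),
                phecode = sample(phecodes, 30L, TRUE),
                occurrence_date = as.Date("2012-01-01"))

  ## additivity: score over P_k equals the sum over a partition of P_k
  dm_full <- data.table(disease_id = "D", phecode = phecodes)
  dm_a <- data.table(disease_id = "D", phecode = phecodes[1:4])
  dm_b <- data.table(disease_id = "D", phecode = phecodes[5:8])
  s_full <- calc_scores(wt, phe, dm_full, demos)
  s_a <- calc_scores(wt, phe, dm_a, demos)
  s_b <- calc_scores(wt, phe, dm_b, demos)
  expect_equal(s_full$score, s_a$score + s_b$score)

  ## monotonicity: adding one occurrence never decreases any score
  extra <- validate_cohort_table(
    rbind(phe, data.table(person_id = "P01", phecode = "ph05",
                          occurrence_date = as.Date("2013-01-01"))),
    "phecode_occurrence")
  s_more <- calc_scores(wt, phe = extra, dm_full, demos)
  expect_true(all(s_more$score >= s_full$score))
})

test_that("disease phecodes without weights contribute zero with one warning", {
  demos <- toy_demos(2L)
  wt <- weight_table("a", 2)
  dm <- data.table(disease_id = "D1", phecode = c("a", "unseen"))
  phe <- as_phe(person_id = "P01", phecode = c("a", "unseen"),
                occurrence_date = as.Date("2011-01-01"))
  expect_warning(sc <- calc_scores(wt, phe, dm, demos), "unseen")
  expect_equal(sc[person_id == "P01", score], 2)
})

test_that("residual scores have mean 0 and unit variance under the n-p convention", {
  sim <- sim_scored(n = 200L, seed = 21L)
  rs <- calc_residual_scores(sim$demographics, sim$scores)
  n <- nrow(sim$demographics)
  p <- 4L  # intercept + sex + age + span
  for (d in unique(rs$disease_id)) {
    r <- rs[disease_id == d, residual_score]
    expect_lt(abs(mean(r)), 1e-10)
    expect_lt(abs(sum(r^2) / (n - p) - 1), 1e-10)
  }
})

test_that("residualization matches a closed-form OLS oracle", {
  sim <- sim_scored(n = 150L, seed = 22L)
  rs <- calc_residual_scores(sim$demographics, sim$scores)
  X <- oracle_design(sim$demographics)
  for (d in unique(rs$disease_id)) {
    y <- sim$scores[disease_id == d][match(sim$demographics$person_id,
                                           person_id), score]
    fit <- ols_oracle(y, X)
    expected <- fit$resid / sqrt(fit$sigma2)
    got <- rs[disease_id == d][match(sim$demographics$person_id, person_id),
                               residual_score]
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("empty covariate list reduces residualization to z-scoring", {
  sim <- sim_scored(n = 80L, seed = 23L)
  rs <- calc_residual_scores(sim$demographics, sim$scores,
                             covariates = character(0))
  for (d in unique(rs$disease_id)) {
    y <- sim$scores[disease_id == d, score]
    z <- (y - mean(y)) / stats::sd(y)
    expect_equal(rs[disease_id == d, residual_score], z, tolerance = 1e-10)
  }
})

test_that("residual scores are invariant to affine covariate rescaling", {
  sim <- sim_scored(n = 100L, seed = 24L)
  demos <- copy(sim$demographics)
  cov0 <- derive_covariates(demos)
  demos[, age_first_visit := cov0$age_first_visit]
  rs1 <- calc_residual_scores(demos, sim$scores)
  demos2 <- copy(demos)[, age_first_visit := 3.7 * age_first_visit - 12]
  rs2 <- calc_residual_scores(demos2, sim$scores)
  expect_equal(rs1$residual_score, rs2$residual_score, tolerance = 1e-8)
})

test_that("degenerate residual fits raise errors", {
  demos <- toy_demos(6L)
  age <- derive_covariates(demos)$age_first_visit
  ## scores exactly linear in age -> zero residual variance
  sc <- data.table(person_id = demos$person_id, disease_id = "D1",
                   score = 2 * age + 1)
  expect_error(calc_residual_scores(demos, sc,
                                    covariates = "age_first_visit"),
               "zero residual variance")

  ## n <= p
  demos3 <- toy_demos(3L)
  sc3 <- data.table(person_id = demos3$person_id, disease_id = "D1",
                    score = c(1, 2, 3))
  expect_error(
    calc_residual_scores(demos3, sc3,
                         covariates = c("sex", "age_first_visit",
                                        "visit_span")),
    "n")

  ## zero-variance covariate is dropped with a warning, not an error
  demos_cv <- copy(toy_demos(10L))[, sex := "female"]
  demos_cv <- validate_cohort_table(demos_cv, "demographics")
  sc_cv <- data.table(person_id = demos_cv$person_id, disease_id = "D1",
                      score = runif(10))
  expect_warning(rs <- calc_residual_scores(demos_cv, sc_cv),
                 "zero variance")
  expect_true("residual_score" %in% names(rs))
})
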