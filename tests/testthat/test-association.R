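test_that("genotype encodings match the exhaustive truth table", {
  truth <- list(
    additive = list(`0` = 0, `1` = 1, `2` = 2),
    dominant = list(`0` = 0, `1` = 1, `2` = 1),
    recessive = list(`0` = 0, `1` = 0, `2` = 1),
    genotypic = list(`0` = c(0, 0), `1` = c(1, 0), `2` = c(0, 1))
  )
  for (m in names(truth)) {
    for (ac in 0:2) {
      enc <- encode_genotype(ac, m)
      expect_equal(unname(drop(enc)), truth[[m]][[as.character(ac)]],
                   info = paste(m, ac))
    }
  }
  expect_equal(colnames(encode_genotype(0:2, "genotypic")),
               c("het", "hom_alt"))
  expect_error(encode_genotype(1L, "overdominant"))
  expect_error(encode_genotype(NA_integer_, "additive"), "missing")
})

## one small deterministic fixture reused across association tests
assoc_fixture <- function(n = 120L, seed = 41L) {
  set.seed(seed)
  demos <- validate_cohort_table(data.table(
    person_id = sprintf("P%03d", 1:n),
    sex = sample(c("female", "male"), n, TRUE),
    first_visit_date = as.Date("2008-01-01") + sample(0:1000, n, TRUE),
    birth_date = as.Date("1950-01-01") + sample(0:15000, n, TRUE),
    last_visit_date = as.Date("2018-01-01") + sample(0:1000, n, TRUE)
  ), "demographics")
  ac <- sample(0:2, n, TRUE, prob = c(0.49, 0.42, 0.09))
  gt <- validate_cohort_table(
    data.table(person_id = demos$person_id, variant_id = "rs1",
               allele_count = ac), "genotype")
  y <- 0.5 + 0.8 * (ac == 2) + rnorm(n)
  sc <- data.table(person_id = demos$person_id, disease_id = "D1",
                   score = y - min(y))
  list(demos = demos, gt = gt, sc = sc, ac = ac)
}

test_that("association fits match the closed-form OLS oracle for every model", {
  fx <- assoc_fixture()
  pairs <- data.table(disease_id = "D1", variant_id = "rs1")
  Xcov <- oracle_design(fx$demos)
  for (m in c("additive", "dominant", "recessive", "genotypic")) {
    res <- run_associations(fx$sc, fx$gt, fx$demos, pairs, model = m,
                            verbose = FALSE)
    G <- encode_genotype(fx$ac, m)
    X <- cbind(Xcov, G)
    y <- fx$sc$score[match(fx$demos$person_id, fx$sc$person_id)]
    fit <- ols_oracle(y, X)
    for (tm in colnames(G)) {
      row <- res[term == tm]
      expect_equal(row$coef, unname(fit$coef[tm]), tolerance = 1e-10)
      expect_equal(row$se, unname(fit$se[tm]), tolerance = 1e-10)
      expect_equal(row$p,
                   2 * pt(abs(fit$coef[tm] / fit$se[tm]), df = fit$df,
                          lower.tail = FALSE)[[1]], tolerance = 1e-10)
    }
    ## genotype counts are model-independent and sum to cohort size
    expect_equal(res$n_hom_ref[1] + res$n_het[1] + res$n_hom_alt[1] +
                   res$n_missing[1], nrow(fx$demos))
    expect_equal(res$n_hom_ref[1], sum(fx$ac == 0))
    ## genotypic has exactly two genetic terms, others one
    expect_equal(nrow(res), if (m == "genotypic") 2L else 1L)
  }
})

test_that("results are invariant to person order", {
  fx <- assoc_fixture()
  pairs <- data.table(disease_id = "D1", variant_id = "rs1")
  r1 <- run_associations(fx$sc, fx$gt, fx$demos, pairs,
                         model = "genotypic", verbose = FALSE)
  perm <- sample(nrow(fx$demos))
  ## validation re-sorts on the key, so shuffled inputs give equal output
  demos2 <- validate_cohort_table(fx$demos[perm], "demographics")
  sc2 <- fx$sc[rev(seq_len(nrow(fx$sc)))]
  gt2 <- validate_cohort_table(fx$gt[perm], "genotype")
  r2 <- run_associations(sc2, gt2, demos2, pairs, model = "genotypic",
                         verbose = FALSE)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("missing genotypes are excluded pairwise, counted cohort-wide", {
  fx <- assoc_fixture()
  gt <- copy(fx$gt)[1:10, allele_count := NA_integer_]
  res <- run_associations(fx$sc, gt, fx$demos,
                          data.table(disease_id = "D1", variant_id = "rs1"),
                          model = "additive", verbose = FALSE)
  expect_equal(res$n_missing, 10L)
  expect_equal(res$n_used, nrow(fx$demos) - 10L)
})

test_that("a design without hom-alt carriers is flagged non-estimable", {
  fx <- assoc_fixture()
  gt <- copy(fx$gt)[allele_count == 2L, allele_count := 1L]
  res <- run_associations(fx$sc, gt, fx$demos,
                          data.table(disease_id = "D1", variant_id = "rs1"),
                          model = "recessive", verbose = FALSE)
  expect_false(res$estimable)
  expect_true(is.na(res$coef))
})

test_that("bonferroni adjustment scales p by the number of pairs", {
  fx <- assoc_fixture()
  gt2 <- validate_cohort_table(
    rbind(fx$gt, copy(fx$gt)[, variant_id := "rs2"]), "genotype")
  pairs <- data.table(disease_id = "D1", variant_id = c("rs1", "rs2"))
  res <- run_associations(fx$sc, gt2, fx$demos, pairs, model = "additive",
                          adjust = "bonferroni", verbose = FALSE)
  expect_equal(res$p_adjusted, pmin(1, res$p * 2))
})

test_that("a planted recessive effect is recovered and a benign variant is null", {
  ## mirrors the expected pattern: strongly positive hom-alt coefficient
  ## for the pathogenic variant, het and benign coefficients near zero
  sim <- sim_scored(n = 4000L, seed = 43L)
  pairs <- data.table(disease_id = "OMIM:219700",
                      variant_id = c("var_pathogenic", "var_benign"))
  res <- run_associations(sim$scores, sim$genotypes, sim$demographics,
                          pairs, model = "genotypic",
                          score_column = "score", verbose = FALSE)
  path_hom <- res[variant_id == "var_pathogenic" & term == "hom_alt"]
  path_het <- res[variant_id == "var_pathogenic" & term == "het"]
  expect_lt(abs(path_hom$coef - 2), 2 * path_hom$se)
  expect_lt(abs(path_het$coef), 3 * path_het$se)
  for (tm in c("het", "hom_alt")) {
    ben <- res[variant_id == "var_benign" & term == tm]
    expect_lt(abs(ben$coef), 3 * ben$se)
  }
})
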