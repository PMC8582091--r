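test_that("standardized residuals match a brute-force normal-equations solve", {
  age <- c(65, 70, 75, 80)
  sex <- factor(rep("female", 4), levels = c("female", "male"))
  y <- c(2, 1, 4, 3)
  cz <- residual_zscore(y, age, sex)

  # independent oracle: closed-form OLS on intercept + age
  X <- cbind(1, age)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - as.vector(X %*% beta)
  expect_equal(cz$z, res / sd(res), tolerance = 1e-12)
  expect_equal(unname(cz$coefficients["age"]), beta[2], tolerance = 1e-12)
})

test_that("z-scores are centred, unit-scaled and orthogonal to age and sex", {
  coh <- complete_cohort(350, seed = 18)
  sexm <- as.numeric(coh$sex == "male")
  for (v in c("balance", "physical_activity", "chronic_diseases")) {
    cz <- residual_zscore(coh[[v]], coh$age, coh$sex, v)
    expect_lt(abs(mean(cz$z)), 1e-10)
    expect_lt(abs(sd(cz$z) - 1), 1e-8)
    expect_lt(abs(cor(cz$z, coh$age)), 1e-8)
    expect_lt(abs(cor(cz$z, sexm)), 1e-8)
  }
})

test_that("degenerate components are refused by name", {
  age <- c(66, 70, 74, 78, 82)
  sex <- factor(c("female", "male", "female", "male", "female"),
                levels = c("female", "male"))
  expect_error(residual_zscore(rep(5, 5), age, sex, "gait"),
               "degenerate component 'gait'")
  expect_error(residual_zscore(2 * age, age, sex, "balance"),
               "degenerate component 'balance'")
  expect_error(residual_zscore(c(1, NA, 2, 3, 4), age, sex, "gait"),
               "missing")
  expect_error(residual_zscore(1:3, age[1:3], sex[1:3]), "at least 4")
})

test_that("composition flips exactly the protective components", {
  n <- 5
  z <- matrix(0, n, 10, dimnames = list(NULL, component_registry()$name))
  expect_equal(compose_cfrs(z)$cfrs, rep(0, n))
  z[1, "balance"] <- 1            # protective: contributes -1
  z[2, "fear_of_falling"] <- 1    # risk-increasing: contributes +1
  out <- compose_cfrs(z)
  expect_equal(out$cfrs[1:2], c(-1, 1))
  # linear in any single component
  z2 <- z; z2[1, "balance"] <- 3
  expect_equal(compose_cfrs(z2)$cfrs[1], -3)
  expect_error(compose_cfrs(z[, 1:9]), "environmental_hazards")
})

test_that("the composed score has mean zero over any fitting sample", {
  for (seed in c(3, 77, 2024)) {
    coh <- complete_cohort(150, seed = seed)
    sc <- cfrs_score(coh)
    expect_lt(abs(mean(sc$cfrs)), 1e-8)
    sc2 <- cfrs_score(coh, stratify_by_sex = TRUE)
    expect_lt(abs(mean(sc2$cfrs)), 1e-8)
  }
})

test_that("sex-stratified scoring standardizes within each sex", {
  coh <- complete_cohort(400, seed = 19)
  sc <- cfrs_score(coh, stratify_by_sex = TRUE)
  for (lev in c("female", "male")) {
    idx <- coh$sex == lev
    expect_lt(abs(mean(sc$z[idx, "gait"])), 1e-8)
    expect_lt(abs(sd(sc$z[idx, "gait"]) - 1), 1e-6)
    expect_lt(abs(mean(sc$cfrs[idx])), 1e-8)
  }
})

test_that("raising a risk-increasing value never lowers its contribution", {
  set.seed(20)
  coh <- complete_cohort(50, seed = 20)
  v <- "fear_of_falling"
  s <- score_signs()[v]
  for (i in c(1, 17, 42)) {
    base <- residual_zscore(coh[[v]], coh$age, coh$sex, v)
    bumped_vals <- coh[[v]]
    bumped_vals[i] <- bumped_vals[i] + 4
    bumped <- residual_zscore(bumped_vals, coh$age, coh$sex, v)
    expect_gte(s * bumped$z[i], s * base$z[i])
  }
})

test_that("scores separate the faller groups on generator cohorts", {
  coh <- complete_cohort(1000, seed = 21)
  sc <- cfrs_score(coh)
  rec <- classify_fall_status(coh$falls_12m)$binary == "recurrent"
  expect_gt(mean(sc$cfrs[rec]), mean(sc$cfrs[!rec]))
})

test_that("a frozen model reproduces and transfers the fit", {
  coh <- complete_cohort(300, seed = 22)
  sc <- cfrs_score(coh)
  expect_equal(predict(sc$model, coh), sc$cfrs, tolerance = 1e-10)

  path <- tempfile(fileext = ".yml")
  save_cfrs_model(sc$model, path)
  reloaded <- load_cfrs_model(path)
  newdata <- complete_cohort(80, seed = 23)
  expect_equal(predict(reloaded, newdata), predict(sc$model, newdata),
               tolerance = 1e-6)

  sc_str <- cfrs_score(coh, stratify_by_sex = TRUE)
  expect_equal(predict(sc_str$model, coh), sc_str$cfrs, tolerance = 1e-10)
})

test_that("scoring refuses incomplete or unbalanced cohorts", {
  coh <- simulate_cohort(cohort_config(n = 100, seed = 24))
  expect_error(cfrs_score(coh), "impute")
  complete <- complete_cohort(100, seed = 24)
  one_sex <- complete[complete$sex == "female", ]
  expect_error(cfrs_score(one_sex), "each sex")
})
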