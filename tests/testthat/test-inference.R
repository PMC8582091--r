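# Published two-group summaries (occasional n = 356, recurrent n = 148)
# and the effect sizes printed alongside them.
published_rows <- data.frame(
  variable = c("cfrs", "cognitive", "fear_of_falling", "balance",
               "physical_function", "gait", "environmental_hazards",
               "physical_activity", "affordance_error", "age"),
  m_occ = c(-1.24, 27.0, 20.1, 30.3, 21.2, 11.6, 11.2, 2069.5, 8.5, 73.1),
  s_occ = c(3.2, 3.2, 4.9, 6.1, 3.5, 1.1, 6.5, 1933.7, 7.3, 6.4),
  m_rec = c(2.99, 22.2, 25.9, 26.5, 19.1, 11.1, 9.5, 1753.6, 7.9, 73.8),
  s_rec = c(4.1, 4.2, 8.6, 9.0, 5.1, 1.8, 6.8, 1712.9, 7.0, 6.5),
  d = c(1.21, -1.36, 0.93, -0.54, -0.52, -0.37, -0.26, -0.17, -0.08, 0.11))

test_that("Cohen's d from summaries reproduces the published column", {
  for (i in seq_len(nrow(published_rows))) {
    r <- published_rows[i, ]
    es <- cohens_d_from_summary(r$m_occ, r$s_occ, 356, r$m_rec, r$s_rec,
                                148)
    expect_equal(round(es$d, 2), r$d, info = r$variable)
  }
  # composed-score row: the 90% normal-approximation interval too
  es <- cohens_d_from_summary(-1.24, 3.2, 356, 2.99, 4.1, 148)
  expect_equal(round(c(es$ci_low, es$ci_high), 2), c(1.04, 1.39))
  expect_equal(es$magnitude, "large")
})

test_that("Cohen's d is antisymmetric with a mirrored interval", {
  a <- cohens_d_from_summary(10, 2, 30, 12, 3, 40)
  b <- cohens_d_from_summary(12, 3, 40, 10, 2, 30)
  expect_equal(a$d, -b$d)
  expect_equal(a$ci_low, -b$ci_high)
  expect_equal(a$ci_high, -b$ci_low)
  zero <- cohens_d_from_summary(5, 1, 20, 5, 1, 20)
  expect_equal(zero$d, 0)
  expect_equal(zero$magnitude, "trivial")
  expect_error(cohens_d_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("noncentral-t interval brackets d and nears the normal one", {
  es_n <- cohens_d_from_summary(27.0, 3.2, 356, 22.2, 4.2, 148)
  es_t <- cohens_d_from_summary(27.0, 3.2, 356, 22.2, 4.2, 148,
                                method = "noncentral_t")
  expect_lt(es_t$ci_low, es_t$d)
  expect_gt(es_t$ci_high, es_t$d)
  expect_lt(abs(es_t$ci_low - es_n$ci_low), 0.03)
  expect_lt(abs(es_t$ci_high - es_n$ci_high), 0.03)
})

test_that("magnitude bands follow the published thresholds", {
  expect_equal(classify_magnitude(0.11), "trivial")
  expect_equal(classify_magnitude(0.93), "moderate")
  expect_equal(classify_magnitude(1.21), "large")
  expect_equal(classify_magnitude(-1.36), "large")
  expect_equal(classify_magnitude(0.2), "small")
  expect_equal(classify_magnitude(0.6), "moderate")
  expect_equal(classify_magnitude(1.2), "large")
  expect_equal(classify_magnitude(2.0), "very_large")  # boundary policy
  expect_error(classify_magnitude(Inf), "finite")
})

test_that("pooled t-test matches the textbook formula on a 6+6 sample", {
  a <- c(12.1, 9.8, 11.4, 10.2, 13.0, 10.9)
  b <- c(8.7, 9.9, 7.5, 10.1, 8.2, 9.0)
  out <- two_sample_t(a, b)
  sp2 <- (5 * var(a) + 5 * var(b)) / 10
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 10), tolerance = 1e-12)

  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_lt(two_sample_t(1:3, 1:3 + 10)$p, 0.01)
  expect_equal(two_sample_t(rep(2, 3), rep(2, 4))$p, 1)  # degenerate
  welch <- two_sample_t(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(welch$p, out$p)))
})

test_that("Pearson chi-square matches the 4-cell arithmetic", {
  prop <- chi_square_prop(rbind(c(10, 20), c(30, 60)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)

  tab <- rbind(c(20, 10), c(10, 20))
  out <- chi_square_prop(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  swapped <- chi_square_prop(tab[2:1, ])
  expect_equal(swapped$statistic, out$statistic)
  expect_error(chi_square_prop(rbind(c(0, 0), c(3, 4))), "marginal")
  yates <- chi_square_prop(tab, correct = TRUE)
  expect_lt(yates$statistic, out$statistic)
})

test_that("one-way ANOVA F matches the sum-of-squares formula", {
  y <- c(1, 2, 3, 5, 6, 7, 9, 10, 11)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  out <- anova_tukey(y, g)
  gm <- tapply(y, g, mean)
  ssb <- sum(3 * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(out$F, f_hand, tolerance = 1e-12)
  expect_equal(nrow(out$tukey), 3)

  flat <- anova_tukey(rep(c(1, 1, 1), 3), g)
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  expect_true(all(flat$tukey$p_adj == 1))
})

test_that("with two groups the ANOVA reproduces the pooled t-test", {
  set.seed(30)
  a <- rnorm(15, 0); b <- rnorm(12, 1)
  an <- anova_tukey(c(a, b), rep(c("x", "y"), c(15, 12)))
  tt <- two_sample_t(a, b)
  expect_equal(an$F, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p, tolerance = 1e-10)
})

test_that("well-separated fall groups give Tukey p < 0.001 everywhere", {
  set.seed(31)
  y <- c(rnorm(100, -1.66, 0.5), rnorm(100, 0.05, 0.5),
         rnorm(100, 2.82, 0.5))
  g <- factor(rep(c("zero", "one", "two_plus"), each = 100),
              levels = c("zero", "one", "two_plus"))
  out <- anova_tukey(y, g)
  expect_true(all(out$tukey$p_adj < 0.001))
  # permutation oracle for the overall F
  f_obs <- out$F
  f_perm <- replicate(200, anova_tukey(sample(y), g)$F)
  expect_equal(mean(f_perm >= f_obs), 0)
  expect_error(anova_tukey(y[1:200], g), "mismatch|group")
})

test_that("sample-size planning follows the finite-population formula", {
  expect_equal(min_sample_size(182988, 1.96, 0.05, 0.5), 384)
  expect_equal(min_sample_size(1e6, 1.96, 0.05, 1e-9), 1)  # p -> 0 limit
  expect_equal(min_sample_size(10, 1.96, 0.05, 0.5), 10)   # capped at N
  # monotone in the error and maximized at p = 0.5
  n1 <- min_sample_size(182988, 1.96, 0.03, 0.5)
  n2 <- min_sample_size(182988, 1.96, 0.05, 0.5)
  expect_gte(n1, n2)
  expect_gte(min_sample_size(182988, 1.96, 0.05, 0.5),
             min_sample_size(182988, 1.96, 0.05, 0.3))
})

test_that("the group table reports every requested variable", {
  coh <- complete_cohort(400, seed = 32)
  sc <- cfrs_score(coh)
  tab <- fall_group_table(coh, cfrs = sc$cfrs)
  expect_equal(tab$variable,
               c("age", component_registry()$name, "cfrs"))
  expect_true(all(tab$n_occasional + tab$n_recurrent == 400))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  cfrs_row <- tab[tab$variable == "cfrs", ]
  expect_gt(cfrs_row$mean_recurrent, cfrs_row$mean_occasional)
  expect_true(cfrs_row$d_ci_low <= cfrs_row$d &
                cfrs_row$d <= cfrs_row$d_ci_high)
})
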