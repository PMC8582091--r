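# brute-force pairwise AUC: mean over positive-negative pairs with ties
# counted one half
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

test_that("ROC handles the canonical small instances", {
  expect_equal(roc_curve(1:4, c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
  expect_error(roc_curve(c(1, NA, 3), c(0, 1, 1)), "finite")
})

test_that("sensitivity decreases and specificity increases with threshold", {
  set.seed(40)
  sc <- round(rnorm(80), 1)
  lb <- rbinom(80, 1, plogis(sc))
  r <- roc_curve(sc, lb)
  expect_true(all(diff(r$sensitivity) <= 0))
  expect_true(all(diff(r$specificity) >= 0))
  expect_equal(r$sensitivity[1], 1)                # threshold -Inf
  expect_equal(r$specificity[length(r$thresholds)], 1)  # threshold Inf
})

test_that("trapezoid, mid-rank and brute-force pairwise AUC agree", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    sc <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    lb <- c(0, 1, rbinom(n - 2, 1, 0.4))
    a_trap <- roc_curve(sc, lb)$auc
    a_mw <- auc_mann_whitney(sc, lb)
    expect_equal(a_trap, a_mw, tolerance = 1e-12)
    expect_equal(a_mw, pairwise_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("swapping the labels complements the AUC", {
  set.seed(42)
  sc <- rnorm(50); lb <- c(0, 1, rbinom(48, 1, 0.3))
  expect_equal(auc_mann_whitney(sc, lb) + auc_mann_whitney(sc, 1 - lb), 1)
})

test_that("the AUC equals pROC's on a shared instance", {
  skip_if_not_installed("pROC")
  set.seed(43)
  sc <- round(rnorm(120), 1)
  lb <- rbinom(120, 1, plogis(sc - 0.3))
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_mann_whitney(sc, lb), ref, tolerance = 1e-12)
  expect_equal(roc_curve(sc, lb)$auc, ref, tolerance = 1e-12)
})

test_that("Youden cutoff equals the exhaustive scan, lowest tie wins", {
  set.seed(44)
  sc <- c(rnorm(100, 0), rnorm(100, 1.2))
  lb <- rep(c(0, 1), each = 100)
  r <- roc_curve(sc, lb)
  y <- youden_cutoff(r)
  # independent exhaustive scan over candidate thresholds
  cand <- c(-Inf, sort(unique(sc)), Inf)
  j <- vapply(cand, function(t) {
    mean(sc[lb == 1] >= t) + mean(sc[lb == 0] < t) - 1
  }, numeric(1))
  expect_equal(y$youden_index, max(j), tolerance = 1e-12)
  expect_equal(y$cutoff, cand[which.max(j)])
  expect_equal(y$sensitivity + y$specificity - 1, y$youden_index)

  # perfect separation: cutoff at the lowest positive score
  yp <- youden_cutoff(roc_curve(1:4, c(0, 0, 1, 1)))
  expect_equal(yp$cutoff, 3)
  expect_equal(c(yp$sensitivity, yp$specificity), c(1, 1))

  # all scores tied: J = 0 everywhere, lowest threshold returned
  yt <- youden_cutoff(roc_curve(rep(1, 6), c(0, 1, 0, 1, 0, 1)))
  expect_equal(yt$youden_index, 0)
  expect_equal(yt$cutoff, -Inf)
})

test_that("the Youden index is invariant to monotone score transforms", {
  set.seed(45)
  sc <- rnorm(150); lb <- rbinom(150, 1, plogis(2 * sc))
  y1 <- youden_cutoff(roc_curve(sc, lb))
  y2 <- youden_cutoff(roc_curve(exp(sc), lb))
  expect_equal(y2$youden_index, y1$youden_index, tolerance = 1e-12)
  expect_equal(y2$cutoff, exp(y1$cutoff), tolerance = 1e-12)
  expect_equal(roc_curve(exp(sc), lb)$auc, roc_curve(sc, lb)$auc,
               tolerance = 1e-12)
})

test_that("AUC bands follow the printed partition", {
  expect_equal(auc_band(0.790), "moderately_accurate")
  expect_equal(auc_band(0.5), "noninformative")
  expect_equal(auc_band(1.0), "perfect")
  expect_equal(auc_band(0.7), "less_accurate")
  expect_equal(auc_band(0.9), "moderately_accurate")
  expect_equal(auc_band(0.95), "highly_accurate")
  expect_equal(auc_band(0.3), "noninformative")
  expect_error(auc_band(1.2), "\\[0, 1\\]")
})

test_that("confusion summary counts and Wilson intervals are exact", {
  # engineered counts: tp = 98, fn = 50, fp = 23, tn = 89
  sc <- c(rep(2, 98), rep(0, 50), rep(2, 23), rep(0, 89))
  lb <- c(rep(1, 148), rep(0, 112))
  out <- confusion_at(sc, lb, cutoff = 1, n_boot = 50, seed = 1)
  expect_equal(c(out$tp, out$fn, out$fp, out$tn), c(98, 50, 23, 89))
  expect_equal(out$sensitivity, 98 / 148)

  # independent closed-form Wilson evaluation for 98 successes of 148
  z <- qnorm(0.975); p <- 98 / 148; n <- 148
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(out$sensitivity_ci, c(centre - half, centre + half),
               tolerance = 1e-12)
  expect_true(out$ppv_ci[1] <= out$ppv && out$ppv <= out$ppv_ci[2])
})

test_that("degenerate classifiers behave as declared", {
  perfect <- confusion_at(c(1, 1, 0, 0), c(1, 1, 0, 0), cutoff = 1,
                          n_boot = 5, seed = 2)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv), c(1, 1, 1, 1))
  expect_warning(
    allpos <- confusion_at(c(1, 2, 3, 4), c(0, 1, 0, 1), cutoff = -5,
                           n_boot = 5, seed = 3),
    "undefined")
  expect_true(is.na(allpos$npv))
})

test_that("a single bootstrap resample collapses the interval", {
  set.seed(46)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.5 + 0.3 * (sc > 0))
  lb[1:2] <- c(0, 1)
  out <- confusion_at(sc, lb, cutoff = 0, n_boot = 1, seed = 7)
  expect_equal(out$ppv_ci[1], out$ppv_ci[2])
})

test_that("Hanley-McNeil AUC intervals behave across regimes", {
  sep <- c(rnorm(100, 0, 0.1), rnorm(100, 5, 0.1))
  lab <- rep(c(0, 1), each = 100)
  ci <- auc_ci(sep, lab)
  expect_equal(ci$auc, 1)
  expect_gt(ci$ci[1], 0.95)
  expect_lte(ci$ci[2], 1)

  set.seed(47)
  chance <- rnorm(500); clab <- rbinom(500, 1, 0.3)
  ci2 <- auc_ci(chance, clab)
  expect_true(ci2$ci[1] < 0.5 && ci2$ci[2] > 0.5)
  expect_true(all(ci2$ci >= 0 & ci2$ci <= 1))

  boot <- auc_ci(chance, clab, method = "bootstrap", n_boot = 200,
                 seed = 5)
  expect_true(boot$ci[1] < 0.5 && boot$ci[2] > 0.5)
})

test_that("component AUC report is risk-oriented for every component", {
  coh <- complete_cohort(600, seed = 48)
  sc <- cfrs_score(coh)
  lab <- classify_fall_status(coh$falls_12m)$binary == "recurrent"
  aucs <- discrimination_aucs(sc, lab)
  expect_equal(names(aucs)[1], "cfrs")
  expect_length(aucs, 11)
  # protective components discriminate in the risk direction once signed
  expect_gt(aucs[["cognitive"]], 0.5)
  expect_gt(aucs[["fear_of_falling"]], 0.5)
})
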