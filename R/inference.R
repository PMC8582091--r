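#' Cohen's d between fall-status groups from summary statistics
#'
#' Standardized mean difference \eqn{d = (m_{cmp} - m_{ref}) / s_p} with
#' the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_{ref}-1) sd_{ref}^2 + (n_{cmp}-1) sd_{cmp}^2) /
#' (n_{ref}+n_{cmp}-2)}}. The reference group is the occasional fallers
#' and the comparison group the recurrent fallers, so a positive d means
#' the recurrent group scores higher. The confidence interval (default
#' 90\%) uses the normal-approximation standard error
#' \eqn{\sqrt{(n_{ref}+n_{cmp})/(n_{ref} n_{cmp}) + d^2 /
#' (2(n_{ref}+n_{cmp}))}}; a noncentral-t interval is available via
#' \code{method = "noncentral_t"}.
#'
#' @param mean_ref,sd_ref,n_ref Mean, SD and size of the reference group.
#' @param mean_cmp,sd_cmp,n_cmp Mean, SD and size of the comparison group.
#' @param ci_level Confidence level (default 0.90).
#' @param method CI method: \code{"normal"} (default) or
#'   \code{"noncentral_t"}.
#' @return List of class \code{"effect_size"} with \code{d},
#'   \code{ci_low}, \code{ci_high}, \code{ci_level} and \code{magnitude}
#'   (see [classify_magnitude()]).
#' @examples
#' # cognitive performance, occasional vs recurrent fallers
#' cohens_d_from_summary(27.0, 3.2, 356, 22.2, 4.2, 148)$d  # ~ -1.36
#' @export
cohens_d_from_summary <- function(mean_ref, sd_ref, n_ref,
                                  mean_cmp, sd_cmp, n_cmp,
                                  ci_level = 0.90,
                                  method = c("normal", "noncentral_t")) {
  method <- match.arg(method)
  if (sd_ref <= 0 || sd_cmp <= 0) stop("SDs must be positive",
                                       call. = FALSE)
  if (n_ref < 2 || n_cmp < 2) stop("each group needs n >= 2",
                                   call. = FALSE)
  sp <- sqrt(((n_ref - 1) * sd_ref^2 + (n_cmp - 1) * sd_cmp^2) /
               (n_ref + n_cmp - 2))
  d <- (mean_cmp - mean_ref) / sp
  if (method == "normal") {
    se <- sqrt((n_ref + n_cmp) / (n_ref * n_cmp) +
                 d^2 / (2 * (n_ref + n_cmp)))
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    ci <- d + c(-1, 1) * z * se
  } else {
    # invert the noncentral t distribution of the observed t statistic
    nc <- d * sqrt(n_ref * n_cmp / (n_ref + n_cmp))
    df <- n_ref + n_cmp - 2
    alpha <- (1 - ci_level) / 2
    f <- function(delta, p) stats::pt(nc, df, ncp = delta) - p
    lims <- c(nc - 8 - abs(nc), nc + 8 + abs(nc))
    lo <- stats::uniroot(f, lims, p = 1 - alpha)$root
    hi <- stats::uniroot(f, lims, p = alpha)$root
    ci <- c(lo, hi) / sqrt(n_ref * n_cmp / (n_ref + n_cmp))
  }
  structure(list(d = d, ci_low = ci[1], ci_high = ci[2],
                 ci_level = ci_level, magnitude = classify_magnitude(d)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.2f (%.0f%% CI %.2f; %.2f) — %s\n", x$d,
              100 * x$ci_level, x$ci_low, x$ci_high, x$magnitude))
  invisible(x)
}

#' Magnitude label of a standardized effect
#'
#' Classifies \eqn{|d|} against the customary thresholds: trivial
#' (< 0.2), small (0.2 to < 0.6), moderate (0.6 to < 1.2), large (1.2 to
#' < 2.0), very large (>= 2.0). The published bands leave exactly 2.0
#' unassigned ("large" up to but excluding 2.0, "very large" above it);
#' this implementation assigns the boundary to \code{very_large}.
#'
#' @param d Finite effect size (sign ignored).
#' @return One of \code{"trivial"}, \code{"small"}, \code{"moderate"},
#'   \code{"large"}, \code{"very_large"}.
#' @export
classify_magnitude <- function(d) {
  if (!is.finite(d)) stop("d must be finite", call. = FALSE)
  a <- abs(d)
  if (a < 0.2) "trivial"
  else if (a < 0.6) "small"
  else if (a < 1.2) "moderate"
  else if (a < 2.0) "large"
  else "very_large"
}

#' Two-sample t-test between fall-status groups
#'
#' Student's pooled-variance independent-samples t-test (the default),
#' with Welch's unequal-variance variant available by flag. When both
#' groups are constant with equal means the comparison is vacuous and
#' \code{p = 1} by convention.
#'
#' @param values_a,values_b Numeric vectors (each n >= 2).
#' @param welch Use Welch's test instead of the pooled test.
#' @return List of class \code{"group_comparison"}: \code{variable},
#'   \code{means}, \code{sds}, \code{ns}, \code{statistic}, \code{p},
#'   \code{kind = "t"}.
#' @export
two_sample_t <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  degenerate <- stats::var(values_a) == 0 && stats::var(values_b) == 0
  if (degenerate && mean(values_a) == mean(values_b)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else if (degenerate) {
    tt <- list(statistic = c(t = Inf * sign(mean(values_b) -
                                              mean(values_a))),
               p.value = 0)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  }
  structure(list(variable = NA_character_,
                 means = c(mean(values_a), mean(values_b)),
                 sds = c(stats::sd(values_a), stats::sd(values_b)),
                 ns = c(length(values_a), length(values_b)),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 kind = "t"),
            class = "group_comparison")
}

#' Pearson chi-square test of a 2x2 proportion table
#'
#' Pearson statistic \eqn{\sum (O - E)^2 / E} on a 2x2 contingency table,
#' without continuity correction by default (Yates correction by flag).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param correct Apply Yates continuity correction.
#' @return \code{"group_comparison"} with \code{statistic}, \code{p},
#'   \code{kind = "chi_square"}.
#' @export
chi_square_prop <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be a 2x2 table of non-negative integers",
         call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(variable = NA_character_, counts = counts,
                 ns = rowSums(counts),
                 statistic = unname(ct$statistic), p = ct$p.value,
                 kind = "chi_square"),
            class = "group_comparison")
}

#' One-way ANOVA with Tukey post hoc across the three fall-count groups
#'
#' Tests how a quantity (typically the composed fall risk score) varies
#' over the three-level fall grouping (zero falls, one fall, two or
#' more), then compares each pair of groups with Tukey's honestly
#' significant difference based on the studentized range distribution.
#'
#' @param values Numeric vector.
#' @param groups Factor (or vector coercible to one) of group labels
#'   aligned with \code{values}; every group needs >= 2 observations.
#' @return List of class \code{"anova_result"} with \code{F}, \code{p},
#'   \code{group_means}, and \code{tukey}, a data.frame with one row per
#'   pair (\code{pair}, \code{diff}, \code{lwr}, \code{upr},
#'   \code{p_adj}).
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 300, seed = 11))
#' coh <- pool_imputations(impute_fcs(coh, m = 2, maxit = 3, seed = 1))
#' sc <- cfrs_score(coh)
#' anova_tukey(sc$cfrs, classify_fall_status(coh$falls_12m)$three_level)
#' @export
anova_tukey <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  if (length(values) != length(groups)) stop("length mismatch",
                                             call. = FALSE)
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  gm <- tapply(values, groups, mean)
  ssb <- sum(table(groups) * (gm - mean(values))^2)
  sst <- sum((values - mean(values))^2)
  if (ssb <= 1e-12 * max(sst, 1e-12)) {  # identical group means
    Fstat <- 0; p <- 1
    cmb <- utils::combn(levels(groups), 2)
    tk <- data.frame(pair = paste(cmb[2, ], "-", cmb[1, ]),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1)
  } else {
    tab <- summary(fit)[[1]]
    Fstat <- tab["g", "F value"]; p <- tab["g", "Pr(>F)"]
    th <- stats::TukeyHSD(fit)$g
    tk <- data.frame(pair = rownames(th), diff = th[, "diff"],
                     lwr = th[, "lwr"], upr = th[, "upr"],
                     p_adj = th[, "p adj"], row.names = NULL)
  }
  structure(list(F = Fstat, p = p,
                 group_means = tapply(values, groups, mean),
                 group_ns = as.vector(table(groups)), tukey = tk),
            class = "anova_result")
}

#' Minimum sample size for estimating a population proportion
#'
#' Finite-population-corrected sample size for a proportion, as used by
#' the standard epidemiological calculators:
#' \deqn{n = \lceil N z^2 p (1-p) / (e^2 (N-1) + z^2 p (1-p)) \rceil,}
#' capped at the population size \eqn{N}.
#'
#' @param population_N Population size.
#' @param z Normal quantile for the confidence level (1.96 for 95\%).
#' @param error_d Absolute sampling error (e.g. 0.05).
#' @param p Hypothesized outcome frequency in \eqn{(0, 1)}.
#' @return Integer minimum number of participants.
#' @examples
#' min_sample_size(182988, 1.96, 0.05, 0.5)  # 384
#' @export
min_sample_size <- function(population_N, z = 1.96, error_d = 0.05,
                            p = 0.5) {
  stopifnot(population_N >= 1, error_d > 0, p > 0, p < 1, z > 0)
  n <- ceiling((population_N * z^2 * p * (1 - p)) /
                 (error_d^2 * (population_N - 1) + z^2 * p * (1 - p)))
  min(n, population_N)
}

#' Fall-status comparison table for a cohort
#'
#' Builds the descriptive comparison of occasional vs recurrent fallers:
#' group means and SDs, Student's t p-value and Cohen's d with its 90\%
#' interval for every numeric variable supplied (components plus any
#' extras such as age or the composed score).
#'
#' @param cohort A cohort data.frame.
#' @param variables Character vector of numeric column names to compare;
#'   defaults to age plus every registered component present.
#' @param cfrs Optional numeric vector of composed scores to append as a
#'   \code{cfrs} row.
#' @return Data.frame with one row per variable: group means/sds/ns, p,
#'   d, d CI bounds and magnitude.
#' @export
fall_group_table <- function(cohort, variables = NULL, cfrs = NULL) {
  status <- classify_fall_status(cohort$falls_12m)$binary
  if (is.null(variables)) {
    variables <- c("age", intersect(component_registry()$name,
                                    names(cohort)))
  }
  dat <- cohort[, variables, drop = FALSE]
  if (!is.null(cfrs)) dat$cfrs <- cfrs
  rows <- lapply(names(dat), function(v) {
    x <- dat[[v]]
    occ <- x[status == "occasional" & !is.na(x)]
    rec <- x[status == "recurrent" & !is.na(x)]
    tt <- two_sample_t(occ, rec)
    es <- cohens_d_from_summary(mean(occ), stats::sd(occ), length(occ),
                                mean(rec), stats::sd(rec), length(rec))
    data.frame(variable = v,
               mean_occasional = mean(occ), sd_occasional = stats::sd(occ),
               n_occasional = length(occ),
               mean_recurrent = mean(rec), sd_recurrent = stats::sd(rec),
               n_recurrent = length(rec),
               p = tt$p, d = es$d, d_ci_low = es$ci_low,
               d_ci_high = es$ci_high, magnitude = es$magnitude)
  })
  do.call(rbind, rows)
}
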