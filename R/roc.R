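#' ROC curve for discriminating recurrent fallers
#'
#' Builds the full ROC curve of a score against a binary recurrent-faller
#' indicator under the decision rule "positive if score >= threshold".
#' Thresholds are the sorted unique observed scores plus the sentinels
#' \code{-Inf} (everyone positive) and \code{Inf} (everyone negative).
#' The AUC is the trapezoid area over (1 - specificity, sensitivity),
#' which equals the Mann-Whitney probability that a randomly drawn
#' positive outscores a randomly drawn negative (ties counted one half).
#'
#' @param scores Numeric score vector (finite).
#' @param labels Binary indicator of the positive class (recurrent
#'   faller): 0/1, logical, or a factor whose second level is positive.
#' @return Object of class \code{"cfrs_roc"}: list with \code{thresholds}
#'   (increasing), \code{sensitivity}, \code{specificity}, \code{auc},
#'   \code{n_pos}, \code{n_neg}.
#' @examples
#' r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' r$auc  # 0.75
#' @export
roc_curve <- function(scores, labels) {
  lab <- as_binary_label(labels)
  if (length(scores) != length(lab)) stop("length mismatch", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present in labels", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & lab == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & lab == 0) / n_neg,
                 numeric(1))
  # trapezoid over the curve sorted by decreasing threshold
  fpr <- rev(1 - spec); tpr <- rev(sens)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "cfrs_roc")
}

as_binary_label <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary (0 = occasional, 1 = recurrent)",
         call. = FALSE)
  }
  labels
}

#' Mann-Whitney AUC
#'
#' The probability that a randomly drawn positive has a higher score than
#' a randomly drawn negative, ties counted one half — computed from mid
#' ranks, and numerically identical to the trapezoid AUC of [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc_mann_whitney <- function(scores, labels) {
  lab <- as_binary_label(labels)
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present in labels", call. = FALSE)
  }
  r <- rank(scores)  # mid ranks handle ties as 1/2
  (sum(r[lab == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Returns the threshold maximizing Youden's index
#' \eqn{J = sensitivity + specificity - 1}. Ties are broken toward the
#' lowest threshold (the more sensitive cutoff).
#'
#' @param roc A [roc_curve()] result.
#' @return List with \code{cutoff}, \code{sensitivity}, \code{specificity}
#'   and \code{youden_index} at the selected threshold.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "cfrs_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  i <- which.max(j)  # first index = lowest threshold among ties
  list(cutoff = roc$thresholds[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], youden_index = j[i])
}

#' Interpretation band of an AUC
#'
#' Maps an AUC onto the customary accuracy bands: equal to chance at 0.5
#' (noninformative), less accurate in (0.5, 0.7], moderately accurate in
#' (0.7, 0.9], highly accurate in (0.9, 1.0), and perfect at 1.0. An AUC
#' below 0.5 (worse than chance in the stated direction) is labelled
#' noninformative.
#'
#' @param auc Numeric in \eqn{[0, 1]}.
#' @return One of \code{"noninformative"}, \code{"less_accurate"},
#'   \code{"moderately_accurate"}, \code{"highly_accurate"},
#'   \code{"perfect"}.
#' @export
auc_band <- function(auc) {
  if (length(auc) != 1 || is.na(auc) || auc < 0 || auc > 1) {
    stop("auc must be a single value in [0, 1]", call. = FALSE)
  }
  if (auc == 1) "perfect"
  else if (auc > 0.9) "highly_accurate"
  else if (auc > 0.7) "moderately_accurate"
  else if (auc > 0.5) "less_accurate"
  else "noninformative"
}

# Wilson score interval for a binomial proportion (no continuity
# correction unless requested) — the interval family used by the standard
# clinical sensitivity/specificity calculators.
wilson_ci <- function(x, n, conf = 0.95, correct = FALSE) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  if (!correct) {
    mid <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- mid - half; hi <- mid + half
  } else {
    denom <- 2 * (n + z^2)
    lo <- (2 * n * p + z^2 - 1 -
             z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / denom
    hi <- (2 * n * p + z^2 + 1 +
             z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / denom
    if (p == 0) lo <- 0
    if (p == 1) hi <- 1
  }
  c(max(0, lo), min(1, hi))
}

#' Confusion summary at a cutoff
#'
#' Classifies with the rule "score >= cutoff is a predicted recurrent
#' faller" and reports sensitivity, specificity, and positive/negative
#' predictive values. Sensitivity and specificity carry Wilson score 95\%
#' intervals; the predictive values carry percentile-bootstrap intervals
#' over participant-level resamples at the fixed cutoff.
#'
#' @inheritParams roc_curve
#' @param cutoff Decision threshold in score units.
#' @param n_boot Bootstrap resamples for the predictive-value intervals.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return List with counts \code{tp}, \code{fp}, \code{tn}, \code{fn}
#'   and, for each of \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}, the point estimate and \code{ci} (length 2). A predictive
#'   value is \code{NA} (with a warning) when no participant falls in the
#'   predicted class.
#' @export
confusion_at <- function(scores, labels, cutoff, n_boot = 2000,
                         seed = 1L, conf = 0.95) {
  lab <- as_binary_label(labels)
  stopifnot(length(scores) == length(lab), n_boot >= 1)
  counts <- function(sc, lb) {
    pred <- sc >= cutoff
    c(tp = sum(pred & lb == 1), fp = sum(pred & lb == 0),
      tn = sum(!pred & lb == 0), fn = sum(!pred & lb == 1))
  }
  ct <- counts(scores, lab)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(ct["tp"], ct["tp"] + ct["fn"])
  spec <- rate(ct["tn"], ct["tn"] + ct["fp"])
  ppv <- rate(ct["tp"], ct["tp"] + ct["fp"])
  npv <- rate(ct["tn"], ct["tn"] + ct["fn"])
  if (is.na(ppv) || is.na(npv)) {
    warning("cutoff assigns every participant to one class; the empty ",
            "class's predictive value is undefined", call. = FALSE)
  }
  set.seed(seed)
  n <- length(scores)
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("ppv", "npv")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cb <- counts(scores[idx], lab[idx])
    boot[b, 1] <- rate(cb["tp"], cb["tp"] + cb["fp"])
    boot[b, 2] <- rate(cb["tn"], cb["tn"] + cb["fn"])
  }
  a <- (1 - conf) / 2
  bci <- function(col) {
    v <- boot[, col]
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    unname(stats::quantile(v, c(a, 1 - a), type = 7))
  }
  list(tp = unname(ct["tp"]), fp = unname(ct["fp"]),
       tn = unname(ct["tn"]), fn = unname(ct["fn"]),
       cutoff = cutoff,
       sensitivity = unname(sens),
       sensitivity_ci = wilson_ci(ct["tp"], ct["tp"] + ct["fn"], conf),
       specificity = unname(spec),
       specificity_ci = wilson_ci(ct["tn"], ct["tn"] + ct["fp"], conf),
       ppv = unname(ppv), ppv_ci = bci("ppv"),
       npv = unname(npv), npv_ci = bci("npv"))
}

#' Confidence interval for the AUC
#'
#' Default method: Hanley-McNeil standard error of the Mann-Whitney AUC
#' with a normal interval, clipped into \eqn{[0, 1]}. Alternatively a
#' percentile bootstrap over participant-level resamples.
#'
#' @inheritParams roc_curve
#' @param conf Confidence level (default 0.95).
#' @param method \code{"hanley_mcneil"} or \code{"bootstrap"}.
#' @param n_boot,seed Bootstrap settings (used only for
#'   \code{method = "bootstrap"}).
#' @return List with \code{auc}, \code{ci} (length 2) and \code{method}.
#' @export
auc_ci <- function(scores, labels, conf = 0.95,
                   method = c("hanley_mcneil", "bootstrap"),
                   n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  lab <- as_binary_label(labels)
  a <- auc_mann_whitney(scores, lab)
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)
  if (method == "hanley_mcneil") {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                  (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- c(max(0, a - z * se), min(1, a + z * se))
  } else {
    set.seed(seed)
    n <- length(scores)
    reps <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(lab[idx])) < 2) NA_real_
      else auc_mann_whitney(scores[idx], lab[idx])
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(auc = a, ci = ci, method = method)
}

#' Component-wise and composite discrimination of recurrent fallers
#'
#' Convenience wrapper used by the reporting pipeline: computes the AUC of
#' the composed score and of each individual component's signed z-score
#' (risk-oriented, so protective components are negated and every AUC is
#' comparable on the "higher = riskier" scale).
#'
#' @param score A \code{"cfrs_score"} from [cfrs_score()].
#' @param labels Binary recurrent-faller indicator aligned with the score.
#' @return Named numeric vector of AUCs: \code{cfrs} first, then one per
#'   component.
#' @export
discrimination_aucs <- function(score, labels) {
  stopifnot(inherits(score, "cfrs_score"))
  lab <- as_binary_label(labels)
  out <- c(cfrs = auc_mann_whitney(score$cfrs, lab))
  for (v in colnames(score$z)) {
    out[v] <- auc_mann_whitney(score$signs[v] * score$z[, v], lab)
  }
  out
}
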