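#' Fully conditional specification imputation of missing components
#'
#' Replaces missing component values by chained stochastic regressions:
#' for each of \code{m} completed tables, missing cells are initialized by
#' random draws from the variable's observed values, then the algorithm
#' cycles \code{maxit} times over the variables with missingness,
#' regressing each on all other components plus age and sex (on the
#' currently completed data) and replacing its missing cells with the
#' regression prediction plus Gaussian noise scaled by the residual
#' standard deviation. Imputed values are clipped into the component's
#' valid range (and rounded for count-valued components). Observed cells
#' are never altered. Demographics (\code{age}, \code{sex},
#' \code{falls_12m}) must be fully observed and are used as predictors
#' only; body-composition fields are not imputed.
#'
#' @param cohort A cohort data.frame (see [cohort]).
#' @param m Number of completed tables (default 8).
#' @param maxit Burn-in cycles over the incomplete variables per table.
#' @param seed Integer seed; a fixed seed makes the result bit-identical.
#' @param registry Component registry.
#' @return Object of class \code{"cfrs_imputation"}: list with
#'   \code{data} (the input), \code{imputations} (list of \code{m}
#'   completed cohorts), \code{m}, \code{maxit}, \code{seed}, and
#'   \code{trace}, a data.frame of per-iteration means of the imputed
#'   cells (columns \code{imputation}, \code{iteration}, \code{variable},
#'   \code{mean_imputed}) for convergence checking.
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 150, seed = 3))
#' imp <- impute_fcs(coh, m = 2, maxit = 3, seed = 9)
#' sapply(imp$imputations, function(d) sum(is.na(d$balance)))
#' @export
impute_fcs <- function(cohort, m = 8, maxit = 10, seed = 1L,
                       registry = component_registry()) {
  cohort <- validate_cohort(cohort, registry)
  stopifnot(m >= 1, maxit >= 1)
  if (anyNA(cohort$age) || anyNA(cohort$sex) || anyNA(cohort$falls_12m)) {
    stop("age, sex and falls_12m must be fully observed", call. = FALSE)
  }
  comps <- intersect(registry$name, names(cohort))
  na_counts <- vapply(cohort[comps], function(x) sum(is.na(x)), integer(1))
  incomplete <- comps[na_counts > 0]
  for (v in incomplete) {
    n_obs <- sum(!is.na(cohort[[v]]))
    if (n_obs == 0) stop("variable '", v, "' is fully missing",
                         call. = FALSE)
    if (n_obs < 10) stop("variable '", v, "' has fewer than 10 observed ",
                         "cells; cannot impute", call. = FALSE)
  }

  set.seed(seed)
  sexm <- as.numeric(cohort$sex == "male")
  trace <- list()
  imputations <- vector("list", m)
  for (k in seq_len(m)) {
    work <- cohort
    if (length(incomplete) == 0) {
      imputations[[k]] <- work
      next
    }
    for (v in incomplete) {  # initialize from the observed distribution
      obs <- work[[v]][!is.na(work[[v]])]
      nas <- is.na(work[[v]])
      work[[v]][nas] <- sample(obs, sum(nas), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in incomplete) {
        nas <- is.na(cohort[[v]])
        preds <- setdiff(comps, v)
        X <- cbind(1, as.matrix(work[, preds, drop = FALSE]),
                   age = cohort$age, sexmale = sexm)
        fit <- stats::lm.fit(X, work[[v]])
        keep <- !is.na(fit$coefficients)
        sigma <- sqrt(sum(fit$residuals^2) /
                        max(1, length(fit$residuals) - sum(keep)))
        pred <- X[nas, keep, drop = FALSE] %*% fit$coefficients[keep]
        draw <- pred + stats::rnorm(sum(nas)) * sigma
        lo <- registry[v, "lower"]; hi <- registry[v, "upper"]
        if (registry[v, "integer"]) draw <- round(draw)
        work[[v]][nas] <- pmin(pmax(draw, lo), hi)
        trace[[length(trace) + 1]] <- data.frame(
          imputation = k, iteration = it, variable = v,
          mean_imputed = mean(work[[v]][nas]))
      }
    }
    imputations[[k]] <- work
  }
  structure(list(data = cohort, imputations = imputations, m = m,
                 maxit = maxit, seed = seed,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(imputation = integer(),
                                         iteration = integer(),
                                         variable = character(),
                                         mean_imputed = numeric())),
            class = "cfrs_imputation")
}

#' @export
print.cfrs_imputation <- function(x, ...) {
  nmiss <- sum(is.na(as.matrix(
    x$data[intersect(component_registry()$name, names(x$data))])))
  cat("FCS imputation:", x$m, "completed tables,", x$maxit,
      "iterations,", nmiss, "missing cells filled per table\n")
  invisible(x)
}

#' Pool aligned per-imputation vectors
#'
#' Element-wise mean of \code{m} aligned vectors (e.g. one score vector
#' per completed table), the default policy for collapsing multiple
#' imputations into a single per-participant quantity.
#'
#' @param per_table A list of numeric vectors of equal length, or a
#'   matrix with one column per imputation.
#' @return Numeric vector of element-wise means.
#' @examples
#' pool_scores(list(c(1, 5), c(3, 7)))  # c(2, 6)
#' @export
pool_scores <- function(per_table) {
  if (is.list(per_table)) {
    lens <- lengths(per_table)
    if (length(unique(lens)) != 1) {
      stop("vectors have mismatched lengths: ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    }
    per_table <- do.call(cbind, per_table)
  }
  rowMeans(as.matrix(per_table))
}

#' Average the completed tables into one pooled cohort
#'
#' Collapses an imputation result by replacing every imputed component
#' cell with its mean across the \code{m} completions (observed cells are
#' identical across completions and pass through unchanged). This is the
#' default "average, then score" policy; the alternative — score every
#' completed table and average the scores with [pool_scores()] — is
#' available by iterating over \code{x$imputations}.
#'
#' @param x A \code{"cfrs_imputation"} result.
#' @return A single complete cohort data.frame.
#' @export
pool_imputations <- function(x) {
  stopifnot(inherits(x, "cfrs_imputation"))
  out <- x$imputations[[1]]
  comps <- intersect(component_registry()$name, names(out))
  if (x$m > 1) {
    for (v in comps) {
      stack <- vapply(x$imputations, function(d) d[[v]],
                      numeric(nrow(out)))
      out[[v]] <- rowMeans(stack)
    }
  }
  attr(out, "provenance") <- c(attr(x$data, "provenance"),
                               list(imputation = "pooled mean of m tables",
                                    m = x$m, imputation_seed = x$seed))
  out
}
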