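#' Age- and sex-adjusted standardized residual of one component
#'
#' Regresses a component on age and sex by ordinary least squares and
#' returns the standardized residuals \eqn{z_i = (y_i - \hat y_i) / s},
#' where \eqn{s} is the sample standard deviation (denominator \eqn{n-1})
#' of the residuals. Over the fitting sample the z-scores have mean 0,
#' SD 1, and are uncorrelated with age and with the sex indicator.
#'
#' When the sample contains a single sex (as inside the sex-stratified
#' scoring mode) the sex term is dropped and the adjustment is on age
#' alone.
#'
#' @param values Numeric component vector, no missing values, length >= 4.
#' @param age Numeric age vector (non-constant).
#' @param sex Factor with levels \code{female}, \code{male}.
#' @param name Component name used in error messages.
#' @return Object of class \code{"component_z"}: a list with \code{z},
#'   \code{coefficients} (intercept, age slope and, when present, the
#'   male-vs-female contrast), \code{residual_sd} and \code{n}.
#' @examples
#' z <- residual_zscore(c(2, 1, 4, 3), c(65, 70, 75, 80),
#'                      factor(rep("female", 4), c("female", "male")))
#' round(mean(z$z), 12)
#' @export
residual_zscore <- function(values, age, sex, name = "component") {
  n <- length(values)
  stopifnot(length(age) == n, length(sex) == n)
  if (anyNA(values) || anyNA(age) || anyNA(sex)) {
    stop(name, ": missing values; impute before scoring", call. = FALSE)
  }
  if (n < 4) stop(name, ": need at least 4 observations", call. = FALSE)
  if (stats::var(age) == 0) stop("age is constant", call. = FALSE)
  sex <- factor(sex, levels = c("female", "male"))
  X <- cbind(`(Intercept)` = 1, age = age)
  if (nlevels(droplevels(sex)) == 2) {
    X <- cbind(X, sexmale = as.numeric(sex == "male"))
  }
  fit <- stats::lm.fit(X, values)
  res <- fit$residuals
  rsd <- stats::sd(res)
  if (!is.finite(rsd) || rsd <= 1e-8 * max(1, stats::sd(values))) {
    stop("degenerate component '", name,
         "': residual variance is (numerically) zero after the age/sex ",
         "regression", call. = FALSE)
  }
  structure(list(z = res / rsd, coefficients = fit$coefficients,
                 residual_sd = rsd, n = n),
            class = "component_z")
}

#' Compose the continuous fall risk score from component z-scores
#'
#' Sums the per-component standardized residuals with sign \eqn{-1} for
#' protective components and \eqn{+1} for risk-increasing components:
#' \eqn{cFRs_i = \sum_k s_k z_{ik}}. Over the fitting sample the score has
#' mean zero by construction.
#'
#' @param z Either a numeric matrix (participants x components, columns
#'   named by component) or a named list of [residual_zscore()] results.
#' @param registry Component registry; all its components must be present.
#' @return List with \code{cfrs} (numeric vector), \code{z} (the unsigned
#'   z matrix) and \code{signs} (the direction map used).
#' @export
compose_cfrs <- function(z, registry = component_registry()) {
  if (is.list(z) && !is.data.frame(z) && !is.matrix(z)) {
    z <- vapply(z, function(c) {
      if (inherits(c, "component_z")) c$z else as.numeric(c)
    }, numeric(length(if (inherits(z[[1]], "component_z")) z[[1]]$z
                      else z[[1]])))
  }
  z <- as.matrix(z)
  absent <- setdiff(registry$name, colnames(z))
  if (length(absent)) {
    stop("cannot compose score; missing component(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  z <- z[, registry$name, drop = FALSE]
  s <- score_signs(registry)
  list(cfrs = as.vector(z %*% s), z = z, signs = s)
}

#' Continuous fall risk score of a complete cohort
#'
#' End-to-end scoring: fits the age/sex regression of every registered
#' component over the cohort, standardizes the residuals, applies the
#' protective-component sign flips and sums. The cohort must be complete
#' (no missing component values); run [impute_fcs()] first when needed.
#'
#' By default a single pooled regression with a sex indicator is fitted
#' per component. With \code{stratify_by_sex = TRUE} each component is
#' instead regressed on age separately within women and within men, and
#' standardized within the stratum, yielding a fully sex-specific score.
#'
#' @param cohort A complete cohort data.frame (see [cohort]) with at
#'   least two participants of each sex and non-constant age.
#' @param registry Component registry.
#' @param stratify_by_sex Fit and standardize per sex instead of pooling
#'   with a sex covariate.
#' @return Object of class \code{"cfrs_score"}: list with \code{cfrs}
#'   (per-participant score, input order preserved), \code{z} (unsigned
#'   z matrix), \code{signs}, and \code{model} (a \code{"cfrs_model"}
#'   holding the fitted coefficients and residual SDs, reusable on new
#'   data via [predict.cfrs_model()]).
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 120, missing_rates =
#'   stats::setNames(numeric(10), component_registry()$name), seed = 7))
#' sc <- cfrs_score(coh)
#' round(mean(sc$cfrs), 10)  # 0 by construction
#' @export
cfrs_score <- function(cohort, registry = component_registry(),
                       stratify_by_sex = FALSE) {
  cohort <- validate_cohort(cohort, registry)
  absent <- setdiff(registry$name, names(cohort))
  if (length(absent)) {
    stop("cohort lacks component column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) < 4) stop("need at least 4 participants", call. = FALSE)
  if (min(table(cohort$sex)) < 2) {
    stop("need at least 2 participants of each sex", call. = FALSE)
  }
  comp <- as.matrix(cohort[, registry$name, drop = FALSE])
  if (anyNA(comp)) {
    stop("cohort has missing component values; impute first (impute_fcs)",
         call. = FALSE)
  }

  n <- nrow(cohort)
  zmat <- matrix(NA_real_, n, nrow(registry),
                 dimnames = list(NULL, registry$name))
  fits <- list()
  if (!stratify_by_sex) {
    for (v in registry$name) {
      cz <- residual_zscore(comp[, v], cohort$age, cohort$sex, name = v)
      zmat[, v] <- cz$z
      fits[[v]] <- cz[c("coefficients", "residual_sd")]
    }
  } else {
    for (lev in levels(cohort$sex)) {
      idx <- which(cohort$sex == lev)
      for (v in registry$name) {
        cz <- residual_zscore(comp[idx, v], cohort$age[idx],
                              cohort$sex[idx], name = paste0(v, ":", lev))
        zmat[idx, v] <- cz$z
        fits[[lev]][[v]] <- cz[c("coefficients", "residual_sd")]
      }
    }
  }
  comp_out <- compose_cfrs(zmat, registry)
  model <- structure(list(fits = fits, stratified = stratify_by_sex,
                          signs = comp_out$signs,
                          components = registry$name),
                     class = "cfrs_model")
  structure(list(cfrs = comp_out$cfrs, z = zmat, signs = comp_out$signs,
                 model = model, stratified = stratify_by_sex),
            class = "cfrs_score")
}

#' @export
print.cfrs_score <- function(x, ...) {
  cat("Continuous fall risk score:", length(x$cfrs), "participants",
      if (x$stratified) "(sex-stratified fit)" else "(pooled fit)", "\n")
  cat(sprintf("  mean %.3f, sd %.3f, range [%.2f, %.2f]\n",
              mean(x$cfrs), stats::sd(x$cfrs), min(x$cfrs), max(x$cfrs)))
  invisible(x)
}

#' Apply a frozen score model to new participants
#'
#' Scores new data against the regression coefficients and residual SDs
#' of an earlier fit, instead of re-standardizing within the new sample.
#' The score is sample-specific: z-scores of the new participants are
#' relative to the reference cohort the model was fitted on.
#'
#' @param object A \code{"cfrs_model"} from [cfrs_score()].
#' @param newdata A complete cohort data.frame.
#' @param ... Unused.
#' @return Numeric vector of scores, one per row of \code{newdata}.
#' @export
predict.cfrs_model <- function(object, newdata, ...) {
  comp <- as.matrix(newdata[, object$components, drop = FALSE])
  if (anyNA(comp)) stop("newdata has missing component values",
                        call. = FALSE)
  sexm <- as.numeric(factor(newdata$sex,
                            levels = c("female", "male")) == "male")
  one_z <- function(fit, y, age, male) {
    b <- fit$coefficients
    pred <- b[["(Intercept)"]] + b[["age"]] * age +
      (if ("sexmale" %in% names(b)) b[["sexmale"]] * male else 0)
    (y - pred) / fit$residual_sd
  }
  z <- matrix(NA_real_, nrow(newdata), length(object$components),
              dimnames = list(NULL, object$components))
  if (!object$stratified) {
    for (v in object$components) {
      z[, v] <- one_z(object$fits[[v]], comp[, v], newdata$age, sexm)
    }
  } else {
    for (lev in c("female", "male")) {
      idx <- which(newdata$sex == lev)
      if (!length(idx)) next
      for (v in object$components) {
        z[idx, v] <- one_z(object$fits[[lev]][[v]], comp[idx, v],
                           newdata$age[idx], sexm[idx])
      }
    }
  }
  as.vector(z %*% object$signs[object$components])
}

#' Save / load a frozen score model as structured text
#'
#' The model artifact (coefficients, residual SDs, direction map, mode)
#' is serialized as YAML so reference fits can be stored in version
#' control and reapplied with [predict.cfrs_model()].
#'
#' @param model A \code{"cfrs_model"}.
#' @param path File path.
#' @return \code{path} invisibly (save) or the model (load).
#' @export
save_cfrs_model <- function(model, path) {
  stopifnot(inherits(model, "cfrs_model"))
  obj <- list(stratified = model$stratified,
              components = as.list(model$components),
              signs = as.list(model$signs),
              fits = rapply(model$fits, as.list, how = "replace"))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_cfrs_model
#' @export
load_cfrs_model <- function(path) {
  obj <- yaml::read_yaml(path)
  tidy <- function(f) list(coefficients = unlist(f$coefficients),
                           residual_sd = f$residual_sd)
  fits <- if (obj$stratified) lapply(obj$fits, lapply, tidy)
          else lapply(obj$fits, tidy)
  structure(list(fits = fits, stratified = obj$stratified,
                 signs = unlist(obj$signs),
                 components = unlist(obj$components)),
            class = "cfrs_model")
}
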