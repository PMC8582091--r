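#' Two-group component profile used as generator default
#'
#' Per-component means and standard deviations for occasional fallers
#' (one fall or none in 12 months) and recurrent fallers (two or more),
#' as reported for the Portuguese community-dwelling cohort of 504 older
#' adults in which the continuous fall risk score was developed. These are
#' the default marginals of [simulate_cohort()].
#'
#' @return Data.frame with columns \code{name}, \code{mean_occasional},
#'   \code{sd_occasional}, \code{mean_recurrent}, \code{sd_recurrent};
#'   row names equal component names.
#' @export
default_component_profile <- function() {
  p <- data.frame(
    name = component_registry()$name,
    mean_occasional = c(2.2, 2.4, 27.0, 21.2, 30.3, 20.1, 8.5, 11.6,
                        2069.5, 11.2),
    sd_occasional   = c(1.6, 1.5, 3.2, 3.5, 6.1, 4.9, 7.3, 1.1,
                        1933.7, 6.5),
    mean_recurrent  = c(3.3, 4.0, 22.2, 19.1, 26.5, 25.9, 7.9, 11.1,
                        1753.6, 9.5),
    sd_recurrent    = c(2.2, 1.7, 4.2, 5.1, 9.0, 8.6, 7.0, 1.8,
                        1712.9, 6.8),
    stringsAsFactors = FALSE
  )
  rownames(p) <- p$name
  p
}

#' Default marginal missingness rates per component
#'
#' The per-variable missingness proportions observed in the development
#' cohort; components absent from the list were fully observed.
#'
#' @return Named numeric vector over all ten components.
#' @export
default_missing_rates <- function() {
  r <- stats::setNames(numeric(10), component_registry()$name)
  r[c("cognitive", "physical_function", "balance", "fear_of_falling",
      "affordance_error", "gait", "physical_activity")] <-
    c(0.013, 0.028, 0.011, 0.017, 0.085, 0.043, 0.046)
  r
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of [simulate_cohort()]. The defaults emulate the
#' development cohort: 29.4\% recurrent fallers, 77.6\% women, the
#' two-group component means/SDs of [default_component_profile()], group
#' ages 73.1 (SD 6.4) and 73.8 (SD 6.5) years, and the observed per-variable
#' missingness rates. Within each fall-status group the components are
#' drawn from a multivariate normal with exchangeable correlation
#' \code{rho} applied on the risk-aligned scale (protective components are
#' negated before correlating and negated back), so that a positive
#' \code{rho} means deficits co-occur: a participant with many impairments
#' also tends toward worse balance, worse gait and more fear of falling.
#'
#' @param n Number of participants.
#' @param prevalence_recurrent Probability of being a recurrent faller.
#' @param prop_female Probability of being female.
#' @param profile Component profile data.frame, see
#'   [default_component_profile()].
#' @param rho Exchangeable within-group correlation between risk-aligned
#'   components, in \eqn{(-1/9, 1]} for positive semi-definiteness.
#' @param age_occasional,age_recurrent Length-2 \code{c(mean, sd)} of age
#'   per group (years; draws are clipped at 65).
#' @param zero_split Probability that an occasional faller reports zero
#'   falls rather than one.
#' @param falls_lambda Poisson mean of the number of falls beyond two for
#'   recurrent fallers (\code{falls_12m = 2 + rpois(falls_lambda)}).
#' @param missing_rates Named vector of marginal missingness proportions
#'   per component, each in \eqn{[0, 1)}.
#' @param include_body Also generate weight/height/waist and derived bmi?
#' @param seed Integer seed governing all randomness of the draw.
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n = 504,
                          prevalence_recurrent = 0.294,
                          prop_female = 0.776,
                          profile = default_component_profile(),
                          rho = 0.2,
                          age_occasional = c(73.1, 6.4),
                          age_recurrent = c(73.8, 6.5),
                          zero_split = 0.7,
                          falls_lambda = 1,
                          missing_rates = default_missing_rates(),
                          include_body = TRUE,
                          seed = 1L) {
  cfg <- list(n = n, prevalence_recurrent = prevalence_recurrent,
              prop_female = prop_female, profile = profile, rho = rho,
              age_occasional = age_occasional, age_recurrent = age_recurrent,
              zero_split = zero_split, falls_lambda = falls_lambda,
              missing_rates = missing_rates, include_body = include_body,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  reg <- component_registry()
  if (cfg$n < 0 || cfg$n != round(cfg$n)) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  props <- c(cfg$prevalence_recurrent, cfg$prop_female, cfg$zero_split)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(cfg$profile$name, reg$name)) {
    stop("profile must cover exactly the registered components",
         call. = FALSE)
  }
  if (any(cfg$profile$sd_occasional <= 0) ||
      any(cfg$profile$sd_recurrent <= 0)) {
    stop("component SDs must be positive", call. = FALSE)
  }
  if (any(c(cfg$age_occasional[2], cfg$age_recurrent[2]) <= 0)) {
    stop("age SDs must be positive", call. = FALSE)
  }
  k <- nrow(reg)
  if (cfg$rho > 1 || cfg$rho <= -1 / (k - 1)) {
    stop("rho outside the positive semi-definite range (-1/",
         k - 1, ", 1]", call. = FALSE)
  }
  mr <- cfg$missing_rates
  if (is.null(names(mr)) || !all(names(mr) %in% reg$name)) {
    stop("missing_rates must be named by registered components",
         call. = FALSE)
  }
  if (any(mr < 0 | mr >= 1)) {
    stop("missing rates must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a cohort with the two-faller-group structure
#'
#' Draws a synthetic cohort under a [cohort_config()]: fall-status group
#' membership is Bernoulli, components come from a group-conditional
#' multivariate normal with exchangeable risk-aligned correlation,
#' count-valued components are rounded, every component is clipped into
#' its registry range, fall counts are drawn consistently with the group,
#' and missingness is applied missing-at-random with the probability
#' depending on the (always observed) age tertile: the oldest tertile has
#' 1.5 times the rate of the younger two, renormalized so the marginal
#' rate matches the configured target.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer overriding \code{config$seed}.
#' @return A validated cohort data.frame (see [cohort]) with a
#'   \code{"provenance"} attribute recording kind, seed and n.
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 200, seed = 42))
#' table(classify_fall_status(coh$falls_12m)$binary)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  reg <- component_registry()
  k <- nrow(reg)
  n <- config$n

  empty <- function() {
    cols <- c(mandatory_columns(), reg$name,
              if (config$include_body) body_columns())
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
    out$id <- character(0)
    out$sex <- factor(character(0), levels = c("female", "male"))
    attr(out, "provenance") <- list(kind = "synthetic", seed = seed, n = 0)
    out
  }
  if (n == 0) return(empty())

  set.seed(seed)
  # Draw order is fixed and documented: group, sex, age, component error
  # matrix, falls, body fields, missingness mask.
  recurrent <- stats::rbinom(n, 1, config$prevalence_recurrent) == 1
  sex <- factor(ifelse(stats::rbinom(n, 1, config$prop_female) == 1,
                       "female", "male"), levels = c("female", "male"))
  age_par <- rbind(config$age_occasional, config$age_recurrent)
  g <- recurrent + 1L
  age <- pmax(65, stats::rnorm(n, age_par[g, 1], age_par[g, 2]))

  # Exchangeable correlation on the risk-aligned scale: negate protective
  # columns, correlate, negate back — equivalent to conjugating R by the
  # sign vector.
  s <- score_signs(reg)
  R <- matrix(config$rho, k, k) + diag(1 - config$rho, k)
  R <- R * tcrossprod(s)
  diag(R) <- 1
  E <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)

  prof <- config$profile[reg$name, ]
  mu <- cbind(prof$mean_occasional, prof$mean_recurrent)
  sdv <- cbind(prof$sd_occasional, prof$sd_recurrent)
  comp <- mu[cbind(rep(seq_len(k), each = n), rep(g, k))] +
    sdv[cbind(rep(seq_len(k), each = n), rep(g, k))] * as.vector(E)
  comp <- matrix(comp, n, k, dimnames = list(NULL, reg$name))
  for (j in seq_len(k)) {
    if (reg$integer[j]) comp[, j] <- round(comp[, j])
    comp[, j] <- pmin(pmax(comp[, j], reg$lower[j]), reg$upper[j])
  }

  falls <- integer(n)
  n_occ <- sum(!recurrent)
  falls[!recurrent] <- stats::rbinom(n_occ, 1, 1 - config$zero_split)
  falls[recurrent] <- 2L + stats::rpois(sum(recurrent),
                                        config$falls_lambda)

  out <- data.frame(id = sprintf("S%05d", seq_len(n)), age = age,
                    sex = sex, falls_12m = falls,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(comp))

  if (config$include_body) {
    body_mu <- rbind(occ = c(70.0, 155.8, 97.0), rec = c(69.5, 155.4, 96.1))
    body_sd <- rbind(occ = c(11.9, 8.6, 10.9), rec = c(11.3, 7.7, 11.0))
    out$weight <- pmax(35, stats::rnorm(n, body_mu[g, 1], body_sd[g, 1]))
    out$height <- pmax(130, stats::rnorm(n, body_mu[g, 2], body_sd[g, 2]))
    out$waist <- pmax(50, stats::rnorm(n, body_mu[g, 3], body_sd[g, 3]))
    out$bmi <- out$weight / (out$height / 100)^2
  }

  # MAR missingness keyed to age tertile: the oldest third carries a 1.5x
  # relative rate; rates renormalized so the marginal matches the target.
  tert <- age >= stats::quantile(age, 2 / 3)
  mult <- ifelse(tert, 1.5, 1)
  scale <- mean(mult)  # ~ (2 + 1.5) / 3
  for (v in names(config$missing_rates)) {
    rate <- config$missing_rates[[v]]
    if (rate > 0) {
      p_cell <- pmin(rate * mult / scale, 0.99)
      out[[v]][stats::runif(n) < p_cell] <- NA
    }
  }

  out <- validate_cohort(out, reg)
  attr(out, "provenance") <- list(kind = "synthetic", seed = seed, n = n)
  out
}
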