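# Shared fixtures, built in code.

no_missing <- stats::setNames(numeric(10), component_registry()$name)

# A fully observed synthetic cohort.
complete_cohort <- function(n = 200, seed = 1, ...) {
  simulate_cohort(cohort_config(n = n, missing_rates = no_missing,
                                seed = seed, ...))
}

# A tiny hand-written cohort for IO tests: 3 participants, one missing
# affordance cell.
tiny_cohort_csv <- function(path = tempfile(fileext = ".csv"),
                            mmse = c(28, 26, 24)) {
  lines <- c(
    paste("id,age,sex,falls_12m,chronic_diseases,physical_impairments,",
          "cognitive,physical_function,balance,fear_of_falling,",
          "affordance_error,gait,physical_activity,environmental_hazards",
          sep = ""),
    sprintf("p1,70,F,0,2,1,%s,22,35,18,5.5,12,1200,8", mmse[1]),
    sprintf("p2,81,male,2,4,3,%s,18,25,30,,10,400,15", mmse[2]),
    sprintf("p3,67,Female,1,1,2,%s,24,38,16,2.1,11,2500,3", mmse[3]))
  writeLines(lines, path)
  path
}

# Expected mean of clip(X, lo, hi) for X ~ N(mu, sd): closed form for the
# censored normal; for integer-valued components the draw is rounded
# first, so the expectation is the exact sum over the integer grid.
clipped_normal_mean <- function(mu, sd, lo, hi, integer = FALSE) {
  if (!integer) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    lo_term <- if (is.finite(lo)) lo * stats::pnorm(a) else 0
    hi_term <- if (is.finite(hi)) hi * (1 - stats::pnorm(b)) else 0
    mid <- mu * (stats::pnorm(b) - stats::pnorm(a)) -
      sd * (stats::dnorm(b) - stats::dnorm(a))
    lo_term + hi_term + mid
  } else {
    ks <- seq(max(lo, floor(mu - 12 * sd)),
              min(hi, ceiling(mu + 12 * sd)))
    p <- stats::pnorm(ks + 0.5, mu, sd) - stats::pnorm(ks - 0.5, mu, sd)
    # probability mass clipped onto the bounds
    p[1] <- p[1] + stats::pnorm(ks[1] - 0.5, mu, sd)
    p[length(p)] <- p[length(p)] +
      (1 - stats::pnorm(ks[length(ks)] + 0.5, mu, sd))
    sum(ks * p)
  }
}
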