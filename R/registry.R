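#' Registry of the ten fall-risk score components
#'
#' Returns the component registry used throughout the package: one row per
#' score component, declaring its role (intrinsic risk factor vs. exposure),
#' its direction with respect to fall risk, its valid range, and whether it
#' is count-valued. The six \code{protective} components (cognitive
#' performance, physical function, multidimensional balance, affordance
#' perception accuracy, gait, and physical activity) are the ones whose
#' standardized residuals are multiplied by \eqn{-1} before summation into
#' the continuous fall risk score, so that a higher score always means a
#' higher risk of falling.
#'
#' @return A data.frame with one row per component and columns
#'   \code{name}, \code{label}, \code{role} (\code{"intrinsic"} or
#'   \code{"exposure"}), \code{direction} (\code{"risk_increasing"} or
#'   \code{"protective"}), \code{lower}, \code{upper} (valid closed range;
#'   \code{Inf} for unbounded above), \code{integer} (count-valued?) and
#'   \code{units}. Row names equal \code{name}.
#'
#' @examples
#' reg <- component_registry()
#' reg[reg$direction == "protective", "name"]
#'
#' @seealso [score_signs()], [validate_cohort()]
#' @export
component_registry <- function() {
  reg <- data.frame(
    name = c("chronic_diseases", "physical_impairments", "cognitive",
             "physical_function", "balance", "fear_of_falling",
             "affordance_error", "gait", "physical_activity",
             "environmental_hazards"),
    label = c("Chronic diseases", "Physical impairments",
              "Cognitive performance (MMSE)", "Physical function (CPF)",
              "Multidimensional balance (FAB)", "Fear of falling (FES-I)",
              "Affordance perception absolute error", "Gait score",
              "Physical activity (IPAQ)", "Environmental hazards"),
    role = c("intrinsic", "intrinsic", "intrinsic", "intrinsic", "intrinsic",
             "intrinsic", "intrinsic", "intrinsic", "exposure", "exposure"),
    direction = c("risk_increasing", "risk_increasing", "protective",
                  "protective", "protective", "risk_increasing",
                  "protective", "protective", "protective",
                  "risk_increasing"),
    lower = c(0, 0, 0, 0, 0, 16, 0, 0, 0, 0),
    upper = c(Inf, 6, 30, 24, 40, 64, Inf, 12, Inf, 34),
    integer = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, TRUE),
    units = c("count", "count (0-6)", "score (0-30)", "score (0-24)",
              "score (0-40)", "score (16-64)", "cm", "score (0-12)",
              "MET-min/week", "count (0-34)"),
    stringsAsFactors = FALSE
  )
  rownames(reg) <- reg$name
  reg
}

#' Summation signs for the score components
#'
#' The continuous fall risk score is the signed sum of component Z-scores:
#' protective components enter with sign \eqn{-1}, risk-increasing
#' components with sign \eqn{+1}.
#'
#' @param registry A component registry, see [component_registry()].
#' @return Named numeric vector of \eqn{\pm 1}, one entry per component.
#' @export
score_signs <- function(registry = component_registry()) {
  s <- ifelse(registry$direction == "protective", -1, 1)
  names(s) <- registry$name
  s
}

# Column names a cohort table must always carry.
mandatory_columns <- function() c("id", "age", "sex", "falls_12m")

# Optional body-composition columns (never imputed, never scored).
body_columns <- function() c("weight", "height", "waist", "bmi")
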