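#' @title Cohort tables
#' @description
#' A cohort is an ordinary data.frame with one row per participant and
#' columns \code{id}, \code{age} (years), \code{sex} (factor with levels
#' \code{female}, \code{male}), \code{falls_12m} (self-reported falls in the
#' previous 12 months) plus the ten score components of
#' [component_registry()] and, optionally, body-composition fields
#' (\code{weight}, \code{height}, \code{waist}, \code{bmi}). Missing
#' component values are \code{NA}. A \code{"provenance"} attribute records
#' whether the table was loaded or simulated, and under which seed.
#' @name cohort
NULL

canonical_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("f", "female")] <- "female"
  out[key %in% c("m", "male")] <- "male"
  bad <- !is.na(key) & key != "" & is.na(out)
  if (any(bad)) {
    stop("unrecognized sex value(s): ",
         paste(unique(key[bad]), collapse = ", "),
         " (accepted: F/M/female/male, case-insensitive)", call. = FALSE)
  }
  factor(out, levels = c("female", "male"))
}

#' Classify fall status from the 12-month fall count
#'
#' Participants reporting two or more falls in the previous 12 months are
#' recurrent fallers; those reporting one fall or none are occasional
#' fallers. The three-level grouping distinguishes zero falls, exactly one
#' fall, and two or more.
#'
#' @param falls_12m Vector of non-negative integer fall counts.
#' @return A data.frame with factor columns \code{binary} (levels
#'   \code{occasional}, \code{recurrent}) and \code{three_level} (levels
#'   \code{zero_falls}, \code{one_fall}, \code{two_plus}), one row per
#'   input count.
#' @examples
#' classify_fall_status(c(0, 1, 2, 5))
#' @export
classify_fall_status <- function(falls_12m) {
  if (length(falls_12m) == 0) {
    return(data.frame(
      binary = factor(character(), levels = c("occasional", "recurrent")),
      three_level = factor(character(),
                           levels = c("zero_falls", "one_fall", "two_plus"))))
  }
  if (!is.numeric(falls_12m) || anyNA(falls_12m)) {
    stop("falls_12m must be non-missing and numeric", call. = FALSE)
  }
  if (any(falls_12m < 0) || any(falls_12m != round(falls_12m))) {
    stop("falls_12m must be non-negative integers", call. = FALSE)
  }
  three <- cut(falls_12m, breaks = c(-0.5, 0.5, 1.5, Inf),
               labels = c("zero_falls", "one_fall", "two_plus"))
  binary <- factor(ifelse(falls_12m >= 2, "recurrent", "occasional"),
                   levels = c("occasional", "recurrent"))
  data.frame(binary = binary, three_level = three)
}

#' Weekly metabolic expenditure from IPAQ short-form items
#'
#' Total MET-minutes per week from time spent walking and in moderate and
#' vigorous activity, using the standard intensities: walking 3.3 MET,
#' moderate activity 4.0 MET, vigorous activity 8.0 MET.
#'
#' @param walk_min_day,mod_min_day,vig_min_day Minutes per day of each
#'   activity type.
#' @param walk_days,mod_days,vig_days Days per week of each activity type
#'   (0 to 7).
#' @return MET-min/week: \code{3.3*walk + 4.0*moderate + 8.0*vigorous}.
#' @examples
#' ipaq_met_week(30, 5, 60, 2, 20, 1)  # 495 + 480 + 160 = 1135
#' @export
ipaq_met_week <- function(walk_min_day, walk_days, mod_min_day, mod_days,
                          vig_min_day, vig_days) {
  args <- list(walk_min_day, walk_days, mod_min_day, mod_days,
               vig_min_day, vig_days)
  if (any(vapply(args, function(a) any(a < 0, na.rm = TRUE), logical(1)))) {
    stop("IPAQ inputs must be non-negative", call. = FALSE)
  }
  if (any(c(walk_days, mod_days, vig_days) > 7, na.rm = TRUE)) {
    stop("days per week cannot exceed 7", call. = FALSE)
  }
  3.3 * walk_min_day * walk_days + 4.0 * mod_min_day * mod_days +
    8.0 * vig_min_day * vig_days
}

#' Absolute error of affordance perception
#'
#' The stepping-forward affordance perception outcome: the absolute
#' difference (cm) between the real and the estimated maximal
#' stepping-forward distance.
#'
#' @param real_cm Real stepping-forward distance (cm).
#' @param estimated_cm Estimated stepping-forward distance (cm).
#' @return \code{|real_cm - estimated_cm|}.
#' @export
affordance_abs_error <- function(real_cm, estimated_cm) {
  if (any(real_cm < 0, na.rm = TRUE) || any(estimated_cm < 0, na.rm = TRUE)) {
    stop("stepping distances must be non-negative", call. = FALSE)
  }
  abs(real_cm - estimated_cm)
}

#' Validate a cohort table
#'
#' Checks structure and ranges: mandatory columns present, unique ids,
#' ages at least 65, integer non-negative fall counts, every present
#' component value inside its registry range, and consistency of
#' \code{bmi} with \code{weight}/\code{height} when all three are present.
#'
#' @param cohort A cohort data.frame (see [cohort]).
#' @param registry Component registry; defaults to [component_registry()].
#' @param permissive If \code{TRUE}, out-of-range component values are
#'   coerced to \code{NA} with a warning instead of raising an error.
#' @return The validated (and possibly coerced) cohort, invisibly unchanged
#'   otherwise.
#' @export
validate_cohort <- function(cohort, registry = component_registry(),
                            permissive = FALSE) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(mandatory_columns(), names(cohort))
  if (length(miss)) {
    stop("cohort is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0) return(cohort)
  if (anyDuplicated(cohort$id)) {
    stop("participant ids are not unique", call. = FALSE)
  }
  if (anyNA(cohort$age) || any(cohort$age < 65)) {
    stop("age must be observed and >= 65 for every participant",
         call. = FALSE)
  }
  if (!is.factor(cohort$sex)) cohort$sex <- canonical_sex(cohort$sex)
  if (anyNA(cohort$sex)) stop("sex must be observed", call. = FALSE)
  classify_fall_status(cohort$falls_12m)  # raises on bad counts

  problems <- character()
  for (v in intersect(registry$name, names(cohort))) {
    x <- cohort[[v]]
    lo <- registry[v, "lower"]; hi <- registry[v, "upper"]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad)) {
      if (permissive) {
        cohort[[v]][bad] <- NA
        warning(sprintf("%s: %d out-of-range value(s) set to NA (rows %s)",
                        v, length(bad),
                        paste(utils::head(bad, 5), collapse = ",")),
                call. = FALSE)
      } else {
        problems <- c(problems, sprintf(
          "%s out of range [%g, %g] in row(s) %s", v, lo, hi,
          paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("out-of-range values:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  if (all(c("bmi", "weight", "height") %in% names(cohort))) {
    ok <- is.na(cohort$bmi) | is.na(cohort$weight) | is.na(cohort$height) |
      abs(cohort$bmi - cohort$weight / (cohort$height / 100)^2) < 0.1
    if (!all(ok)) {
      stop("bmi inconsistent with weight/height in row(s) ",
           paste(utils::head(which(!ok), 5), collapse = ", "), call. = FALSE)
    }
  }
  cohort
}

#' Read a cohort table from CSV
#'
#' Reads a per-participant CSV (header row; one row per participant;
#' empty cells or \code{"NA"} mark missing values), canonicalizes the sex
#' encoding, and validates ranges via [validate_cohort()]. Unparseable
#' numeric cells are reported with their row and column. The column
#' dictionary ships with the package:
#' \code{system.file("extdata", "column_dictionary.csv", package = "cfrs")}.
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_cohort
#' @return A validated cohort data.frame with a \code{"provenance"}
#'   attribute recording the source path.
#' @seealso [write_cohort()], [simulate_cohort()]
#' @export
load_cohort <- function(path, registry = component_registry(),
                        permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE,
                         strip.white = TRUE)
  miss <- setdiff(mandatory_columns(), names(raw))
  if (length(miss)) {
    stop("CSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(names(raw), c("id", "sex"))
  for (v in numeric_cols) {
    conv <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(!is.na(raw[[v]]) & is.na(conv))
    if (length(bad)) {
      stop(sprintf("unparseable numeric cell(s) in column '%s', row(s) %s",
                   v, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    raw[[v]] <- conv
  }
  raw$sex <- canonical_sex(raw$sex)
  out <- validate_cohort(raw, registry = registry, permissive = permissive)
  attr(out, "provenance") <- list(source = path, kind = "loaded")
  out
}

#' Write a cohort table to CSV
#'
#' Numeric cells are written with at most 6 significant digits; missing
#' values are written as empty cells. [load_cohort()] on the result
#' round-trips the numeric content at that precision.
#'
#' @param cohort A cohort data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (v in names(out)) {
    if (is.numeric(out[[v]])) {
      out[[v]] <- ifelse(is.na(out[[v]]), "",
                         format(signif(out[[v]], 6), trim = TRUE,
                                scientific = FALSE))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
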