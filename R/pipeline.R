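#' Evaluate how well a score discriminates recurrent fallers
#'
#' One-stop ROC evaluation of a per-participant score: full curve, AUC
#' with Hanley-McNeil 95\% interval and interpretation band, the
#' Youden-optimal cutoff (or a user-supplied one), and the confusion
#' summary at that cutoff including Wilson intervals for sensitivity and
#' specificity and bootstrap intervals for the predictive values.
#'
#' @inheritParams roc_curve
#' @param cutoff Optional decision threshold; when \code{NULL} the
#'   Youden-optimal cutoff is used.
#' @param n_boot Bootstrap resamples for the predictive-value intervals.
#' @param seed Seed for the bootstrap.
#' @return List of class \code{"cfrs_evaluation"}: \code{roc},
#'   \code{auc}, \code{auc_ci}, \code{band}, \code{youden},
#'   \code{cutoff}, \code{confusion}.
#' @export
evaluate_score <- function(scores, labels, cutoff = NULL, n_boot = 2000,
                           seed = 1L) {
  roc <- roc_curve(scores, labels)
  ac <- auc_ci(scores, labels)
  yj <- youden_cutoff(roc)
  use_cut <- if (is.null(cutoff)) yj$cutoff else cutoff
  conf <- confusion_at(scores, labels, use_cut, n_boot = n_boot,
                       seed = seed)
  structure(list(roc = roc, auc = roc$auc, auc_ci = ac$ci,
                 band = auc_band(roc$auc), youden = yj, cutoff = use_cut,
                 confusion = conf),
            class = "cfrs_evaluation")
}

#' @export
print.cfrs_evaluation <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %s\n", x$auc, x$auc_ci[1],
              x$auc_ci[2], x$band))
  cat(sprintf("cutoff %.2f: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$confusion$sensitivity,
              100 * x$confusion$specificity))
  invisible(x)
}

default_pipeline_config <- function() {
  list(input = NULL,
       simulate = list(n = 504),
       impute = list(m = 8, maxit = 10),
       score = list(stratify_by_sex = FALSE),
       evaluate = list(cutoff = NULL, n_boot = 2000),
       output_dir = "cfrs_output",
       seed = 1L)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(config$simulate)) cfg$simulate <- config$simulate
  cfg$seed <- as.integer(cfg$seed)
  known <- names(default_pipeline_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config field(s): ",
                          paste(extra, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    stop("config error: input file does not exist: ", cfg$input,
         call. = FALSE)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains every stage on one configuration: obtain a cohort (load a CSV
#' or simulate one), impute missing components by fully conditional
#' specification, pool the completions, compose the continuous fall risk
#' score, evaluate its discrimination of recurrent fallers, and emit the
#' descriptive group-comparison and ANOVA reports. All artifacts are
#' written under \code{output_dir} together with a JSON manifest listing
#' each file with its MD5 hash, the seed, a hash of the effective
#' configuration and the package version; identical configuration and
#' seed yield identical manifests. A stage failure leaves a
#' \code{<stage>.partial} marker beside any partial output and aborts
#' with a stage-named error.
#'
#' @param config Either a list or the path of a YAML file. Recognized
#'   fields (all optional): \code{input} (cohort CSV path; when absent a
#'   cohort is simulated), \code{simulate} (arguments for
#'   [cohort_config()]), \code{impute} (\code{m}, \code{maxit}),
#'   \code{score} (\code{stratify_by_sex}), \code{evaluate}
#'   (\code{cutoff}, \code{n_boot}), \code{output_dir}, \code{seed}.
#' @return Invisibly, the manifest as a list.
#' @examples
#' \donttest{
#' out <- tempfile("cfrs_run")
#' run_pipeline(list(simulate = list(n = 120), output_dir = out,
#'                   impute = list(m = 2, maxit = 3),
#'                   evaluate = list(n_boot = 50), seed = 5))
#' }
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(out(paste0(name, ".partial")))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  files <- character()

  cohort <- stage("cohort", {
    if (!is.null(cfg$input)) {
      load_cohort(cfg$input)
    } else {
      sim <- cfg$simulate
      if (is.null(sim$seed)) sim$seed <- cfg$seed
      simulate_cohort(do.call(cohort_config, sim))
    }
  })
  write_cohort(cohort, out("cohort.csv"))
  files <- c(files, "cohort.csv")

  imp <- stage("impute", impute_fcs(cohort, m = cfg$impute$m,
                                    maxit = cfg$impute$maxit,
                                    seed = cfg$seed))
  for (k in seq_len(imp$m)) {
    write_cohort(imp$imputations[[k]], out(sprintf("cohort_imp%d.csv", k)))
    files <- c(files, sprintf("cohort_imp%d.csv", k))
  }
  utils::write.csv(imp$trace, out("imputation_trace.csv"),
                   row.names = FALSE)
  files <- c(files, "imputation_trace.csv")
  pooled <- pool_imputations(imp)

  sc <- stage("score", cfrs_score(pooled,
                                  stratify_by_sex =
                                    isTRUE(cfg$score$stratify_by_sex)))
  scores_df <- data.frame(id = pooled$id)
  zt <- sc$z; colnames(zt) <- paste0("z_", colnames(zt))
  scores_df <- cbind(scores_df, as.data.frame(zt), cfrs = sc$cfrs)
  utils::write.csv(format_num_df(scores_df), out("scores.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, "scores.csv")

  status <- classify_fall_status(pooled$falls_12m)
  ev <- stage("evaluate", evaluate_score(sc$cfrs,
                                         status$binary == "recurrent",
                                         cutoff = cfg$evaluate$cutoff,
                                         n_boot = cfg$evaluate$n_boot,
                                         seed = cfg$seed))
  roc_df <- data.frame(threshold = ev$roc$thresholds,
                       sensitivity = ev$roc$sensitivity,
                       specificity = ev$roc$specificity)
  utils::write.csv(format_num_df(roc_df), out("roc.csv"),
                   row.names = FALSE, quote = FALSE)
  ev_json <- list(auc = ev$auc, auc_ci = ev$auc_ci, band = ev$band,
                  youden_cutoff = ev$youden$cutoff, cutoff = ev$cutoff,
                  component_aucs = as.list(
                    discrimination_aucs(sc, status$binary == "recurrent")),
                  confusion = ev$confusion)
  jsonlite::write_json(ev_json, out("evaluation.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  files <- c(files, "roc.csv", "evaluation.json")

  rep <- stage("report", {
    list(groups = fall_group_table(pooled, cfrs = sc$cfrs),
         anova = anova_tukey(sc$cfrs, status$three_level))
  })
  utils::write.csv(format_num_df(rep$groups), out("group_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  anova_df <- cbind(data.frame(F = rep$anova$F, p = rep$anova$p),
                    rep$anova$tukey)
  utils::write.csv(format_num_df(anova_df), out("anova.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, "group_comparison.csv", "anova.csv")

  cfg_for_hash <- cfg
  cfg_for_hash$output_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("cfrs")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(
      local({f <- tempfile(); yaml::write_yaml(cfg_for_hash, f); f}))),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(out(f))))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# fixed-precision formatting so written reports are byte-stable
format_num_df <- function(df, digits = 6) {
  for (v in names(df)) {
    if (is.numeric(df[[v]])) {
      df[[v]] <- ifelse(is.na(df[[v]]), "",
                        format(signif(df[[v]], digits), trim = TRUE,
                               scientific = FALSE))
    }
  }
  df
}
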