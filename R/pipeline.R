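#' Configuration for the end-to-end derivation pipeline
#'
#' @param cohort A [cohort_config()]; its `n` and `prevalence` default to
#'   the derivation cohort's 13,977 pregnancies and 13.78% EPL rate.
#' @param candidates Candidate predictors offered to stepwise screening:
#'   by default every variable measurable at the day-27-29 scan.
#' @param alpha_stay Wald p-value threshold for stepwise retention.
#' @param B_rule Rule mapping fitted coefficients to the points base
#'   constant (default: 5 times the maternal-age coefficient).
#' @param cutoff Clinical score cutoff for the classification stage.
#' @param train_fraction Fraction of the cohort labelled year 1 and used
#'   for derivation; the remainder is the verification set. The default
#'   mirrors the 7261/6716 temporal split.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "fit", "derive", "evaluate")`. Later stages require
#'   earlier ones (or a `cohort` supplied to [run_pipeline()]).
#' @param seed Seed recorded in the config and used by default.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            candidates = c("ma", "bmi", "duration", "hcg",
                                           "em", "gsd", "ysd", "el", "ehr",
                                           "iuh"),
                            alpha_stay = 0.10,
                            B_rule = function(coefs) 5 * coefs[["ma"]],
                            cutoff = 5,
                            train_fraction = 7261 / 13977,
                            stages = c("simulate", "fit", "derive",
                                       "evaluate"),
                            seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_config"))
  bad <- setdiff(stages, c("simulate", "fit", "derive", "evaluate"))
  if (length(bad)) abort("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  structure(list(cohort = cohort, candidates = candidates,
                 alpha_stay = alpha_stay, B_rule = B_rule, cutoff = cutoff,
                 train_fraction = train_fraction, stages = stages,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full derivation and validation pipeline
#'
#' Simulate a cohort, split it into a year-1 training set and a year-2
#' verification set, fit the logistic model with stepwise screening on
#' the training set, derive an integer point system from the retained
#' coefficients, attach a risk table fitted on training totals, and
#' evaluate per-cutoff performance on both splits. Each stage logs one
#' line (record counts included) when `verbose`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built cohort `data.frame` (used when the
#'   `"simulate"` stage is switched off).
#' @param out_dir Optional directory: when given, the bundle is written
#'   out (derived system JSON, performance tables CSV, report JSON with
#'   provenance: config, seed, package and R versions).
#' @param template Category definitions for point derivation; defaults
#'   to the published system's intervals and representative values.
#' @param verbose Print one log line per stage.
#' @return A list of class `pipeline_bundle` with (depending on enabled
#'   stages) `cohort`, `split`, `stepwise`, `fit`, `system`,
#'   `risk_table`, `performance` (`$train`, `$verify`),
#'   `classification` (contingency at the configured cutoff),
#'   `auc` (`$train`, `$verify`), `point_comparison` (derived
#'   vs. published points per category) and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL, template = published_system(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  bundle <- list(provenance = list(
    seed = config$seed,
    config = list(n = config$cohort$n, prevalence = config$cohort$prevalence,
                  mode = config$cohort$mode, candidates = config$candidates,
                  alpha_stay = config$alpha_stay, cutoff = config$cutoff,
                  train_fraction = config$train_fraction,
                  stages = config$stages),
    package_version = as.character(utils::packageVersion("eplscore")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")))
  if (!length(config$stages)) return(structure(bundle, class = "pipeline_bundle"))

  if ("simulate" %in% config$stages) {
    cohort <- stage("simulate", switch(config$cohort$mode,
      group_conditional = generate_group_conditional(config$cohort,
                                                     seed = config$seed),
      logistic_generative = generate_logistic(config$cohort,
                                              seed = config$seed)))
    say("simulate: %d records, %d EPL (%.2f%%)", nrow(cohort),
        sum(cohort$outcome == "epl"), 100 * mean(cohort$outcome == "epl"))
  }
  later <- intersect(config$stages, c("fit", "derive", "evaluate"))
  if (length(later) && is.null(cohort)) {
    abort("stages %s need a cohort: enable 'simulate' or pass one",
          paste(later, collapse = ", "))
  }
  if (!is.null(cohort)) {
    n_train <- round(nrow(cohort) * config$train_fraction)
    year <- rep(c(1L, 2L), c(n_train, nrow(cohort) - n_train))
    bundle$cohort <- cohort
    bundle$split <- year
    say("split: %d training (year 1), %d verification (year 2)",
        n_train, nrow(cohort) - n_train)
  }

  if ("fit" %in% config$stages) {
    train <- cohort[bundle$split == 1L, , drop = FALSE]
    sw <- stage("fit", stepwise_select(train, config$candidates,
                                       alpha_stay = config$alpha_stay))
    bundle$stepwise <- sw
    bundle$fit <- sw$fit
    say("fit: stepwise retained {%s} of %d candidates",
        paste(sw$selected, collapse = ", "), length(config$candidates))
  }

  if ("derive" %in% config$stages) {
    if (is.null(bundle$fit)) abort("stage 'derive' needs the 'fit' stage")
    train <- cohort[bundle$split == 1L, , drop = FALSE]
    tmpl_factors <- if (inherits(template, "point_system")) {
      template$factors
    } else template
    tmpl_names <- vapply(tmpl_factors, `[[`, character(1), "name")
    fit <- bundle$fit
    scorable <- intersect(fit$coefficients$term, tmpl_names)
    if (length(scorable) < nrow(fit$coefficients)) {
      # screening may retain covariates that have no category definitions
      # (e.g. hCG); the point system can only carry factors with intervals,
      # so refit on the scorable subset before converting to points
      dropped <- setdiff(fit$coefficients$term, scorable)
      if (!length(scorable)) {
        abort("pipeline stage 'derive' failed: no retained variable has category definitions")
      }
      fit <- stage("derive", fit_logistic(train, scorable))
      bundle$fit_scorable <- fit
      say("derive: refit on scorable factors {%s} (no categories for: %s)",
          paste(scorable, collapse = ", "), paste(dropped, collapse = ", "))
    }
    sys <- stage("derive", derive_point_system(fit, template,
                                               B_rule = config$B_rule))
    totals <- score_cohort(train, sys)
    sys$risk_table <- stage("derive",
      empirical_risk_table(totals, train$outcome,
                           range = seq(sys$score_min, sys$score_max)))
    bundle$system <- sys
    bundle$risk_table <- sys$risk_table
    bundle$point_comparison <- compare_point_tables(sys, published_system())
    say("derive: B = %.4f, totals %d..%d, %d/%d categories match the published points",
        sys$B, sys$score_min, sys$score_max,
        sum(bundle$point_comparison$match), nrow(bundle$point_comparison))
  }

  if ("evaluate" %in% config$stages) {
    if (is.null(bundle$system)) abort("stage 'evaluate' needs the 'derive' stage")
    sys <- bundle$system
    perf <- list()
    aucs <- list()
    cls <- list()
    for (part in c("train", "verify")) {
      idx <- bundle$split == if (part == "train") 1L else 2L
      sub <- cohort[idx, , drop = FALSE]
      totals <- score_cohort(sub, sys)
      perf[[part]] <- stage("evaluate",
        performance_table(totals, sub$outcome, sys$risk_table))
      aucs[[part]] <- auc_rank(totals, sub$outcome)
      cls[[part]] <- contingency_at_cutoff(totals, sub$outcome, config$cutoff)
      say("evaluate (%s): n = %d, AUC = %.3f", part, nrow(sub), aucs[[part]])
    }
    bundle$performance <- perf
    bundle$auc <- aucs
    bundle$classification <- cls
  }

  bundle <- structure(bundle, class = "pipeline_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Total scores for every record of a cohort
#'
#' @param cohort Cohort `data.frame` with the system's scoring columns.
#' @param system A `point_system`.
#' @return Integer vector of totals, one per row.
#' @export
score_cohort <- function(cohort, system) {
  stopifnot(inherits(system, "point_system"))
  n <- nrow(cohort)
  totals <- integer(n)
  for (f in system$factors) {
    col <- cohort[[f$name]]
    if (is.null(col)) abort("cohort lacks scoring column '%s'", f$name)
    cats <- f$categories
    idx <- rep(NA_integer_, n)
    for (j in rev(seq_len(nrow(cats)))) {
      hit <- col < cats$upper[j] | (cats$upper_closed[j] & col == cats$upper[j])
      idx[hit] <- j
    }
    if (anyNA(idx) || any(col < 0)) {
      bad <- which(is.na(idx) | col < 0)[1]
      abort("row %d: invalid value for '%s' (%s)", bad, f$name,
            format(col[bad]))
    }
    totals <- totals + cats$points[idx]
  }
  totals
}

#' Compare two point systems category by category
#'
#' @param derived,reference `point_system` objects sharing factor names
#'   and category layouts.
#' @return A `data.frame` with one row per category: factor, label,
#'   derived and reference points, and whether they match.
#' @export
compare_point_tables <- function(derived, reference) {
  rows <- lapply(names(derived$factors), function(nm) {
    d <- derived$factors[[nm]]$categories
    r <- reference$factors[[nm]]$categories
    if (nrow(d) != nrow(r)) {
      abort("factor '%s': category layouts differ", nm)
    }
    data.frame(factor = nm, label = d$label, derived = d$points,
               reference = r$points, match = d$points == r$points,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$system)) {
    write_point_system(bundle$system, file.path(out_dir, "derived_system.json"),
                       name = "Pipeline-derived EPL scoring system")
  }
  if (!is.null(bundle$performance)) {
    for (part in names(bundle$performance)) {
      utils::write.csv(bundle$performance[[part]],
                       file.path(out_dir, sprintf("performance_%s.csv", part)),
                       row.names = FALSE, na = "")
    }
  }
  report <- list(provenance = bundle$provenance)
  if (!is.null(bundle$fit)) {
    report$fit <- list(coefficients = bundle$fit$coefficients,
                       intercept = bundle$fit$intercept,
                       n = bundle$fit$n, n_dropped = bundle$fit$n_dropped)
  }
  if (!is.null(bundle$stepwise)) report$selected <- bundle$stepwise$selected
  if (!is.null(bundle$system)) {
    report$B <- bundle$system$B
    report$score_range <- c(bundle$system$score_min, bundle$system$score_max)
  }
  if (!is.null(bundle$point_comparison)) {
    report$point_comparison <- bundle$point_comparison
  }
  if (!is.null(bundle$auc)) report$auc <- bundle$auc
  if (!is.null(bundle$classification)) {
    report$classification <- lapply(bundle$classification, unclass)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(out_dir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("EPL derivation pipeline bundle\n")
  if (!is.null(x$cohort)) {
    cat(sprintf("  cohort: %d records (%.2f%% EPL), split %d/%d\n",
                nrow(x$cohort), 100 * mean(x$cohort$outcome == "epl"),
                sum(x$split == 1L), sum(x$split == 2L)))
  }
  if (!is.null(x$stepwise)) {
    cat("  selected:", paste(x$stepwise$selected, collapse = ", "), "\n")
  }
  if (!is.null(x$system)) {
    cat(sprintf("  derived system: B = %.4f, totals %d..%d (%d/%d categories match published)\n",
                x$system$B, x$system$score_min, x$system$score_max,
                sum(x$point_comparison$match), nrow(x$point_comparison)))
  }
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC: train %.3f, verify %.3f\n",
                x$auc$train, x$auc$verify))
  }
  invisible(x)
}

#' Score one patient and format the clinical recommendation
#'
#' Computes the total score, per-factor breakdown and estimated risk for
#' the six scan-time measurements and appends the follow-up
#' recommendation: a repeat scan in 7-10 days when the total reaches the
#' cutoff, otherwise the next routine scan on day 45 after transfer.
#'
#' @param ma,em,gsd,ysd,el,ehr The six scoring measurements (years, mm,
#'   mm, mm, mm, bpm).
#' @param cutoff Score triggering the repeat-scan recommendation.
#' @param system Scoring system; defaults to the published one.
#' @return A list of class `score_report` with `score` (the
#'   `patient_score`), `recommendation` (string) and `lines` (formatted
#'   output, one string per line).
#' @export
#' @examples
#' score_command(ma = 38, em = 8, gsd = 10, ysd = 2.2, el = 2.5, ehr = 88)
score_command <- function(ma, em, gsd, ysd, el, ehr, cutoff = 5,
                          system = published_system()) {
  rec <- patient_record(ma = ma, em = em, gsd = gsd, ysd = ysd,
                        el = el, ehr = ehr)
  sc <- score_patient(rec, system)
  recommendation <- if (sc$total >= cutoff) {
    "High risk of early pregnancy loss: repeat the ultrasound scan in 7-10 days to confirm embryonic viability."
  } else {
    "Low risk of early pregnancy loss: next routine scan on day 45 after embryo transfer."
  }
  lines <- c(sprintf("Total score: %d (range %d..%d)", sc$total,
                     system$score_min, system$score_max),
             sprintf("  %-4s %-10s %+d", names(sc$breakdown),
                     sc$categories, sc$breakdown),
             if (!is.na(sc$risk))
               sprintf("Estimated risk of miscarriage: %.2f%%", sc$risk),
             recommendation)
  structure(list(score = sc, recommendation = recommendation, lines = lines),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}
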