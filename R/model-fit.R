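#' Fit a binary logistic regression for early pregnancy loss
#'
#' Maximum-likelihood logistic regression of the EPL outcome on the
#' requested variables, fitted by iteratively reweighted least squares
#' (via [stats::glm()] with a tight convergence tolerance). Standard
#' errors come from the observed information matrix; per-variable odds
#' ratios, Wald 95% confidence intervals and two-sided p-values are
#' attached via [wald_summary()].
#'
#' Rows with a missing value in any requested variable are dropped; the
#' number dropped is recorded in the result.
#'
#' @param cohort A cohort `data.frame` with an `outcome` column
#'   (`"ongoing"`/`"epl"`, or logical with `TRUE` = event).
#' @param variables Character vector of predictor column names. Logical
#'   predictors are treated as 0/1.
#' @param epsilon Relative log-likelihood convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `epl_fit`: a list with `coefficients` (a
#'   `data.frame` with columns `term, estimate, se, z, p, or, ci_low,
#'   ci_high`), `intercept`, `converged`, `iterations`, `n`,
#'   `n_dropped`, `loglik` and the underlying `glm` object.
#' @export
fit_logistic <- function(cohort, variables, epsilon = 1e-10, maxit = 100) {
  stopifnot(is.data.frame(cohort), length(variables) >= 1L)
  missing_cols <- setdiff(c(variables, "outcome"), names(cohort))
  if (length(missing_cols)) {
    abort("cohort lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  y <- cohort$outcome
  if (!is.logical(y)) y <- y == "epl"
  dat <- cohort[, variables, drop = FALSE]
  for (v in variables) if (is.logical(dat[[v]])) dat[[v]] <- as.numeric(dat[[v]])
  keep <- stats::complete.cases(dat) & !is.na(y)
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    abort("outcome has a single class after dropping incomplete rows")
  }
  constant <- variables[vapply(dat, function(x) stats::var(x) == 0, logical(1))]
  if (length(constant)) {
    abort("constant predictor column(s): %s", paste(constant, collapse = ", "))
  }
  dat$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(variables, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    abort("IRLS did not converge in %d iterations (deviance %.6g)",
          fit$iter, fit$deviance)
  }
  coefs <- stats::coef(fit)
  # quasi-separation: a diverging coefficient with fitted probabilities at
  # the boundary; report the offending variable rather than a huge OR
  slope_sd <- vapply(dat[variables], stats::sd, numeric(1))
  standardized <- abs(coefs[variables]) * slope_sd
  if (any(standardized > 15, na.rm = TRUE) &&
      (min(fit$fitted.values) < 1e-12 || max(fit$fitted.values) > 1 - 1e-12)) {
    abort("perfect or quasi-perfect separation detected for variable '%s'",
          variables[which.max(standardized)])
  }
  se <- sqrt(diag(stats::vcov(fit)))
  terms <- variables
  rows <- lapply(terms, function(v) {
    ws <- wald_summary(coefs[[v]], se[[v]])
    data.frame(term = v, estimate = coefs[[v]], se = se[[v]],
               z = coefs[[v]] / se[[v]], p = ws$p, or = ws$or,
               ci_low = ws$ci[1], ci_high = ws$ci[2],
               stringsAsFactors = FALSE)
  })
  structure(list(coefficients = do.call(rbind, rows),
                 intercept = unname(coefs[["(Intercept)"]]),
                 intercept_se = unname(se[["(Intercept)"]]),
                 converged = fit$converged, iterations = fit$iter,
                 n = nrow(dat), n_dropped = n_dropped,
                 loglik = as.numeric(stats::logLik(fit)),
                 glm = fit),
            class = "epl_fit")
}

#' @export
print.epl_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d (%d dropped), logLik = %.2f, %d IRLS iterations\n",
              x$n, x$n_dropped, x$loglik, x$iterations))
  tab <- x$coefficients
  tab$p <- format.pval(tab$p, digits = 3)
  print.data.frame(cbind(term = tab$term,
                         round(tab[, c("estimate", "se", "or",
                                       "ci_low", "ci_high")], 4),
                         p = tab$p), row.names = FALSE)
  cat(sprintf("Intercept: %.4f\n", x$intercept))
  invisible(x)
}

#' Wald summary of a logistic coefficient
#'
#' Odds ratio, 95% confidence interval and two-sided p-value from a
#' coefficient and its standard error: `OR = exp(beta)`,
#' `CI = exp(beta +/- 1.96 * se)`, `p = 2 * pnorm(-|beta / se|)`.
#'
#' @param coefficient Log-odds coefficient.
#' @param se Standard error; must be > 0.
#' @return A list with `or`, `ci` (length-2 vector), `p`.
#' @export
#' @examples
#' wald_summary(0.0920, 0.0107)  # maternal age: OR 1.096
wald_summary <- function(coefficient, se) {
  if (!is.numeric(se) || se <= 0) abort("se must be > 0")
  or <- exp(coefficient)
  ci <- exp(coefficient + c(-1, 1) * 1.96 * se)
  p <- 2 * stats::pnorm(-abs(coefficient / se))
  list(or = or, ci = ci, p = p)
}

#' Stepwise variable screening by Wald p-value
#'
#' Backward elimination (default): fit all candidates, repeatedly drop
#' the variable with the largest Wald p-value at or above `alpha_stay`,
#' refit, and stop when every retained variable has p < `alpha_stay`.
#' Forward selection adds, at each round, the candidate with the smallest
#' Wald p-value below `alpha_stay` in the expanded model. Both paths are
#' deterministic given the data.
#'
#' The default `alpha_stay = 0.10` keeps borderline predictors such as a
#' U-shaped yolk-sac effect (retained at p = 0.06 in the published
#' model), which a 0.05 rule would drop.
#'
#' @param cohort Cohort `data.frame` with an `outcome` column.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_stay Wald p-value threshold to stay in the model.
#' @param direction `"backward"` or `"forward"`.
#' @return A list of class `stepwise_result` with `selected` (character
#'   vector, possibly empty), `fit` (the final [fit_logistic()] result,
#'   or `NULL` for an intercept-only model), and `path` (a `data.frame`
#'   logging each step).
#' @export
stepwise_select <- function(cohort, candidates, alpha_stay = 0.10,
                            direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(length(candidates) >= 1L)
  steps <- list()
  log_step <- function(action, variable, p) {
    steps[[length(steps) + 1L]] <<- data.frame(
      action = action, variable = variable, p = p, stringsAsFactors = FALSE)
  }
  if (direction == "backward") {
    current <- candidates
    fit <- fit_logistic(cohort, current)
    repeat {
      p <- stats::setNames(fit$coefficients$p, fit$coefficients$term)
      worst <- names(which.max(p))
      if (p[[worst]] < alpha_stay) break
      log_step("drop", worst, p[[worst]])
      current <- setdiff(current, worst)
      if (!length(current)) {
        warning("all candidates eliminated; returning intercept-only model",
                call. = FALSE)
        fit <- NULL
        break
      }
      fit <- fit_logistic(cohort, current)
    }
  } else {
    current <- character(0)
    fit <- NULL
    repeat {
      remaining <- setdiff(candidates, current)
      if (!length(remaining)) break
      trial_p <- vapply(remaining, function(v) {
        f <- fit_logistic(cohort, c(current, v))
        f$coefficients$p[f$coefficients$term == v]
      }, numeric(1))
      best <- names(which.min(trial_p))
      if (trial_p[[best]] >= alpha_stay) break
      log_step("add", best, trial_p[[best]])
      current <- c(current, best)
      fit <- fit_logistic(cohort, current)
    }
    if (!length(current)) {
      warning("no candidate entered the model; returning intercept-only model",
              call. = FALSE)
    }
  }
  path <- if (length(steps)) do.call(rbind, steps) else
    data.frame(action = character(0), variable = character(0),
               p = numeric(0), stringsAsFactors = FALSE)
  structure(list(selected = if (is.null(fit)) character(0) else
                   fit$coefficients$term,
                 fit = fit, path = path, alpha_stay = alpha_stay,
                 direction = direction),
            class = "stepwise_result")
}

#' Derive an integer point system from a fitted model
#'
#' Applies the Sullivan/Framingham conversion to the fitted coefficients:
#' each factor's categories (intervals, representative values and base
#' category) come from a template, the per-unit log-odds come from the
#' fit, and points are `round(beta * (W - W_ref) / B)`.
#'
#' @param fit An [fit_logistic()] result.
#' @param template Category definitions: a list of [risk_factor()]
#'   objects (or a `point_system`, e.g. [published_system()], whose
#'   factors supply intervals and representative values). Every variable
#'   in the fit must appear in the template.
#' @param B_rule Function mapping the named coefficient vector to the
#'   points base constant; the default takes 5 times the maternal-age
#'   coefficient, the convention used by the published system.
#' @param B Explicit base constant, overriding `B_rule`.
#' @return A `point_system` built from the fitted coefficients.
#' @export
derive_point_system <- function(fit, template,
                                B_rule = function(coefs) 5 * coefs[["ma"]],
                                B = NULL) {
  stopifnot(inherits(fit, "epl_fit"))
  if (inherits(template, "point_system")) template <- template$factors
  template_names <- vapply(template, `[[`, character(1), "name")
  coefs <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  missing_t <- setdiff(names(coefs), template_names)
  if (length(missing_t)) {
    abort("no category definitions for fitted variable(s): %s",
          paste(missing_t, collapse = ", "))
  }
  if (is.null(B)) {
    B <- tryCatch(B_rule(coefs), error = function(e) {
      abort("B_rule failed (%s); supply B directly", conditionMessage(e))
    })
    if (!is.numeric(B) || !is.finite(B) || B <= 0) {
      abort("B_rule produced an invalid base constant (%s); supply B directly",
            format(B))
    }
  }
  factors <- lapply(names(coefs), function(v) {
    f <- template[[match(v, template_names)]]
    f$beta <- coefs[[v]]
    f
  })
  build_point_system(factors, B = B)
}

#' Analytic risk curve over point totals
#'
#' An analytic approximation relating the total score to the estimated
#' miscarriage risk: `risk(t) = plogis(c + B * t)`, where B is the
#' log-odds value of one point. This is a constant-slope logistic in the
#' total, clearly distinct from the published empirical risk table (which
#' is canonical and is not reproduced exactly by any constant-slope
#' curve). If `intercept` is omitted, `c` is calibrated by least squares
#' on the logit scale against a reference risk table (with the slope held
#' at B, the least-squares intercept is the mean logit residual).
#'
#' @param intercept Log-odds intercept `c`; `NULL` to calibrate.
#' @param B Log-odds per point (>= 0; 0 gives a flat curve).
#' @param totals Integer totals at which to evaluate the curve.
#' @param reference A risk table (`total`, `risk` in percent) used to
#'   calibrate `c` when `intercept` is `NULL`.
#' @return A `data.frame` with columns `total`, `risk` (percent) and
#'   attributes `intercept`, `slope` and `label =
#'   "analytic approximation"`.
#' @export
estimate_risk_curve <- function(intercept = NULL, B, totals,
                                reference = NULL) {
  if (!is.numeric(B) || length(B) != 1L || B < 0) abort("B must be >= 0")
  if (is.null(intercept)) {
    if (is.null(reference)) {
      abort("either an intercept or a reference risk table is required")
    }
    logit <- stats::qlogis(reference$risk / 100)
    intercept <- mean(logit - B * reference$total)
  }
  out <- data.frame(total = as.integer(totals),
                    risk = 100 * stats::plogis(intercept + B * totals))
  attr(out, "intercept") <- intercept
  attr(out, "slope") <- B
  attr(out, "label") <- "analytic approximation"
  out
}

#' Empirical risk table from scored outcomes
#'
#' Fits a single-covariate logistic regression of the outcome on the
#' total score and evaluates the fitted risk at each integer total. Used
#' by the derivation pipeline to attach risks to a freshly derived point
#' system; the fitted curve is monotone by construction and smooths the
#' raw per-total event fractions.
#'
#' @param totals Integer total scores, one per patient.
#' @param outcomes Outcome labels (`"ongoing"`/`"epl"` or logical).
#' @param range Integer totals at which to evaluate (default: the
#'   observed score range).
#' @return A [risk_table()] with attributes `intercept` and `slope`.
#' @export
empirical_risk_table <- function(totals, outcomes,
                                 range = seq(min(totals), max(totals))) {
  y <- if (is.logical(outcomes)) outcomes else outcomes == "epl"
  fit <- stats::glm(y ~ totals, family = stats::binomial())
  cf <- stats::coef(fit)
  out <- risk_table(total = as.integer(range),
                    risk = 100 * stats::plogis(cf[[1]] + cf[[2]] * range))
  attr(out, "intercept") <- cf[[1]]
  attr(out, "slope") <- cf[[2]]
  out
}
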