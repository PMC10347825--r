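#' Configuration for synthetic IVF-ET cohorts
#'
#' Describes the statistical structure of a simulated cohort of
#' intrauterine singleton pregnancies scanned on days 27-29 after embryo
#' transfer. Defaults reproduce the group-conditional summary statistics
#' of the 13,977-patient derivation cohort: an early-pregnancy-loss (EPL)
#' prevalence of 1926/13977 and per-outcome-group means and standard
#' deviations for maternal age, BMI, infertility duration, day-14 hCG,
#' endometrial thickness, gestational sac diameter, yolk sac diameter,
#' embryonic length and embryonic heart rate, plus Bernoulli rates for
#' intrauterine hematoma.
#'
#' Continuous variables are drawn from normals truncated below at 0
#' (measurements cannot be negative). The EPL-group heart rate is the one
#' exception: a mixture of a point mass at 0 bpm (no cardiac activity)
#' and a truncated normal for embryos with a beating heart, because no
#' single truncated normal attains mean 42.4 bpm with SD 53.5 bpm on the
#' non-negative half-line. The mixture weight and the positive-component
#' mean are solved from those two moments at configuration time, with the
#' positive-component SD fixed at 12.2 bpm (the viable-pregnancy spread);
#' the solution puts roughly 61% of EPL embryos at 0 bpm with survivors
#' beating near 108 bpm.
#'
#' Variables are drawn independently within outcome group unless a
#' `copula` correlation matrix is supplied, in which case a Gaussian
#' copula couples the continuous variables while preserving each one's
#' marginal distribution.
#'
#' @param n Number of pregnancies to simulate.
#' @param prevalence Probability that a pregnancy ends in EPL by 12
#'   weeks.
#' @param mode `"group_conditional"` (draw outcome first, then variables
#'   from the outcome group's distributions) or `"logistic_generative"`
#'   (draw variables from the pooled population, then the outcome from a
#'   logistic model; see [generate_logistic()]).
#' @param group_params Named list with elements `ongoing` and `epl`, each
#'   a named list of `c(mean, sd)` pairs for the continuous variables and
#'   a scalar `iuh` rate. Defaults as described above.
#' @param truncation Named list of `c(lower, upper)` truncation bounds;
#'   default `c(0, Inf)` for every variable.
#' @param ehr_positive_sd SD of the beating-heart component of the
#'   EPL-group heart-rate mixture, bpm.
#' @param copula Optional correlation matrix (9 x 9, variable order
#'   `ma, bmi, duration, hcg, em, gsd, ysd, el, ehr`) for the Gaussian
#'   copula; `NULL` (default) draws variables independently.
#' @param seed Default seed used by the generators when they are called
#'   without one.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 13977,
                          prevalence = 1926 / 13977,
                          mode = c("group_conditional", "logistic_generative"),
                          group_params = NULL,
                          truncation = NULL,
                          ehr_positive_sd = 12.2,
                          copula = NULL,
                          seed = 20160601) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("n must be a positive integer")
  }
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    abort("prevalence must lie in [0, 1]")
  }
  defaults <- list(
    ongoing = list(ma = c(30.9, 4.5), bmi = c(21.8, 2.4),
                   duration = c(4.0, 3.0), hcg = c(594.4, 301.7),
                   em = c(12.6, 2.0), gsd = c(18.5, 3.6),
                   ysd = c(3.6, 0.4), el = c(3.5, 0.9),
                   ehr = c(114.5, 12.2), iuh = 0.1600),
    epl     = list(ma = c(33.3, 5.4), bmi = c(22.1, 2.6),
                   duration = c(4.4, 3.6), hcg = c(430.5, 283.9),
                   em = c(12.3, 1.9), gsd = c(13.2, 4.8),
                   ysd = c(2.6, 1.5), el = c(1.2, 1.6),
                   ehr = c(42.4, 53.5), iuh = 0.1885))
  gp <- defaults
  if (!is.null(group_params)) {
    for (g in names(group_params)) {
      gp[[g]][names(group_params[[g]])] <- group_params[[g]]
    }
  }
  for (g in c("ongoing", "epl")) {
    sds <- vapply(gp[[g]][cohort_variables()], `[`, numeric(1), 2L)
    if (any(sds <= 0)) abort("group '%s': all sds must be > 0", g)
  }
  trunc <- stats::setNames(rep(list(c(0, Inf)), length(cohort_variables())),
                           cohort_variables())
  if (!is.null(truncation)) trunc[names(truncation)] <- truncation
  for (v in names(trunc)) {
    if (trunc[[v]][1] >= trunc[[v]][2]) {
      abort("truncation bounds for '%s' must be ordered", v)
    }
  }
  if (!is.null(copula)) {
    k <- length(cohort_variables())
    if (!is.matrix(copula) || any(dim(copula) != k)) {
      abort("copula must be a %d x %d correlation matrix", k, k)
    }
  }
  # EPL heart-rate mixture solved once, here, from the group moments
  ehr_mix <- solve_ehr_mixture(mean = gp$epl$ehr[1], sd = gp$epl$ehr[2],
                               positive_sd = ehr_positive_sd)
  structure(list(n = as.integer(n), prevalence = prevalence, mode = mode,
                 group_params = gp, truncation = trunc,
                 ehr_mixture = ehr_mix, copula = copula, seed = seed),
            class = "cohort_config")
}

cohort_variables <- function() {
  c("ma", "bmi", "duration", "hcg", "em", "gsd", "ysd", "el", "ehr")
}

#' Solve the zero-inflated heart-rate mixture from its moments
#'
#' Finds the weight `w0` of the point mass at 0 bpm and the mean `mu` of
#' the beating-heart normal component such that the mixture
#' `w0 * delta_0 + (1 - w0) * N(mu, positive_sd)` has the requested mean
#' and standard deviation. The two moment equations reduce to a quadratic
#' in the beating fraction `q = 1 - w0`:
#' `q^2 * sigma^2 - q * (m^2 + s^2) + m^2 = 0`; the root in (0, 1] is
#' taken.
#'
#' @param mean,sd Target group mean and SD, bpm.
#' @param positive_sd SD of the beating-heart component, bpm.
#' @return A list with `w0`, `mu`, `sigma`.
#' @export
solve_ehr_mixture <- function(mean, sd, positive_sd = 12.2) {
  m <- mean; s <- sd; sigma <- positive_sd
  if (m <= 0) return(list(w0 = 1, mu = 0, sigma = sigma))
  disc <- (m^2 + s^2)^2 - 4 * sigma^2 * m^2
  if (disc < 0) {
    abort("no zero-inflated mixture attains mean %g, sd %g with component sd %g",
          m, s, sigma)
  }
  q <- ((m^2 + s^2) - sqrt(disc)) / (2 * sigma^2)
  if (q <= 0 || q > 1) {
    abort("mixture solution infeasible (beating fraction %g)", q)
  }
  list(w0 = 1 - q, mu = m / q, sigma = sigma)
}

# Quantile of a normal truncated to [lower, upper]; u in [0, 1].
qtruncnorm <- function(u, mean, sd, lower = 0, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# Quantile function for variable v in outcome group g under a config.
quantile_for <- function(config, v, g) {
  pars <- config$group_params[[g]][[v]]
  tr <- config$truncation[[v]]
  if (v == "ehr" && g == "epl") {
    mix <- config$ehr_mixture
    function(u) {
      out <- numeric(length(u))
      beating <- u >= mix$w0
      out[beating] <- qtruncnorm((u[beating] - mix$w0) / (1 - mix$w0),
                                 mix$mu, mix$sigma, max(tr[1], 0), tr[2])
      out
    }
  } else {
    function(u) qtruncnorm(u, pars[1], pars[2], tr[1], tr[2])
  }
}

# n x k matrix of uniforms: independent, or coupled by a Gaussian copula.
draw_uniforms <- function(n, k, copula) {
  if (is.null(copula)) {
    matrix(stats::runif(n * k), nrow = n, ncol = k)
  } else {
    z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k) %*% chol(copula)
    stats::pnorm(z)
  }
}

#' Simulate a cohort with outcome-group-conditional distributions
#'
#' Draws each pregnancy's outcome from `Bernoulli(prevalence)`, then its
#' measurements from the outcome group's truncated-normal (and, for the
#' EPL heart rate, zero-inflated mixture) distributions. This mode
#' emulates the published group summary statistics directly and is the
#' default input to the derivation pipeline.
#'
#' @param config A [cohort_config()] with `mode = "group_conditional"`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `data.frame` with columns
#'   `ma, bmi, duration, hcg, em, gsd, ysd, el, ehr, iuh, outcome`
#'   (`iuh` logical, `outcome` in `{"ongoing", "epl"}`).
#' @export
#' @examples
#' cohort <- generate_group_conditional(cohort_config(n = 500), seed = 1)
#' table(cohort$outcome)
generate_group_conditional <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "group_conditional") {
    abort("config mode is '%s'; expected 'group_conditional'", config$mode)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  vars <- cohort_variables()
  outcome <- ifelse(stats::runif(n) < config$prevalence, "epl", "ongoing")
  u <- draw_uniforms(n, length(vars), config$copula)
  colnames(u) <- vars
  out <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    x <- numeric(n)
    for (g in c("ongoing", "epl")) {
      idx <- outcome == g
      if (any(idx)) x[idx] <- quantile_for(config, v, g)(u[idx, v])
    }
    out[[v]] <- x
  }
  iuh_rate <- ifelse(outcome == "epl",
                     config$group_params$epl$iuh,
                     config$group_params$ongoing$iuh)
  out$iuh <- stats::runif(n) < iuh_rate
  out$outcome <- outcome
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Logistic generative model for synthetic outcomes
#'
#' @param intercept Log-odds intercept. `NULL` (default) calibrates the
#'   intercept at generation time so the cohort's expected EPL rate
#'   equals the configured prevalence given the realized covariates.
#' @param betas Named vector of per-unit log-odds coefficients; must
#'   cover the six scoring variables. Defaults are the published
#'   regression coefficients.
#' @return A list of class `generative_model`.
#' @export
generative_model <- function(intercept = NULL,
                             betas = c(ma = 0.0920, gsd = -0.1150,
                                       el = -0.2450, ehr = -0.0340,
                                       ysd = -0.1590, em = -0.074)) {
  required <- c("ma", "gsd", "el", "ehr", "ysd", "em")
  missing_b <- setdiff(required, names(betas))
  if (length(missing_b)) {
    abort("generative model lacks beta(s) for scoring variable(s): %s",
          paste(missing_b, collapse = ", "))
  }
  structure(list(intercept = intercept, betas = betas),
            class = "generative_model")
}

#' Simulate a cohort from a logistic outcome model
#'
#' Draws covariates from the pooled population (the prevalence-weighted
#' mixture of the two outcome groups' distributions) and then the outcome
#' from `Bernoulli(plogis(intercept + sum(beta * x)))`. Because the
#' outcome truly follows a logistic model in this mode, it supports
#' parameter-recovery experiments for the model-fitting stage.
#'
#' @param config A [cohort_config()] with `mode = "logistic_generative"`.
#' @param model A [generative_model()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A cohort `data.frame` as in [generate_group_conditional()],
#'   with attributes `intercept` (the value used) and `mean_prob` (the
#'   average generated event probability).
#' @export
generate_logistic <- function(config, model = generative_model(),
                              seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "logistic_generative") {
    abort("config mode is '%s'; expected 'logistic_generative'", config$mode)
  }
  stopifnot(inherits(model, "generative_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  vars <- cohort_variables()
  # latent group picks the covariate mixture component only
  latent <- ifelse(stats::runif(n) < config$prevalence, "epl", "ongoing")
  u <- draw_uniforms(n, length(vars), config$copula)
  colnames(u) <- vars
  out <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    x <- numeric(n)
    for (g in c("ongoing", "epl")) {
      idx <- latent == g
      if (any(idx)) x[idx] <- quantile_for(config, v, g)(u[idx, v])
    }
    out[[v]] <- x
  }
  iuh_rate <- ifelse(latent == "epl",
                     config$group_params$epl$iuh,
                     config$group_params$ongoing$iuh)
  out$iuh <- stats::runif(n) < iuh_rate

  eta <- rep(0, n)
  for (v in names(model$betas)) {
    if (is.null(out[[v]])) abort("model beta refers to unknown variable '%s'", v)
    eta <- eta + model$betas[[v]] * out[[v]]
  }
  intercept <- model$intercept
  if (is.null(intercept)) {
    intercept <- calibrate_intercept(eta, config$prevalence)
  }
  prob <- stats::plogis(intercept + eta)
  out$outcome <- ifelse(stats::runif(n) < prob, "epl", "ongoing")
  cohort <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(cohort, "intercept") <- intercept
  attr(cohort, "mean_prob") <- mean(prob)
  cohort
}

# Solve c so that mean(plogis(c + eta)) = target over the realized eta.
calibrate_intercept <- function(eta, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(c) mean(stats::plogis(c + eta)) - target
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}
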