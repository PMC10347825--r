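test_that("a single binary predictor recovers the contingency-table log odds ratio", {
  # 2x2 closed form: beta = log((a*d)/(b*c)) for exposed/unexposed events
  a <- 30; b <- 70; c2 <- 10; d <- 90
  cohort <- data.frame(
    x = c(rep(1, a + b), rep(0, c2 + d)),
    outcome = c(rep("epl", a), rep("ongoing", b),
                rep("epl", c2), rep("ongoing", d)))
  fit <- fit_logistic(cohort, "x")
  expect_equal(fit$coefficients$estimate, log((a * d) / (b * c2)),
               tolerance = 1e-8)
  expect_equal(fit$intercept, log(c2 / d), tolerance = 1e-8)
})

test_that("wald_summary transforms coefficients to odds-ratio scale", {
  ws <- wald_summary(0, 1)
  expect_equal(ws$or, 1)
  expect_equal(ws$ci, exp(c(-1.96, 1.96)))
  expect_equal(ws$p, 1)
  # reciprocal symmetry: flipping the sign inverts OR and mirrors the CI
  a <- wald_summary(0.3, 0.1)
  b <- wald_summary(-0.3, 0.1)
  expect_equal(a$or * b$or, 1)
  expect_equal(a$ci, rev(1 / b$ci))
  expect_equal(a$p, b$p)
  expect_error(wald_summary(0.3, 0), "se")
})

test_that("published coefficients map to the published odds ratios", {
  expect_equal(wald_summary(0.0920, 0.0107)$or, 1.096, tolerance = 5e-4)
  expect_equal(wald_summary(-0.2450, 0.0785)$or, 0.783, tolerance = 5e-4)
  expect_equal(wald_summary(-0.1590, 0.0846)$or, 0.853, tolerance = 5e-4)
  expect_equal(wald_summary(-0.074, 0.0253)$or, 0.929, tolerance = 5e-4)
})

test_that("fitting a well-specified logistic cohort recovers the generating coefficients", {
  cfg <- cohort_config(n = 5e4, mode = "logistic_generative")
  cohort <- generate_logistic(cfg, generative_model(), seed = 101)
  fit <- fit_logistic(cohort, names(true_betas))
  z <- abs(fit$coefficients$estimate - true_betas[fit$coefficients$term]) /
    fit$coefficients$se
  expect_true(all(z < 3), label = paste("recovery z-scores:",
                                        paste(round(z, 2), collapse = " ")))
  expect_true(fit$converged)
})

test_that("the fit is invariant to row order and equivariant to covariate rescaling", {
  cfg <- cohort_config(n = 5000, mode = "logistic_generative")
  cohort <- generate_logistic(cfg, generative_model(), seed = 55)
  vars <- c("ma", "gsd", "ehr")
  fit <- fit_logistic(cohort, vars)
  shuffled <- cohort[sample(nrow(cohort)), ]
  fit2 <- fit_logistic(shuffled, vars)
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-6)
  # gsd in centimetres: coefficient scales by 10, Wald p unchanged
  rescaled <- cohort
  rescaled$gsd <- rescaled$gsd / 10
  fit3 <- fit_logistic(rescaled, vars)
  i <- match("gsd", fit$coefficients$term)
  expect_equal(fit3$coefficients$estimate[i], 10 * fit$coefficients$estimate[i],
               tolerance = 1e-6)
  expect_equal(fit3$coefficients$p, fit$coefficients$p, tolerance = 1e-6)
})

test_that("degenerate inputs are diagnosed", {
  cohort <- data.frame(x = rnorm(50), outcome = rep("ongoing", 50))
  expect_error(fit_logistic(cohort, "x"), "single class")
  cohort2 <- data.frame(x = rep(1, 50),
                        outcome = rep(c("epl", "ongoing"), 25))
  expect_error(fit_logistic(cohort2, "x"), "constant")
  # perfectly separated predictor
  cohort3 <- data.frame(x = c(rnorm(40, 10), rnorm(40, -10)),
                        z = rnorm(80),
                        outcome = rep(c("epl", "ongoing"), each = 40))
  expect_error(fit_logistic(cohort3, c("x", "z")), "separation.*'x'")
})

test_that("rows with missing predictors are dropped and counted", {
  cohort <- generate_logistic(cohort_config(n = 2000, mode = "logistic_generative"),
                              generative_model(), seed = 4)
  cohort$gsd[1:25] <- NA
  fit <- fit_logistic(cohort, c("ma", "gsd"))
  expect_identical(fit$n_dropped, 25L)
  expect_identical(fit$n, 1975L)
})

test_that("Wald p-values for a pure-noise coefficient are approximately uniform", {
  set.seed(321)
  reps <- 300
  pvals <- replicate(reps, {
    n <- 600
    cohort <- data.frame(noise = rnorm(n),
                         outcome = ifelse(runif(n) < 0.3, "epl", "ongoing"))
    fit_logistic(cohort, "noise")$coefficients$p
  })
  # rejection rate at alpha = 0.05 within 3 binomial SEs
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  # and the full distribution passes a KS uniformity check
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("backward elimination keeps truly predictive variables and alpha_stay = 1 keeps all", {
  set.seed(99)
  reps <- 15
  hits <- 0
  for (r in seq_len(reps)) {
    model <- generative_model(betas = c(ma = 0, gsd = -0.115, el = 0,
                                        ehr = -0.034, ysd = 0, em = 0))
    cohort <- generate_logistic(cohort_config(n = 2e4,
                                              mode = "logistic_generative"),
                                model, seed = 1000 + r)
    sel <- stepwise_select(cohort, c("ma", "bmi", "em", "gsd", "ysd", "ehr"),
                           alpha_stay = 0.10)
    if (all(c("gsd", "ehr") %in% sel$selected)) hits <- hits + 1
  }
  expect_gte(hits, reps - 1)  # the true signals are practically always kept

  cohort <- generate_logistic(cohort_config(n = 5000,
                                            mode = "logistic_generative"),
                              generative_model(), seed = 7)
  all_kept <- stepwise_select(cohort, c("ma", "bmi", "gsd", "ehr"),
                              alpha_stay = 1.0)
  expect_setequal(all_kept$selected, c("ma", "bmi", "gsd", "ehr"))
})

test_that("pure-noise candidates are retained at roughly the alpha_stay rate", {
  set.seed(2718)
  reps <- 150
  k <- 3
  retained <- 0
  for (r in seq_len(reps)) {
    n <- 500
    cohort <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                         outcome = ifelse(runif(n) < 0.3, "epl", "ongoing"))
    sel <- suppressWarnings(
      stepwise_select(cohort, c("n1", "n2", "n3"), alpha_stay = 0.05))
    retained <- retained + length(sel$selected)
  }
  rate <- retained / (reps * k)
  # marginal retention of a null variable sits near the alpha level
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / (reps * k)) + 0.02)
})

test_that("forward selection finds the same strong predictors as backward on clean signal", {
  cohort <- generate_logistic(cohort_config(n = 2e4, mode = "logistic_generative"),
                              generative_model(), seed = 12)
  back <- stepwise_select(cohort, names(true_betas), alpha_stay = 0.10)
  fwd <- stepwise_select(cohort, names(true_betas), alpha_stay = 0.10,
                         direction = "forward")
  expect_setequal(back$selected, names(true_betas))
  expect_setequal(fwd$selected, names(true_betas))
})

test_that("derive_point_system reproduces the published table from exact coefficients", {
  coeffs <- data.frame(term = names(true_betas), estimate = unname(true_betas),
                       se = 0.01, z = 1, p = 0.001, or = exp(unname(true_betas)),
                       ci_low = 1, ci_high = 1)
  fit <- structure(list(coefficients = coeffs, intercept = 0, converged = TRUE,
                        iterations = 5L, n = 100L, n_dropped = 0L, loglik = 0),
                   class = "epl_fit")
  sys <- derive_point_system(fit, published_system())
  expect_equal(sys$B, 0.46)
  cmp <- compare_point_tables(sys, published_system())
  expect_true(all(cmp$match))
  # all-zero coefficients give an all-zero point table (explicit B needed
  # because the default B rule degenerates)
  coeffs0 <- coeffs
  coeffs0$estimate <- 0
  fit0 <- structure(list(coefficients = coeffs0, intercept = 0, converged = TRUE,
                         iterations = 5L, n = 100L, n_dropped = 0L, loglik = 0),
                    class = "epl_fit")
  sys0 <- derive_point_system(fit0, published_system(), B = 0.46)
  expect_true(all(unlist(lapply(sys0$factors,
                                function(f) f$categories$points)) == 0L))
  expect_error(derive_point_system(fit0, published_system()), "B_rule")
  # a fitted variable without category definitions is a specification error
  extra <- coeffs
  extra$term[1] <- "hcg"
  fitx <- structure(list(coefficients = extra, intercept = 0, converged = TRUE,
                         iterations = 5L, n = 100L, n_dropped = 0L, loglik = 0),
                    class = "epl_fit")
  expect_error(derive_point_system(fitx, published_system()), "hcg")
})

test_that("the analytic risk curve calibrates against the published table", {
  ref <- published_system()$risk_table
  curve <- estimate_risk_curve(B = 0.46, totals = -8:14, reference = ref)
  c0 <- attr(curve, "intercept")
  expect_gt(c0, -3.5)
  expect_lt(c0, -2.5)
  expect_true(all(diff(curve$risk) > 0))
  # flat curve at B = 0
  flat <- estimate_risk_curve(intercept = -1, B = 0, totals = -8:14)
  expect_true(all(flat$risk == 100 * plogis(-1)))
  expect_identical(attr(curve, "label"), "analytic approximation")
})

test_that("confidence intervals cover the generating coefficients at the nominal rate", {
  reps <- 150
  covered <- 0
  total <- 0
  for (r in seq_len(reps)) {
    cohort <- generate_logistic(cohort_config(n = 4000,
                                              mode = "logistic_generative"),
                                generative_model(), seed = 5000 + r)
    fit <- fit_logistic(cohort, names(true_betas))
    lo <- fit$coefficients$estimate - 1.96 * fit$coefficients$se
    hi <- fit$coefficients$estimate + 1.96 * fit$coefficients$se
    truth <- true_betas[fit$coefficients$term]
    covered <- covered + sum(truth >= lo & truth <= hi)
    total <- total + length(truth)
  }
  rate <- covered / total
  # per-coefficient coverage draws are positively correlated within a
  # replicate, so allow 3 SEs at the per-replicate effective sample size
  expect_lt(abs(rate - 0.95), 3 * sqrt(0.95 * 0.05 / reps))
})
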