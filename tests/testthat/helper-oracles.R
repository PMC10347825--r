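# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# O(n^2) pairwise AUC: proportion of event/non-event pairs ranked
# correctly, ties counting one half.
brute_force_auc <- function(scores, outcomes) {
  event <- if (is.logical(outcomes)) outcomes else outcomes == "epl"
  s1 <- scores[event]
  s0 <- scores[!event]
  total <- 0
  for (a in s1) {
    for (b in s0) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(s1) * length(s0))
}

# Mean of N(mean, sd) truncated to [lower, upper], by numerical
# integration of x * density / mass.
truncnorm_mean_oracle <- function(mean, sd, lower = 0, upper = Inf) {
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd),
                   lower, upper, rel.tol = 1e-10)$value / mass
}

# A tiny deterministic cohort for order/format tests.
toy_cohort <- function() {
  data.frame(
    ma = c(38, 30, 42, 25, 33, 29),
    bmi = c(22, NA, 24, 21, 23, 22.5),
    duration = c(3, 4, 6, 2, 5, 3.5),
    hcg = c(500, 600, 300, 700, 450, NA),
    em = c(8, 12, 9, 13, 11, 16),
    gsd = c(10, 19, 7, 20, 12, 28),
    ysd = c(2.2, 3.8, 5.5, 4.0, 2.9, 3.5),
    el = c(2.5, 4.0, 0.0, 4.5, 1.5, 7.0),
    ehr = c(88, 115, 0, 120, 95, 132),
    iuh = c(TRUE, FALSE, TRUE, FALSE, NA, FALSE),
    outcome = c("epl", "ongoing", "epl", "ongoing", "epl", "ongoing"),
    stringsAsFactors = FALSE)
}

# The six published factor coefficients, used as ground truth in
# parameter-recovery experiments.
true_betas <- c(ma = 0.0920, gsd = -0.1150, el = -0.2450,
                ehr = -0.0340, ysd = -0.1590, em = -0.074)
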