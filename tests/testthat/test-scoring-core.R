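sys <- published_system()

test_that("categorize resolves printed intervals under the half-open convention", {
  cases <- list(
    list("ma", 38, "30-39"), list("ma", 30, "30-39"), list("ma", 29.9, "<29"),
    list("ma", 26, "<29"),
    list("ma", 40, ">=40"),
    list("gsd", 27.0, "13.0-27.0"),   # explicit "-27.0" keeps its boundary
    list("gsd", 27.05, ">27.0"), list("gsd", 9.0, "9.0-12.9"),
    list("gsd", 12.95, "9.0-12.9"),
    list("el", 6.3, "2.1-6.3"), list("el", 6.35, ">6.3"), list("el", 2.0, "2.1-6.3"),
    list("el", 0, "<2.0"),            # absent embryo
    list("ehr", 88, "<100"), list("ehr", 130, ">=130"),  # explicit ">=" wins
    list("ehr", 0, "<100"),           # absent cardiac activity
    list("ysd", 2.2, "<3.00"), list("ysd", 5.0, ">=5.00"),
    list("em", 15.0, ">=15.0"), list("em", 10.0, "10.0-14.99"))
  for (case in cases) {
    f <- sys$factors[[case[[1]]]]
    expect_identical(f$categories$label[categorize(case[[2]], f)], case[[3]],
                     label = sprintf("%s = %g", case[[1]], case[[2]]))
  }
})

test_that("categorize rejects non-finite and negative measurements, naming the factor", {
  expect_error(categorize(-1, sys$factors$gsd), "gsd")
  expect_error(categorize(NaN, sys$factors$ma), "ma")
  expect_error(categorize(Inf, sys$factors$ehr), "ehr")
})

test_that("category points follow the scaled-coefficient formula with half-away rounding", {
  # maternal age >= 40: 0.0920 * (42 - 34.5) / 0.46 = 1.5, a tie -> 2
  ma <- sys$factors$ma
  expect_identical(compute_category_points(ma, 3L, 0.46), 2L)
  # heart rate < 100: -0.034 * (50 - 115) / 0.46 = 4.804 -> 5
  expect_identical(compute_category_points(sys$factors$ehr, 1L, 0.46), 5L)
  # yolk sac >= 5.00 uses the absolute deviation: both sides score +1
  expect_identical(compute_category_points(sys$factors$ysd, 3L, 0.46), 1L)
  expect_identical(compute_category_points(sys$factors$ysd, 1L, 0.46), 1L)
  # base categories are exactly zero for every factor
  for (f in sys$factors) {
    expect_identical(compute_category_points(f, which(f$categories$is_base), 0.46), 0L)
  }
  expect_error(compute_category_points(ma, 1L, 0), "positive")
})

test_that("rounding is half away from zero in both directions", {
  expect_identical(round_half_away(c(1.5, -1.5, 2.5, -2.5, 0.49, -0.49)),
                   c(2, -2, 3, -3, 0, 0))
  expect_identical(round_half_away(62.8364, 2), 62.84)
})

test_that("the published fixture rebuilds the full 19-category point table", {
  expected <- list(
    ma  = c(-2L, 0L, 2L),
    gsd = c(3L, 2L, 0L, -2L),
    el  = c(2L, 0L, -1L),
    ehr = c(5L, 0L, -2L),
    ysd = c(1L, 0L, 1L),
    em  = c(1L, 0L, -1L))
  for (nm in names(expected)) {
    expect_identical(sys$factors[[nm]]$categories$points, expected[[nm]],
                     label = paste("points for", nm))
  }
  expect_identical(sys$B, 0.46)
  expect_length(sys$factors, 6L)
})

test_that("score range comes from per-factor extremes and exhaustive enumeration agrees", {
  expect_identical(sys$score_min, -8L)
  expect_identical(sys$score_max, 14L)
  totals <- enumerate_totals(sys)
  expect_length(totals, 3 * 4 * 3 * 3 * 3 * 3)
  expect_identical(range(totals), c(-8L, 14L))
})

test_that("a single-factor system with only a base category scores the zero range", {
  f <- risk_factor("x", beta = 0.5,
                   categories = factor_category("all", Inf, 1.0, is_base = TRUE))
  one <- build_point_system(list(f), B = 0.46)
  expect_identical(c(one$score_min, one$score_max), c(0L, 0L))
})

test_that("malformed factor definitions are rejected", {
  expect_error(risk_factor("x", 0.1, rbind(
    factor_category("a", 5, 1), factor_category("b", 5, 6, is_base = TRUE))),
    "increasing")
  expect_error(risk_factor("x", 0.1, rbind(
    factor_category("a", 5, 1), factor_category("b", Inf, 6))),
    "base")
  expect_error(risk_factor("x", 0.1,
    factor_category("a", 5, 1, is_base = TRUE)), "Inf")
})

test_that("points are monotone in the representative value (signed) or its deviation (absolute)", {
  for (f in sys$factors) {
    pts <- f$categories$points
    w <- f$categories$representative
    if (f$deviation_mode == "signed") {
      expect_true(all(diff(pts[order(w)]) * sign(f$beta) >= 0),
                  label = paste("monotone points for", f$name))
    } else {
      dev <- abs(w - reference_value(f))
      expect_true(all(diff(pts[order(dev)]) >= 0),
                  label = paste("deviation-monotone points for", f$name))
    }
  }
})

test_that("the worked example scores 9 with the published breakdown and risk", {
  rec <- patient_record(ma = 38, em = 8, gsd = 10, ysd = 2.2, el = 2.5, ehr = 88)
  sc <- score_patient(rec, sys)
  expect_identical(sc$total, 9L)
  expect_identical(sc$breakdown,
                   c(ma = 0L, gsd = 2L, el = 0L, ehr = 5L, ysd = 1L, em = 1L))
  expect_identical(sc$risk, 70.67)
})

test_that("base-category measurements score zero and maximal-risk ones score 14", {
  base <- patient_record(ma = 34.5, em = 12.5, gsd = 19, ysd = 4, el = 4.2, ehr = 115)
  expect_identical(score_patient(base, sys)$total, 0L)
  worst <- patient_record(ma = 45, em = 8, gsd = 6, ysd = 2, el = 0, ehr = 0)
  expect_identical(score_patient(worst, sys)$total, 14L)
})

test_that("scoring is invariant to factor order and reports missing fields by name", {
  shuffled <- sys
  shuffled$factors <- rev(shuffled$factors)
  rec <- patient_record(ma = 38, em = 8, gsd = 10, ysd = 2.2, el = 2.5, ehr = 88)
  expect_identical(score_patient(rec, shuffled)$total, score_patient(rec, sys)$total)
  expect_error(score_patient(list(ma = 38, em = 8, gsd = 10, ysd = 2.2, el = 2.5),
                             sys), "ehr")
})

test_that("risk lookup returns fixture values and enforces range", {
  expect_identical(lookup_risk(9, sys), 70.67)
  expect_identical(lookup_risk(5, sys), 30.03)
  expect_identical(lookup_risk(-8, sys), 0.18)
  expect_identical(lookup_risk(14, sys), 95.42)
  expect_error(lookup_risk(15, sys), "-8\\.\\.14")
  expect_error(lookup_risk(-9, sys), "-8\\.\\.14")
})

test_that("the published risk table is strictly increasing over its 23 rows", {
  expect_identical(nrow(sys$risk_table), 23L)
  expect_identical(sys$risk_table$total, -8:14)
  expect_true(all(diff(sys$risk_table$risk) > 0))
  expect_true(all(sys$risk_table$risk > 0 & sys$risk_table$risk < 100))
})

test_that("risk tables reject gaps, non-monotone risks and out-of-(0,100) values", {
  expect_error(risk_table(c(0, 2), c(1, 2)), "consecutive")
  expect_error(risk_table(c(0, 1), c(2, 1)), "increasing")
  expect_error(risk_table(c(0, 1), c(0, 50)), "strictly between")
})

test_that("point systems round-trip through JSON with points re-derived", {
  path <- withr::local_tempfile(fileext = ".json")
  write_point_system(sys, path, name = "round trip")
  back <- read_point_system(path)
  expect_identical(back$score_min, sys$score_min)
  expect_identical(back$score_max, sys$score_max)
  for (nm in names(sys$factors)) {
    expect_identical(back$factors[[nm]]$categories$points,
                     sys$factors[[nm]]$categories$points)
    expect_equal(back$factors[[nm]]$beta, sys$factors[[nm]]$beta)
  }
  expect_equal(back$risk_table$risk, sys$risk_table$risk)
})

test_that("patient records validate their scoring fields", {
  expect_error(patient_record(ma = 38, em = 8, gsd = -1, ysd = 2, el = 2, ehr = 88),
               "gsd")
  expect_error(patient_record(ma = 38, em = 8, gsd = 10, ysd = 2, el = 2, ehr = NA),
               "ehr")
  expect_error(patient_record(ma = 38, em = 8, gsd = 10, ysd = 2, el = 2, ehr = 88,
                              outcome = "maybe"), "outcome")
  rec <- patient_record(ma = 38, em = 8, gsd = 10, ysd = 2, el = 0, ehr = 0)
  expect_identical(rec$el, 0)  # absent embryo is a value, not missing
})
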