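#' Define a category of a scoring risk factor
#'
#' A risk factor is discretized into ordered intervals that partition the
#' real line. Each interval carries a representative value (roughly its
#' midpoint in the derivation cohort) whose deviation from the base
#' category's reference value determines the integer points assigned to
#' the interval.
#'
#' Intervals are half-open `[lower, upper)` by default. Where a printed
#' category label makes its upper boundary explicit (e.g. an interval
#' ending "-27.0" followed by ">27.0"), set `upper_closed = TRUE` so the
#' boundary value falls in this category; the next category then starts
#' strictly above it.
#'
#' @param label Human-readable interval label, e.g. `"30-39"`.
#' @param upper Exclusive upper bound (inclusive if `upper_closed`);
#'   `Inf` for the top category. Lower bounds are implied by the ordering
#'   when categories are assembled by [risk_factor()].
#' @param representative Representative value of the interval, in factor
#'   units.
#' @param is_base `TRUE` for the single reference category; its
#'   representative value is the factor's reference value and it scores 0
#'   points.
#' @param upper_closed Whether `upper` itself belongs to this category.
#' @return A one-row `data.frame` describing the category.
#' @seealso [risk_factor()], [build_point_system()]
#' @export
factor_category <- function(label, upper, representative, is_base = FALSE,
                            upper_closed = FALSE) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(upper), length(upper) == 1L,
            is.numeric(representative), is.finite(representative))
  data.frame(label = label, upper = as.numeric(upper),
             upper_closed = isTRUE(upper_closed),
             representative = as.numeric(representative),
             is_base = isTRUE(is_base), stringsAsFactors = FALSE)
}

#' Define a scoring risk factor
#'
#' Bundles a variable's per-unit log-odds coefficient with its ordered
#' interval categories. Categories must partition the real line: they are
#' supplied in increasing order of `upper`, the first implicitly starts at
#' `-Inf` and the last must end at `Inf`.
#'
#' `deviation_mode` controls how a category's representative value is
#' compared with the reference value when points are computed:
#' * `"signed"` (the usual case): points follow the sign of
#'   `beta * (W - W_ref)`.
#' * `"absolute"`: points use `|beta| * |W - W_ref|`, for U-shaped factors
#'   where deviation in either direction raises risk (yolk sac diameter in
#'   the published system: both small and large yolk sacs score +1).
#'
#' @param name Factor name (one of `ma`, `gsd`, `el`, `ehr`, `ysd`, `em`
#'   in the published system, but arbitrary names are allowed).
#' @param beta Logistic regression coefficient, log-odds per factor unit.
#' @param categories A `data.frame` of categories, typically
#'   `rbind()` of [factor_category()] rows in increasing order.
#' @param deviation_mode `"signed"` or `"absolute"`.
#' @return An object of class `risk_factor`.
#' @export
risk_factor <- function(name, beta, categories,
                        deviation_mode = c("signed", "absolute")) {
  deviation_mode <- match.arg(deviation_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(beta), is.finite(beta), is.data.frame(categories))
  required <- c("label", "upper", "upper_closed", "representative", "is_base")
  missing_cols <- setdiff(required, names(categories))
  if (length(missing_cols)) {
    abort("factor '%s': categories lack column(s) %s", name,
          paste(missing_cols, collapse = ", "))
  }
  n <- nrow(categories)
  if (n < 1L) abort("factor '%s': needs at least one category", name)

  # implied lower bounds: first category opens at -Inf
  categories$lower <- c(-Inf, categories$upper[-n])
  bad <- which(categories$lower >= categories$upper)
  if (length(bad)) {
    abort("factor '%s': categories must be in strictly increasing order (row %d: [%g, %g))",
          name, bad[1L], categories$lower[bad[1L]], categories$upper[bad[1L]])
  }
  if (is.finite(categories$upper[n])) {
    abort("factor '%s': top category must extend to Inf (got upper = %g)",
          name, categories$upper[n])
  }
  if (sum(categories$is_base) != 1L) {
    abort("factor '%s': exactly one category must be the base (found %d)",
          name, sum(categories$is_base))
  }
  categories$points <- rep(NA_integer_, n)
  rownames(categories) <- NULL
  structure(list(name = name, beta = as.numeric(beta),
                 deviation_mode = deviation_mode,
                 categories = categories),
            class = "risk_factor")
}

#' Reference value of a risk factor
#'
#' The representative value of the factor's base category (`W_ref`).
#'
#' @param factor A [risk_factor()].
#' @return A number in factor units.
#' @export
reference_value <- function(factor) {
  stopifnot(inherits(factor, "risk_factor"))
  factor$categories$representative[factor$categories$is_base]
}

#' Locate the category containing a measured value
#'
#' @param value A finite, non-negative measurement in factor units.
#' @param factor A [risk_factor()].
#' @return The integer index of the unique category whose interval
#'   contains `value`.
#' @export
#' @examples
#' sys <- published_system()
#' categorize(38, sys$factors$ma)   # maternal age 38 -> "30-39"
#' categorize(88, sys$factors$ehr)  # heart rate 88 bpm -> "<100"
categorize <- function(value, factor) {
  stopifnot(inherits(factor, "risk_factor"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    abort("factor '%s': value must be a single finite number", factor$name)
  }
  if (value < 0) {
    abort("factor '%s': value must be >= 0 (got %g)", factor$name, value)
  }
  cats <- factor$categories
  for (j in seq_len(nrow(cats))) {
    if (value < cats$upper[j] || (cats$upper_closed[j] && value == cats$upper[j])) {
      return(j)
    }
  }
  abort("factor '%s': no category contains %g", factor$name, value)  # unreachable
}

#' Integer points for one category of a factor
#'
#' Implements the Sullivan/Framingham conversion of a regression
#' coefficient to points: the category's contribution to the linear
#' predictor, `beta * (W - W_ref)`, is expressed in multiples of the base
#' constant `B` and rounded to the nearest integer (halves away from
#' zero). In absolute mode the magnitude of the deviation is used, so
#' departures on either side of the reference score positive points.
#' The base category scores exactly 0.
#'
#' @param factor A [risk_factor()].
#' @param category Index of the category within `factor`.
#' @param B Points base constant, in log-odds per point; must be > 0.
#' @return An integer number of points.
#' @export
compute_category_points <- function(factor, category, B) {
  stopifnot(inherits(factor, "risk_factor"))
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B <= 0) {
    abort("points base constant B must be a single positive number")
  }
  cats <- factor$categories
  if (!(is.numeric(category) && length(category) == 1L &&
        category %in% seq_len(nrow(cats)))) {
    abort("factor '%s': category index out of range", factor$name)
  }
  if (cats$is_base[category]) return(0L)
  dev <- cats$representative[category] - reference_value(factor)
  contribution <- switch(factor$deviation_mode,
    signed   = factor$beta * dev,
    absolute = abs(factor$beta) * abs(dev))
  as.integer(round_half_away(contribution / B))
}

#' Assemble a point system from factor specifications
#'
#' Populates every category's integer points via
#' [compute_category_points()] and records the achievable score range
#' (`score_min`/`score_max`, the sums of the per-factor minima and
#' maxima).
#'
#' @param factors A list of [risk_factor()] objects.
#' @param B Points base constant (log-odds per point), > 0. The published
#'   system uses 5 times the maternal-age coefficient, B = 0.46.
#' @param risk_table Optional [risk_table()] mapping total scores to
#'   estimated risk; if supplied it must span exactly
#'   `score_min..score_max`.
#' @return An object of class `point_system` with elements `factors`
#'   (named list), `B`, `score_min`, `score_max` and optionally
#'   `risk_table`.
#' @export
#' @examples
#' sys <- published_system()
#' sys2 <- build_point_system(sys$factors, B = sys$B)
#' sys2$score_min; sys2$score_max
build_point_system <- function(factors, B, risk_table = NULL) {
  if (!is.list(factors) || !length(factors) ||
      !all(vapply(factors, inherits, logical(1), "risk_factor"))) {
    abort("factors must be a non-empty list of risk_factor objects")
  }
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort("duplicate factor names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  factors <- lapply(factors, function(f) {
    f$categories$points <- vapply(seq_len(nrow(f$categories)),
                                  function(j) compute_category_points(f, j, B),
                                  integer(1))
    f
  })
  names(factors) <- nms
  per_min <- vapply(factors, function(f) min(f$categories$points), integer(1))
  per_max <- vapply(factors, function(f) max(f$categories$points), integer(1))
  sys <- structure(list(factors = factors, B = as.numeric(B),
                        score_min = as.integer(sum(per_min)),
                        score_max = as.integer(sum(per_max)),
                        risk_table = NULL),
                   class = "point_system")
  if (!is.null(risk_table)) {
    risk_table <- as_risk_table(risk_table)
    if (min(risk_table$total) != sys$score_min ||
        max(risk_table$total) != sys$score_max) {
      abort("risk table spans %d..%d but the point system spans %d..%d",
            min(risk_table$total), max(risk_table$total),
            sys$score_min, sys$score_max)
    }
    sys$risk_table <- risk_table
  }
  sys
}

#' Risk lookup table for point totals
#'
#' Validates and classes a table of estimated miscarriage risks, one row
#' per achievable total score. Totals must be consecutive integers and
#' risks strictly increasing within (0, 100) percent.
#'
#' @param total Integer vector of consecutive point totals.
#' @param risk Estimated risk of early pregnancy loss at each total, in
#'   percent.
#' @return A `data.frame` of class `risk_table` with columns `total`,
#'   `risk`.
#' @export
risk_table <- function(total, risk) {
  as_risk_table(data.frame(total = total, risk = risk))
}

as_risk_table <- function(x) {
  stopifnot(is.data.frame(x), all(c("total", "risk") %in% names(x)))
  x <- x[order(x$total), c("total", "risk")]
  if (any(x$total != round(x$total))) abort("risk table totals must be integers")
  x$total <- as.integer(x$total)
  if (nrow(x) > 1L && any(diff(x$total) != 1L)) {
    abort("risk table totals must be consecutive integers")
  }
  if (any(x$risk <= 0 | x$risk >= 100)) {
    abort("estimated risks must lie strictly between 0 and 100 percent")
  }
  if (nrow(x) > 1L && any(diff(x$risk) <= 0)) {
    abort("estimated risk must be strictly increasing in the total score")
  }
  rownames(x) <- NULL
  class(x) <- c("risk_table", "data.frame")
  x
}

#' Look up the estimated risk for a total score
#'
#' @param total Integer total score within the table's range.
#' @param table A [risk_table()] (or a `point_system` carrying one).
#' @return Estimated risk of early pregnancy loss, in percent.
#' @export
#' @examples
#' sys <- published_system()
#' lookup_risk(9, sys$risk_table)  # 70.67
#' lookup_risk(5, sys)             # 30.03
lookup_risk <- function(total, table) {
  if (inherits(table, "point_system")) {
    if (is.null(table$risk_table)) abort("point system carries no risk table")
    table <- table$risk_table
  }
  table <- as_risk_table(table)
  if (!is.numeric(total) || length(total) != 1L || total != round(total)) {
    abort("total must be a single integer")
  }
  i <- match(as.integer(total), table$total)
  if (is.na(i)) {
    abort("total %d outside the table range %d..%d",
          as.integer(total), min(table$total), max(table$total))
  }
  table$risk[i]
}

#' Score a patient with a point system
#'
#' Categorizes each of the patient's scoring measurements and sums the
#' per-factor integer points.
#'
#' @param record A [patient_record()] (or a named list/one-row data frame
#'   carrying a value for every factor in the system).
#' @param system A [build_point_system()] result.
#' @return A list of class `patient_score` with `total` (integer),
#'   `breakdown` (named integer vector, one entry per factor),
#'   `categories` (the matched interval labels), and `risk` (percent, if
#'   the system carries a risk table, else `NA`).
#' @export
#' @examples
#' sys <- published_system()
#' score_patient(patient_record(ma = 38, em = 8, gsd = 10, ysd = 2.2,
#'                              el = 2.5, ehr = 88), sys)
score_patient <- function(record, system) {
  stopifnot(inherits(system, "point_system"))
  rec <- unclass(record)
  breakdown <- integer(0)
  labels <- character(0)
  for (f in system$factors) {
    value <- rec[[f$name]]
    if (is.null(value) || length(value) != 1L || is.na(value)) {
      abort("patient record is missing scoring field '%s'", f$name)
    }
    j <- categorize(value, f)
    breakdown[f$name] <- f$categories$points[j]
    labels[f$name] <- f$categories$label[j]
  }
  total <- as.integer(sum(breakdown))
  risk <- if (!is.null(system$risk_table)) {
    lookup_risk(total, system$risk_table)
  } else NA_real_
  structure(list(total = total, breakdown = breakdown,
                 categories = labels, risk = risk),
            class = "patient_score")
}

#' @export
print.patient_score <- function(x, ...) {
  cat("Total score:", x$total, "\n")
  for (nm in names(x$breakdown)) {
    cat(sprintf("  %-4s %-10s %+d\n", nm, x$categories[nm], x$breakdown[nm]))
  }
  if (!is.na(x$risk)) cat(sprintf("Estimated risk of miscarriage: %.2f%%\n", x$risk))
  invisible(x)
}

#' @export
print.risk_factor <- function(x, ...) {
  cat(sprintf("Risk factor '%s': beta = %g (%s deviation)\n",
              x$name, x$beta, x$deviation_mode))
  print.data.frame(x$categories[, c("label", "lower", "upper",
                                    "representative", "is_base", "points")])
  invisible(x)
}

#' @export
print.point_system <- function(x, ...) {
  cat(sprintf("Point system: %d factors, B = %g, totals %d..%d\n",
              length(x$factors), x$B, x$score_min, x$score_max))
  for (f in x$factors) {
    pts <- sprintf("%+d", f$categories$points)
    pts[f$categories$is_base] <- "0 (base)"
    cat(sprintf("  %-4s %s\n", f$name,
                paste(sprintf("%s: %s", f$categories$label, pts), collapse = "; ")))
  }
  if (!is.null(x$risk_table)) {
    cat(sprintf("Risk table: %d rows, %.2f%%..%.2f%%\n", nrow(x$risk_table),
                min(x$risk_table$risk), max(x$risk_table$risk)))
  }
  invisible(x)
}

#' Enumerate all achievable total scores
#'
#' Walks every combination of one category per factor and returns the
#' distribution of total points. Used to verify that `score_min` and
#' `score_max` are attained.
#'
#' @param system A `point_system`.
#' @return An integer vector of totals, one per category combination.
#' @export
enumerate_totals <- function(system) {
  stopifnot(inherits(system, "point_system"))
  pts <- lapply(system$factors, function(f) f$categories$points)
  grid <- expand.grid(pts, KEEP.OUT.ATTRS = FALSE)
  as.integer(rowSums(grid))
}
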