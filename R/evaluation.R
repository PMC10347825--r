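as_event <- function(outcomes) {
  if (is.logical(outcomes)) return(outcomes)
  as.character(outcomes) == "epl"
}

#' Contingency table at a score cutoff
#'
#' Classifies a patient as predicted-EPL when the total score is greater
#' than or equal to the cutoff (the convention under which the published
#' performance table's extreme rows — sensitivity 100% at the minimum
#' total, specificity 100% at the maximum — are reproduced).
#'
#' @param scores Integer total scores.
#' @param outcomes Observed outcomes (`"ongoing"`/`"epl"`, or logical
#'   with `TRUE` = EPL).
#' @param cutoff Integer cutoff; scores `>= cutoff` are positive.
#' @return A list of class `contingency` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
contingency_at_cutoff <- function(scores, outcomes, cutoff) {
  if (length(scores) != length(outcomes)) {
    abort("scores (%d) and outcomes (%d) differ in length",
          length(scores), length(outcomes))
  }
  if (!length(scores)) abort("empty cohort")
  event <- as_event(outcomes)
  positive <- scores >= cutoff
  structure(list(tp = sum(positive & event),
                 fp = sum(positive & !event),
                 fn = sum(!positive & event),
                 tn = sum(!positive & !event)),
            class = "contingency")
}

#' Contingency table from explicit counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A list of class `contingency`.
#' @export
contingency <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("contingency counts must be non-negative integers")
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(observed = c("epl", "ongoing"),
                              predicted = c("epl", "ongoing")))
  print(m)
  invisible(x)
}

#' Diagnostic metrics of a contingency table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy, in percent at full precision. A metric whose denominator is
#' zero is `NA` ("undefined", not 0): e.g. PPV when nobody tests
#' positive. Rounding to two decimals happens only at presentation
#' ([format_percent()]).
#'
#' @param table A `contingency` (from [contingency_at_cutoff()] or
#'   [contingency()]).
#' @return A list with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (percent) and `prevalence` (proportion).
#' @export
#' @examples
#' metrics(contingency(tp = 607, fp = 76, fn = 359, tn = 6219))
metrics <- function(table) {
  stopifnot(inherits(table, "contingency"))
  n <- table$tp + table$fp + table$fn + table$tn
  if (n == 0) abort("contingency table is empty")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(sensitivity = ratio(table$tp, table$tp + table$fn),
       specificity = ratio(table$tn, table$tn + table$fp),
       ppv = ratio(table$tp, table$tp + table$fp),
       npv = ratio(table$tn, table$tn + table$fn),
       accuracy = ratio(table$tp + table$tn, n),
       prevalence = (table$tp + table$fn) / n)
}

#' Format a percentage for tabular display
#'
#' Two decimal places, halves rounded away from zero; undefined values
#' (`NA`) render as a dash, mirroring conventional performance-table
#' typography.
#'
#' @param x Numeric vector of percentages (may contain `NA`).
#' @param na Replacement string for undefined entries.
#' @return Character vector.
#' @export
format_percent <- function(x, na = "-") {
  out <- sprintf("%.2f", round_half_away(x, 2))
  out[is.na(x)] <- na
  out
}

#' Per-cutoff performance table
#'
#' One row per integer cutoff across the scoring range, joining the
#' estimated risk at that total with the diagnostic metrics of the
#' "score >= cutoff" classification. This reproduces the layout of the
#' published system's performance table.
#'
#' @param scores Integer total scores.
#' @param outcomes Observed outcomes.
#' @param risk_table Optional table (`total`, `risk`) supplying the
#'   estimated risk column; its range also fixes the cutoffs. Without
#'   it, cutoffs span the observed score range and the risk column is
#'   `NA`.
#' @return A `data.frame` with columns `cutoff`, `risk`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (percent, full precision;
#'   `NA` = undefined).
#' @export
performance_table <- function(scores, outcomes, risk_table = NULL) {
  if (is.null(risk_table)) {
    cutoffs <- seq(min(scores), max(scores))
    risks <- rep(NA_real_, length(cutoffs))
  } else {
    stopifnot(all(c("total", "risk") %in% names(risk_table)))
    if (min(scores) < min(risk_table$total) ||
        max(scores) > max(risk_table$total)) {
      abort("risk table spans %d..%d but observed scores span %d..%d",
            min(risk_table$total), max(risk_table$total),
            min(scores), max(scores))
    }
    cutoffs <- sort(risk_table$total)
    risks <- risk_table$risk[order(risk_table$total)]
  }
  rows <- lapply(seq_along(cutoffs), function(i) {
    m <- metrics(contingency_at_cutoff(scores, outcomes, cutoffs[i]))
    data.frame(cutoff = as.integer(cutoffs[i]), risk = risks[i],
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_table", "data.frame")
  out
}

#' @export
print.performance_table <- function(x, ...) {
  disp <- data.frame(cutoff = x$cutoff,
                     risk = format_percent(x$risk),
                     sens = format_percent(x$sensitivity),
                     spec = format_percent(x$specificity),
                     ppv = format_percent(x$ppv),
                     npv = format_percent(x$npv),
                     acc = format_percent(x$accuracy))
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney with tie correction)
#'
#' Area under the ROC curve computed from midranks:
#' `AUC = (sum of event ranks - n1 (n1 + 1) / 2) / (n1 * n0)`, which
#' equals the proportion of event/non-event pairs ordered correctly,
#' counting ties as one half.
#'
#' @param scores Numeric scores (higher = more likely event).
#' @param outcomes Observed outcomes; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, outcomes) {
  event <- as_event(outcomes)
  if (length(scores) != length(event)) {
    abort("scores and outcomes differ in length")
  }
  n1 <- sum(event)
  n0 <- sum(!event)
  if (n1 == 0 || n0 == 0) abort("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[event]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
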