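#' Construct a validated patient record
#'
#' One intrauterine singleton pregnancy at the first routine transvaginal
#' scan (days 27-29 after embryo transfer), with the six scoring
#' measurements and optional covariates.
#'
#' Absent cardiac activity is encoded as `ehr = 0` bpm and an absent
#' embryo as `el = 0` mm; both are valid measurements, not missing data.
#'
#' @param ma Maternal age, years.
#' @param em Endometrial thickness on transfer day, mm.
#' @param gsd Mean gestational sac diameter, mm.
#' @param ysd Mean yolk sac diameter, mm.
#' @param el Embryonic length (greatest length), mm.
#' @param ehr Embryonic heart rate, beats per minute (0 = no cardiac
#'   activity).
#' @param bmi Optional body mass index, kg/m^2.
#' @param hcg Optional day-14 serum beta-hCG, mIU/ml.
#' @param iuh Optional logical: intrauterine hematoma present.
#' @param outcome Optional outcome at 12 weeks: `"ongoing"` or `"epl"`.
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(ma, em, gsd, ysd, el, ehr,
                           bmi = NA_real_, hcg = NA_real_, iuh = NA,
                           outcome = NA_character_) {
  scoring <- list(ma = ma, em = em, gsd = gsd, ysd = ysd, el = el, ehr = ehr)
  for (nm in names(scoring)) {
    v <- scoring[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      abort("scoring field '%s' is missing", nm)
    }
    if (!is.numeric(v) || !is.finite(v) || v < 0) {
      abort("scoring field '%s' must be a finite non-negative number (got %s)",
            nm, format(v))
    }
  }
  if (!is.na(outcome) && !outcome %in% c("ongoing", "epl")) {
    abort("outcome must be 'ongoing' or 'epl' (got '%s')", outcome)
  }
  structure(c(lapply(scoring, as.numeric),
              list(bmi = as.numeric(bmi), hcg = as.numeric(hcg),
                   iuh = if (is.na(iuh)) NA else isTRUE(iuh),
                   outcome = as.character(outcome))),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient: MA %g y, EM %g mm, GSD %g mm, YSD %g mm, EL %g mm, EHR %g bpm\n",
              x$ma, x$em, x$gsd, x$ysd, x$el, x$ehr))
  extras <- character(0)
  if (!is.na(x$bmi)) extras <- c(extras, sprintf("BMI %g", x$bmi))
  if (!is.na(x$hcg)) extras <- c(extras, sprintf("hCG %g", x$hcg))
  if (!is.na(x$iuh)) extras <- c(extras, sprintf("IUH %s", if (x$iuh) "yes" else "no"))
  if (!is.na(x$outcome)) extras <- c(extras, sprintf("outcome %s", x$outcome))
  if (length(extras)) cat(" ", paste(extras, collapse = ", "), "\n")
  invisible(x)
}
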