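the_published <- new.env(parent = emptyenv())

#' The published six-factor EPL scoring system
#'
#' Loads the scoring system derived from 13,977 IVF-ET singleton
#' pregnancies: maternal age, gestational sac diameter, embryonic length,
#' embryonic heart rate, yolk sac diameter and endometrial thickness,
#' with points base constant B = 0.46 (five times the maternal-age
#' coefficient) and the 23-row risk table for totals -8..14.
#'
#' The fixture file stores only the coefficients, category intervals,
#' representative values, B and the risk table; the integer points are
#' re-derived on load via [build_point_system()], so the published point
#' table is always consistent with the stated derivation formula.
#'
#' @return A `point_system` carrying a `risk_table`.
#' @export
#' @examples
#' sys <- published_system()
#' sys$B
#' lookup_risk(5, sys)
published_system <- function() {
  if (is.null(the_published$system)) {
    path <- system.file("extdata", "published_epl_system.json",
                        package = "eplscore", mustWork = TRUE)
    the_published$system <- read_point_system(path)
  }
  the_published$system
}

#' Read a point system from JSON
#'
#' Inverse of [write_point_system()]. Category points are re-derived from
#' the stored coefficients and B rather than trusted from the file.
#'
#' @param path Path to a point-system JSON file.
#' @return A `point_system`.
#' @export
read_point_system <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$factors) || is.null(spec$B)) {
    abort("'%s' is not a point-system specification (needs 'factors' and 'B')",
          path)
  }
  factors <- lapply(spec$factors, function(f) {
    cats <- do.call(rbind, lapply(f$categories, function(cc) {
      factor_category(label = cc$label,
                      upper = if (is.null(cc$upper)) Inf else cc$upper,
                      representative = cc$representative,
                      is_base = isTRUE(cc$is_base),
                      upper_closed = isTRUE(cc$upper_closed))
    }))
    risk_factor(name = f$name, beta = f$beta, categories = cats,
                deviation_mode = f$deviation_mode %||% "signed")
  })
  rt <- if (!is.null(spec$risk_table)) {
    risk_table(total = unlist(spec$risk_table$total),
               risk = unlist(spec$risk_table$risk))
  }
  build_point_system(factors, B = spec$B, risk_table = rt)
}

#' Write a point system to JSON
#'
#' Serializes the factor coefficients, category intervals, representative
#' values, derived points, base constant and (if present) risk table.
#'
#' @param system A `point_system`.
#' @param path Output file path.
#' @param name Optional descriptive name stored in the file.
#' @return `path`, invisibly.
#' @export
write_point_system <- function(system, path, name = NULL) {
  stopifnot(inherits(system, "point_system"))
  factors <- lapply(system$factors, function(f) {
    cats <- lapply(seq_len(nrow(f$categories)), function(j) {
      cc <- f$categories[j, ]
      list(label = cc$label,
           upper = if (is.finite(cc$upper)) cc$upper else NULL,
           upper_closed = cc$upper_closed,
           representative = cc$representative,
           is_base = cc$is_base,
           points = cc$points)
    })
    list(name = f$name, beta = f$beta, deviation_mode = f$deviation_mode,
         categories = cats)
  })
  out <- list(name = name, B = system$B, factors = unname(factors))
  if (!is.null(system$risk_table)) {
    out$risk_table <- list(total = system$risk_table$total,
                           risk = system$risk_table$risk)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
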