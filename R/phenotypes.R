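#' PANSS reduction rate
#'
#' The trial's primary treatment-response outcome:
#' `(baseline - endpoint) / (baseline - 30) * 100`, in percent. The PANSS
#' total score has a floor of 30, so the denominator is the attainable
#' improvement; the rate can be negative (worsening) and is at most 100 when
#' `endpoint >= 30`.
#'
#' @param baseline,endpoint PANSS total scores; `baseline` must exceed 30 and
#'   `endpoint` must be at least 30.
#' @return reduction rate in percent.
#' @examples
#' panss_reduction_rate(90, 60)  # 50
#' panss_reduction_rate(90, 30)  # 100
#' @export
panss_reduction_rate <- function(baseline, endpoint) {
  if (any(baseline <= 30, na.rm = TRUE)) {
    abort("PANSS baseline must exceed the scale minimum of 30")
  }
  if (any(endpoint < 30, na.rm = TRUE)) {
    abort("PANSS endpoint below the scale minimum of 30")
  }
  (baseline - endpoint) / (baseline - 30) * 100
}

#' Responder label from a reduction rate
#'
#' Responders (RES) are defined by a PANSS reduction rate of at least 50%;
#' the boundary value 50 is a responder.
#'
#' @param reduction_rate percent reduction rate.
#' @return character vector, `"RES"` or `"non-RES"` (`NA` preserved).
#' @export
res_label <- function(reduction_rate) {
  dplyr::if_else(reduction_rate >= 50, "RES", "non-RES")
}

#' Scale a reduction rate to `[-1, 1]`
#'
#' Fixed affine map `clip(rate, -100, 100) / 100`, used as the regression
#' target of the response models. The fixed map (rather than per-cohort
#' min-max) keeps the transform leakage-free and invertible:
#' `rate = 100 * scaled` for unclipped values.
#'
#' @param reduction_rate percent reduction rate.
#' @return value in `[-1, 1]`.
#' @export
scale_reduction <- function(reduction_rate) {
  pmin(pmax(reduction_rate, -100), 100) / 100
}

#' Chlorpromazine-equivalent dose
#'
#' Converts an antipsychotic daily dose to chlorpromazine-equivalent mg/d
#' via a user-supplied conversion table (the multipliers are study
#' configuration data, not package constants).
#'
#' @param drug drug name (matched case-insensitively against the table).
#' @param dose daily dose in mg/d, must be positive.
#' @param conversion_table named numeric vector or two-column data frame
#'   (`drug`, `multiplier`).
#' @return chlorpromazine-equivalent dose in mg/d.
#' @examples
#' cpz_equivalent_dose("olanzapine", 10, c(olanzapine = 20))  # 200
#' @export
cpz_equivalent_dose <- function(drug, dose, conversion_table) {
  if (is.data.frame(conversion_table)) {
    tab <- setNames(conversion_table$multiplier, conversion_table$drug)
  } else {
    tab <- conversion_table
  }
  names(tab) <- tolower(names(tab))
  if (any(dose <= 0)) abort("dose must be positive")
  key <- tolower(drug)
  unknown <- setdiff(unique(key), names(tab))
  if (length(unknown)) {
    abort(sprintf("unknown drug(s): %s (known: %s)",
                  paste(unknown, collapse = ", "),
                  paste(names(tab), collapse = ", ")))
  }
  unname(dose * tab[key])
}

#' Derive outcome records from trial phenotypes
#'
#' Computes the reduction rate, responder label and scaled rate for every
#' case with both PANSS scores; controls and incomplete records get `NA`
#' outcomes.
#'
#' @param phenotypes data frame with `sample_id`, `panss_baseline`,
#'   `panss_endpoint` (controls may carry `NA`).
#' @return the input tibble with `reduction_rate`, `res_label` and
#'   `scaled_rate` columns added/overwritten.
#' @export
derive_outcomes <- function(phenotypes) {
  ph <- tibble::as_tibble(phenotypes)
  ok <- !is.na(ph$panss_baseline) & !is.na(ph$panss_endpoint)
  rate <- rep(NA_real_, nrow(ph))
  rate[ok] <- panss_reduction_rate(ph$panss_baseline[ok], ph$panss_endpoint[ok])
  ph$reduction_rate <- rate
  ph$res_label <- res_label(rate)
  ph$scaled_rate <- scale_reduction(rate)
  ph
}

validate_trial_phenotypes <- function(ph) {
  ph <- tibble::as_tibble(ph)
  scored <- !is.na(ph$panss_baseline)
  if (any(ph$panss_baseline[scored] < 30) ||
      any(ph$panss_endpoint[!is.na(ph$panss_endpoint)] < 30)) {
    abort("PANSS totals below the scale minimum of 30")
  }
  if (!is.null(ph$is_case) && any(!ph$is_case & scored)) {
    abort("controls must not carry PANSS scores")
  }
  both <- !is.na(ph$panss_baseline) & !is.na(ph$panss_endpoint)
  if (!is.null(ph$res_label) && any(xor(both, !is.na(ph$res_label)))) {
    abort("res_label must be present exactly when both PANSS scores are")
  }
  ph
}
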