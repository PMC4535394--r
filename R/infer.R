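#' Full inference report for an observed trial
#'
#' Runs the requested methods on one observed outcome and returns one tidy
#' row per method:
#'
#' * `"LR"` — likelihood-ratio ordering: mid-p value ([lr_pvalue()]),
#'   acceptance-region confidence interval ([lr_ci()]), UMVUE point estimate.
#' * `"KC"` — Koyama-Chen conditional method: p-value ([kc_pvalue()]),
#'   median-unbiased estimate and inverted confidence interval ([kc_ci()]).
#' * `"UMVUE"` — UMVUE point estimate with the UMVUE-ordering exact interval
#'   ([ci_umvue_order()]); no p-value is attached to this ordering.
#'
#' A Koyama-Chen failure (`x1 > rt`) is reported as a structured row with
#' `degenerate = "x1_exceeds_rt"` and missing values rather than aborting
#' the other methods. For a stage-1 stop the KC row carries the exact
#' stage-1 tail p-value and the binomial-tail interval.
#'
#' @param outcome A [trial_outcome()].
#' @param pi0 Null response rate; defaults to the design's `pi0`.
#' @param level Confidence level for all intervals.
#' @param methods Subset of `c("LR", "KC", "UMVUE")`.
#' @return A tibble with columns `method`, `estimate`, `p_value`, `lower`,
#'   `upper`, `level`, `pi0`, `pi_star`, `degenerate`.
#' @examples
#' d <- simon_design(3, 19, 8, 39, pi0 = 0.15)
#' infer(trial_outcome(d, 8, 4, n2_actual = 6), level = 0.90)
#' @export
infer <- function(outcome, pi0 = outcome$design$pi0, level = 0.90,
                  methods = c("LR", "KC", "UMVUE")) {
  stopifnot(inherits(outcome, "trial_outcome"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(pi0)) {
    rlang::abort("`pi0` is missing and the design carries no null rate.",
                 class = "simon2stage_error_config")
  }
  rows <- list()
  if ("LR" %in% methods) {
    ci <- lr_ci(outcome, level)
    rows$lr <- tibble::tibble(
      method = "LR", estimate = ci$estimate,
      p_value = lr_pvalue(outcome, pi0),
      lower = ci$lower, upper = ci$upper, level = level, pi0 = pi0,
      pi_star = NA_real_, degenerate = "none"
    )
  }
  if ("KC" %in% methods) {
    rows$kc <- kc_infer_row(outcome, pi0, level)
  }
  if ("UMVUE" %in% methods) {
    ci <- ci_umvue_order(outcome, level)
    rows$umvue <- tibble::tibble(
      method = "UMVUE-ordering", estimate = ci$estimate, p_value = NA_real_,
      lower = ci$lower, upper = ci$upper, level = level, pi0 = pi0,
      pi_star = NA_real_, degenerate = "none"
    )
  }
  dplyr::bind_rows(rows)
}

kc_infer_row <- function(outcome, pi0, level) {
  if (outcome$m == 1L) {
    ci <- kc_ci(outcome, level)
    return(tibble::tibble(
      method = "KC", estimate = ci$estimate,
      p_value = stage1_pvalue(outcome$x1, outcome$design$n1, pi0),
      lower = ci$lower, upper = ci$upper, level = level, pi0 = pi0,
      pi_star = NA_real_, degenerate = "none"
    ))
  }
  if (outcome$x1 > outcome$design$rt) {
    return(tibble::tibble(
      method = "KC", estimate = NA_real_, p_value = NA_real_,
      lower = NA_real_, upper = NA_real_, level = level, pi0 = pi0,
      pi_star = NA_real_, degenerate = "x1_exceeds_rt"
    ))
  }
  pv <- suppressWarnings(kc_pvalue(outcome, pi0))
  ci <- kc_ci(outcome, level)
  tibble::tibble(
    method = "KC", estimate = ci$estimate, p_value = pv$p_value,
    lower = ci$lower, upper = ci$upper, level = level, pi0 = pi0,
    pi_star = pv$pi_star, degenerate = pv$degenerate
  )
}
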