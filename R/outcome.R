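#' Record an observed sample path of a two-stage trial
#'
#' An outcome is identified by the stopping stage `M`, the cumulative number
#' of responders `S_M` and the realised sample size `N_M`. The trial stops at
#' stage 1 exactly when `x1 <= r1`; otherwise it proceeds to stage 2 with an
#' actual stage-2 size `n2_actual`, which may differ from the planned
#' `design$n2` when the study was extended or shortened for reasons unrelated
#' to the observed responses.
#'
#' @param design A [simon_design()].
#' @param x1 Stage-1 responders.
#' @param x2 Stage-2 responders; must be omitted when the trial stopped at
#'   stage 1 (`x1 <= r1`).
#' @param n2_actual Actual stage-2 sample size; defaults to the planned
#'   `design$n2` for a stage-2 outcome.
#'
#' @return An object of class `trial_outcome`: a list with elements `m`,
#'   `x1`, `x2`, `n2_actual`, `s` (cumulative responders), `n_total` and
#'   `design`.
#'
#' @examples
#' d <- simon_design(3, 19, 8, 39, pi0 = 0.15)
#' trial_outcome(d, x1 = 8, x2 = 4, n2_actual = 6)
#' @export
trial_outcome <- function(design, x1, x2 = NULL, n2_actual = NULL) {
  stopifnot(inherits(design, "simon_design"))
  if (!is_count(x1) || x1 < 0 || x1 > design$n1) {
    rlang::abort(sprintf("`x1` must be an integer in [0, n1 = %d].", design$n1),
                 class = "simon2stage_error_input")
  }
  x1 <- as.integer(x1)
  if (x1 <= design$r1) {
    if (!is.null(x2) || !is.null(n2_actual)) {
      rlang::abort(
        sprintf("x1 = %d <= r1 = %d stops the trial at stage 1; `x2` and `n2_actual` must be omitted.",
                x1, design$r1),
        class = "simon2stage_error_input"
      )
    }
    out <- list(m = 1L, x1 = x1, x2 = NULL, n2_actual = NULL,
                s = x1, n_total = design$n1, design = design)
  } else {
    if (is.null(n2_actual)) n2_actual <- design$n2
    if (!is_count(n2_actual) || n2_actual < 1) {
      rlang::abort("`n2_actual` must be a positive integer.",
                   class = "simon2stage_error_input")
    }
    n2_actual <- as.integer(n2_actual)
    if (is.null(x2)) {
      rlang::abort(
        sprintf("x1 = %d > r1 = %d continues to stage 2; `x2` is required.",
                x1, design$r1),
        class = "simon2stage_error_input"
      )
    }
    if (!is_count(x2) || x2 < 0 || x2 > n2_actual) {
      rlang::abort(sprintf("`x2` must be an integer in [0, n2_actual = %d].", n2_actual),
                   class = "simon2stage_error_input")
    }
    x2 <- as.integer(x2)
    out <- list(m = 2L, x1 = x1, x2 = x2, n2_actual = n2_actual,
                s = x1 + x2, n_total = design$n1 + n2_actual, design = design)
  }
  structure(out, class = "trial_outcome")
}

#' @export
print.trial_outcome <- function(x, ...) {
  if (x$m == 1L) {
    cat(sprintf("Trial outcome: stopped at stage 1 with %d/%d responders\n",
                x$x1, x$n_total))
  } else {
    cat(sprintf(
      "Trial outcome: stage 2 with x1 = %d/%d, x2 = %d/%d (S = %d/%d)\n",
      x$x1, x$design$n1, x$x2, x$n2_actual, x$s, x$n_total))
    if (x$n2_actual != x$design$n2) {
      cat(sprintf("  actual stage-2 size %d deviates from planned %d\n",
                  x$n2_actual, x$design$n2))
    }
  }
  invisible(x)
}

#' @rdname tidy.simon_design
#' @method tidy trial_outcome
#' @export
tidy.trial_outcome <- function(x, ...) {
  tibble::tibble(
    m = x$m, x1 = x$x1,
    x2 = if (x$m == 2L) x$x2 else NA_integer_,
    n2_actual = if (x$m == 2L) x$n2_actual else NA_integer_,
    s = x$s, n_total = x$n_total
  )
}
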