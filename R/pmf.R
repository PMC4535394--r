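# Exact distribution of (M, S_M) under a Simon two-stage design.
#
# The pmf of the stopping stage M and cumulative responders S_M at response
# rate pi is
#   f(1, s | pi) = C(n1, s) pi^s (1-pi)^(n1-s),                 0 <= s <= r1
#   f(2, s | pi) = sum_{x1} C(n1, x1) C(n2, s-x1) pi^s (1-pi)^(n1+n2-s),
# with x1 running from max(r1+1, s-n2) to min(s, n1), and the actual stage-2
# size substituted for n2 when the study deviated from plan. Coefficients are
# accumulated in log space so large designs do not underflow.

# support table: one row per path, with the log of the pi-free coefficient
support_paths <- function(design, n2_actual = design$n2) {
  r1 <- design$r1; n1 <- design$n1
  s1 <- 0:r1
  s2 <- (r1 + 1):(n1 + n2_actual)
  log_coef2 <- vapply(s2, function(s) {
    x1 <- max(r1 + 1, s - n2_actual):min(s, n1)
    logsumexp(lchoose(n1, x1) + lchoose(n2_actual, s - x1))
  }, numeric(1))
  tibble::tibble(
    m = c(rep(1L, length(s1)), rep(2L, length(s2))),
    s = c(s1, s2),
    n_total = c(rep(n1, length(s1)), rep(n1 + n2_actual, length(s2))),
    log_coef = c(lchoose(n1, s1), log_coef2)
  )
}

# probability vector over the rows of a support table
support_probs <- function(support, pi) {
  exp(support$log_coef + log_bern_kernel(support$s, support$n_total, pi))
}

#' Exact probability of a sample path
#'
#' Probability mass function of the stopping stage and cumulative responder
#' count `(m, s)` at response rate `pi`, with the actual stage-2 sample size
#' in place of the planned one. Paths outside the support of the design raise
#' an error naming the violated boundary, which catches caller bugs; use
#' [path_distribution()] to enumerate the full support.
#'
#' @param design A [simon_design()].
#' @param m Stopping stage, 1 or 2.
#' @param s Cumulative number of responders at the stopping stage.
#' @param pi Response rate in `[0, 1]`.
#' @param n2_actual Actual stage-2 sample size (defaults to the planned
#'   `design$n2`).
#' @return The probability `f(m, s | pi)`.
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' pmf_path(d, m = 1, s = 2, pi = 0.15)
#' @export
pmf_path <- function(design, m, s, pi, n2_actual = design$n2) {
  stopifnot(inherits(design, "simon_design"))
  check_prob(pi, "pi")
  if (!is_count(m) || !(m %in% c(1, 2))) {
    rlang::abort("`m` must be 1 or 2.", class = "simon2stage_error_input")
  }
  if (!is_count(s)) {
    rlang::abort("`s` must be a single integer.", class = "simon2stage_error_input")
  }
  if (m == 1) {
    if (s < 0 || s > design$r1) {
      rlang::abort(
        sprintf("out of support: m=1 requires 0 <= s <= r1 = %d, got s = %d.",
                design$r1, s),
        class = "simon2stage_error_support"
      )
    }
    return(stats::dbinom(s, design$n1, pi))
  }
  smax <- design$n1 + n2_actual
  if (s <= design$r1 || s > smax) {
    rlang::abort(
      sprintf("out of support: m=2 requires r1 + 1 = %d <= s <= n1 + n2_actual = %d, got s = %d.",
              design$r1 + 1L, smax, s),
      class = "simon2stage_error_support"
    )
  }
  x1 <- max(design$r1 + 1, s - n2_actual):min(s, design$n1)
  lc <- logsumexp(lchoose(design$n1, x1) + lchoose(n2_actual, s - x1))
  exp(lc + log_bern_kernel(s, design$n1 + n2_actual, pi))
}

#' Enumerate the full sample-path distribution
#'
#' Materialises the support of `(M, S_M)` for a design at an actual stage-2
#' sample size, with the exact probability of each path at rate `pi`. The
#' support is `{(1, s): 0 <= s <= r1}` together with
#' `{(2, s): r1 + 1 <= s <= n1 + n2_actual}`.
#'
#' @inheritParams pmf_path
#' @return A tibble with columns `m`, `s`, `n_total`, `prob`, carrying the
#'   evaluation rate and design as attributes `pi`, `n2_actual`, `design`.
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' path_distribution(d, pi = 0.15, n2_actual = 6)
#' @export
path_distribution <- function(design, pi, n2_actual = design$n2) {
  stopifnot(inherits(design, "simon_design"))
  check_prob(pi, "pi")
  if (!is_count(n2_actual) || n2_actual < 1) {
    rlang::abort("`n2_actual` must be a positive integer.",
                 class = "simon2stage_error_input")
  }
  supp <- support_paths(design, n2_actual)
  out <- dplyr::mutate(dplyr::select(supp, -"log_coef"),
                       prob = support_probs(supp, pi))
  attr(out, "pi") <- pi
  attr(out, "n2_actual") <- as.integer(n2_actual)
  attr(out, "design") <- design
  out
}

#' Rejection decision for an observed outcome
#'
#' For a stage-1 stop the null is never rejected. For a stage-2 outcome at
#' the planned sample size the rule is the design's threshold rule
#' `s > rt`. When the actual stage-2 size deviates from plan the planned
#' conditional rejection rate `A(x1, n2, pi0)` is kept as the conditional
#' critical value: reject when `P_pi0[X2 >= x2 | n2_actual] <= A(x1, n2, pi0)`.
#' At `n2_actual = n2` the two rules coincide.
#'
#' @param design A [simon_design()] carrying `pi0`.
#' @param outcome A [trial_outcome()].
#' @return `TRUE` if the null response rate is rejected.
#' @examples
#' d <- simon_design(3, 19, 8, 39, pi0 = 0.15)
#' reject_h0(d, trial_outcome(d, x1 = 8, x2 = 4, n2_actual = 6))
#' @export
reject_h0 <- function(design, outcome) {
  stopifnot(inherits(design, "simon_design"), inherits(outcome, "trial_outcome"))
  if (outcome$m == 1L) return(FALSE)
  if (outcome$n2_actual == design$n2) return(outcome$s > design$rt)
  if (is.null(design$pi0)) {
    rlang::abort("the deviated-n2 rejection rule needs `pi0` on the design.",
                 class = "simon2stage_error_config")
  }
  tail_obs <- stats::pbinom(outcome$x2 - 1, outcome$n2_actual, design$pi0,
                            lower.tail = FALSE)
  a <- conditional_rejection_rate(design, outcome$x1, design$pi0)
  tail_obs <= a
}

#' Exact operating characteristics of a planned design
#'
#' The exact probability of rejecting the null at response rate `pi` under
#' the planned design,
#' `sum_x P_pi[X1 = x | n1] P_pi[X2 > rt - x | n2]` over `x` from `r1 + 1` to
#' `n1`, together with the probability of early termination
#' `PET = P(X1 <= r1)` and the expected total sample size
#' `n1 + (1 - PET) n2`.
#'
#' @inheritParams pmf_path
#' @return A one-row tibble with columns `pi`, `reject_prob`, `pet`,
#'   `expected_n`.
#' @examples
#' d <- simon_design(3, 17, 10, 37)
#' operating_characteristics(d, pi = 0.2)
#' @export
operating_characteristics <- function(design, pi) {
  stopifnot(inherits(design, "simon_design"))
  check_prob(pi, "pi")
  x <- (design$r1 + 1):design$n1
  reject <- sum(stats::dbinom(x, design$n1, pi) *
                  stats::pbinom(design$rt - x, design$n2, pi, lower.tail = FALSE))
  pet <- stats::pbinom(design$r1, design$n1, pi)
  tibble::tibble(pi = pi, reject_prob = reject, pet = pet,
                 expected_n = design$n1 + (1 - pet) * design$n2)
}
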