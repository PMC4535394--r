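# The Koyama-Chen conditional method.
#
# Given x1 stage-1 responders, the planned conditional rejection rate is
#   A(x, n2, pi) = P_pi[X2 > rt - x | n2],
# the probability of final rejection under the planned stage-2 size. With a
# deviated actual size n2*, the observed stage-2 tail P_pi0[X2 >= x2 | n2*]
# is mapped back onto the planned design by solving
#   A(x1, n2, pi*) = P_pi0[X2 >= x2 | n2*]
# for pi*, and the p-value is sum_x P_pi0[X1 = x | n1] A(x, n2, pi*). The
# same two steps with a generic rate pi in both roles define a monotone
# p-value function g(pi), inverted for a median-unbiased estimate
# (g = 1/2) and confidence limits (g = alpha/2 and 1 - alpha/2).
#
# Two documented failure modes: when x1 > rt, A(x1, n2, .) is identically 1
# and pi* does not exist; when x2 = 0 the observed tail is identically 1, so
# pi* = 1 and the p-value collapses to P_pi0[X1 > r1], independent of both
# x1 and n2*.

#' Conditional rejection rate given the stage-1 responder count
#'
#' `A(x, n2, pi) = P_pi[X2 > rt - x | n2]`, the probability that a trial
#' with `x > r1` stage-1 responders goes on to reject the null under the
#' planned stage-2 size. Identically 1 when `x > rt`.
#'
#' @param design A [simon_design()].
#' @param x Stage-1 responder count with `r1 < x <= n1`.
#' @param pi Response rate; vectorised.
#' @return A probability (vector along `pi`).
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' conditional_rejection_rate(d, x = 8, pi = 0.15)
#' @export
conditional_rejection_rate <- function(design, x, pi) {
  stopifnot(inherits(design, "simon_design"))
  if (!is_count(x) || x <= design$r1 || x > design$n1) {
    rlang::abort(
      sprintf("`x` must satisfy r1 = %d < x <= n1 = %d (no stage 2 otherwise).",
              design$r1, design$n1),
      class = "simon2stage_error_input"
    )
  }
  stopifnot(all(pi >= 0), all(pi <= 1))
  if (x > design$rt) return(rep(1, length(pi)))
  stats::pbinom(design$rt - x, design$n2, pi, lower.tail = FALSE)
}

#' Exact stage-1 p-value
#'
#' For a trial stopped at stage 1, the p-value is the upper binomial tail
#' `P_pi0[X1 >= x1 | n1]`, including the observed count.
#'
#' @param x1 Observed stage-1 responders.
#' @param n1 Stage-1 sample size.
#' @param pi0 Null response rate.
#' @return A probability.
#' @examples
#' stage1_pvalue(2, 19, 0.15)
#' @export
stage1_pvalue <- function(x1, n1, pi0) {
  stopifnot(is_count(x1), x1 >= 0, x1 <= n1)
  check_prob(pi0, "pi0")
  stats::pbinom(x1 - 1, n1, pi0, lower.tail = FALSE)
}

kc_abort_undefined <- function(outcome) {
  rlang::abort(
    sprintf("Koyama-Chen method undefined: x1 = %d exceeds rt = %d, so A(x1, n2, .) is identically 1 and pi* cannot be solved.",
            outcome$x1, outcome$design$rt),
    class = "simon2stage_error_kc_undefined"
  )
}

# upper binomial tail P[X >= k | n, pi] as a function of pi is the beta cdf
# pbeta(pi, k, n - k + 1); its inversion in pi is therefore exact via qbeta
binom_uppertail_in_pi <- function(pi, k, n) {
  if (k <= 0) rep(1, length(pi)) else stats::pbeta(pi, k, n - k + 1)
}

# solve A(x1, n2, pi*) = target for pi*; requires x1 <= rt
solve_pi_star <- function(design, x1, target) {
  k <- design$rt - x1 + 1 # stage-2 responders needed to reject under plan
  stats::qbeta(target, k, design$n2 - k + 1)
}

kc_steps <- function(outcome, pi) {
  d <- outcome$design
  if (outcome$x2 == 0) {
    # observed tail is identically 1, so pi* = 1, every A(x, n2, 1) = 1 and
    # the sum collapses to the exact stage-1 continuation probability
    return(list(pi_star = 1,
                p = stats::pbinom(d$r1, d$n1, pi, lower.tail = FALSE)))
  }
  target <- binom_uppertail_in_pi(pi, outcome$x2, outcome$n2_actual)
  pi_star <- solve_pi_star(d, outcome$x1, target)
  x <- (d$r1 + 1):d$n1
  a <- rep(1, length(x))
  below <- x <= d$rt
  k <- d$rt - x[below] + 1
  a[below] <- stats::pbeta(pi_star, k, d$n2 - k + 1)
  list(pi_star = pi_star, p = sum(stats::dbinom(x, d$n1, pi) * a))
}

#' Koyama-Chen conditional p-value
#'
#' Implements the two-step construction for a stage-2 outcome with actual
#' stage-2 size `n2_actual`: solve `A(x1, n2, pi*) = P_pi0[X2 >= x2 |
#' n2_actual]` for `pi*` (exactly, through the beta-quantile representation
#' of the binomial tail), then sum `P_pi0[X1 = x | n1] A(x, n2, pi*)` over
#' `x` from `r1 + 1` to `n1`.
#'
#' When `x1 > rt` the method is undefined (error of class
#' `simon2stage_error_kc_undefined`): `A(x1, n2, .)` is identically 1 and no
#' `pi*` exists. When `x2 = 0` the solution is `pi* = 1` and the p-value
#' degenerates to `P_pi0[X1 > r1]`, independent of `x1` and `n2_actual`; the
#' result is returned with `degenerate = "x2_zero"` and a warning. For a
#' stage-1 stop use [stage1_pvalue()].
#'
#' @param outcome A [trial_outcome()] with `m = 2`.
#' @param pi0 Null response rate; defaults to the design's `pi0`.
#' @return A one-row tibble with columns `p_value`, `pi_star`, `pi0`,
#'   `degenerate` (`"none"` or `"x2_zero"`).
#' @examples
#' d <- simon_design(3, 19, 8, 39, pi0 = 0.15)
#' kc_pvalue(trial_outcome(d, 8, 4, n2_actual = 6))
#' @export
kc_pvalue <- function(outcome, pi0 = outcome$design$pi0) {
  stopifnot(inherits(outcome, "trial_outcome"))
  if (outcome$m == 1L) {
    rlang::abort("outcome stopped at stage 1; use stage1_pvalue().",
                 class = "simon2stage_error_input")
  }
  if (is.null(pi0)) {
    rlang::abort("`pi0` is missing and the design carries no null rate.",
                 class = "simon2stage_error_config")
  }
  if (!is_prob(pi0) || pi0 <= 0 || pi0 >= 1) {
    rlang::abort("`pi0` must lie strictly inside (0, 1).",
                 class = "simon2stage_error_input")
  }
  if (outcome$x1 > outcome$design$rt) kc_abort_undefined(outcome)
  st <- kc_steps(outcome, pi0)
  degenerate <- if (outcome$x2 == 0) "x2_zero" else "none"
  if (degenerate == "x2_zero") {
    rlang::warn("x2 = 0: the Koyama-Chen p-value equals P_pi0[X1 > r1], independent of x1 and n2_actual.",
                class = "simon2stage_warning_kc_degenerate")
  }
  tibble::tibble(p_value = st$p, pi_star = st$pi_star, pi0 = pi0,
                 degenerate = degenerate)
}

#' Koyama-Chen p-value function
#'
#' The two-step p-value with a generic rate `pi` in both roles (the observed
#' stage-2 tail and the stage-1 weights). `g(pi)` is nondecreasing in `pi`
#' and runs from 0 to 1, which makes it invertible for the median-unbiased
#' estimate and confidence limits. Monotonicity is asserted on a coarse grid
#' before any inversion.
#'
#' @inheritParams kc_pvalue
#' @param pi Response rate(s) in `(0, 1)`; vectorised.
#' @return `g(pi)`, a probability vector along `pi`.
#' @export
kc_pvalue_function <- function(outcome, pi) {
  stopifnot(inherits(outcome, "trial_outcome"))
  if (outcome$m == 1L) {
    rlang::abort("outcome stopped at stage 1; use stage1_pvalue().",
                 class = "simon2stage_error_input")
  }
  if (outcome$x1 > outcome$design$rt) kc_abort_undefined(outcome)
  stopifnot(all(pi > 0), all(pi < 1))
  vapply(pi, function(p) kc_steps(outcome, p)$p, numeric(1))
}

check_g_monotone <- function(g_vals) {
  if (any(diff(g_vals) < -1e-8)) {
    rlang::abort("Koyama-Chen p-value function is not monotone on the check grid; refusing to invert.",
                 class = "simon2stage_error_internal")
  }
}

kc_invert <- function(outcome, targets) {
  g <- function(p) kc_pvalue_function(outcome, p)
  check_g_monotone(g(seq(0.01, 0.99, length.out = 11)))
  vapply(targets, function(t) {
    lo <- g(1e-9); hi <- g(1 - 1e-9)
    if (t <= lo) return(0)
    if (t >= hi) return(1)
    stats::uniroot(function(p) g(p) - t, c(1e-9, 1 - 1e-9), tol = 1e-9)$root
  }, numeric(1))
}

#' Koyama-Chen median-unbiased estimate
#'
#' The rate at which the Koyama-Chen p-value function equals one half,
#' `g(pi) = 0.5`. For a stage-1 stop the estimate falls back to `x1 / n1`.
#'
#' @inheritParams kc_pvalue
#' @return A single rate.
#' @examples
#' d <- simon_design(3, 19, 8, 39, pi0 = 0.15)
#' kc_estimate(trial_outcome(d, 8, 4, n2_actual = 6))
#' @export
kc_estimate <- function(outcome) {
  stopifnot(inherits(outcome, "trial_outcome"))
  if (outcome$m == 1L) return(outcome$x1 / outcome$design$n1)
  kc_invert(outcome, 0.5)
}

#' Koyama-Chen confidence interval
#'
#' Inverts the p-value function at the two tail levels: the lower limit
#' solves `g(pi_L) = (1 - level) / 2` and the upper limit solves
#' `g(pi_U) = 1 - (1 - level) / 2`. For a stage-1 stop the same convention
#' is applied to the exact stage-1 tail `P_pi[X1 >= x1]` (so both methods
#' agree on first-stage trials); with `x1 = 0` that tail is identically 1
#' and the degenerate interval `(0, 1)` is returned.
#'
#' @inheritParams kc_pvalue
#' @param level Confidence level in `(0, 1)`.
#' @return A one-row tibble with columns `method`, `estimate`, `lower`,
#'   `upper`, `level`.
#' @examples
#' d <- simon_design(3, 19, 8, 39, pi0 = 0.15)
#' kc_ci(trial_outcome(d, 8, 4, n2_actual = 6), level = 0.90)
#' @export
kc_ci <- function(outcome, level = 0.90) {
  stopifnot(inherits(outcome, "trial_outcome"))
  check_prob(level, "level", open = TRUE)
  a2 <- (1 - level) / 2
  if (outcome$m == 1L) {
    x1 <- outcome$x1; n1 <- outcome$design$n1
    if (x1 == 0) {
      lims <- c(0, 1)
    } else {
      lims <- stats::qbeta(c(a2, 1 - a2), x1, n1 - x1 + 1)
    }
    est <- x1 / n1
  } else {
    lims <- kc_invert(outcome, c(a2, 1 - a2))
    est <- kc_estimate(outcome)
  }
  tibble::tibble(method = "KC", estimate = est,
                 lower = lims[1], upper = lims[2], level = level)
}
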