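# Point estimation of the response rate after sequential stopping.
#
# (M, S_M) is complete and sufficient for pi, so the Rao-Blackwellisation of
# the always-unbiased stage-1 proportion X1/n1 gives the UMVUE
#   m = 1:  x1 / n1
#   m = 2:  sum_x1 C(n1-1, x1-1) C(n2, s-x1)  /  sum_x1 C(n1, x1) C(n2, s-x1)
# with x1 from max(r1+1, s-n2) to min(s, n1), and the actual stage-2 size in
# place of n2 when the study deviated. The MLE S_M / N_M ignores the stopping
# rule and is biased.

#' Maximum likelihood estimate of the response rate
#'
#' The MLE is the raw proportion `S_M / N_M`. It ignores the sequential
#' stopping rule and is biased under the two-stage sampling scheme; see
#' [estimate_umvue()] and [estimator_bias()].
#'
#' @param outcome A [trial_outcome()].
#' @return A single rate.
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' estimate_mle(trial_outcome(d, 8, 4, n2_actual = 6))
#' @export
estimate_mle <- function(outcome) {
  stopifnot(inherits(outcome, "trial_outcome"))
  outcome$s / outcome$n_total
}

# UMVUE for every stage-2 support point at once; exact integer sums in
# double precision, falling back to a log-sum-exp ratio once the
# coefficient sums would leave the exactly-representable integer range.
umvue_stage2 <- function(n1, r1, n2, s) {
  vapply(s, function(sm) {
    x1 <- max(r1 + 1, sm - n2):min(sm, n1)
    num <- sum(choose(n1 - 1, x1 - 1) * choose(n2, sm - x1))
    den <- sum(choose(n1, x1) * choose(n2, sm - x1))
    if (is.finite(den) && den < 2^53) {
      num / den
    } else {
      exp(logsumexp(lchoose(n1 - 1, x1 - 1) + lchoose(n2, sm - x1)) -
            logsumexp(lchoose(n1, x1) + lchoose(n2, sm - x1)))
    }
  }, numeric(1))
}

# UMVUE for every row of a support table
umvue_support <- function(design, support, n2_actual) {
  ifelse(support$m == 1L,
         support$s / design$n1,
         umvue_stage2(design$n1, design$r1, n2_actual, support$s))
}

#' Uniformly minimum variance unbiased estimate of the response rate
#'
#' Conditional on a non-informatively realised stage-2 sample size, the
#' UMVUE is the ratio of binomial-coefficient sums given in the package
#' vignette, evaluated with the actual stage-2 size in place of the planned
#' one; at a stage-1 stop it reduces to `x1 / n1`. The ratio is computed in
#' exact integer arithmetic whenever the sums are exactly representable.
#'
#' @inheritParams estimate_mle
#' @return A single rate.
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' estimate_umvue(trial_outcome(d, 8, 4, n2_actual = 6))
#' @export
estimate_umvue <- function(outcome) {
  stopifnot(inherits(outcome, "trial_outcome"))
  d <- outcome$design
  if (outcome$m == 1L) return(outcome$x1 / d$n1)
  umvue_stage2(d$n1, d$r1, outcome$n2_actual, outcome$s)
}

# mass of the UMVUE-ordering event {umvue(path) >= umvue_obs} at rate pi;
# ties are included, as the ordering event is written with >=
umvue_order_mass <- function(support, umvue_all, umvue_obs, pi) {
  in_event <- umvue_all >= umvue_obs - 1e-12
  sum(support_probs(support, pi)[in_event])
}

#' Exact confidence interval from the UMVUE ordering of the sample space
#'
#' Orders the support of `(M, S_M)` by the UMVUE and inverts the exact tail
#' equations: the lower limit solves
#' `P(umvue(M, S_M) >= umvue_obs | pi) = (1 - level) / 2` and the upper limit
#' solves the same probability equal to `1 - (1 - level) / 2`. The event
#' includes ties. When the observed path attains the minimum of the ordering
#' the lower limit is 0; when it attains the maximum the upper limit is 1.
#' The ordering probability is monotone in `pi`, so each endpoint is a
#' unique root, found by bisection to `1e-9`.
#'
#' @param outcome A [trial_outcome()].
#' @param level Confidence level in `(0, 1)`, e.g. `0.90`.
#' @return A one-row tibble with columns `method`, `estimate` (the UMVUE),
#'   `lower`, `upper`, `level`.
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' ci_umvue_order(trial_outcome(d, 8, 4, n2_actual = 6), level = 0.90)
#' @export
ci_umvue_order <- function(outcome, level = 0.90) {
  stopifnot(inherits(outcome, "trial_outcome"))
  check_prob(level, "level", open = TRUE)
  d <- outcome$design
  n2a <- if (outcome$m == 2L) outcome$n2_actual else d$n2
  supp <- support_paths(d, n2a)
  uv <- umvue_support(d, supp, n2a)
  obs <- estimate_umvue(outcome)
  a2 <- (1 - level) / 2
  mass <- function(pi) umvue_order_mass(supp, uv, obs, pi)

  is_min <- obs <= min(uv) + 1e-12
  is_max <- obs >= max(uv) - 1e-12
  lower <- if (is_min) 0 else {
    stats::uniroot(function(p) mass(p) - a2, c(0, 1), tol = 1e-9)$root
  }
  # a minimal observed path puts the whole support in the ordering event
  # (mass is identically 1), so the upper equation has no root either
  upper <- if (is_max || is_min) 1 else {
    stats::uniroot(function(p) mass(p) - (1 - a2), c(0, 1), tol = 1e-9)$root
  }
  tibble::tibble(method = "UMVUE-ordering", estimate = obs,
                 lower = min(max(lower, 0), 1), upper = min(max(upper, 0), 1),
                 level = level)
}

#' Exact bias of an estimator by enumeration
#'
#' Enumerates the full support of `(M, S_M)` at a fixed actual stage-2 size
#' and returns the signed bias `sum f(m, s | pi) (estimate(m, s) - pi)`. The
#' UMVUE has exact bias 0 for every fixed `n2_actual`; the MLE does not.
#'
#' @inheritParams pmf_path
#' @param estimator `"MLE"` or `"UMVUE"`.
#' @return The signed bias at `pi`.
#' @examples
#' d <- simon_design(3, 17, 10, 37)
#' estimator_bias(d, n2_actual = 20, pi = 0.3, estimator = "MLE")
#' @export
estimator_bias <- function(design, n2_actual = design$n2, pi,
                           estimator = c("MLE", "UMVUE")) {
  stopifnot(inherits(design, "simon_design"))
  estimator <- match.arg(estimator)
  check_prob(pi, "pi")
  supp <- support_paths(design, n2_actual)
  est <- if (estimator == "MLE") {
    supp$s / supp$n_total
  } else {
    umvue_support(design, supp, n2_actual)
  }
  sum(support_probs(supp, pi) * (est - pi))
}
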