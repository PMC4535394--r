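# Likelihood-ratio ordering of the two-stage sample space.
#
# Each path (m, s) with realised total n is scored by the conditional
# likelihood ratio
#   T(m, s, pi0) = pihat^s (1 - pihat)^(n - s) / (pi0^s (1 - pi0)^(n - s)),
# pihat = s / n, compared in log space. Paths with larger T are more extreme
# against H0: pi = pi0, and the mid-p value adds half the probability of the
# observed path to the mass of strictly more extreme ones. Inverting the
# mid-p acceptance region {pi0 : p(pi0) >= 1 - level} gives a confidence
# interval that exists for every path, including the two cases where the
# Koyama-Chen construction breaks down (x1 > rt, and x2 = 0).

# relative tie tolerance for log-T comparisons
LOGT_TOL <- 1e-12

logT_values <- function(s, n, pi0) {
  pihat <- s / n
  log_bern_kernel(s, n, pihat) - log_bern_kernel(s, n, pi0)
}

#' Conditional likelihood ratio of a sample path
#'
#' The likelihood ratio of `H1: pi = s / n_total` against `H0: pi = pi0` for
#' a path with `s` responders among `n_total` patients, with the convention
#' `0^0 = 1` at the boundaries. Always at least 1. Computation is done in
#' log space; set `log = TRUE` to retrieve the log ratio (the ratio itself
#' can overflow for extreme paths of large designs).
#'
#' @param s Number of responders, `0 <= s <= n_total`. Vectorised.
#' @param n_total Realised total sample size.
#' @param pi0 Null response rate, strictly inside `(0, 1)`.
#' @param log Return the log likelihood ratio instead of the ratio.
#' @return The likelihood ratio `T` (or its log).
#' @examples
#' lr_statistic(12, 25, pi0 = 0.15)
#' @export
lr_statistic <- function(s, n_total, pi0, log = FALSE) {
  if (!is_prob(pi0) || pi0 <= 0 || pi0 >= 1) {
    rlang::abort("`pi0` must lie strictly inside (0, 1).",
                 class = "simon2stage_error_input")
  }
  stopifnot(all(s >= 0), all(s <= n_total))
  lt <- logT_values(s, n_total, pi0)
  if (log) lt else exp(lt)
}

# mid-p for one observed row of a support table, literal tie handling:
# strictly larger T counts fully, the observed path counts half, other paths
# exactly tied with the observed one contribute nothing
lr_midp_at <- function(support, i_obs, pi0, tie_mode = "literal") {
  lt <- logT_values(support$s, support$n_total, pi0)
  f <- support_probs(support, pi0)
  tol <- LOGT_TOL * pmax(1, abs(lt[i_obs]))
  strict <- lt > lt[i_obs] + tol
  p <- sum(f[strict])
  if (tie_mode == "literal") {
    p + 0.5 * f[i_obs]
  } else {
    tied <- !strict & lt >= lt[i_obs] - tol
    p + 0.5 * sum(f[tied])
  }
}

# mid-p for every support row at every pi0 in a grid; returns a
# length(grid) x nrow(support) matrix (literal tie handling)
lr_midp_grid <- function(support, pi0_grid) {
  P <- matrix(NA_real_, length(pi0_grid), nrow(support))
  for (j in seq_along(pi0_grid)) {
    lt <- logT_values(support$s, support$n_total, pi0_grid[j])
    f <- support_probs(support, pi0_grid[j])
    o <- order(lt)
    mass_from <- rev(cumsum(rev(f[o]))) # mass of ranks >= k in ascending order
    tol <- LOGT_TOL * pmax(1, abs(lt))
    k <- findInterval(lt + tol, lt[o]) # paths with T <= T_i + tol
    strict <- ifelse(k < length(lt), mass_from[k + 1], 0)
    P[j, ] <- strict + 0.5 * f
  }
  P
}

find_obs_row <- function(support, outcome) {
  i <- which(support$m == outcome$m & support$s == outcome$s)
  stopifnot(length(i) == 1)
  i
}

outcome_support <- function(outcome) {
  d <- outcome$design
  support_paths(d, if (outcome$m == 2L) outcome$n2_actual else d$n2)
}

#' Mid-p value from the likelihood-ratio ordering
#'
#' Enumerates the support of `(M, S_M)` at the actual stage-2 sample size,
#' orders it by the conditional likelihood ratio at `pi0`, and returns the
#' mid-p value: the null mass of strictly more extreme paths plus half the
#' mass of the observed path. Defined for every outcome, including stage-1
#' stops (scored against the planned stage-2 size), `x1 > rt` and `x2 = 0`.
#'
#' @param outcome A [trial_outcome()].
#' @param pi0 Null response rate; defaults to the design's `pi0`.
#' @param tie_mode `"literal"` (default) adds half mass only for the observed
#'   path and drops paths whose likelihood ratio is exactly tied with it, as
#'   the mid-p definition is written; `"symmetric"` instead adds half the
#'   total tied mass. Ties are compared with relative tolerance `1e-12` on
#'   the log scale.
#' @param detail Return a one-row tibble with diagnostics instead of a bare
#'   number.
#' @return The mid-p value in `(0, 1)`, or with `detail = TRUE` a tibble with
#'   columns `p_value`, `pi0`, `log_t_obs`, `n_strict` (count of strictly
#'   more extreme paths) and `tie_mode`.
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' lr_pvalue(trial_outcome(d, 8, 4, n2_actual = 6), pi0 = 0.15)
#' @export
lr_pvalue <- function(outcome, pi0 = outcome$design$pi0,
                      tie_mode = c("literal", "symmetric"), detail = FALSE) {
  stopifnot(inherits(outcome, "trial_outcome"))
  tie_mode <- match.arg(tie_mode)
  if (is.null(pi0)) {
    rlang::abort("`pi0` is missing and the design carries no null rate.",
                 class = "simon2stage_error_config")
  }
  if (!is_prob(pi0) || pi0 <= 0 || pi0 >= 1) {
    rlang::abort("`pi0` must lie strictly inside (0, 1).",
                 class = "simon2stage_error_input")
  }
  supp <- outcome_support(outcome)
  i <- find_obs_row(supp, outcome)
  p <- lr_midp_at(supp, i, pi0, tie_mode)
  if (!detail) return(p)
  lt <- logT_values(supp$s, supp$n_total, pi0)
  tol <- LOGT_TOL * pmax(1, abs(lt[i]))
  tibble::tibble(p_value = p, pi0 = pi0, log_t_obs = lt[i],
                 n_strict = sum(lt > lt[i] + tol), tie_mode = tie_mode)
}

#' Likelihood-ratio test decision
#'
#' Rejects `H0: pi = pi0` when the mid-p value is at most `alpha` (a p-value
#' exactly equal to `alpha` rejects).
#'
#' @inheritParams lr_pvalue
#' @param alpha Rejection level.
#' @return `TRUE` or `FALSE`.
#' @export
lr_reject <- function(outcome, pi0 = outcome$design$pi0, alpha = 0.05) {
  lr_pvalue(outcome, pi0) <= alpha
}

# acceptance-region boundary refinement: bisect between a pi0 known to be
# inside {p >= alpha} and one known to be outside, to tolerance 1e-9
refine_boundary <- function(p_fun, inside, outside, alpha) {
  for (k in 1:52) {
    mid <- (inside + outside) / 2
    if (p_fun(mid) >= alpha) inside <- mid else outside <- mid
    if (abs(inside - outside) < 1e-9) break
  }
  inside
}

# clip pi0 away from {0, 1}, where the likelihood ratio is undefined
GRID_EPS <- 1e-10

lr_ci_from_support <- function(support, i_obs, level, grid_n = 2001,
                               tie_mode = "literal") {
  alpha <- 1 - level
  grid <- seq(GRID_EPS, 1 - GRID_EPS, length.out = grid_n)
  p_fun <- function(p0) lr_midp_at(support, i_obs, p0, tie_mode)
  pv <- lr_midp_grid(support, grid)[, i_obs]
  if (tie_mode != "literal") pv <- vapply(grid, p_fun, numeric(1))
  acc <- which(pv >= alpha)
  if (length(acc) == 0) {
    rlang::abort("empty acceptance region; this indicates a bug.",
                 class = "simon2stage_error_internal")
  }
  lo_i <- min(acc); hi_i <- max(acc)
  lower <- if (lo_i == 1) 0 else {
    refine_boundary(p_fun, grid[lo_i], grid[lo_i - 1], alpha)
  }
  upper <- if (hi_i == grid_n) 1 else {
    refine_boundary(p_fun, grid[hi_i], grid[hi_i + 1], alpha)
  }
  contiguous <- all(diff(acc) == 1)
  list(lower = lower, upper = upper, contiguous = contiguous)
}

#' Confidence interval by inverting the likelihood-ratio mid-p value
#'
#' The interval is the acceptance region `{pi0 : p(pi0) >= 1 - level}` of
#' the mid-p value of [lr_pvalue()]. Boundaries are located on a uniform
#' grid of `grid_n` null rates and refined by bisection to `1e-9`. The
#' region is an interval for all but rare configurations; if it is not, its
#' convex hull is returned and a warning is attached (`contiguous = FALSE`).
#'
#' @inheritParams lr_pvalue
#' @param level Confidence level in `(0, 1)`.
#' @param grid_n Number of grid points used to bracket the boundaries.
#' @return A one-row tibble with columns `method`, `estimate` (the UMVUE),
#'   `lower`, `upper`, `level`, `contiguous`.
#' @examples
#' d <- simon_design(3, 19, 8, 39)
#' lr_ci(trial_outcome(d, 8, 4, n2_actual = 6), level = 0.90)
#' @export
lr_ci <- function(outcome, level = 0.90, grid_n = 2001,
                  tie_mode = c("literal", "symmetric")) {
  stopifnot(inherits(outcome, "trial_outcome"))
  check_prob(level, "level", open = TRUE)
  tie_mode <- match.arg(tie_mode)
  supp <- outcome_support(outcome)
  i <- find_obs_row(supp, outcome)
  res <- lr_ci_from_support(supp, i, level, grid_n, tie_mode)
  if (!res$contiguous) {
    rlang::warn("likelihood-ratio acceptance region is not contiguous; returning its convex hull.",
                class = "simon2stage_warning_noncontiguous")
  }
  tibble::tibble(method = "LR", estimate = estimate_umvue(outcome),
                 lower = res$lower, upper = res$upper, level = level,
                 contiguous = res$contiguous)
}
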