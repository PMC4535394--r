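#' Search for a Simon two-stage design
#'
#' Enumerates all designs `(r1, n1, rt, nt)` with `nt <= n_max` whose exact
#' type I error at `pi0` is at most `alpha` and whose exact power at `pi1` is
#' at least `1 - beta`, and returns the optimal design (minimum expected
#' sample size under the null) or the minimax design (minimum `nt`, then
#' minimum expected size). Ties are broken by smaller `nt`, then smaller
#' `n1`, then smaller `r1`, so the result is deterministic.
#'
#' @param pi0,pi1 Null and alternative response rates, `0 < pi0 < pi1 < 1`.
#' @param alpha Nominal one-sided type I error bound.
#' @param beta Nominal type II error bound.
#' @param criterion `"optimal"` or `"minimax"`.
#' @param n_max Largest total sample size to enumerate.
#' @return A [simon_design()] carrying the planning rates and error levels.
#' @examples
#' search_design(0.1, 0.5, 0.05, 0.2, n_max = 25)
#' @export
search_design <- function(pi0, pi1, alpha, beta,
                          criterion = c("optimal", "minimax"),
                          n_max = 55) {
  criterion <- match.arg(criterion)
  check_prob(pi0, "pi0", open = TRUE)
  check_prob(pi1, "pi1", open = TRUE)
  if (pi0 >= pi1) {
    rlang::abort("need pi0 < pi1.", class = "simon2stage_error_input")
  }
  check_prob(alpha, "alpha")
  check_prob(beta, "beta")
  if (!is_count(n_max) || n_max < 2) {
    rlang::abort("`n_max` must be an integer >= 2.",
                 class = "simon2stage_error_input")
  }

  best <- NULL
  best_key <- c(Inf, Inf, Inf, Inf) # (objective, nt, n1, r1)
  for (nt in 2:n_max) {
    if (criterion == "minimax" && !is.null(best)) break
    for (n1 in 1:(nt - 1)) {
      n2 <- nt - n1
      d1_0 <- stats::dbinom(0:n1, n1, pi0)
      d1_1 <- stats::dbinom(0:n1, n1, pi1)
      for (r1 in 0:(n1 - 1)) {
        # power cannot exceed the probability of passing stage 1 at pi1
        pass1 <- 1 - stats::pbinom(r1, n1, pi1)
        if (pass1 < 1 - beta) break
        pet0 <- stats::pbinom(r1, n1, pi0)
        en0 <- n1 + (1 - pet0) * n2
        key <- if (criterion == "optimal") c(en0, nt, n1, r1) else c(nt, en0, n1, r1)
        cmp <- key - best_key
        first <- cmp[cmp != 0][1]
        if (!is.null(best) && (is.na(first) || first > 0)) next
        # type I error and power for every rt at once (both decreasing in rt)
        x <- (r1 + 1):n1
        rts <- r1:(nt - 1)
        tail0 <- outer(x, rts, function(xx, rr)
          stats::pbinom(rr - xx, n2, pi0, lower.tail = FALSE))
        type1 <- as.vector(d1_0[x + 1] %*% tail0)
        ok1 <- which(type1 <= alpha)
        if (length(ok1) == 0) next
        rt <- rts[ok1[1]]
        tail1 <- stats::pbinom(rt - x, n2, pi1, lower.tail = FALSE)
        power <- sum(d1_1[x + 1] * tail1)
        if (power < 1 - beta) next
        best <- c(r1 = r1, n1 = n1, rt = rt, nt = nt)
        best_key <- key
      }
    }
  }
  if (is.null(best)) {
    rlang::abort(
      sprintf("infeasible: no design with nt <= %d meets alpha = %g, beta = %g.",
              n_max, alpha, beta),
      class = "simon2stage_error_infeasible"
    )
  }
  simon_design(best["r1"], best["n1"], best["rt"], best["nt"],
               pi0 = pi0, pi1 = pi1,
               alpha = if (alpha < 1) alpha, beta = if (beta < 1) beta)
}
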