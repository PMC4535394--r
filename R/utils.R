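# internal numerical helpers

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# s*log(p) + (n-s)*log(1-p) with the 0^0 = 1 convention at p in {0, 1}
log_bern_kernel <- function(s, n, p) {
  lo <- ifelse(s == 0, 0, s * log(p))
  hi <- ifelse(n - s == 0, 0, (n - s) * log1p(-p))
  lo + hi
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == trunc(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

check_prob <- function(x, name, open = FALSE) {
  ok <- is_prob(x) && (!open || (x > 0 && x < 1))
  if (!ok) {
    rlang::abort(
      sprintf("`%s` must be a single rate in %s, got %s.",
              name, if (open) "(0, 1)" else "[0, 1]",
              paste(format(x), collapse = ", ")),
      class = "simon2stage_error_input"
    )
  }
  as.numeric(x)
}
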