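# Independent brute-force oracles: enumerate raw (x1, x2) sample paths with
# direct binomial products, never through the package's coefficient-based
# pmf. Only suitable for small designs.

# distribution of (m, s) by raw-path enumeration
oracle_path_table <- function(r1, n1, n2a, pi) {
  rows <- list()
  for (x1 in 0:n1) {
    p1 <- dbinom(x1, n1, pi)
    if (x1 <= r1) {
      rows[[length(rows) + 1]] <- data.frame(m = 1, s = x1, prob = p1)
    } else {
      for (x2 in 0:n2a) {
        rows[[length(rows) + 1]] <-
          data.frame(m = 2, s = x1 + x2, prob = p1 * dbinom(x2, n2a, pi))
      }
    }
  }
  agg <- aggregate(prob ~ m + s, do.call(rbind, rows), sum)
  agg[order(agg$m, agg$s), ]
}

# likelihood ratio by the direct formula (safe for small n)
oracle_lr_stat <- function(s, n, pi0) {
  ph <- s / n
  num <- (if (s == 0) 1 else ph^s) * (if (s == n) 1 else (1 - ph)^(n - s))
  num / (pi0^s * (1 - pi0)^(n - s))
}

# mid-p by enumeration: strictly-larger-T mass plus half the observed mass
oracle_midp <- function(r1, n1, n2a, m_obs, s_obs, pi0) {
  tab <- oracle_path_table(r1, n1, n2a, pi0)
  n_tot <- ifelse(tab$m == 1, n1, n1 + n2a)
  tvals <- mapply(oracle_lr_stat, tab$s, n_tot, pi0)
  i <- which(tab$m == m_obs & tab$s == s_obs)
  stopifnot(length(i) == 1)
  sum(tab$prob[tvals > tvals[i] * (1 + 1e-10)]) + 0.5 * tab$prob[i]
}

# exact UMVUE mean by enumeration, estimating each path with `est_fun`
oracle_mean_estimate <- function(r1, n1, n2a, pi, est_fun) {
  tab <- oracle_path_table(r1, n1, n2a, pi)
  sum(tab$prob * mapply(est_fun, tab$m, tab$s))
}

# designs reused across tests
tiny_design <- function() simon2stage::simon_design(0, 1, 0, 2)

small_designs <- function() {
  list(
    simon2stage::simon_design(1, 4, 2, 7, pi0 = 0.3),
    simon2stage::simon_design(0, 3, 3, 8, pi0 = 0.25),
    simon2stage::simon_design(2, 6, 4, 10, pi0 = 0.2)
  )
}

# the fully published hepatobiliary trial: optimal design for
# pi0 = 0.15 vs pi1 = 0.30 at level 0.10, power 80%
gi_design <- function() {
  simon2stage::simon_design(3, 19, 8, 39, pi0 = 0.15, pi1 = 0.30)
}

gi_outcome <- function() {
  simon2stage::trial_outcome(gi_design(), x1 = 8, x2 = 4, n2_actual = 6)
}

# the twelve designs of the simulation study, grouped by the error levels
# they attain (verified exactly in the acceptance suite)
study_designs <- function() {
  mk <- function(v) simon2stage::simon_design(
    v[1], v[2], v[3], v[4], pi0 = v[5], pi1 = v[6], alpha = v[7], beta = v[8])
  list(
    mk(c(3, 17, 10, 37, .2, .4, .10, .10)),
    mk(c(7, 22, 17, 46, .3, .5, .10, .10)),
    mk(c(7, 18, 22, 46, .4, .6, .10, .10)),
    mk(c(11, 21, 26, 45, .5, .7, .10, .10)),
    mk(c(3, 13, 12, 43, .2, .4, .05, .20)),
    mk(c(5, 15, 18, 46, .3, .5, .05, .20)),
    mk(c(7, 16, 23, 46, .4, .6, .05, .20)),
    mk(c(8, 15, 26, 43, .5, .7, .05, .20)),
    mk(c(4, 19, 15, 54, .2, .4, .05, .10)),
    mk(c(8, 24, 24, 63, .3, .5, .05, .10)),
    mk(c(11, 25, 32, 66, .4, .6, .05, .10)),
    mk(c(13, 24, 36, 61, .5, .7, .05, .10))
  )
}
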