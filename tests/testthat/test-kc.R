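test_that("conditional rejection rate has its closed forms and monotonicity", {
  d <- gi_design() # rt = 8, n2 = 20
  expect_equal(conditional_rejection_rate(d, 9, 0.37), 1)  # x > rt
  expect_equal(conditional_rejection_rate(d, 19, 0.001), 1)
  p <- 0.15
  expect_equal(conditional_rejection_rate(d, 8, p), 1 - (1 - p)^20) # x = rt
  expect_error(conditional_rejection_rate(d, 3, 0.2),
               class = "simon2stage_error_input")
  # nondecreasing in both arguments
  pis <- seq(0, 1, by = 0.05)
  for (x in 4:19) {
    expect_true(all(diff(conditional_rejection_rate(d, x, pis)) >= -1e-12))
  }
  for (p in c(0.1, 0.5)) {
    ax <- vapply(4:19, function(x) conditional_rejection_rate(d, x, p),
                 numeric(1))
    expect_true(all(diff(ax) >= -1e-12))
  }
})

test_that("stage-1 p-value is the exact upper binomial tail", {
  expect_equal(stage1_pvalue(0, 19, 0.15), 1)
  expect_equal(stage1_pvalue(19, 19, 0.15), 0.15^19)
  expect_equal(stage1_pvalue(2, 19, 0.15), 1 - pbinom(1, 19, 0.15))
})

test_that("KC p-value solves pi* exactly and flags its degenerate cases", {
  d <- gi_design()
  res <- kc_pvalue(trial_outcome(d, 8, 4, n2_actual = 6), pi0 = 0.15)
  # pi* satisfies the defining equation A(x1, n2, pi*) = P_0.15[X2 >= 4 | 6]
  expect_equal(conditional_rejection_rate(d, 8, res$pi_star),
               pbinom(3, 6, 0.15, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$degenerate, "none")

  # x2 = 0: p collapses to P[X1 > r1], independent of x1 and n2_actual
  expect_warning(
    r0 <- kc_pvalue(trial_outcome(d, 5, 0, n2_actual = 6), pi0 = 0.15),
    class = "simon2stage_warning_kc_degenerate")
  expect_equal(r0$p_value, pbinom(3, 19, 0.15, lower.tail = FALSE))
  expect_equal(r0$pi_star, 1)
  r0b <- suppressWarnings(kc_pvalue(trial_outcome(d, 8, 0, n2_actual = 13),
                                    pi0 = 0.15))
  expect_equal(r0b$p_value, r0$p_value)

  # x1 > rt: the method is undefined and says so
  expect_error(kc_pvalue(trial_outcome(d, 9, 2, n2_actual = 6), pi0 = 0.15),
               class = "simon2stage_error_kc_undefined")
  expect_error(kc_pvalue(trial_outcome(d, 2), pi0 = 0.15),
               class = "simon2stage_error_input")
})

test_that("KC and the planned-design p-value agree where pi* equals pi0", {
  # at the planned stage-2 size with x1 + x2 = rt + 1, the observed stage-2
  # tail equals the conditional critical value, so pi* = pi0 and the KC sum
  # reduces to the planned-design tail expression
  d <- gi_design()
  eq1 <- function(x1, x2, p0) {
    x <- (d$r1 + 1):d$n1
    sum(dbinom(x, d$n1, p0) *
          pbinom(x1 + x2 - x - 1, d$n2, p0, lower.tail = FALSE))
  }
  for (x1 in c(4, 6, 8)) {
    x2 <- d$rt + 1 - x1
    res <- kc_pvalue(trial_outcome(d, x1, x2, n2_actual = d$n2), pi0 = 0.15)
    expect_equal(res$p_value, eq1(x1, x2, 0.15), tolerance = 1e-10)
  }
})

test_that("the KC p-value function is monotone with limits 0 and 1", {
  o <- gi_outcome()
  grid <- seq(0.01, 0.99, length.out = 99)
  g <- kc_pvalue_function(o, grid)
  expect_true(all(diff(g) >= -1e-10))
  expect_lt(kc_pvalue_function(o, 1e-8), 1e-6)
  expect_gt(kc_pvalue_function(o, 1 - 1e-8), 1 - 1e-6)
})

test_that("KC estimate and interval invert the p-value function", {
  o <- gi_outcome()
  est <- kc_estimate(o)
  expect_equal(kc_pvalue_function(o, est), 0.5, tolerance = 1e-7)
  ci <- kc_ci(o, level = 0.90)
  expect_equal(kc_pvalue_function(o, ci$lower), 0.05, tolerance = 1e-7)
  expect_equal(kc_pvalue_function(o, ci$upper), 0.95, tolerance = 1e-7)
  expect_true(ci$lower < est && est < ci$upper)
  # nested in the level
  ci95 <- kc_ci(o, level = 0.95)
  expect_lte(ci95$lower, ci$lower)
  expect_gte(ci95$upper, ci$upper)
})

test_that("KC inversion agrees with a hand bisection on a tiny design", {
  d <- simon_design(0, 2, 1, 4, pi0 = 0.5)
  o <- trial_outcome(d, 1, 2, n2_actual = 2)
  g <- function(p) kc_pvalue_function(o, p)
  lo <- 1e-9; hi <- 1 - 1e-9
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0.5) lo <- mid else hi <- mid
  }
  expect_equal(kc_estimate(o), lo, tolerance = 1e-6)
})

test_that("stage-1 fallback matches the exact binomial-tail inversion", {
  d <- gi_design()
  ci <- kc_ci(trial_outcome(d, 2), level = 0.90)
  expect_equal(ci$estimate, 2 / 19)
  expect_equal(ci$lower, qbeta(0.05, 2, 18))
  expect_equal(ci$upper, qbeta(0.95, 2, 18))
  ci0 <- kc_ci(trial_outcome(d, 0), level = 0.90)
  expect_equal(c(ci0$lower, ci0$upper), c(0, 1))
  expect_equal(kc_estimate(trial_outcome(d, 2)), 2 / 19)
})

test_that("where KC fails the likelihood-ratio method still answers", {
  d <- gi_design()
  for (x1 in (d$rt + 1):d$n1) {
    o <- trial_outcome(d, x1, 1, n2_actual = 6)
    expect_error(kc_pvalue(o, 0.15), class = "simon2stage_error_kc_undefined")
    expect_error(kc_estimate(o), class = "simon2stage_error_kc_undefined")
    p <- lr_pvalue(o, 0.15)
    expect_true(p > 0 && p < 1)
    # extreme paths can have a (documented) non-contiguous acceptance
    # region; the convex hull is still a valid interval
    ci <- suppressWarnings(lr_ci(o, 0.90))
    expect_true(ci$lower >= 0 && ci$upper <= 1 && ci$lower < ci$upper)
  }
})

test_that("combined inference reports all methods, with KC failures structured", {
  d <- gi_design()
  res <- infer(gi_outcome(), level = 0.90)
  expect_setequal(res$method, c("LR", "KC", "UMVUE-ordering"))
  expect_equal(res$estimate[res$method == "LR"], 2496144 / 5200300)
  fail <- infer(trial_outcome(d, 10, 2, n2_actual = 6), level = 0.90)
  kc_row <- fail[fail$method == "KC", ]
  expect_equal(kc_row$degenerate, "x1_exceeds_rt")
  expect_true(is.na(kc_row$estimate))
  expect_false(any(is.na(fail$estimate[fail$method != "KC"])))
  # stage-1 stop: the report uses the exact stage-1 tail for KC
  s1 <- infer(trial_outcome(d, 2), level = 0.90)
  expect_equal(s1$p_value[s1$method == "KC"], stage1_pvalue(2, 19, 0.15))
  expect_equal(s1$estimate[s1$method == "KC"], 2 / 19)
})
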