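test_that("design and outcome constructors enforce the sampling-scheme invariants", {
  expect_s3_class(simon_design(3, 19, 8, 39), "simon_design")
  expect_error(simon_design(5, 5, 8, 39), class = "simon2stage_error_input")
  expect_error(simon_design(3, 19, 2, 39), class = "simon2stage_error_input")
  expect_error(simon_design(3, 19, 8, 19), class = "simon2stage_error_input")
  expect_error(simon_design(3, 19, 8, 39, pi0 = 0.4, pi1 = 0.2),
               class = "simon2stage_error_input")

  d <- simon_design(3, 19, 8, 39)
  o1 <- trial_outcome(d, 2)
  expect_equal(o1$m, 1L)
  expect_equal(o1$s, 2L)
  expect_equal(o1$n_total, 19L)
  o2 <- trial_outcome(d, 8, 4, n2_actual = 6)
  expect_equal(c(o2$m, o2$s, o2$n_total), c(2L, 12L, 25L))
  # stage follows from x1 vs r1, never from the caller
  expect_error(trial_outcome(d, 2, x2 = 1, n2_actual = 6),
               class = "simon2stage_error_input")
  expect_error(trial_outcome(d, 8), class = "simon2stage_error_input")
  expect_error(trial_outcome(d, 8, x2 = 9, n2_actual = 6),
               class = "simon2stage_error_input")
})

test_that("pmf matches the complete tiny-design enumeration algebraically", {
  d <- tiny_design() # r1 = 0, n1 = 1, nt = 2
  for (p in c(0, 0.15, 0.5, 0.9, 1)) {
    expect_equal(pmf_path(d, 1, 0, p, n2_actual = 1), 1 - p)
    expect_equal(pmf_path(d, 2, 1, p, n2_actual = 1), p * (1 - p))
    expect_equal(pmf_path(d, 2, 2, p, n2_actual = 1), p^2)
  }
})

test_that("pmf agrees with direct binomial oracles", {
  d <- gi_design()
  expect_equal(pmf_path(d, 1, 2, 0.15, n2_actual = 6),
               choose(19, 2) * 0.15^2 * 0.85^17)
  # stage-2 value against raw-path enumeration
  tab <- oracle_path_table(3, 19, 6, 0.15)
  for (s in c(4, 9, 12, 25)) {
    expect_equal(pmf_path(d, 2, s, 0.15, n2_actual = 6),
                 tab$prob[tab$m == 2 & tab$s == s], tolerance = 1e-12)
  }
})

test_that("out-of-support paths raise errors naming the boundary", {
  d <- gi_design()
  expect_error(pmf_path(d, 1, 5, 0.15), class = "simon2stage_error_support")
  expect_error(pmf_path(d, 1, 5, 0.15), "r1")
  expect_error(pmf_path(d, 2, 2, 0.15), class = "simon2stage_error_support")
  expect_error(pmf_path(d, 2, 40, 0.15, n2_actual = 6),
               class = "simon2stage_error_support")
  expect_error(pmf_path(d, 3, 2, 0.15), class = "simon2stage_error_input")
})

test_that("path distributions have the stated support and normalise exactly", {
  d <- gi_design()
  pd <- path_distribution(d, pi = 0.15, n2_actual = 6)
  expect_equal(nrow(pd), (3 + 1) + (19 + 6 - 3)) # 26 paths
  expect_equal(sum(pd$prob), 1, tolerance = 1e-12)
  # degenerate rates
  pd0 <- path_distribution(d, pi = 0)
  expect_equal(pd0$prob[pd0$m == 1 & pd0$s == 0], 1)
  expect_equal(sum(pd0$prob), 1)

  # 200 random configurations: exact normalisation and the stage-1 marginal
  set.seed(42)
  for (k in 1:200) {
    n1 <- sample(2:25, 1)
    r1 <- sample(0:(n1 - 1), 1)
    n2a <- sample(1:30, 1)
    nt <- n1 + sample(1:30, 1)
    rt <- sample(r1:(nt - 1), 1)
    d <- simon_design(r1, n1, rt, nt)
    p <- runif(1)
    pd <- path_distribution(d, pi = p, n2_actual = n2a)
    expect_equal(sum(pd$prob), 1, tolerance = 1e-12)
    expect_equal(sum(pd$prob[pd$m == 1]), pbinom(r1, n1, p), tolerance = 1e-12)
  }
})

test_that("large-design probabilities stay finite (log-space kernels)", {
  d <- simon_design(100, 300, 250, 700)
  pd <- path_distribution(d, pi = 0.4)
  expect_true(all(is.finite(pd$prob)))
  expect_equal(sum(pd$prob), 1, tolerance = 1e-10)
})

test_that("rejection rule reduces to the threshold rule at the planned n2", {
  for (d in small_designs()) {
    pd <- path_distribution(d, pi = 0.5)
    for (i in seq_len(nrow(pd))) {
      if (pd$m[i] == 1) {
        expect_false(reject_h0(d, trial_outcome(d, pd$s[i])))
      } else {
        # any (x1, x2) split of s gives the same planned-design decision
        x1 <- min(pd$s[i], d$n1)
        x1 <- max(x1, d$r1 + 1)
        o <- trial_outcome(d, x1, pd$s[i] - x1, n2_actual = d$n2)
        expect_equal(reject_h0(d, o), pd$s[i] > d$rt)
      }
    }
  }
})

test_that("deviated-n2 rejection uses the planned conditional critical value", {
  d <- gi_design()
  o <- trial_outcome(d, 8, 4, n2_actual = 6)
  tail_obs <- pbinom(3, 6, 0.15, lower.tail = FALSE) # P[X2 >= 4 | 6]
  a <- pbinom(0, 20, 0.15, lower.tail = FALSE)       # A(8, 20, 0.15), rt - x1 = 0
  expect_equal(reject_h0(d, o), tail_obs <= a)
  # boundary behaviour at the planned size
  expect_false(reject_h0(d, trial_outcome(d, 4, 4, n2_actual = 20))) # s = rt
  expect_true(reject_h0(d, trial_outcome(d, 4, 5, n2_actual = 20)))  # s = rt + 1
  expect_error(reject_h0(simon_design(3, 19, 8, 39),
                         trial_outcome(simon_design(3, 19, 8, 39), 8, 4, 6)),
               class = "simon2stage_error_config")
})

test_that("operating characteristics match binomial oracles and the pmf", {
  d <- simon_design(3, 17, 10, 37, pi0 = 0.2, pi1 = 0.4)
  oc <- operating_characteristics(d, 0.2)
  expect_equal(oc$pet, pbinom(3, 17, 0.2))
  expect_equal(oc$expected_n, 17 + (1 - pbinom(3, 17, 0.2)) * 20)
  oc1 <- operating_characteristics(d, 1)
  expect_equal(oc1$reject_prob, 1)
  expect_equal(oc1$pet, 0)
  expect_equal(oc1$expected_n, 37)

  # self-consistency: rejection probability equals pmf mass of rejecting paths
  for (d in small_designs()) {
    for (p in c(0.2, 0.6)) {
      pd <- path_distribution(d, pi = p)
      rej <- pd$m == 2 & pd$s > d$rt
      expect_equal(operating_characteristics(d, p)$reject_prob,
                   sum(pd$prob[rej]), tolerance = 1e-12)
    }
  }
})

test_that("design search returns feasible designs with deterministic tie-breaks", {
  d <- search_design(0.2, 0.4, 0.10, 0.10, n_max = 40)
  expect_equal(c(d$r1, d$n1, d$rt, d$nt), c(3, 17, 10, 37))
  g <- glance(d)
  expect_lte(g$type1, 0.10)
  expect_gte(g$power, 0.90)

  mm <- search_design(0.2, 0.4, 0.10, 0.10, criterion = "minimax", n_max = 40)
  expect_lte(mm$nt, d$nt)
  gmm <- glance(mm)
  expect_lte(gmm$type1, 0.10)
  expect_gte(gmm$power, 0.90)
  # optimal minimises expected size under the null
  expect_lte(g$expected_n0, gmm$expected_n0)

  # vacuous constraints give the smallest enumerable design
  v <- search_design(0.3, 0.5, 1, 1, n_max = 10)
  expect_equal(v$nt, 2L)
  expect_error(search_design(0.2, 0.4, 0.01, 0.01, n_max = 12),
               class = "simon2stage_error_infeasible")
})

test_that("designs round-trip through YAML and JSON", {
  d <- gi_design()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_design(d, path)
    d2 <- read_design(path)
    expect_equal(tidy(d2), tidy(d))
  }
})
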