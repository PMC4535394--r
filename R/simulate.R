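# Monte Carlo study of inference under random second-stage deviations.
#
# Trials are simulated under a design at a grid of true response rates; a
# trial that continues to stage 2 realises an actual stage-2 size drawn
# uniformly from ceil(n2/3) .. floor(1.5 n2). Every method is evaluated on
# the same simulated trials. Because inference depends on the data only
# through (x1, x2, n2_actual), results are computed once per distinct
# realised outcome and joined back, so cost is bounded by the support size
# rather than the replicate count.

#' Default support of the realised stage-2 sample size
#'
#' All integers from `ceil(n2 / 3)` to `floor(1.5 n2)`, the equal-probability
#' range used by the package's simulation study.
#'
#' @param design A [simon_design()].
#' @return An integer vector.
#' @export
default_n2_support <- function(design) {
  seq.int(ceiling(design$n2 / 3), floor(1.5 * design$n2))
}

#' Draw actual stage-2 sample sizes
#'
#' Equal-probability draws from the admissible set of realised stage-2
#' sizes (by default [default_n2_support()]).
#'
#' @param design A [simon_design()] with `n2 >= 2`.
#' @param n Number of draws.
#' @param n2_support Optional explicit support (positive integers).
#' @return An integer vector of length `n`.
#' @export
draw_n2_actual <- function(design, n = 1, n2_support = NULL) {
  stopifnot(inherits(design, "simon_design"))
  if (is.null(n2_support)) {
    if (design$n2 < 2) {
      rlang::abort("`design` must have a planned n2 >= 2 to deviate from.",
                   class = "simon2stage_error_config")
    }
    n2_support <- default_n2_support(design)
  }
  if (length(n2_support) == 0 || any(n2_support < 1)) {
    rlang::abort("`n2_support` must be a nonempty set of positive integers.",
                 class = "simon2stage_error_config")
  }
  # index-based draw so a length-one support is not expanded to 1:n2
  as.integer(n2_support[sample.int(length(n2_support), n, replace = TRUE)])
}

#' Simulate trials under a design
#'
#' Stage-1 responders are binomial `(n1, pi)`; the trial stops when
#' `x1 <= r1`, and otherwise realises an actual stage-2 size via
#' [draw_n2_actual()] and binomial stage-2 responders.
#'
#' @inheritParams draw_n2_actual
#' @param pi True response rate.
#' @return A tibble with one row per trial: `m`, `x1`, `x2`, `n2_actual`,
#'   `s`, `n_total` (stage-1 stops carry `NA` for `x2` and `n2_actual`).
#' @examples
#' d <- simon_design(3, 17, 10, 37)
#' draw_trial(d, pi = 0.3, n = 5)
#' @export
draw_trial <- function(design, pi, n = 1, n2_support = NULL) {
  stopifnot(inherits(design, "simon_design"))
  check_prob(pi, "pi")
  x1 <- stats::rbinom(n, design$n1, pi)
  go <- x1 > design$r1
  n2a <- rep(NA_integer_, n)
  x2 <- rep(NA_integer_, n)
  if (any(go)) {
    n2a[go] <- draw_n2_actual(design, sum(go), n2_support)
    x2[go] <- stats::rbinom(sum(go), n2a[go], pi)
  }
  tibble::tibble(
    m = ifelse(go, 2L, 1L), x1 = x1, x2 = x2, n2_actual = n2a,
    s = ifelse(go, x1 + x2, x1),
    n_total = ifelse(go, design$n1 + n2a, design$n1)
  )
}

#' Configure a simulation study
#'
#' @param designs A [simon_design()] or a list of them; each must carry
#'   `pi0` (used as the null rate for testing).
#' @param pi_grid True response rates to simulate at.
#' @param reps Replicates per (design, rate) cell.
#' @param level Confidence level of all intervals.
#' @param alpha_test One-sided rejection level used for the power columns.
#' @param n2_support Optional explicit support for the realised stage-2
#'   size; default is [default_n2_support()] of each design.
#' @param methods Subset of `c("LR", "KC")`.
#' @param seed Integer seed; the study is bit-reproducible given the
#'   configuration and seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(designs, pi_grid, reps = 5000, level = 0.90,
                       alpha_test = 0.05, n2_support = NULL,
                       methods = c("LR", "KC"), seed = 1L) {
  if (inherits(designs, "simon_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1,
            all(vapply(designs, inherits, logical(1), "simon_design")))
  if (any(vapply(designs, function(d) is.null(d$pi0), logical(1)))) {
    rlang::abort("every design in a simulation must carry pi0.",
                 class = "simon2stage_error_config")
  }
  stopifnot(all(pi_grid >= 0), all(pi_grid <= 1), is_count(reps), reps >= 1)
  check_prob(level, "level", open = TRUE)
  check_prob(alpha_test, "alpha_test", open = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(
    list(designs = designs, pi_grid = as.numeric(pi_grid),
         reps = as.integer(reps), level = level, alpha_test = alpha_test,
         n2_support = n2_support, methods = methods, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# ---- per-distinct-outcome inference, cached across cells of one design ----

# LR results for a batch of needed (m, s) paths at one n2_actual: confidence
# interval and mid-p rejection, sharing one support enumeration and one
# pi0-grid evaluation across all paths
lr_batch <- function(design, n2a, need, level, pi0, alpha_test,
                     grid_n = 2001) {
  supp <- support_paths(design, n2a)
  idx <- match(paste(need$m, need$s), paste(supp$m, supp$s))
  stopifnot(!anyNA(idx))
  alpha <- 1 - level
  grid <- seq(GRID_EPS, 1 - GRID_EPS, length.out = grid_n)
  P <- lr_midp_grid(supp, grid)
  uv <- umvue_support(design, supp, n2a)
  purrr::map_dfr(seq_len(nrow(need)), function(r) {
    i <- idx[r]
    pv <- P[, i]
    acc <- which(pv >= alpha)
    p_fun <- function(p0) lr_midp_at(supp, i, p0)
    lo_i <- min(acc); hi_i <- max(acc)
    lower <- if (lo_i == 1) 0 else refine_boundary(p_fun, grid[lo_i], grid[lo_i - 1], alpha)
    upper <- if (hi_i == grid_n) 1 else refine_boundary(p_fun, grid[hi_i], grid[hi_i + 1], alpha)
    tibble::tibble(m = need$m[r], s = need$s[r],
                   lr_est = uv[i], lr_lower = lower, lr_upper = upper,
                   lr_rej = p_fun(pi0) <= alpha_test)
  })
}

# KC results for one distinct stage-2 outcome (x1, x2, n2a)
kc_one <- function(design, x1, x2, n2a, level, pi0) {
  if (x1 > design$rt) {
    # conditional criterion still rejects (A == 1 dominates any tail), but
    # the method provides no estimate or interval
    return(tibble::tibble(kc_est = NA_real_, kc_lower = NA_real_,
                          kc_upper = NA_real_, kc_rej = TRUE, kc_fail = TRUE))
  }
  out <- trial_outcome(design, x1, x2, n2_actual = n2a)
  ci <- kc_ci(out, level)
  tibble::tibble(kc_est = ci$estimate, kc_lower = ci$lower,
                 kc_upper = ci$upper,
                 kc_rej = reject_h0(design, out), kc_fail = FALSE)
}

# stage-1 inference shared by both methods: estimate x1/n1, exact
# binomial-tail interval, never rejects under KC
stage1_rows <- function(design, x1s, level, pi0, alpha_test) {
  a2 <- (1 - level) / 2
  purrr::map_dfr(x1s, function(x1) {
    out <- trial_outcome(design, x1)
    # non-contiguous acceptance regions are expected for extreme stage-1
    # paths; the convex hull is the intended interval here
    lci <- withCallingHandlers(
      lr_ci(out, level),
      simon2stage_warning_noncontiguous = function(w) {
        invokeRestart("muffleWarning")
      })
    kci <- kc_ci(out, level)
    tibble::tibble(
      x1 = x1,
      lr_est = x1 / design$n1, lr_lower = lci$lower, lr_upper = lci$upper,
      lr_rej = lr_pvalue(out, pi0) <= alpha_test,
      kc_est = x1 / design$n1, kc_lower = kci$lower, kc_upper = kci$upper,
      kc_rej = FALSE, kc_fail = FALSE
    )
  })
}

# ---- the study ----

#' Run the simulation study
#'
#' Simulates `reps` trials per (design, true-rate) cell, applies the
#' likelihood-ratio and Koyama-Chen methods to every trial, and summarises
#' per cell and method: mean confidence-interval width among trials reaching
#' stage 2, coverage of the true rate over all trials (percent), rejection
#' rate of the null at `alpha_test` over all trials (percent), and the
#' absolute and signed bias of the point estimate. Trials where the
#' Koyama-Chen method is undefined (`x1 > rt`) are excluded from its
#' coverage, width and bias denominators and counted in `n_kc_failures`
#' (they still reject under the conditional decision rule). Identical
#' configurations and seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `simon_sim_summary` with columns `design_id`,
#'   `pi_true`, `method`, `width`, `coverage_pct`, `power_pct`, `abs_bias`,
#'   `bias`, `n_stage2`, `n_kc_failures`, `reps`.
#' @examples
#' d <- simon_design(3, 17, 10, 37, pi0 = 0.2, pi1 = 0.4)
#' cfg <- sim_config(d, pi_grid = c(0.2, 0.4), reps = 50, seed = 7)
#' run_study(cfg)
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- purrr::imap_dfr(config$designs, function(design, d_i) {
    caches <- new_caches()
    purrr::imap_dfr(config$pi_grid, function(pi_true, p_i) {
      cell_seed <- (config$seed + 100003L * d_i + 1009L * p_i) %% 2147483647L
      set.seed(cell_seed)
      trials <- draw_trial(design, pi_true, config$reps, config$n2_support)
      res <- evaluate_trials(design, trials, config, caches)
      summarise_cell(res, design, d_i, pi_true, config)
    })
  })
  attr(out, "config") <- config
  class(out) <- c("simon_sim_summary", class(out))
  out
}

# per-design caches of inference results for distinct realised outcomes
new_caches <- function() {
  e <- new.env(parent = emptyenv())
  e$s1_tbl <- tibble::tibble(
    x1 = integer(), lr_est = numeric(), lr_lower = numeric(),
    lr_upper = numeric(), lr_rej = logical(), kc_est = numeric(),
    kc_lower = numeric(), kc_upper = numeric(), kc_rej = logical(),
    kc_fail = logical()
  )
  e$lr_tbl <- tibble::tibble(n2_actual = integer(), s = integer(),
                             lr_est = numeric(), lr_lower = numeric(),
                             lr_upper = numeric(), lr_rej = logical())
  e$kc_tbl <- tibble::tibble(n2_actual = integer(), x1 = integer(),
                             x2 = integer(), kc_est = numeric(),
                             kc_lower = numeric(), kc_upper = numeric(),
                             kc_rej = logical(), kc_fail = logical())
  e
}

evaluate_trials <- function(design, trials, config, caches) {
  pi0 <- design$pi0
  level <- config$level; alpha_test <- config$alpha_test

  t1 <- dplyr::filter(trials, .data$m == 1L)
  if (nrow(t1) > 0) {
    new1 <- setdiff(unique(t1$x1), caches$s1_tbl$x1)
    if (length(new1) > 0) {
      caches$s1_tbl <- dplyr::bind_rows(
        caches$s1_tbl, stage1_rows(design, new1, level, pi0, alpha_test))
    }
    t1 <- dplyr::left_join(t1, caches$s1_tbl, by = "x1")
  }

  t2 <- dplyr::filter(trials, .data$m == 2L)
  if (nrow(t2) > 0) {
    need_lr <- dplyr::anti_join(dplyr::distinct(t2[, c("n2_actual", "s")]),
                                caches$lr_tbl, by = c("n2_actual", "s"))
    for (n2a in sort(unique(need_lr$n2_actual))) {
      need <- tibble::tibble(m = 2L, s = need_lr$s[need_lr$n2_actual == n2a])
      rows <- lr_batch(design, n2a, need, level, pi0, alpha_test)
      rows$n2_actual <- as.integer(n2a)
      caches$lr_tbl <- dplyr::bind_rows(
        caches$lr_tbl,
        rows[, c("n2_actual", "s", "lr_est", "lr_lower", "lr_upper", "lr_rej")])
    }
    need_kc <- dplyr::anti_join(
      dplyr::distinct(t2[, c("n2_actual", "x1", "x2")]),
      caches$kc_tbl, by = c("n2_actual", "x1", "x2"))
    if (nrow(need_kc) > 0) {
      rows <- purrr::pmap_dfr(need_kc, function(n2_actual, x1, x2) {
        dplyr::bind_cols(
          tibble::tibble(n2_actual = n2_actual, x1 = x1, x2 = x2),
          kc_one(design, x1, x2, n2_actual, level, pi0))
      })
      caches$kc_tbl <- dplyr::bind_rows(caches$kc_tbl, rows)
    }
    t2 <- dplyr::left_join(t2, caches$lr_tbl, by = c("n2_actual", "s"))
    t2 <- dplyr::left_join(t2, caches$kc_tbl, by = c("n2_actual", "x1", "x2"))
  }
  if (nrow(t1) == 0) t2 else if (nrow(t2) == 0) t1 else dplyr::bind_rows(t1, t2)
}

summarise_cell <- function(res, design, d_i, pi_true, config) {
  level <- config$level
  cover <- function(lo, hi) lo <= pi_true & pi_true <= hi
  n2 <- sum(res$m == 2L)
  rows <- list()
  if ("LR" %in% config$methods) {
    rows$lr <- tibble::tibble(
      design_id = d_i, pi_true = pi_true, method = "LR",
      width = if (n2 > 0) mean((res$lr_upper - res$lr_lower)[res$m == 2L]) else NA_real_,
      coverage_pct = 100 * mean(cover(res$lr_lower, res$lr_upper)),
      power_pct = 100 * mean(res$lr_rej),
      abs_bias = abs(mean(res$lr_est) - pi_true),
      bias = mean(res$lr_est) - pi_true,
      n_stage2 = n2, n_kc_failures = 0L, reps = nrow(res)
    )
  }
  if ("KC" %in% config$methods) {
    ok <- !res$kc_fail
    n2ok <- sum(res$m == 2L & ok)
    rows$kc <- tibble::tibble(
      design_id = d_i, pi_true = pi_true, method = "KC",
      width = if (n2ok > 0) mean((res$kc_upper - res$kc_lower)[res$m == 2L & ok]) else NA_real_,
      coverage_pct = 100 * mean(cover(res$kc_lower[ok], res$kc_upper[ok])),
      power_pct = 100 * mean(res$kc_rej),
      abs_bias = abs(mean(res$kc_est[ok]) - pi_true),
      bias = mean(res$kc_est[ok]) - pi_true,
      n_stage2 = n2, n_kc_failures = sum(res$kc_fail), reps = nrow(res)
    )
  }
  dplyr::bind_rows(rows)
}

#' Export a simulation summary to CSV and JSON
#'
#' @param summary A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @param basename Base file name without extension.
#' @return Invisibly, the paths of the two files written.
#' @export
export_tables <- function(summary, dir, basename = "simulation_summary") {
  stopifnot(is.data.frame(summary))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(basename, ".csv"))
  json <- file.path(dir, paste0(basename, ".json"))
  utils::write.csv(as.data.frame(summary), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(summary), json, digits = NA, na = "null")
  invisible(c(csv = csv, json = json))
}
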