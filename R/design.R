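#' Define a Simon two-stage design
#'
#' A Simon two-stage design enrols `n1` patients and stops for futility when
#' the number of responders is at most `r1`; otherwise it enrols to a planned
#' total of `nt` patients and rejects the null response rate when the total
#' number of responders exceeds `rt`. There is no early stopping for efficacy.
#'
#' @param r1 Stage-1 futility boundary (stop if stage-1 responders `<= r1`).
#' @param n1 Stage-1 sample size.
#' @param rt Final futility boundary (reject the null if total responders
#'   `> rt`).
#' @param nt Planned total sample size; the planned stage-2 size is
#'   `n2 = nt - n1`.
#' @param pi0,pi1 Optional planning response rates: the null (clinically
#'   uninteresting) rate and the alternative rate the design is powered at.
#' @param alpha,beta Optional nominal one-sided type I error and type II
#'   error the design was constructed for.
#'
#' @return An object of class `simon_design`: a list with elements `r1`,
#'   `n1`, `rt`, `nt`, `n2`, `pi0`, `pi1`, `alpha`, `beta`.
#'
#' @examples
#' simon_design(3, 19, 8, 39, pi0 = 0.15, pi1 = 0.30)
#' @export
simon_design <- function(r1, n1, rt, nt,
                         pi0 = NULL, pi1 = NULL,
                         alpha = NULL, beta = NULL) {
  for (v in list(r1 = r1, n1 = n1, rt = rt, nt = nt)) {
    if (!is_count(v)) {
      rlang::abort("`r1`, `n1`, `rt`, `nt` must be single integers.",
                   class = "simon2stage_error_input")
    }
  }
  r1 <- as.integer(r1); n1 <- as.integer(n1)
  rt <- as.integer(rt); nt <- as.integer(nt)
  if (!(0L <= r1 && r1 < n1)) {
    rlang::abort("invalid design: need 0 <= r1 < n1.",
                 class = "simon2stage_error_input")
  }
  if (!(r1 <= rt && rt < nt)) {
    rlang::abort("invalid design: need r1 <= rt < nt.",
                 class = "simon2stage_error_input")
  }
  if (!(n1 < nt)) {
    rlang::abort("invalid design: need n1 < nt (so that n2 >= 1).",
                 class = "simon2stage_error_input")
  }
  if (!is.null(pi0)) pi0 <- check_prob(pi0, "pi0")
  if (!is.null(pi1)) pi1 <- check_prob(pi1, "pi1")
  if (!is.null(pi0) && !is.null(pi1) && !(0 < pi0 && pi0 < pi1 && pi1 <= 1)) {
    rlang::abort("planning rates must satisfy 0 < pi0 < pi1 <= 1.",
                 class = "simon2stage_error_input")
  }
  if (!is.null(alpha)) alpha <- check_prob(alpha, "alpha", open = TRUE)
  if (!is.null(beta))  beta  <- check_prob(beta, "beta", open = TRUE)
  structure(
    list(r1 = r1, n1 = n1, rt = rt, nt = nt, n2 = nt - n1,
         pi0 = pi0, pi1 = pi1, alpha = alpha, beta = beta),
    class = "simon_design"
  )
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf("Simon two-stage design (r1, n1, rt, nt) = (%d, %d, %d, %d)\n",
              x$r1, x$n1, x$rt, x$nt))
  cat(sprintf("  stage 1: stop for futility if responders <= %d of %d\n",
              x$r1, x$n1))
  cat(sprintf("  stage 2: planned n2 = %d; reject H0 if total responders > %d of %d\n",
              x$n2, x$rt, x$nt))
  if (!is.null(x$pi0) || !is.null(x$pi1)) {
    cat(sprintf("  planning rates: pi0 = %s, pi1 = %s\n",
                format(x$pi0), format(x$pi1)))
  }
  if (!is.null(x$alpha) || !is.null(x$beta)) {
    cat(sprintf("  nominal errors: alpha = %s, beta = %s\n",
                format(x$alpha), format(x$beta)))
  }
  invisible(x)
}

#' Tidy a Simon design into a one-row tibble
#'
#' @param x A [simon_design()].
#' @param ... Unused.
#' @return A one-row tibble with the design parameters.
#' @method tidy simon_design
#' @export
tidy.simon_design <- function(x, ...) {
  tibble::tibble(
    r1 = x$r1, n1 = x$n1, rt = x$rt, nt = x$nt, n2 = x$n2,
    pi0 = x$pi0 %||% NA_real_, pi1 = x$pi1 %||% NA_real_,
    alpha = x$alpha %||% NA_real_, beta = x$beta %||% NA_real_
  )
}

#' Summarise a Simon design's exact operating characteristics
#'
#' Requires planning rates `pi0` and `pi1` on the design. Reports the exact
#' attained type I error (rejection probability at `pi0`), attained power
#' (rejection probability at `pi1`), probability of early termination and
#' expected sample size, both evaluated at `pi0`.
#'
#' @inheritParams tidy.simon_design
#' @return A one-row tibble with columns `type1`, `power`, `pet0`,
#'   `expected_n0` and the design parameters.
#' @method glance simon_design
#' @export
glance.simon_design <- function(x, ...) {
  if (is.null(x$pi0) || is.null(x$pi1)) {
    rlang::abort("glance() needs planning rates pi0 and pi1 on the design.",
                 class = "simon2stage_error_config")
  }
  oc0 <- operating_characteristics(x, x$pi0)
  oc1 <- operating_characteristics(x, x$pi1)
  dplyr::bind_cols(
    tidy(x),
    tibble::tibble(type1 = oc0$reject_prob, power = oc1$reject_prob,
                   pet0 = oc0$pet, expected_n0 = oc0$expected_n)
  )
}

#' Serialize a design to a flat key-value file, or read one back
#'
#' The file format (YAML or JSON, by extension) is a flat mapping with keys
#' `r1`, `n1`, `rt`, `nt` and optionally `pi0`, `pi1`, `alpha`, `beta`.
#'
#' @param design A [simon_design()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a `simon_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "simon_design"))
  x <- design[c("r1", "n1", "rt", "nt", "pi0", "pi1", "alpha", "beta")]
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  simon_design(x$r1, x$n1, x$rt, x$nt,
               pi0 = x$pi0, pi1 = x$pi1, alpha = x$alpha, beta = x$beta)
}
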