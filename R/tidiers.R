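#' Tidy a log-rank test result
#'
#' @param x A `kdsig_logrank` object from [logrank_test()].
#' @param ... Unused.
#' @return A tibble with one row per group: `group`, `n`, `observed`,
#'   `expected`.
#' @method tidy kdsig_logrank
#' @export
tidy.kdsig_logrank <- function(x, ...) {
  tibble::tibble(
    group = x$groups,
    n = unname(x$n),
    observed = unname(x$observed),
    expected = unname(x$expected)
  )
}

#' @rdname tidy.kdsig_logrank
#' @return `glance()` returns a one-row tibble: `chi_square`, `df`,
#'   `p_value`, `hr_estimate`.
#' @method glance kdsig_logrank
#' @export
glance.kdsig_logrank <- function(x, ...) {
  tibble::tibble(
    chi_square = x$chi_square, df = x$df,
    p_value = x$p_value, hr_estimate = x$hr_estimate
  )
}

#' Tidy a best-cutoff scan
#'
#' @param x A `kdsig_cutoff` object from [best_cutoff()].
#' @param ... Unused.
#' @return `tidy()` returns the scan tibble (`cutoff`, `p_nominal`);
#'   `glance()` a one-row summary (`cutoff`, `p_nominal`, `p_adjusted`,
#'   `n_candidates`).
#' @method tidy kdsig_cutoff
#' @export
tidy.kdsig_cutoff <- function(x, ...) x$scan

#' @rdname tidy.kdsig_cutoff
#' @method glance kdsig_cutoff
#' @export
glance.kdsig_cutoff <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, p_nominal = x$p_nominal,
    p_adjusted = x$p_adjusted, n_candidates = x$n_candidates
  )
}

#' Tidy a GSEA result table
#'
#' Drops the list-columns (running sums, hit positions), leaving the per-set
#' statistics.
#'
#' @param x A `kdsig_gsea` tibble from [gsea()].
#' @param ... Unused.
#' @return A tibble: `set`, `size`, `es`, `nes`, `p_nominal`, `p_floor`.
#' @method tidy kdsig_gsea
#' @export
tidy.kdsig_gsea <- function(x, ...) {
  tibble::as_tibble(x[, c("set", "size", "es", "nes", "p_nominal", "p_floor")])
}
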