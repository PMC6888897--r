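#' Kaplan-Meier product-limit estimate
#'
#' Native product-limit estimator, computed per group: at each distinct event
#' time `t_i` with `n_i` subjects at risk and `d_i` events, the survival
#' probability multiplies by `(1 - d_i / n_i)`. Censored subjects leave the
#' risk set after their censoring time; at a tied time, events precede
#' censorings (the standard convention, so a subject censored at `t` is still
#' at risk for an event at `t`).
#'
#' @param data A data frame with columns `time` (non-negative), `event`
#'   (1 = event, 0 = censored) and, unless `group` is given, a `group` column.
#' @param group Optional single group label to restrict to; default uses all
#'   rows, split by their `group` column (absent column = one group `"all"`).
#' @param weights Optional non-negative case weights (one per row).
#' @return A tibble of class `kdsig_km` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, one row per distinct
#'   observed time per group; `survival` is the estimate at (just after) that
#'   time. The curve starts at 1 before the first event.
#' @examples
#' km_estimate(tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1)))
#' @export
km_estimate <- function(data, group = NULL, weights = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("time", "event") %in% names(data)))
  if (!all(is.finite(data$time)) || any(data$time < 0)) {
    rlang::abort("times must be finite and non-negative.")
  }
  if (!all(data$event %in% c(0, 1))) rlang::abort("event must be 0 or 1.")
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (!"group" %in% names(data)) data$group <- "all"
  if (!is.null(group)) {
    keep <- data$group == group
    if (!any(keep)) rlang::abort(sprintf("no records in group '%s'.", group))
    data <- data[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  out <- lapply(split(seq_len(nrow(data)), as.character(data$group)), function(idx) {
    km_one_group(data$time[idx], data$event[idx], weights[idx])
  })
  res <- dplyr::bind_rows(out, .id = "group")
  class(res) <- c("kdsig_km", class(res))
  res
}

km_one_group <- function(time, event, w) {
  ts <- sort(unique(time))
  n_event <- vapply(ts, function(t) sum(w[time == t & event == 1]), numeric(1))
  n_censor <- vapply(ts, function(t) sum(w[time == t & event == 0]), numeric(1))
  n_risk <- vapply(ts, function(t) sum(w[time >= t]), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  tibble::tibble(
    time = ts, n_risk = n_risk, n_event = n_event,
    n_censor = n_censor, survival = surv
  )
}

#' Two-group log-rank test with O/E hazard-ratio estimate
#'
#' Native log-rank test. At each distinct event time with `n` subjects at
#' risk overall, `d` events and `n1` at risk in group 1, the expected events
#' in group 1 accrue by `d * n1 / n` and the hypergeometric variance by
#' `d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)` (0 when `n = 1`). The
#' statistic is `(O1 - E1)^2 / V`, referred to a chi-square with 1 df. The
#' hazard ratio is approximated by the observed/expected ratio
#' `(O1 / E1) / (O2 / E2)` — the quantity KM-plot annotations conventionally
#' report — and is `NA` when any of the four terms is 0.
#'
#' @param data A data frame with columns `time`, `event` and `group`
#'   (exactly two distinct labels).
#' @return An object of class `kdsig_logrank`: a list with `chi_square`,
#'   `df`, `p_value`, `observed`, `expected` (named per group),
#'   `hr_estimate` (group 1 vs group 2, by factor/sort order) and `groups`.
#'   Use [tidy()] / [glance()] for tabular views.
#' @export
logrank_test <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("time", "event", "group") %in% names(data)))
  glev <- if (is.factor(data$group)) levels(droplevels(data$group)) else sort(unique(as.character(data$group)))
  if (length(glev) != 2L) rlang::abort("logrank_test needs exactly two groups.")
  g1 <- as.character(data$group) == glev[1]
  if (sum(data$event) == 0) rlang::abort("no events observed; log-rank test undefined.")
  st <- logrank_stat(data$time, data$event, g1)
  if (st$V == 0) rlang::abort("log-rank variance is zero; test undefined.")
  chi <- (st$O1 - st$E1)^2 / st$V
  O <- c(st$O1, st$O2)
  E <- c(st$E1, st$E2)
  hr <- if (all(c(O, E) > 0)) (O[1] / E[1]) / (O[2] / E[2]) else NA_real_
  structure(
    list(
      chi_square = chi, df = 1L,
      p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
      observed = stats::setNames(O, glev),
      expected = stats::setNames(E, glev),
      hr_estimate = hr, groups = glev,
      n = stats::setNames(c(sum(g1), sum(!g1)), glev)
    ),
    class = "kdsig_logrank"
  )
}

# O1/E1/O2/E2/V accumulated over distinct event times; g1 logical for group 1.
# Vectorised over event times so the best-cutoff scan stays fast.
logrank_stat <- function(time, event, g1) {
  ev_times <- sort(unique(time[event == 1]))
  d <- vapply(ev_times, function(t) sum(event == 1 & time == t), numeric(1))
  d1 <- vapply(ev_times, function(t) sum(event == 1 & time == t & g1), numeric(1))
  n <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n1 <- vapply(ev_times, function(t) sum(time >= t & g1), numeric(1))
  E1 <- sum(d * n1 / n)
  vterm <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  list(
    O1 = sum(d1), O2 = sum(d) - sum(d1),
    E1 = E1, E2 = sum(d) - E1, V = sum(vterm)
  )
}

#' @export
print.kdsig_logrank <- function(x, ...) {
  cat("Log-rank test (", paste(x$groups, collapse = " vs "), ")\n", sep = "")
  cat(sprintf(
    "  chi-square = %.4g on %d df, p = %.4g\n", x$chi_square, x$df, x$p_value
  ))
  cat(sprintf(
    "  O/E: %s %.3g/%.3g, %s %.3g/%.3g; HR (O/E ratio) = %.3g\n",
    x$groups[1], x$observed[1], x$expected[1],
    x$groups[2], x$observed[2], x$expected[2], x$hr_estimate
  ))
  invisible(x)
}

#' Best-cutoff stratification with permutation-adjusted p
#'
#' Scans every distinct score value between the `q_lo` and `q_hi` quantiles
#' as a candidate threshold (low group = score at or below the threshold),
#' picks the cutoff minimising the nominal log-rank p-value, and corrects
#' that minimum for the multiplicity of the scan by permuting the
#' score-survival pairing and recording the permutation distribution of the
#' minimum p. The nominal p of the chosen cutoff is anti-conservative and is
#' reported alongside the adjusted p, never instead of it.
#'
#' @param scores Per-sample scores: a tibble with `sample_id` and a score
#'   column, or a named numeric vector aligned with `clinical$sample_id`.
#' @param clinical A data frame with `sample_id`, `time`, `event`
#'   (at least 10 samples after joining).
#' @param q_lo,q_hi Quantile bounds of the scanned threshold range.
#' @param n_perm Number of permutations for the adjusted p (default 1000).
#' @param seed Integer seed for the permutations.
#' @param score_col Score column name (default `"kd_score"`).
#' @return A list of class `kdsig_cutoff`: `cutoff`, `p_nominal`,
#'   `p_adjusted`, `n_candidates`, `scan` (tibble of threshold vs nominal p),
#'   `groups` (stratified tibble at the chosen cutoff).
#' @export
best_cutoff <- function(scores, clinical, q_lo = 0.1, q_hi = 0.9,
                        n_perm = 1000, seed = 1, score_col = "kd_score") {
  merged <- join_scores_clinical(scores, clinical, score_col)
  x <- merged[[score_col]]
  if (nrow(merged) < 10L) rlang::abort("best_cutoff needs at least 10 samples.")
  qs <- stats::quantile(x, c(q_lo, q_hi), names = FALSE)
  cand <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  cand <- cand[cand < max(x)]  # a threshold at the max leaves the high group empty
  if (length(cand) < 2L) rlang::abort("fewer than 2 candidate cutoffs in the quantile range.")
  scan <- logrank_scanner(merged$time, merged$event, cand)
  ps <- scan(x)
  best <- which.min(ps)
  perm_min <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) min(scan(sample(x))), numeric(1))
  })
  p_adj <- (1 + sum(perm_min <= ps[best])) / (1 + n_perm)
  structure(
    list(
      cutoff = cand[best], p_nominal = ps[best], p_adjusted = p_adj,
      n_candidates = length(cand),
      scan = tibble::tibble(cutoff = cand, p_nominal = ps),
      groups = dplyr::mutate(
        merged,
        group = factor(ifelse(.data[[score_col]] <= cand[best], "low", "high"),
                       levels = c("low", "high"))
      )
    ),
    class = "kdsig_cutoff"
  )
}

# Closure computing nominal log-rank p for every candidate threshold at once.
# Risk sets depend only on (time, event), which the permutations never touch,
# so those are pre-computed; each call costs a few matrix operations.
logrank_scanner <- function(time, event, cand) {
  ord <- order(time)
  ts <- time[ord]
  es <- event[ord]
  n <- length(ts)
  ev <- unique(ts[es == 1])               # ascending: ts is sorted
  k <- findInterval(ev, ts, left.open = TRUE) + 1  # first index at risk
  n_at <- n - k + 1
  d <- tabulate(match(ts[es == 1], ev), nbins = length(ev))
  vf <- ifelse(n_at > 1, d * (n_at - d) / (n_at - 1), 0)
  ev_rows <- which(es == 1)
  ev_grp <- match(ts[ev_rows], ev)
  function(x) {
    A <- 1 * outer(x[ord], cand, "<=")                 # n x C membership
    S <- apply(A[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
    n1 <- S[k, , drop = FALSE]                          # at risk in low group
    d1 <- rowsum(A[ev_rows, , drop = FALSE], ev_grp)
    O1 <- colSums(d1)
    E1 <- colSums(d * n1 / n_at)
    V <- colSums(vf * (n1 / n_at) * (1 - n1 / n_at))
    p <- rep(1, length(cand))
    ok <- V > 0
    p[ok] <- stats::pchisq((O1[ok] - E1[ok])^2 / V[ok], df = 1, lower.tail = FALSE)
    p
  }
}

#' @export
print.kdsig_cutoff <- function(x, ...) {
  cat(sprintf(
    "Best-cutoff stratification: cutoff = %.4g (%d candidates scanned)\n  nominal p = %.4g, permutation-adjusted p = %.4g\n",
    x$cutoff, x$n_candidates, x$p_nominal, x$p_adjusted
  ))
  invisible(x)
}
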