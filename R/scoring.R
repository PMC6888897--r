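#' Per-gene z-scores across a cohort
#'
#' Standardises every gene row to mean 0 and unit standard deviation across
#' the samples of the matrix being scored (sample SD, n - 1 denominator).
#' The cohort itself is the reference population, so scores are comparable
#' within a dataset but not across datasets. Genes with zero variance are
#' dropped with a warning.
#'
#' @param expr An [expr_matrix] with at least 2 samples.
#' @return An [expr_matrix] of z-scores (same sample order; possibly fewer
#'   genes). The scale attribute is carried through unchanged for bookkeeping.
#' @export
zscore_by_gene <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr) < 2L) rlang::abort("z-score undefined for a single-sample matrix.")
  m <- unclass(expr)
  sds <- apply(m, 1, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    rlang::warn(sprintf("%d zero-variance gene row(s) dropped before z-scoring.", sum(zero)))
    m <- m[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  if (nrow(m) == 0L) rlang::abort("no genes left after dropping zero-variance rows.")
  z <- (m - rowMeans(m)) / sds
  structure(z, scale = attr(expr, "scale"), class = class(expr))
}

#' Per-sample KD score
#'
#' For each sample, the KD score is the sum of z-scores over the signature's
#' up-regulated genes minus the sum over the down-regulated genes. A high
#' score means the sample's transcriptome resembles the knockdown state.
#' Signature genes missing from the matrix are skipped; the numbers actually
#' used are reported per sample.
#'
#' @param z A z-scored [expr_matrix] (from [zscore_by_gene()]).
#' @param sig A [kd_signature].
#' @param normalize Divide each directional sum by the number of genes used
#'   (mean instead of sum). Off by default: the raw sum is the primary
#'   definition; the mean variant only aids comparability across signatures
#'   of different sizes.
#' @return A tibble with columns `sample_id`, `kd_score`, `n_up_used`,
#'   `n_down_used`, one row per sample in matrix order.
#' @examples
#' m <- matrix(c(1, 2, 3, 6, 5, 4), 2, 3, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' z <- zscore_by_gene(expr_matrix(m, "log2"))
#' kd_score(z, kd_signature(up = "A", down = "B"))
#' @export
kd_score <- function(z, sig, normalize = FALSE) {
  stopifnot(inherits(z, "expr_matrix"), inherits(sig, "kd_signature"))
  m <- unclass(z)
  up <- intersect(sig$up, rownames(m))
  down <- intersect(sig$down, rownames(m))
  if (length(up) + length(down) == 0L) {
    rlang::abort(paste0(
      "no signature genes present in the matrix; missing: ",
      paste(c(sig$up, sig$down), collapse = ", ")
    ))
  }
  sum_up <- if (length(up) > 0) colSums(m[up, , drop = FALSE]) else rep(0, ncol(m))
  sum_down <- if (length(down) > 0) colSums(m[down, , drop = FALSE]) else rep(0, ncol(m))
  if (normalize) {
    if (length(up) > 0) sum_up <- sum_up / length(up)
    if (length(down) > 0) sum_down <- sum_down / length(down)
  }
  tibble::tibble(
    sample_id = colnames(m),
    kd_score = unname(sum_up - sum_down),
    n_up_used = length(up),
    n_down_used = length(down)
  )
}

#' Stratify samples by score
#'
#' Splits samples into groups by their KD score (or any per-sample value,
#' e.g. single-gene expression). Under the median rule, samples at or below
#' the median go to the low group (ties go low, deterministically); under a
#' fixed cutoff, low is `score <= cutoff`; tertiles give low/mid/high.
#'
#' @param scores A tibble with columns `sample_id` and a score column, or a
#'   named numeric vector.
#' @param rule One of `"median"`, `"tertiles"`, `"fixed"`.
#' @param cutoff Threshold for `rule = "fixed"`.
#' @param score_col Name of the score column (default `"kd_score"`).
#' @return The input tibble with an added `group` factor (levels
#'   `low` < `high`, or `low` < `mid` < `high` for tertiles).
#' @export
stratify <- function(scores, rule = c("median", "tertiles", "fixed"),
                     cutoff = NULL, score_col = "kd_score") {
  rule <- match.arg(rule)
  if (is.numeric(scores)) {
    nm <- names(scores) %||% as.character(seq_along(scores))
    scores <- tibble::tibble(sample_id = nm, kd_score = unname(scores))
    score_col <- "kd_score"
  }
  x <- scores[[score_col]]
  if (is.null(x)) rlang::abort(sprintf("no column '%s' in scores.", score_col))
  if (length(unique(x)) < 2L) rlang::abort("all scores identical; cannot stratify.")
  if (rule == "median") {
    grp <- factor(ifelse(x <= stats::median(x), "low", "high"), levels = c("low", "high"))
  } else if (rule == "fixed") {
    if (is.null(cutoff)) rlang::abort("rule = 'fixed' needs a `cutoff`.")
    grp <- factor(ifelse(x <= cutoff, "low", "high"), levels = c("low", "high"))
  } else {
    q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
    grp <- cut(x, breaks = c(-Inf, q[1], q[2], Inf), labels = c("low", "mid", "high"))
  }
  if (rule != "tertiles" && min(table(grp)) < 2L) {
    rlang::abort("fewer than 2 samples in a stratification group.")
  }
  scores$group <- grp
  scores
}
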