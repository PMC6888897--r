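#' Per-gene log2 fold changes between two groups
#'
#' Computes case-minus-control log2 fold changes on group means. For a
#' log2-scale matrix this is the difference of group means; for a linear-scale
#' matrix it is `log2(mean(case) / mean(ctrl))`, and genes whose group mean is
#' not positive are excluded with a warning (their ratio is undefined).
#'
#' @param expr An [expr_matrix].
#' @param groups Tibble with columns `sample_id` and `group`, or a named
#'   character vector mapping sample id to group label.
#' @param case,ctrl Group labels to contrast (defaults `"kd"` vs `"ctrl"`,
#'   matching [make_discovery()]).
#' @return A tibble with columns `gene` and `log2fc` (case minus control),
#'   in the gene order of `expr` (minus any excluded genes).
#' @export
fold_changes <- function(expr, groups, case = "kd", ctrl = "ctrl") {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble::tibble(sample_id = names(groups), group = unname(groups))
  }
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  missing <- setdiff(groups$sample_id, colnames(expr))
  if (length(missing) > 0L) {
    rlang::abort(paste0("labeled sample(s) absent from matrix: ", paste(missing, collapse = ", ")))
  }
  case_ids <- groups$sample_id[groups$group == case]
  ctrl_ids <- groups$sample_id[groups$group == ctrl]
  if (length(case_ids) == 0L || length(ctrl_ids) == 0L) {
    rlang::abort(sprintf("each of groups '%s' and '%s' needs at least one sample.", case, ctrl))
  }
  m <- unclass(expr)
  mean_case <- rowMeans(m[, case_ids, drop = FALSE])
  mean_ctrl <- rowMeans(m[, ctrl_ids, drop = FALSE])
  if (expr_scale(expr) == "log2") {
    fc <- mean_case - mean_ctrl
    keep <- rep(TRUE, nrow(m))
  } else {
    keep <- mean_case > 0 & mean_ctrl > 0
    if (!all(keep)) {
      rlang::warn(sprintf(
        "%d gene(s) with a non-positive group mean excluded from fold changes.",
        sum(!keep)
      ))
    }
    fc <- log2(mean_case[keep] / mean_ctrl[keep])
  }
  tibble::tibble(gene = rownames(m)[keep], log2fc = unname(fc))
}

#' Build an up/down signature by fold-change cutoff
#'
#' Genes with `log2fc >= log2(cutoff_fold)` become the up list and genes with
#' `log2fc <= -log2(cutoff_fold)` the down list. The boundary is inclusive: a
#' gene at exactly the cutoff fold change is admitted. Optionally, genes can
#' first be filtered by a Welch two-sample t-test with Benjamini-Hochberg
#' correction (off by default; the plain fold cutoff is the primary rule).
#'
#' @param fc Tibble from [fold_changes()] (columns `gene`, `log2fc`) or a
#'   named numeric vector of log2 fold changes.
#' @param cutoff_fold Fold-change cutoff on the linear scale (> 1; default 2).
#' @param expr,groups,case,ctrl,q_max Only used when `q_max` is given: the
#'   discovery matrix and group labels for the optional per-gene Welch t-test;
#'   genes with BH-adjusted p above `q_max` are dropped before the cutoff.
#' @return A [kd_signature] with the cutoff and list sizes in `meta`.
#' @examples
#' fc <- tibble::tibble(gene = c("A", "B", "C", "D"),
#'                      log2fc = c(1.58, -2, 0.58, 1))
#' build_signature(fc, cutoff_fold = 2)
#' @export
build_signature <- function(fc, cutoff_fold = 2,
                            expr = NULL, groups = NULL, case = "kd",
                            ctrl = "ctrl", q_max = NULL) {
  if (is.numeric(fc) && !is.null(names(fc))) {
    fc <- tibble::tibble(gene = names(fc), log2fc = unname(fc))
  }
  stopifnot(all(c("gene", "log2fc") %in% names(fc)))
  if (cutoff_fold <= 1) rlang::abort("cutoff_fold must be > 1.")
  if (!is.null(q_max)) {
    if (is.null(expr) || is.null(groups)) {
      rlang::abort("q_max filtering needs `expr` and `groups`.")
    }
    q <- welch_q_values(expr, groups, case = case, ctrl = ctrl)
    fc <- fc[fc$gene %in% names(q)[q <= q_max], , drop = FALSE]
  }
  thr <- log2(cutoff_fold)
  up <- fc$gene[fc$log2fc >= thr]
  down <- fc$gene[fc$log2fc <= -thr]
  if (length(up) + length(down) == 0L) {
    rlang::abort(sprintf("no signature genes at a %g-fold cutoff.", cutoff_fold))
  }
  kd_signature(
    up = up, down = down,
    meta = list(cutoff_fold = cutoff_fold, n_genes_tested = nrow(fc),
                q_max = q_max)
  )
}

# BH-adjusted Welch t-test p-values, one per gene
welch_q_values <- function(expr, groups, case, ctrl) {
  m <- unclass(expr)
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble::tibble(sample_id = names(groups), group = unname(groups))
  }
  case_ids <- groups$sample_id[groups$group == case]
  ctrl_ids <- groups$sample_id[groups$group == ctrl]
  p <- apply(m, 1, function(row) {
    stats::t.test(row[case_ids], row[ctrl_ids])$p.value
  })
  stats::p.adjust(p, method = "BH")
}
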