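#' Rank genes for preranked enrichment analysis
#'
#' Builds the ranked list that the enrichment walk consumes: genes sorted by
#' a per-gene association metric, best to worst, with ties broken by gene id
#' (lexicographic) so the ordering is deterministic across platforms.
#'
#' Metrics: `signal2noise` = (mean_case - mean_ctrl) / (sd_case + sd_ctrl)
#' with each group SD floored at 0.2 * |group mean| (and at 0.2 if both mean
#' and SD vanish) so the denominator can never be zero; `t_stat` = Welch
#' two-sample t statistic; `pearson` = correlation of each gene with a
#' continuous per-sample score.
#'
#' @param expr An [expr_matrix].
#' @param labels For two-group metrics, a tibble `sample_id`/`group` or named
#'   character vector; for `pearson`, a named numeric vector or tibble with a
#'   score column `kd_score`.
#' @param metric One of `"signal2noise"`, `"t_stat"`, `"pearson"`.
#' @param case,ctrl Group labels to contrast (metric is case minus control).
#' @return A tibble of class `kdsig_ranked` with columns `gene`, `metric`,
#'   sorted by non-increasing metric.
#' @export
rank_genes <- function(expr, labels, metric = c("signal2noise", "t_stat", "pearson"),
                       case = "kd", ctrl = "ctrl") {
  stopifnot(inherits(expr, "expr_matrix"))
  metric <- match.arg(metric)
  m <- unclass(expr)
  if (metric == "pearson") {
    if (is.data.frame(labels)) {
      labels <- stats::setNames(labels$kd_score, labels$sample_id)
    }
    scores <- labels[colnames(m)]
    if (anyNA(scores)) rlang::abort("every sample in the matrix needs a score.")
    vals <- apply(m, 1, function(row) {
      if (stats::sd(row) == 0) 0 else stats::cor(row, scores)
    })
  } else {
    if (is.character(labels) && !is.null(names(labels))) {
      labels <- tibble::tibble(sample_id = names(labels), group = unname(labels))
    }
    case_ids <- labels$sample_id[labels$group == case]
    ctrl_ids <- labels$sample_id[labels$group == ctrl]
    if (length(case_ids) < 3L || length(ctrl_ids) < 3L) {
      rlang::abort("two-group ranking metrics need at least 3 samples per group.")
    }
    mc <- m[, case_ids, drop = FALSE]
    mt <- m[, ctrl_ids, drop = FALSE]
    m1 <- rowMeans(mc)
    m0 <- rowMeans(mt)
    s1 <- apply(mc, 1, stats::sd)
    s0 <- apply(mt, 1, stats::sd)
    if (metric == "signal2noise") {
      s1 <- pmax(s1, 0.2 * abs(m1))
      s0 <- pmax(s0, 0.2 * abs(m0))
      s1[s1 == 0] <- 0.2
      s0[s0 == 0] <- 0.2
      vals <- (m1 - m0) / (s1 + s0)
    } else {
      se <- sqrt(s1^2 / ncol(mc) + s0^2 / ncol(mt))
      se[se == 0] <- .Machine$double.eps
      vals <- (m1 - m0) / se
    }
  }
  out <- tibble::tibble(gene = rownames(m), metric = unname(vals))
  out <- out[order(-out$metric, out$gene), ]
  class(out) <- c("kdsig_ranked", class(out))
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks down a ranked gene list: at each gene in `set` ("hit") the running
#' sum rises by `|metric|^weight / sum(|metric|^weight over hits)`, at every
#' other gene it falls by `1 / (N - N_hits)`. The enrichment score (ES) is
#' the signed extremum of the walk — the deviation of largest magnitude, with
#' the positive one preferred on an exact tie. By construction the walk ends
#' at 0 and ES lies in [-1, 1].
#'
#' @param ranked A `kdsig_ranked` tibble (columns `gene`, `metric`, sorted
#'   non-increasing) from [rank_genes()], or any tibble of that shape.
#' @param set Character vector of gene ids; must share at least one gene with
#'   the ranked list but not cover it entirely.
#' @param weight Exponent on `|metric|` for hit increments: 0 gives the
#'   classic unweighted Kolmogorov-Smirnov walk, 1 (default) the standard
#'   weighted statistic, 2 over-weights the extremes.
#' @return A list of class `kdsig_es`: `es`, `running_sum` (length N),
#'   `hit_positions` (sorted), `n_hits`, `weight`.
#' @examples
#' rk <- tibble::tibble(gene = c("A", "B", "C"), metric = c(3, 2, 1))
#' enrichment_score(rk, set = "A", weight = 0)$running_sum
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  stopifnot(all(c("gene", "metric") %in% names(ranked)))
  if (anyDuplicated(ranked$gene)) rlang::abort("ranked list contains duplicate genes.")
  if (is.unsorted(rev(ranked$metric))) rlang::abort("ranked metric must be non-increasing.")
  N <- nrow(ranked)
  hits <- which(ranked$gene %in% set)
  if (length(hits) == 0L) rlang::abort("gene set shares no genes with the ranked list.")
  if (length(hits) == N) rlang::abort("gene set covers the entire ranked list.")
  w <- abs(ranked$metric)^weight
  denom <- sum(w[hits])
  delta <- rep(-1 / (N - length(hits)), N)
  delta[hits] <- if (denom > 0) w[hits] / denom else 1 / length(hits)
  running <- cumsum(delta)
  structure(
    list(
      es = signed_extremum(running), running_sum = running,
      hit_positions = hits, n_hits = length(hits), weight = weight
    ),
    class = "kdsig_es"
  )
}

signed_extremum <- function(v) {
  hi <- max(v)
  lo <- min(v)
  if (hi >= -lo) hi else lo
}

# ES for one set of hit positions without materialising the full walk;
# used for the permutation null. Must stay numerically identical to
# enrichment_score() (same increments, same tie rule).
es_at_positions <- function(w, N, hits) {
  hits <- sort.int(hits)
  k <- length(hits)
  wh <- w[hits]
  denom <- sum(wh)
  inc <- if (denom > 0) cumsum(wh) / denom else seq_len(k) / k
  miss <- 1 / (N - k)
  after <- inc - (hits - seq_len(k)) * miss       # walk right after each hit
  before <- c(0, inc[-k]) - (hits - seq_len(k)) * miss  # just before each hit
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment with permutation null
#'
#' For each gene set, computes the observed enrichment score on the ranked
#' list, then a null distribution by gene-label permutation: set membership
#' is reassigned to uniformly random positions of the same size, `n_perm`
#' times. The normalised enrichment score (NES) divides the observed ES by
#' the mean |null ES| of matching sign, and the nominal p is the
#' Laplace-corrected fraction of same-sign null scores at least as extreme.
#' When no null score shares the observed sign, p is reported at its floor
#' `1 / (1 + n_perm)` and flagged.
#'
#' @param ranked A `kdsig_ranked` tibble from [rank_genes()].
#' @param sets A `gene_set_collection` (from [read_gmt()]) or any tibble with
#'   `set` and `genes` columns.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param weight Hit-increment exponent, as in [enrichment_score()].
#' @return A tibble of class `kdsig_gsea` with one row per set: `set`,
#'   `size` (genes found in the ranked list), `es`, `nes`, `p_nominal`,
#'   `p_floor` (TRUE when no same-sign null existed), plus list-columns
#'   `running_sum` and `hit_positions` for plotting.
#' @export
gsea <- function(ranked, sets, n_perm = 1000, seed = 1, weight = 1) {
  stopifnot(all(c("set", "genes") %in% names(sets)))
  if (n_perm < 100) rlang::abort("n_perm must be at least 100.")
  N <- nrow(ranked)
  w <- abs(ranked$metric)^weight
  obs <- purrr::map(sets$genes, ~ enrichment_score(ranked, .x, weight = weight))
  out <- withr::with_seed(seed, {
    purrr::map2_dfr(obs, sets$set, function(o, set_name) {
      null_es <- vapply(
        seq_len(n_perm),
        function(i) es_at_positions(w, N, sample.int(N, o$n_hits)),
        numeric(1)
      )
      same <- null_es[sign(null_es) == sign(o$es)]
      if (length(same) == 0L) {
        tibble::tibble(
          set = set_name, size = o$n_hits, es = o$es,
          nes = sign(o$es) * Inf, p_nominal = 1 / (1 + n_perm), p_floor = TRUE
        )
      } else {
        tibble::tibble(
          set = set_name, size = o$n_hits, es = o$es,
          nes = o$es / mean(abs(same)),
          p_nominal = (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same)),
          p_floor = FALSE
        )
      }
    })
  })
  out$running_sum <- purrr::map(obs, "running_sum")
  out$hit_positions <- purrr::map(obs, "hit_positions")
  class(out) <- c("kdsig_gsea", class(out))
  out
}
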