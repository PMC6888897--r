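two_group_expr <- function(seed = 61) {
  withr::with_seed(seed, {
    m <- rbind(
      A = c(rnorm(4, 0, 1), rnorm(4, 10, 1)),
      B = c(rnorm(4, 5, 1), rnorm(4, 5, 1)),
      C = c(rnorm(4, 6, 1), rnorm(4, 4, 1))
    )
  })
  colnames(m) <- c(paste0("c", 1:4), paste0("k", 1:4))
  expr_matrix(m, "log2")
}

two_group_labels <- tibble::tibble(
  sample_id = c(paste0("c", 1:4), paste0("k", 1:4)),
  group = rep(c("ctrl", "kd"), each = 4)
)

test_that("signal-to-noise ranks a cleanly separated gene first", {
  rk <- rank_genes(two_group_expr(), two_group_labels, metric = "signal2noise")
  expect_identical(rk$gene[1], "A")
  expect_true(!is.unsorted(rev(rk$metric)))
})

test_that("pearson metric ranks a gene perfectly correlated with the score first", {
  x <- rnd_expr(10, 8, seed = 62)
  scores <- unclass(x)["g004", ]
  rk <- rank_genes(x, scores, metric = "pearson")
  expect_identical(rk$gene[1], "g004")
  expect_equal(rk$metric[1], 1.0, tolerance = 1e-12)
})

test_that("label swap negates the metric and reverses the order", {
  x <- rnd_expr(30, 8, seed = 63)
  labs <- tibble::tibble(sample_id = colnames(x),
                         group = rep(c("ctrl", "kd"), each = 4))
  swapped <- dplyr::mutate(labs, group = ifelse(group == "kd", "ctrl", "kd"))
  r1 <- rank_genes(x, labs, metric = "signal2noise")
  r2 <- rank_genes(x, swapped, metric = "signal2noise")
  expect_equal(
    r2$metric[match(r1$gene, r2$gene)], -r1$metric,
    tolerance = 1e-12
  )
})

test_that("two-group metrics require 3 samples per group", {
  x <- rnd_expr(5, 4, seed = 64)
  labs <- tibble::tibble(sample_id = colnames(x),
                         group = rep(c("ctrl", "kd"), each = 2))
  expect_error(rank_genes(x, labs), "3 samples")
})

test_that("unweighted walks match hand enumeration", {
  rk <- tibble::tibble(gene = c("A", "B", "C"), metric = c(3, 2, 1))
  top <- enrichment_score(rk, "A", weight = 0)
  expect_equal(top$running_sum, c(1, 0.5, 0))
  expect_equal(top$es, 1)
  bottom <- enrichment_score(rk, "C", weight = 0)
  expect_equal(bottom$running_sum, c(-0.5, -1, 0))
  expect_equal(bottom$es, -1)
})

test_that("weighted walk matches the brute-force oracle on the 4-gene example", {
  rk <- tibble::tibble(gene = paste0("g", 1:4), metric = c(4, 3, 2, 1))
  res <- enrichment_score(rk, c("g1", "g4"), weight = 1)
  oracle <- brute_force_es(rk$metric, rk$gene %in% c("g1", "g4"), weight = 1)
  expect_equal(res$running_sum, oracle$running, tolerance = 1e-12)
  expect_equal(res$es, oracle$es, tolerance = 1e-12)
  expect_equal(res$running_sum, c(4 / 5, 4 / 5 - 1 / 2, 4 / 5 - 1, 0), tolerance = 1e-12)
})

test_that("enrichment preconditions reject degenerate sets", {
  rk <- tibble::tibble(gene = c("A", "B"), metric = c(2, 1))
  expect_error(enrichment_score(rk, "Z"), "no genes")
  expect_error(enrichment_score(rk, c("A", "B")), "entire")
})

test_that("reversing the ranked list negates the unweighted ES", {
  withr::with_seed(65, {
    genes <- paste0("g", 1:15)
    metric <- sort(rnorm(15), decreasing = TRUE)
    set <- sample(genes, 4)
  })
  fwd <- tibble::tibble(gene = genes, metric = metric)
  rev_list <- tibble::tibble(gene = rev(genes), metric = sort(-metric, decreasing = TRUE))
  e1 <- enrichment_score(fwd, set, weight = 0)$es
  e2 <- enrichment_score(rev_list, set, weight = 0)$es
  expect_equal(e2, -e1, tolerance = 1e-12)
})

test_that("|ES| = 1 exactly when all hits precede all misses", {
  rk <- tibble::tibble(gene = paste0("g", 1:6), metric = 6:1)
  perfect <- enrichment_score(rk, c("g1", "g2"), weight = 0)
  expect_equal(perfect$es, 1)
  broken <- enrichment_score(rk, c("g1", "g3"), weight = 0)
  expect_lt(abs(broken$es), 1)
})

test_that("the closed-form permutation ES equals the full walk", {
  withr::with_seed(66, {
    for (i in 1:30) {
      N <- sample(8:40, 1)
      metric <- sort(rnorm(N), decreasing = TRUE)
      k <- sample(2:min(6, N - 1), 1)
      hits <- sort(sample(N, k))
      w <- sample(0:2, 1)
      rk <- tibble::tibble(gene = paste0("g", 1:N), metric = metric)
      full <- enrichment_score(rk, paste0("g", hits), weight = w)$es
      fast <- kdsig:::es_at_positions(abs(metric)^w, N, hits)
      expect_equal(fast, full, tolerance = 1e-12)
    }
  })
})

test_that("gsea is deterministic under a fixed seed and flags planted sets", {
  d <- make_discovery(n_genes = 400, n_up = 25, n_down = 20, seed = 67)
  rk <- rank_genes(d$expr, d$groups, metric = "signal2noise")
  sets <- tibble::tibble(
    set = c("PLANTED_UP", "PLANTED_DOWN"), description = "",
    genes = list(d$truth$up_genes, d$truth$down_genes)
  )
  g1 <- gsea(rk, sets, n_perm = 200, seed = 7)
  g2 <- gsea(rk, sets, n_perm = 200, seed = 7)
  expect_identical(tidy(g1), tidy(g2))
  expect_gt(g1$nes[g1$set == "PLANTED_UP"], 0)
  expect_lt(g1$nes[g1$set == "PLANTED_DOWN"], 0)
  expect_error(gsea(rk, sets, n_perm = 50), "at least 100")
})

test_that("planted up-sets enrich positively across seeds", {
  hits <- vapply(1:20, function(s) {
    d <- make_discovery(n_genes = 300, n_up = 20, n_down = 15,
                        effect_log2fc = 1.5, seed = s)
    rk <- rank_genes(d$expr, d$groups, metric = "signal2noise")
    sets <- tibble::tibble(set = "UP", description = "",
                           genes = list(d$truth$up_genes))
    res <- gsea(rk, sets, n_perm = 200, seed = s)
    res$nes > 0 && res$p_nominal <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
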