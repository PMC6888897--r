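test_that("z-scoring standardises each gene row with the n-1 denominator", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  x <- expr_matrix(m, "log2")
  expect_warning(z <- zscore_by_gene(x), "zero-variance")
  expect_equal(unname(unclass(z)["A", ]), c(-1, 0, 1))
  expect_false("B" %in% rownames(z))

  single <- expr_matrix(matrix(1, 1, 1, dimnames = list("A", "s1")), "log2")
  expect_error(zscore_by_gene(single), "single-sample")
})

test_that("every retained z-row is centered", {
  z <- zscore_by_gene(rnd_expr(40, 12, seed = 21))
  expect_true(all(abs(rowSums(unclass(z))) < 1e-9))
  expect_true(all(abs(apply(unclass(z), 1, sd) - 1) < 1e-9))
})

test_that("kd_score is the up-sum minus the down-sum of z-scores", {
  z <- structure(
    matrix(c(0.5, -0.3), 2, 1, dimnames = list(c("A", "B"), "s1")),
    scale = "log2", class = c("expr_matrix", "matrix", "array")
  )
  sc <- kd_score(z, kd_signature(up = "A", down = "B"))
  expect_equal(sc$kd_score, 0.8)
  expect_equal(sc$n_up_used, 1)
  expect_equal(sc$n_down_used, 1)
})

test_that("missing signature genes are skipped and counted; all-missing errors", {
  z <- zscore_by_gene(rnd_expr(10, 5, seed = 22))
  sig <- kd_signature(up = c("g001", "ABSENT1"), down = c("g002", "ABSENT2"))
  sc <- kd_score(z, sig)
  expect_true(all(sc$n_up_used == 1))
  expect_true(all(sc$n_down_used == 1))
  expect_error(
    kd_score(z, kd_signature(up = "NOPE1", down = "NOPE2")),
    "missing.*NOPE1"
  )
})

test_that("cohort scores sum to zero by construction", {
  z <- zscore_by_gene(rnd_expr(30, 8, seed = 23))
  sc <- kd_score(z, kd_signature(up = sprintf("g%03d", 1:5),
                                 down = sprintf("g%03d", 6:9)))
  expect_lt(abs(sum(sc$kd_score)), 1e-6)
})

test_that("scores are invariant to gene-wise shifts and rescalings", {
  x <- rnd_expr(25, 10, seed = 24)
  sig <- kd_signature(up = sprintf("g%03d", 1:6), down = sprintf("g%03d", 7:12))
  base <- kd_score(zscore_by_gene(x), sig)$kd_score

  shifted <- unclass(x) + matrix(rnorm(nrow(x)), nrow(x), ncol(x))  # per-gene constant
  s1 <- kd_score(zscore_by_gene(expr_matrix(shifted, "log2")), sig)$kd_score
  expect_equal(s1, base, tolerance = 1e-9)

  rescaled <- unclass(x)
  rescaled["g001", ] <- rescaled["g001", ] * 7  # single-gene rescale
  s2 <- kd_score(zscore_by_gene(expr_matrix(rescaled, "log2")), sig)$kd_score
  expect_equal(s2, base, tolerance = 1e-9)
})

test_that("negating the signature negates every score; sample order is irrelevant", {
  x <- rnd_expr(25, 10, seed = 25)
  sig <- kd_signature(up = sprintf("g%03d", 1:6), down = sprintf("g%03d", 7:12))
  flipped <- kd_signature(up = sig$down, down = sig$up)
  z <- zscore_by_gene(x)
  expect_equal(kd_score(z, flipped)$kd_score, -kd_score(z, sig)$kd_score)

  perm <- sample(ncol(x))
  z2 <- zscore_by_gene(expr_matrix(unclass(x)[, perm], "log2"))
  sc1 <- kd_score(z, sig)
  sc2 <- kd_score(z2, sig)
  expect_equal(
    sc2$kd_score[match(sc1$sample_id, sc2$sample_id)],
    sc1$kd_score,
    tolerance = 1e-9
  )
})

test_that("KD score tracks the latent cohort activity", {
  sig <- fixture_signature(25, 25)
  cors <- vapply(1:20, function(s) {
    co <- make_cohort(sig, n_patients = 100, beta = 1, effect = 1.0,
                      sigma = 0.3, n_extra_genes = 50, seed = s)
    sc <- kd_score(zscore_by_gene(co$expr), sig)
    cor(sc$kd_score, co$truth$activity[sc$sample_id])
  }, numeric(1))
  expect_gte(min(cors), 0.9)
})

test_that("stratification rules split as documented", {
  s4 <- stratify(tibble::tibble(sample_id = letters[1:4], kd_score = 1:4))
  expect_identical(as.character(s4$group), c("low", "low", "high", "high"))

  expect_error(
    stratify(tibble::tibble(sample_id = letters[1:3], kd_score = c(1, 1, 1))),
    "identical"
  )

  fx <- stratify(tibble::tibble(sample_id = letters[1:4], kd_score = c(-2, -1, 1, 2)),
                 rule = "fixed", cutoff = 0)
  expect_identical(as.character(fx$group), c("low", "low", "high", "high"))

  # ties at the median go to the low group
  tied <- stratify(tibble::tibble(sample_id = letters[1:8],
                                  kd_score = c(1, 2, 3, 3, 3, 9, 9, 9)))
  expect_equal(sum(tied$group == "low"), 5)

  tert <- stratify(tibble::tibble(sample_id = letters[1:9], kd_score = 1:9),
                   rule = "tertiles")
  expect_identical(levels(tert$group), c("low", "mid", "high"))
  expect_equal(unname(table(tert$group)), c(3L, 3L, 3L), ignore_attr = TRUE)
})
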