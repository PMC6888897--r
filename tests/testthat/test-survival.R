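test_that("product-limit estimates match hand computation on toys", {
  km <- km_estimate(tibble::tibble(time = c(1, 2), event = c(1, 1)))
  expect_equal(km$survival, c(0.5, 0))

  km2 <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km2$survival, c(2 / 3, 2 / 3, 0))

  censored <- km_estimate(tibble::tibble(time = c(1, 4, 9), event = c(0, 0, 0)))
  expect_true(all(censored$survival == 1))
})

test_that("curves from duplicated records equal curves from weighted records", {
  base <- tibble::tibble(time = c(2, 2, 5, 7, 7, 7), event = c(1, 1, 0, 1, 1, 1))
  dedup <- tibble::tibble(time = c(2, 5, 7), event = c(1, 0, 1))
  a <- km_estimate(base)
  b <- km_estimate(dedup, weights = c(2, 1, 3))
  expect_equal(a$survival, b$survival)
  expect_equal(a$n_risk, b$n_risk)
})

test_that("log-rank toy matches the hand-computed hypergeometric terms", {
  toy <- tibble::tibble(time = c(1, 2), event = c(1, 1), group = c("A", "B"))
  lr <- logrank_test(toy)
  expect_equal(lr$chi_square, 1, tolerance = 1e-12)
  expect_equal(unname(lr$expected["A"]), 0.5)
  expect_equal(lr$p_value, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("mirrored identical groups give a null test", {
  one <- tibble::tibble(time = c(1, 3, 4, 6), event = c(1, 0, 1, 1))
  both <- dplyr::bind_rows(
    dplyr::mutate(one, group = "A"),
    dplyr::mutate(one, group = "B")
  )
  lr <- logrank_test(both)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
})

test_that("swapping group labels preserves chi-square and inverts the HR", {
  dat <- rnd_surv_data(40, seed = 31)
  lr1 <- logrank_test(dat)
  swapped <- dplyr::mutate(dat, group = ifelse(group == "a", "zz", "a"))
  lr2 <- logrank_test(swapped)
  expect_equal(lr2$chi_square, lr1$chi_square, tolerance = 1e-12)
  expect_equal(lr2$p_value, lr1$p_value, tolerance = 1e-12)
  expect_equal(lr2$hr_estimate, 1 / lr1$hr_estimate, tolerance = 1e-12)
})

test_that("degenerate survival inputs raise explicit errors", {
  none <- tibble::tibble(time = c(1, 2), event = c(0, 0), group = c("A", "B"))
  expect_error(logrank_test(none), "no events")
  # the only event happens when a single subject remains at risk: V = 0
  v0 <- tibble::tibble(time = c(1, 5), event = c(0, 1), group = c("B", "A"))
  expect_error(logrank_test(v0), "variance is zero")
  expect_error(
    logrank_test(tibble::tibble(time = 1, event = 1, group = "A")),
    "two groups"
  )
})

test_that("native KM and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  for (s in 1:20) {
    dat <- rnd_surv_data(sample(10:30, 1), seed = 300 + s)
    if (sum(dat$event) == 0 || length(unique(dat$group)) < 2) next
    lr <- tryCatch(logrank_test(dat), error = function(e) NULL)
    if (is.null(lr)) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-8)

    for (g in unique(dat$group)) {
      sub <- dat[dat$group == g, ]
      fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
      ours <- km_estimate(sub)
      expect_equal(ours$survival, fit$surv, tolerance = 1e-8)
      expect_equal(ours$n_risk, fit$n.risk, tolerance = 1e-8)
    }
  }
})

test_that("best_cutoff separates a strong cohort and reports a honest adjusted p", {
  sig <- fixture_signature()
  co <- make_cohort(sig, n_patients = 120, beta = 2, censor_rate = 0.005,
                    n_extra_genes = 50, seed = 41)
  sc <- kd_score(zscore_by_gene(co$expr), sig)
  bc <- best_cutoff(sc, co$clinical, n_perm = 200, seed = 42)
  expect_lt(bc$p_adjusted, 0.05)
  expect_lte(bc$p_nominal, bc$p_adjusted)
  # the scan's nominal p at the chosen cutoff must equal a direct log-rank
  grouped <- bc$groups
  expect_equal(logrank_test(grouped)$p_value, bc$p_nominal, tolerance = 1e-9)
  # chosen cutoff separates low from high activity patients reasonably:
  act <- co$truth$activity[bc$groups$sample_id]
  expect_gt(
    mean(act[bc$groups$group == "high"]),
    mean(act[bc$groups$group == "low"])
  )
})

test_that("best_cutoff enforces its preconditions", {
  small <- tibble::tibble(sample_id = letters[1:5], time = 1:5,
                          event = rep(1, 5), kd_score = 1:5)
  expect_error(best_cutoff(small, small), "at least 10")

  const <- tibble::tibble(
    sample_id = letters[1:12], time = 1:12, event = rep(1, 12),
    kd_score = c(rep(0, 11), 5)
  )
  expect_error(best_cutoff(const, const), "candidate cutoffs")
})

test_that("nominal p never exceeds the permutation-adjusted p", {
  sig <- fixture_signature(10, 10)
  for (s in 1:5) {
    co <- make_cohort(sig, n_patients = 40, beta = 0, n_extra_genes = 20,
                      seed = 50 + s)
    sc <- kd_score(zscore_by_gene(co$expr), sig)
    bc <- best_cutoff(sc, co$clinical, n_perm = 99, seed = s)
    expect_lte(bc$p_nominal, bc$p_adjusted)
  }
})

test_that("adjusted p is roughly uniform under the null", {
  sig <- fixture_signature(10, 10)
  padj <- vapply(1:60, function(s) {
    co <- make_cohort(sig, n_patients = 60, beta = 0, n_extra_genes = 20,
                      seed = 1000 + s)
    sc <- kd_score(zscore_by_gene(co$expr), sig)
    best_cutoff(sc, co$clinical, n_perm = 99, seed = s)$p_adjusted
  }, numeric(1))
  ks <- suppressWarnings(ks.test(padj, "punif"))
  expect_gt(ks$p.value, 0.01)
})
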