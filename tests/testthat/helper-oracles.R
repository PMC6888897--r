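# Independent oracles and small fixture builders shared across tests.
# The enrichment walk here is a deliberate re-implementation by explicit
# position-by-position loop; it shares no code with the package.

brute_force_es <- function(metric, hit, weight) {
  N <- length(metric)
  nh <- sum(hit)
  denom <- sum(abs(metric[hit])^weight)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + if (denom > 0) abs(metric[i])^weight / denom else 1 / nh
    } else {
      cur <- cur - 1 / (N - nh)
    }
    running[i] <- cur
  }
  hi <- max(running)
  lo <- min(running)
  list(es = if (hi >= -lo) hi else lo, running = running)
}

# random genes-by-samples log2 matrix with named dims
rnd_expr <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2), n_genes, n_samples)
  })
  dimnames(m) <- list(
    sprintf("g%03d", seq_len(n_genes)),
    sprintf("s%03d", seq_len(n_samples))
  )
  expr_matrix(m, scale = "log2")
}

# survival value of a KM curve (one group) at time t: step function,
# right-continuous, 1 before the first recorded time
km_value <- function(curve, t) {
  keep <- curve$time <= t
  if (!any(keep)) 1 else curve$survival[max(which(keep))]
}

# random small right-censored two-group dataset with ties
rnd_surv_data <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      time = sample(1:12, n, replace = TRUE) / 2,
      event = rbinom(n, 1, 0.7),
      group = sample(c("a", "b"), n, replace = TRUE)
    )
  })
}

# a fixed mid-sized signature for cohort simulations
fixture_signature <- function(n_up = 25, n_down = 25) {
  kd_signature(
    up = sprintf("up%03d", seq_len(n_up)),
    down = sprintf("dn%03d", seq_len(n_down))
  )
}
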