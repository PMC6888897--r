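#' Simulate a two-condition knockdown discovery experiment
#'
#' Generates a log2-scale genes-by-samples matrix for a control vs knockdown
#' design with a planted set of differentially expressed genes, plus the
#' ground-truth record needed to test signature recovery. Non-planted genes
#' fluctuate around gene-specific baselines with standard deviation `sigma`;
#' planted genes are additionally shifted by `+effect_log2fc` (up genes) or
#' `-effect_log2fc` (down genes) in the knockdown group. The default planted
#' counts (84 up, 73 down) mirror the size of a knockdown signature typical of
#' a stringent 2-fold cutoff on a cell-line RNA-seq contrast.
#'
#' @param n_genes Total number of genes.
#' @param n_ctrl,n_kd Samples per group (each at least 2).
#' @param n_up,n_down Numbers of planted up-/down-regulated genes.
#' @param effect_log2fc Planted absolute log2 fold change (knockdown vs control).
#' @param sigma Within-group standard deviation on the log2 scale.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return A list with elements `expr` (an [expr_matrix], scale log2),
#'   `groups` (tibble `sample_id`, `group` with levels `ctrl`/`kd`) and
#'   `truth` (list: `up_genes`, `down_genes`, `effect_log2fc`, `sigma`).
#' @examples
#' d <- make_discovery(n_genes = 200, n_up = 10, n_down = 8, seed = 1)
#' d$expr
#' @export
make_discovery <- function(n_genes = 1000, n_ctrl = 5, n_kd = 5,
                           n_up = 84, n_down = 73,
                           effect_log2fc = 1.5, sigma = 0.3, seed = 1) {
  if (n_up + n_down > n_genes) {
    rlang::abort("n_up + n_down must not exceed n_genes.")
  }
  if (n_ctrl < 2 || n_kd < 2) rlang::abort("need at least 2 samples per group.")
  if (effect_log2fc < 0 || sigma <= 0) {
    rlang::abort("effect_log2fc must be >= 0 and sigma > 0.")
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- c(sprintf("ctrl_%02d", seq_len(n_ctrl)), sprintf("kd_%02d", seq_len(n_kd)))
  group <- rep(c("ctrl", "kd"), c(n_ctrl, n_kd))
  withr::with_seed(seed, {
    planted <- sample(genes, n_up + n_down)
    up <- planted[seq_len(n_up)]
    down <- planted[n_up + seq_len(n_down)]
    baseline <- stats::rnorm(n_genes, mean = 8, sd = 2)
    vals <- baseline + matrix(
      stats::rnorm(n_genes * length(samples), sd = sigma),
      n_genes, length(samples)
    )
    shift <- numeric(n_genes)
    names(shift) <- genes
    shift[up] <- effect_log2fc
    shift[down] <- -effect_log2fc
    vals[, group == "kd"] <- vals[, group == "kd"] + shift
  })
  dimnames(vals) <- list(genes, samples)
  list(
    expr = expr_matrix(vals, scale = "log2"),
    groups = tibble::tibble(sample_id = samples, group = group),
    truth = list(
      up_genes = up, down_genes = down,
      effect_log2fc = effect_log2fc, sigma = sigma
    )
  )
}

#' Simulate a patient cohort whose hazard tracks signature activity
#'
#' Each patient carries a latent signature activity `a ~ N(0, 1)`. Signature
#' up-genes are shifted by `+a * effect` and down-genes by `-a * effect` on
#' the log2 scale, so a high-activity patient resembles the knockdown state
#' and receives a high KD score. Survival is exponential with hazard
#' `baseline_hazard * exp(-beta * a)`: with `beta > 0`, high activity (high
#' score) means lower hazard, i.e. the low-score group has the worse
#' prognosis. Censoring is independent exponential with rate `censor_rate`.
#'
#' @param signature A [kd_signature] whose genes will be planted.
#' @param n_patients Cohort size.
#' @param beta Log-hazard effect per unit latent activity (0 = null cohort).
#' @param baseline_hazard Baseline event rate per month (> 0).
#' @param censor_rate Rate of the independent exponential censoring process
#'   (>= 0; 0 disables censoring).
#' @param effect Expression shift per unit activity (log2 units).
#' @param sigma Residual within-gene standard deviation on the log2 scale.
#' @param n_extra_genes Background genes unrelated to the signature.
#' @param seed Integer seed.
#' @return A list with elements `expr` ([expr_matrix], log2), `clinical`
#'   (a `clinical_table` tibble: `sample_id`, `time` in months, `event`) and
#'   `truth` (list: `activity`, `beta`, `baseline_hazard`, `censor_rate`).
#' @export
make_cohort <- function(signature, n_patients = 200, beta = 1,
                        baseline_hazard = 0.02, censor_rate = 0.01,
                        effect = 1.0, sigma = 0.3, n_extra_genes = 100,
                        seed = 1) {
  stopifnot(inherits(signature, "kd_signature"))
  if (baseline_hazard <= 0) rlang::abort("baseline_hazard must be > 0.")
  if (censor_rate < 0) rlang::abort("censor_rate must be >= 0.")
  if (n_patients < 2) rlang::abort("need at least 2 patients.")
  sig_genes <- c(signature$up, signature$down)
  genes <- c(sig_genes, sprintf("bg%04d", seq_len(n_extra_genes)))
  samples <- sprintf("p%04d", seq_len(n_patients))
  dir <- c(
    rep(1, length(signature$up)), rep(-1, length(signature$down)),
    rep(0, n_extra_genes)
  )
  withr::with_seed(seed, {
    activity <- stats::rnorm(n_patients)
    baseline <- stats::rnorm(length(genes), mean = 8, sd = 2)
    vals <- baseline +
      outer(dir * effect, activity) +
      matrix(stats::rnorm(length(genes) * n_patients, sd = sigma),
             length(genes), n_patients)
    t_event <- stats::rexp(n_patients, rate = baseline_hazard * exp(-beta * activity))
    t_cens <- if (censor_rate > 0) stats::rexp(n_patients, rate = censor_rate) else rep(Inf, n_patients)
  })
  dimnames(vals) <- list(genes, samples)
  clinical <- tibble::tibble(
    sample_id = samples,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
  attr(clinical, "time_unit") <- "months"
  class(clinical) <- c("clinical_table", class(clinical))
  list(
    expr = expr_matrix(vals, scale = "log2"),
    clinical = clinical,
    truth = list(
      activity = stats::setNames(activity, samples), beta = beta,
      baseline_hazard = baseline_hazard, censor_rate = censor_rate
    )
  )
}

#' Simulate a VIM/CDH1 marker panel across EMT phenotypes
#'
#' Draws linear-scale VIM and CDH1 expression for epithelial, mesenchymal and
#' EMT-intermediate cell lines. Epithelial lines are drawn so their VIM/CDH1
#' ratio falls below 2 with high probability (log2 ratio ~ N(-2, 0.7)),
#' mesenchymal lines above 2 (log2 ratio ~ N(3, 0.7)), and intermediate
#' lines uniformly inside a band straddling the ratio-2 boundary. The default
#' panel sizes (27 epithelial, 19 mesenchymal, 6 intermediate) match a
#' typical breast-cancer cell line panel. The band the intermediates were
#' drawn from is returned in the truth record so [classify_emt()] can be run
#' with an explicit `intermediate_band`.
#'
#' @param n_epithelial,n_mesenchymal,n_intermediate Panel sizes (>= 0, not all 0).
#' @param seed Integer seed.
#' @return A list with elements `expr` (linear-scale [expr_matrix] with rows
#'   `VIM`, `CDH1`), `labels` (tibble `sample_id`, `subtype`) and `truth`
#'   (list with the `band` of intermediate VIM/CDH1 ratios).
#' @export
make_marker_panel <- function(n_epithelial = 27, n_mesenchymal = 19,
                              n_intermediate = 6, seed = 1) {
  n <- c(n_epithelial, n_mesenchymal, n_intermediate)
  if (any(n < 0) || sum(n) == 0) rlang::abort("panel sizes must be >= 0 and not all zero.")
  subtype <- rep(c("epithelial", "mesenchymal", "intermediate"), n)
  samples <- sprintf("cl%03d", seq_along(subtype))
  band_log2 <- c(0.55, 1.45)  # intermediates live here; boundary log2(2) = 1
  withr::with_seed(seed, {
    log2_ratio <- c(
      stats::rnorm(n_epithelial, mean = -2, sd = 0.7),
      stats::rnorm(n_mesenchymal, mean = 3, sd = 0.7),
      stats::runif(n_intermediate, band_log2[1], band_log2[2])
    )
    cdh1 <- 2^stats::rnorm(length(subtype), mean = 7, sd = 1)
  })
  vim <- cdh1 * 2^log2_ratio
  vals <- rbind(VIM = vim, CDH1 = cdh1)
  colnames(vals) <- samples
  list(
    expr = expr_matrix(vals, scale = "linear"),
    labels = tibble::tibble(sample_id = samples, subtype = subtype),
    truth = list(band = 2^c(0.5, 1.5))
  )
}
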