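#' Default pipeline configuration
#'
#' Returns the fully-populated default configuration for [run_all()]: a
#' synthetic discovery experiment (1000 genes, 5 vs 5 samples, 84 planted up
#' and 73 planted down genes at 1.5 log2FC), a 2-fold signature cutoff, a
#' 200-patient synthetic cohort whose hazard decreases with latent signature
#' activity, median-split survival analysis and preranked GSEA of the
#' signature lists against a score-correlation ranking. Any subset of these
#' fields can be overridden by the user config; file-based inputs replace
#' the `simulate` blocks with `expr` / `groups` / `clinical` / `gmt` paths.
#'
#' @return A nested list of configuration defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    discovery = list(
      scale = "log2",
      simulate = list(
        n_genes = 1000, n_ctrl = 5, n_kd = 5, n_up = 84, n_down = 73,
        effect_log2fc = 1.5, sigma = 0.3
      )
    ),
    signature = list(cutoff_fold = 2),
    cohort = list(
      scale = "log2",
      simulate = list(
        n_patients = 200, beta = 1, baseline_hazard = 0.02,
        censor_rate = 0.01, effect = 1.0, sigma = 0.3, n_extra_genes = 100
      )
    ),
    scoring = list(normalize = FALSE),
    survival = list(enabled = TRUE, rule = "median", n_perm = 1000),
    gsea = list(enabled = TRUE, n_perm = 1000, weight = 1)
  )
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) rlang::abort(sprintf("config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merged <- utils::modifyList(default_run_config(), config)
  # file-based inputs replace the simulation defaults outright
  if (!is.null(config$discovery$expr) && is.null(config$discovery$simulate)) {
    merged$discovery$simulate <- NULL
  }
  if (!is.null(config$cohort$expr) && is.null(config$cohort$simulate)) {
    merged$cohort$simulate <- NULL
  }
  merged
}

# Every referenced input must exist before any stage runs.
preflight_check <- function(cfg) {
  paths <- c(
    cfg$discovery$expr, cfg$discovery$groups, cfg$signature$path,
    cfg$cohort$expr, cfg$cohort$clinical, cfg$gsea$gmt
  )
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0L) {
    rlang::abort(paste0("configured input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (is.null(cfg$discovery$simulate) && is.null(cfg$discovery$expr) &&
      is.null(cfg$signature$path)) {
    rlang::abort("no signature source: configure discovery (simulate or expr/groups) or signature$path.")
  }
  if (is.null(cfg$cohort$simulate) && is.null(cfg$cohort$expr)) {
    rlang::abort("no cohort source: configure cohort$simulate or cohort$expr.")
  }
  if (isTRUE(cfg$survival$enabled) && is.null(cfg$cohort$simulate) &&
      is.null(cfg$cohort$clinical)) {
    rlang::abort("survival stage enabled but no clinical data configured.")
  }
  invisible(cfg)
}

#' Run the full knockdown-signature pipeline
#'
#' Executes the analysis end to end from a single declarative configuration:
#' (1) obtain a discovery experiment (simulated or loaded), (2) derive the
#' up/down signature by fold-change cutoff, (3) obtain a patient cohort,
#' (4) z-score the cohort and compute per-patient KD scores, (5) stratify
#' and run Kaplan-Meier + log-rank survival analysis, (6) preranked GSEA of
#' the signature lists (or a supplied GMT) on a score-correlation ranking.
#' All randomness derives from the single configured seed, so a rerun with
#' the same config reproduces every output file byte for byte.
#'
#' @param config A config list or path to a YAML file; unspecified fields
#'   fall back to [default_run_config()]. Any stage error aborts the run
#'   naming the stage.
#' @param out_dir Output directory for the run artifacts (created if
#'   needed). Defaults to `config$out_dir`, else a temp directory.
#' @return The output directory path, invisibly. Artifacts written:
#'   `signature.tsv`, `scores.csv`, `groups.csv`, `km_curves.csv`,
#'   `logrank.json`, `gsea_results.csv`, `manifest.json`, `run.log`.
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  cfg <- load_run_config(config)
  preflight_check(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("kdsig_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    cat(sprintf("%s: %s\n", stage, msg), file = log_path, append = TRUE)
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), parent = e)
    })
  }
  seed <- as.integer(cfg$seed)
  stages <- list()

  # 1. discovery -------------------------------------------------------------
  sig <- NULL
  disc <- NULL
  if (!is.null(cfg$signature$path)) {
    disc_desc <- "skipped (signature loaded from file)"
  } else {
    disc <- stage_wrap("discovery", {
      if (!is.null(cfg$discovery$simulate)) {
        do.call(make_discovery, c(cfg$discovery$simulate, list(seed = seed)))
      } else {
        list(
          expr = read_expression(cfg$discovery$expr, scale = cfg$discovery$scale),
          groups = readr::read_csv(cfg$discovery$groups, show_col_types = FALSE),
          truth = NULL
        )
      }
    })
    disc_desc <- sprintf("%d genes x %d samples", nrow(disc$expr), ncol(disc$expr))
  }
  say("discovery", disc_desc)
  stages$discovery <- disc_desc

  # 2. signature --------------------------------------------------------------
  sig <- stage_wrap("signature", {
    if (!is.null(cfg$signature$path)) {
      read_signature(cfg$signature$path)
    } else {
      fc <- fold_changes(disc$expr, disc$groups)
      build_signature(
        fc, cutoff_fold = cfg$signature$cutoff_fold,
        expr = disc$expr, groups = disc$groups, q_max = cfg$signature$q_max
      )
    }
  })
  write_signature(sig, file.path(out_dir, "signature.tsv"))
  sig_desc <- sprintf("%d up / %d down genes", length(sig$up), length(sig$down))
  say("signature", sig_desc)
  stages$signature <- sig_desc

  # 3. cohort ------------------------------------------------------------------
  cohort <- stage_wrap("cohort", {
    if (!is.null(cfg$cohort$simulate)) {
      do.call(make_cohort, c(list(signature = sig), cfg$cohort$simulate,
                             list(seed = seed + 1L)))
    } else {
      list(
        expr = read_expression(cfg$cohort$expr, scale = cfg$cohort$scale),
        clinical = if (!is.null(cfg$cohort$clinical)) read_clinical(cfg$cohort$clinical),
        truth = NULL
      )
    }
  })
  cohort_desc <- sprintf("%d genes x %d patients", nrow(cohort$expr), ncol(cohort$expr))
  say("cohort", cohort_desc)
  stages$cohort <- cohort_desc

  # 4. scoring -----------------------------------------------------------------
  scores <- stage_wrap("scoring", {
    z <- zscore_by_gene(cohort$expr)
    kd_score(z, sig, normalize = isTRUE(cfg$scoring$normalize))
  })
  readr::write_csv(scores, file.path(out_dir, "scores.csv"), progress = FALSE)
  say("scoring", sprintf("%d KD scores", nrow(scores)))
  stages$scoring <- sprintf("%d KD scores", nrow(scores))

  # 5. survival ----------------------------------------------------------------
  if (isTRUE(cfg$survival$enabled)) {
    surv <- stage_wrap("survival", {
      if (identical(cfg$survival$rule, "best_cutoff")) {
        bc <- best_cutoff(scores, cohort$clinical,
                          n_perm = cfg$survival$n_perm, seed = seed + 2L)
        grouped <- bc$groups
        lr <- logrank_test(grouped)
        list(grouped = grouped, lr = lr, cutoff = glance(bc))
      } else {
        strat <- stratify(scores, rule = cfg$survival$rule,
                          cutoff = cfg$survival$cutoff)
        grouped <- join_scores_clinical(strat, cohort$clinical)
        grouped$group <- strat$group[match(grouped$sample_id, strat$sample_id)]
        lr <- logrank_test(grouped)
        list(grouped = grouped, lr = lr, cutoff = NULL)
      }
    })
    readr::write_csv(surv$grouped, file.path(out_dir, "groups.csv"), progress = FALSE)
    km <- km_estimate(surv$grouped)
    readr::write_csv(tibble::as_tibble(km), file.path(out_dir, "km_curves.csv"), progress = FALSE)
    jsonlite::write_json(
      c(
        as.list(glance(surv$lr)),
        list(observed = surv$lr$observed, expected = surv$lr$expected,
             rule = cfg$survival$rule, best_cutoff = surv$cutoff)
      ),
      file.path(out_dir, "logrank.json"), auto_unbox = TRUE, digits = NA
    )
    surv_desc <- sprintf("log-rank chi^2 = %.3g, p = %.3g", surv$lr$chi_square, surv$lr$p_value)
    say("survival", surv_desc)
    stages$survival <- surv_desc
  } else {
    say("survival", "disabled")
    stages$survival <- "disabled"
  }

  # 6. gsea ---------------------------------------------------------------------
  if (isTRUE(cfg$gsea$enabled)) {
    gres <- stage_wrap("gsea", {
      ranked <- rank_genes(cohort$expr, scores, metric = "pearson")
      sets <- if (!is.null(cfg$gsea$gmt)) {
        read_gmt(cfg$gsea$gmt)
      } else {
        tibble::tibble(
          set = c("SIGNATURE_UP", "SIGNATURE_DOWN"),
          description = c("signature up-regulated genes", "signature down-regulated genes"),
          genes = list(sig$up, sig$down)
        )
      }
      gsea(ranked, sets, n_perm = cfg$gsea$n_perm, seed = seed + 3L,
           weight = cfg$gsea$weight)
    })
    readr::write_csv(tidy(gres), file.path(out_dir, "gsea_results.csv"), progress = FALSE)
    gsea_desc <- sprintf("%d gene sets tested", nrow(gres))
    say("gsea", gsea_desc)
    stages$gsea <- gsea_desc
  } else {
    say("gsea", "disabled")
    stages$gsea <- "disabled"
  }

  manifest <- list(
    package = "kdsig",
    version = as.character(utils::packageVersion("kdsig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = rlang::hash(cfg),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("manifest", sprintf("%d stages recorded", length(stages)))
  invisible(out_dir)
}

#' Summarise a completed pipeline run
#'
#' Reads the artifacts of a [run_all()] directory and renders a markdown
#' summary: signature sizes, KD-score distribution quantiles, the log-rank
#' chi-square / p / hazard ratio (when the survival stage ran) and the top
#' enriched gene sets. Optionally re-draws the Kaplan-Meier plot to a file.
#'
#' @param run_dir Directory produced by [run_all()].
#' @param plot Also write `km.png` into `run_dir` (default FALSE).
#' @return The report text (character vector of markdown lines), invisibly;
#'   the same text is written to `report.md` in `run_dir`.
#' @export
report <- function(run_dir, plot = FALSE) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    rlang::abort(sprintf("'%s' is not a completed run: missing manifest.json.", run_dir))
  }
  manifest <- jsonlite::read_json(manifest_path)
  need <- c("signature.tsv", "scores.csv")
  if (!identical(manifest$stages$survival, "disabled")) {
    need <- c(need, "groups.csv", "km_curves.csv", "logrank.json")
  }
  if (!identical(manifest$stages$gsea, "disabled")) need <- c(need, "gsea_results.csv")
  absent <- need[!file.exists(file.path(run_dir, need))]
  if (length(absent) > 0L) {
    rlang::abort(paste0("incomplete run, missing artifact(s): ", paste(absent, collapse = ", ")))
  }
  sig <- read_signature(file.path(run_dir, "signature.tsv"))
  scores <- readr::read_csv(file.path(run_dir, "scores.csv"), show_col_types = FALSE)
  q <- stats::quantile(scores$kd_score, c(0, 0.25, 0.5, 0.75, 1))
  lines <- c(
    "# kdsig run report",
    "",
    sprintf("- seed: %s; package version: %s", manifest$seed, manifest$version),
    sprintf("- signature: %d up / %d down genes", length(sig$up), length(sig$down)),
    sprintf(
      "- KD score over %d samples: min %.2f, Q1 %.2f, median %.2f, Q3 %.2f, max %.2f",
      nrow(scores), q[1], q[2], q[3], q[4], q[5]
    )
  )
  if (!identical(manifest$stages$survival, "disabled")) {
    lr <- jsonlite::read_json(file.path(run_dir, "logrank.json"))
    lines <- c(
      lines, "",
      "## Survival",
      sprintf(
        "- log-rank: chi-square = %.4g (df %s), p = %.4g, HR (O/E) = %.3g",
        lr$chi_square, lr$df, lr$p_value, lr$hr_estimate
      ),
      sprintf("- stratification rule: %s", lr$rule)
    )
    if (plot) {
      km <- readr::read_csv(file.path(run_dir, "km_curves.csv"), show_col_types = FALSE)
      class(km) <- c("kdsig_km", class(km))
      ggplot2::ggsave(file.path(run_dir, "km.png"), autoplot(km),
                      width = 6, height = 4, dpi = 150)
      lines <- c(lines, "- Kaplan-Meier plot: km.png")
    }
  }
  if (!identical(manifest$stages$gsea, "disabled")) {
    g <- readr::read_csv(file.path(run_dir, "gsea_results.csv"), show_col_types = FALSE)
    g <- g[order(g$p_nominal, -abs(g$nes)), ]
    top <- utils::head(g, 5)
    lines <- c(
      lines, "",
      "## Enrichment",
      sprintf(
        "- %s: ES = %.3f, NES = %.2f, p = %.3g",
        top$set, top$es, top$nes, top$p_nominal
      )
    )
  }
  writeLines(lines, file.path(run_dir, "report.md"))
  invisible(lines)
}
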