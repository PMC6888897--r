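#' Kaplan-Meier step plot
#'
#' @param object A `kdsig_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot: one survival step curve per group, starting at 1.
#' @method autoplot kdsig_km
#' @export
autoplot.kdsig_km <- function(object, ...) {
  # prepend the (0, 1) anchor so every curve starts at full survival
  anchors <- dplyr::distinct(object, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(
    anchors,
    dplyr::select(object, "group", "time", "survival")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival, colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = "Group") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kdsig_km
#' @param data A data frame with `time`, `event` and optional `group`.
#' @export
plot_km <- function(data, ...) autoplot.kdsig_km(km_estimate(data), ...)

#' Enrichment running-sum plot
#'
#' Draws the running enrichment walk for one gene set, with hit positions as
#' a rug along the axis.
#'
#' @param object A `kdsig_es` from [enrichment_score()], or a `kdsig_gsea`
#'   row selected via `set`.
#' @param set When `object` is a `kdsig_gsea` table, the set name to plot.
#' @param ... Unused.
#' @return A ggplot of the running sum against list position.
#' @method autoplot kdsig_es
#' @export
autoplot.kdsig_es <- function(object, ...) {
  df <- tibble::tibble(
    position = seq_along(object$running_sum),
    running_sum = object$running_sum
  )
  hits <- tibble::tibble(position = object$hit_positions)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = .data$position),
                      sides = "b", inherit.aes = FALSE, length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "Rank position", y = "Running enrichment score") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kdsig_es
#' @method autoplot kdsig_gsea
#' @export
autoplot.kdsig_gsea <- function(object, set, ...) {
  i <- match(set, object$set)
  if (is.na(i)) rlang::abort(sprintf("set '%s' not found in GSEA results.", set))
  es_obj <- structure(
    list(
      es = object$es[i], running_sum = object$running_sum[[i]],
      hit_positions = object$hit_positions[[i]], n_hits = object$size[i]
    ),
    class = "kdsig_es"
  )
  autoplot.kdsig_es(es_obj) +
    ggplot2::ggtitle(sprintf("%s  (NES = %.2f, p = %.3g)",
                             set, object$nes[i], object$p_nominal[i]))
}

#' Score distribution by stratification group
#'
#' @param scores A stratified score tibble from [stratify()] (columns
#'   `kd_score`, `group`).
#' @param score_col Score column name.
#' @return A ggplot jitter/box view of scores per group.
#' @export
plot_scores <- function(scores, score_col = "kd_score") {
  ggplot2::ggplot(scores, ggplot2::aes(.data$group, .data[[score_col]], colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "Group", y = "KD score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
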