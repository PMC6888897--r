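#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Join per-sample scores onto a clinical table, preserving clinical row order.
join_scores_clinical <- function(scores, clinical, score_col = "kd_score") {
  stopifnot(all(c("sample_id", "time", "event") %in% names(clinical)))
  if (is.numeric(scores)) {
    scores <- tibble::tibble(sample_id = names(scores), kd_score = unname(scores))
  }
  clin <- tibble::as_tibble(clinical)
  clin <- clin[, setdiff(names(clin), score_col), drop = FALSE]  # avoid .x/.y clash
  merged <- dplyr::inner_join(
    clin,
    tibble::as_tibble(scores)[, c("sample_id", score_col)],
    by = "sample_id"
  )
  if (nrow(merged) == 0L) rlang::abort("no samples shared between scores and clinical table.")
  merged
}
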