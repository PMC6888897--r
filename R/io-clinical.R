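#' Read a clinical follow-up table
#'
#' Reads a CSV with the required columns `sample_id`, `time` (non-negative
#' follow-up, months by default) and `event` (1 = event observed, 0 =
#' censored). Any extra columns are carried along as covariates (subtype,
#' grade, tumour size class, ...). Times are never converted between units;
#' the declared unit travels as an attribute.
#'
#' @param path Path to a CSV file.
#' @param time_unit Unit of the `time` column, recorded as metadata
#'   (default `"months"`).
#' @return A tibble of class `clinical_table` with attribute `time_unit`.
#' @export
read_clinical <- function(path, time_unit = "months") {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "time", "event")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    rlang::abort(paste0("clinical table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  validate_clinical(tbl)
  attr(tbl, "time_unit") <- time_unit
  class(tbl) <- c("clinical_table", class(tbl))
  tbl
}

validate_clinical <- function(tbl) {
  if (anyDuplicated(tbl$sample_id)) {
    rlang::abort("clinical table has duplicated sample_id values.")
  }
  bad_time <- which(!is.finite(tbl$time) | tbl$time < 0)
  bad_event <- which(!tbl$event %in% c(0, 1))
  if (length(bad_time) > 0L || length(bad_event) > 0L) {
    msgs <- c(
      if (length(bad_time) > 0L) {
        sprintf("negative or non-finite time in row(s): %s", paste(bad_time, collapse = ", "))
      },
      if (length(bad_event) > 0L) {
        sprintf("event not in {0, 1} in row(s): %s", paste(bad_event, collapse = ", "))
      }
    )
    rlang::abort(paste(msgs, collapse = "; "))
  }
  invisible(tbl)
}

#' Write a clinical follow-up table
#'
#' @param tbl A `clinical_table` (or tibble with `sample_id`, `time`, `event`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(tbl, path) {
  readr::write_csv(tibble::as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}

#' Covariate columns of a clinical table
#'
#' @param tbl A `clinical_table`.
#' @return Character vector of covariate column names (possibly empty).
#' @export
clinical_covariates <- function(tbl) {
  setdiff(names(tbl), c("sample_id", "time", "event"))
}
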