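#' Read a gene set collection in GMT format
#'
#' Parses the standard GMT dialect: one set per line, tab-separated as
#' `name <TAB> description <TAB> gene <TAB> gene ...`. Member lists are
#' deduplicated preserving first occurrence.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble of class `gene_set_collection` with columns `set`
#'   (character), `description` (character) and `genes` (list of character
#'   vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) rlang::abort("GMT file contains no gene sets.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", short[1]))
  }
  out <- tibble::tibble(
    set = purrr::map_chr(fields, 1),
    description = purrr::map_chr(fields, 2),
    genes = purrr::map(fields, ~ unique(.x[-(1:2)]))
  )
  if (anyDuplicated(out$set)) rlang::abort("duplicate gene set names in GMT file.")
  if (any(lengths(out$genes) == 0L)) rlang::abort("GMT file contains an empty gene set.")
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Write a gene set collection in GMT format
#'
#' @param sets A `gene_set_collection` tibble (or any tibble with `set`,
#'   `description`, `genes` columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(c("set", "description", "genes") %in% names(sets)))
  lines <- purrr::pmap_chr(
    sets[c("set", "description", "genes")],
    function(set, description, genes) paste(c(set, description, genes), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
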