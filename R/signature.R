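#' Up/down knockdown signature
#'
#' A signature is two disjoint gene lists: genes up-regulated in the
#' knockdown (or case) condition and genes down-regulated. The per-sample KD
#' score is later computed as sum of z-scores over `up` minus sum over `down`.
#'
#' @param up Character vector of genes higher in the knockdown condition.
#' @param down Character vector of genes lower in the knockdown condition.
#' @param meta Optional named list of provenance metadata (cutoff used, group
#'   sizes, source description).
#' @return An object of class `kd_signature`.
#' @examples
#' sig <- kd_signature(up = c("VIM", "SNAI2"), down = c("CDH1"))
#' sig
#' @export
kd_signature <- function(up, down, meta = list()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  up <- up[nzchar(up)]
  down <- down[nzchar(down)]
  if (length(up) + length(down) == 0L) rlang::abort("signature has no genes.")
  both <- intersect(up, down)
  if (length(both) > 0L) {
    rlang::abort(paste0(
      "gene(s) listed in both directions: ", paste(both, collapse = ", ")
    ))
  }
  structure(list(up = up, down = down, meta = meta), class = "kd_signature")
}

#' @export
print.kd_signature <- function(x, ...) {
  cat("<kd_signature> ", length(x$up), " up / ", length(x$down), " down genes\n", sep = "")
  if (!is.null(x$meta$cutoff_fold)) cat("  fold-change cutoff: ", x$meta$cutoff_fold, "\n", sep = "")
  invisible(x)
}

#' Read / write a signature as two-column text
#'
#' The on-disk format is a two-column TSV with header `gene`, `direction`
#' and direction values in `{up, down}`. Writing then reading gives back an
#' identical signature.
#'
#' @param sig A [kd_signature].
#' @param path File path.
#' @return `read_signature()` returns a [kd_signature]; `write_signature()`
#'   returns `path` invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "kd_signature"))
  tbl <- tibble::tibble(
    gene = c(sig$up, sig$down),
    direction = rep(c("up", "down"), c(length(sig$up), length(sig$down)))
  )
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(gene = readr::col_character(), direction = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("gene", "direction") %in% names(tbl))) {
    rlang::abort("signature file must have columns `gene` and `direction`.")
  }
  bad <- which(!tbl$direction %in% c("up", "down"))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "direction '%s' (row %d) is not 'up' or 'down'.", tbl$direction[bad[1]], bad[1]
    ))
  }
  kd_signature(
    up = tbl$gene[tbl$direction == "up"],
    down = tbl$gene[tbl$direction == "down"],
    meta = list(source = path)
  )
}
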