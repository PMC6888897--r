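#' Expression matrix with declared scale
#'
#' Constructs a validated genes-by-samples expression matrix. The matrix keeps
#' its measurement scale (`"log2"` or `"linear"`) as an attribute so that
#' downstream fold-change and scoring functions never have to guess how the
#' values were normalised.
#'
#' Invariants enforced: unique gene and sample identifiers, no missing values,
#' and non-negative values when the scale is linear. Rows containing missing
#' values are dropped with a message (z-scores and fold changes are undefined
#' with gaps, and no imputation rule is assumed).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param scale Measurement scale of `values`: `"log2"` or `"linear"`.
#' @return A numeric matrix of class `expr_matrix` with a `scale` attribute.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' x <- expr_matrix(m, scale = "log2")
#' expr_scale(x)
#' @export
expr_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("`values` must have gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    rlang::abort("duplicate gene ids in expression matrix.")
  }
  if (anyDuplicated(colnames(values))) {
    rlang::abort("duplicate sample ids in expression matrix.")
  }
  incomplete <- !stats::complete.cases(values)
  if (any(incomplete)) {
    message(sum(incomplete), " gene row(s) with missing values dropped.")
    values <- values[!incomplete, , drop = FALSE]
  }
  if (nrow(values) == 0L) rlang::abort("expression matrix has no complete gene rows.")
  if (scale == "linear" && any(values < 0)) {
    rlang::abort("linear-scale expression values must be non-negative.")
  }
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) rlang::abort("object carries no `scale` attribute; use expr_matrix().")
  s
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> ", nrow(x), " genes x ", ncol(x), " samples, scale = ",
    expr_scale(x), "\n",
    sep = ""
  )
  n <- min(5L, nrow(x))
  m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids, a first column of gene ids, and numeric
#' expression values. Duplicate gene ids are collapsed by keeping the row with
#' the highest mean (the common microarray collapse convention), with a
#' warning. Empty cells are treated as missing and the whole gene row is
#' dropped with a message; any other non-numeric cell (including the literal
#' text `NA`) is a format error that names the offending gene and sample.
#' Sample order is preserved exactly as in the file.
#'
#' @param path Path to a TSV file (first column gene id, header = sample ids).
#' @param scale Declared scale of the stored values: `"log2"` or `"linear"`.
#' @return An [expr_matrix].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (ncol(raw) < 2L) rlang::abort("expression file needs a gene id column and at least one sample column.")
  genes <- raw[[1]]
  samples <- names(raw)[-1]
  if (any(samples == "" | grepl("^\\.\\.\\.", samples))) {
    rlang::abort("expression file is missing sample names in its header row.")
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rlang::abort(sprintf(
      "non-numeric value %s at gene '%s', sample '%s'.",
      dQuote(cells[bad[1, 1], bad[1, 2]]), genes[bad[1, 1]], samples[bad[1, 2]]
    ))
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    means <- rowMeans(num, na.rm = TRUE)
    ord <- order(-means)            # keep highest-mean row of each duplicate
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)              # restore input gene order among survivors
    rlang::warn(sprintf(
      "%d duplicate gene id(s) collapsed, keeping the highest-mean row.",
      nrow(num) - length(keep)
    ))
    num <- num[keep, , drop = FALSE]
  }
  expr_matrix(num, scale = scale)
}

#' Write an expression matrix to tab-separated text
#'
#' @param x An [expr_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  tbl <- tibble::as_tibble(unclass(x), rownames = "gene")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
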