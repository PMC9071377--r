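# FPKM matrix handling and tissue-predominance calls.

#' Construct an expression matrix
#'
#' @param values Numeric genes x tissues matrix of FPKM values (row and
#'   column names required). `NA` marks missing samples.
#' @param transformed Whether values are already log2(FPKM + 1).
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, transformed = FALSE) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L) .stopf("row names (gene ids) are required")
    rownames(values) <- character(0)
  }
  if (any(values < 0, na.rm = TRUE)) .stopf("FPKM values must be nonnegative")
  structure(list(values = values, transformed = transformed),
            class = "expression_matrix")
}

#' Log-transform an FPKM matrix
#'
#' Elementwise `log2(x + 1)`; missing values stay missing. Transforming twice
#' is a state error.
#'
#' @param m An [expression_matrix()].
#' @return The transformed matrix object.
#' @export
log_transform_matrix <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$transformed) .stopf("matrix is already log2(FPKM + 1)-transformed")
  if (any(m$values < 0, na.rm = TRUE)) .stopf("FPKM values must be nonnegative")
  expression_matrix(log2(m$values + 1), transformed = TRUE)
}

#' Call tissue-predominant expression
#'
#' A gene is predominant in `tissue` iff that tissue attains the unique row
#' maximum, the maximum reaches `min_expression` (linear FPKM), and exceeds
#' `fold_threshold` times the second-largest linear value. Margins are
#' computed on the linear scale; missing tissues are excluded. Rows with all
#' values missing are skipped with a warning.
#'
#' @param m A transformed [expression_matrix()].
#' @param tissue Tissue (column) to test.
#' @param fold_threshold Linear-scale fold margin over the runner-up tissue.
#' @param min_expression Minimum linear FPKM of the maximum.
#' @return Data frame (`gene`, `tissue`, `max_value`, `second_value` on the
#'   linear scale, `fold_margin`, `verdict`).
#' @export
call_tissue_predominance <- function(m, tissue, fold_threshold = 2,
                                     min_expression = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!tissue %in% colnames(m$values))
    .stopf("unknown tissue '%s' (have: %s)", tissue,
           paste(colnames(m$values), collapse = ", "))
  linear <- if (m$transformed) 2^m$values - 1 else m$values
  all_na <- rowSums(!is.na(linear)) == 0L
  if (any(all_na))
    .warnf("%d gene(s) with all-missing expression skipped", sum(all_na))
  linear <- linear[!all_na, , drop = FALSE]
  rows <- lapply(rownames(linear), function(g) {
    v <- linear[g, ]
    v <- v[!is.na(v)]
    mx <- max(v)
    top <- names(v)[v == mx]
    second <- if (length(v) > 1L) max(v[-which.max(v)]) else 0
    verdict <- length(top) == 1L && top == tissue && mx >= min_expression &&
      mx >= fold_threshold * second
    data.frame(gene = g, tissue = tissue, max_value = mx,
               second_value = second,
               fold_margin = if (second > 0) mx / second else Inf,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
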