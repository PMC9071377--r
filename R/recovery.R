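# Scoring of pipeline output against simulator ground truth.

#' Fraction of true ortholog groups recovered exactly
#'
#' A true OG counts as recovered iff some recovered OG has exactly the same
#' member set.
#'
#' @param truth_og Ground-truth membership (`gene`, `og`).
#' @param recovered Recovered membership (`gene`, `og`).
#' @return Fraction in `[0, 1]`.
#' @export
og_recovery <- function(truth_og, recovered) {
  canon <- function(d) {
    sets <- split(d$gene, d$og)
    unique(vapply(sets, function(g) paste(sort(g), collapse = "|"), character(1)))
  }
  ts <- canon(truth_og)
  rs <- canon(recovered)
  mean(ts %in% rs)
}

#' Fraction of planted tandem clusters recovered exactly
#'
#' @param truth_tdg Ground-truth cluster table (`species`, `cluster`,
#'   `gene`).
#' @param detected Detected cluster table in the same layout.
#' @return Fraction in `[0, 1]` (1 when nothing was planted and nothing
#'   detected).
#' @export
tandem_recovery <- function(truth_tdg, detected) {
  canon <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    sets <- split(d$gene, paste(d$species, d$cluster))
    unique(vapply(sets, function(g) paste(sort(g), collapse = "|"), character(1)))
  }
  ts <- canon(truth_tdg)
  rs <- canon(detected)
  if (!length(ts)) return(as.numeric(length(rs) == 0L))
  mean(ts %in% rs)
}

#' Fraction of genes whose predicted label matches the planted label
#'
#' @param truth Data frame (`gene`, label column).
#' @param predicted Data frame (`gene`, label column).
#' @param column Label column name present in both.
#' @return Fraction over the truth genes (missing predictions count as
#'   wrong).
#' @export
label_recovery <- function(truth, predicted, column) {
  pred <- stats::setNames(predicted[[column]], predicted$gene)
  mean(!is.na(pred[truth$gene]) & pred[truth$gene] == truth[[column]])
}
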