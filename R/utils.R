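# Internal helpers shared across modules.

.cucurbHLH_cache <- new.env(parent = emptyenv())

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    .stopf("invalid configuration: '%s' must be a single number >= %s", name, min)
  invisible(x)
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
#' @noRd
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Natural order for chromosome names: chr2 < chr10; unplaced scaffolds sort
# after real chromosomes, lexicographically.
#' @noRd
.chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.integer(sub("^[A-Za-z_]*", "", u)))
  has_num <- !is.na(num)
  ord <- c(u[has_num][order(num[has_num], u[has_num])], sort(u[!has_num]))
  match(as.character(chroms), ord)
}

#' @noRd
.roman_labels <- function(k) as.character(utils::as.roman(seq_len(k)))

# Canonical (sorted) two-column pair key, used to deduplicate symmetric pairs.
#' @noRd
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
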