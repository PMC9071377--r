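# Global pairwise protein alignment (Needleman-Wunsch with affine gaps,
# Gotoh three-state recursion) and back-translation to a codon alignment.

#' @noRd
.default_substitution <- function() {
  if (is.null(.cucurbHLH_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cucurbHLH_cache$blosum62 <- e$BLOSUM62
  }
  .cucurbHLH_cache$blosum62
}

#' Optimal global protein alignment with affine gap costs
#'
#' Three-state Gotoh dynamic programme maximizing
#' `sum(substitution scores) - sum(gap_open + L * gap_extend)` over gap runs of
#' length `L`. Gap-state crossings are allowed, so the optimum is taken over
#' all alignments. Ties are resolved deterministically during traceback
#' (match preferred over a gap in `a`, preferred over a gap in `b`).
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param substitution Substitution score matrix; defaults to BLOSUM62.
#' @param gap_open,gap_extend Nonnegative gap penalties; a gap run of length
#'   `L` costs `gap_open + L * gap_extend`.
#' @return List with gapped strings `a` and `b` (equal length, no gap-gap
#'   column) and the optimal `score`.
#' @export
align_proteins_global <- function(a, b, substitution = NULL,
                                  gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) .stopf("alignment requires non-empty sequences")
  sub <- if (is.null(substitution)) .default_substitution() else substitution
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  bad <- setdiff(c(av, bv), rownames(sub))
  if (length(bad)) .stopf("invalid residues for the substitution matrix: %s",
                          paste(unique(bad), collapse = ", "))
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  if (n > 0) Ix[2:(n + 1), 1] <- -(gap_open + seq_len(n) * gap_extend)
  if (m > 0) Iy[1, 2:(m + 1)] <- -(gap_open + seq_len(m) * gap_extend)
  smat <- sub[av, bv, drop = FALSE]
  jj <- seq_len(m) + 1L
  for (i in seq_len(n) + 1L) {
    best_prev <- pmax(M[i - 1L, jj - 1L], Ix[i - 1L, jj - 1L], Iy[i - 1L, jj - 1L])
    M[i, jj] <- smat[i - 1L, ] + best_prev
    Ix[i, jj] <- pmax(pmax(M[i - 1L, jj], Iy[i - 1L, jj]) - gap_open - gap_extend,
                      Ix[i - 1L, jj] - gap_extend)
    # Iy along the row via running maximum of B[k] + k*ext, B = max(M, Ix)
    Bk <- pmax(M[i, ], Ix[i, ]) + (0:m) * gap_extend
    run <- cummax(Bk)
    Iy[i, jj] <- run[jj - 1L] - gap_open - (jj - 1L) * gap_extend
  }
  # traceback; state preference: M, then Iy (gap in a), then Ix (gap in b)
  eps <- 1e-9
  i <- n + 1L; j <- m + 1L
  fin <- c(M = M[i, j], Iy = Iy[i, j], Ix = Ix[i, j])
  state <- names(fin)[which.max(fin + c(2, 1, 0) * eps)]
  score <- max(fin)
  ga <- character(0); gb <- character(0)
  while (i > 1L || j > 1L) {
    if (state == "M") {
      ga <- c(av[i - 1L], ga); gb <- c(bv[j - 1L], gb)
      prev <- c(M = M[i - 1L, j - 1L], Iy = Iy[i - 1L, j - 1L], Ix = Ix[i - 1L, j - 1L])
      state <- names(prev)[which.max(prev + c(2, 1, 0) * eps)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {
      ga <- c(av[i - 1L], ga); gb <- c("-", gb)
      cand <- c(M = M[i - 1L, j] - gap_open - gap_extend,
                Iy = Iy[i - 1L, j] - gap_open - gap_extend,
                Ix = Ix[i - 1L, j] - gap_extend)
      state <- names(cand)[which.max(cand + c(2, 1, 0) * eps)]
      i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(bv[j - 1L], gb)
      cand <- c(M = M[i, j - 1L] - gap_open - gap_extend,
                Ix = Ix[i, j - 1L] - gap_open - gap_extend,
                Iy = Iy[i, j - 1L] - gap_extend)
      state <- names(cand)[which.max(cand + c(2, 0, 1) * eps)]
      j <- j - 1L
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""), score = score)
}

#' @noRd
.as_codon_vector <- function(cds) {
  if (length(cds) == 1L && nchar(cds[1]) > 3L) split_codons(cds) else cds
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column expands to the source codon of the respective CDS,
#' or to a 3-nt gap (`"---"`) where the protein row is gapped.
#'
#' @param paln Pairwise protein alignment from [align_proteins_global()] (or
#'   any list with gapped strings `a`, `b`).
#' @param cds_a,cds_b Codon vectors (or nucleotide strings) whose translations
#'   equal the ungapped proteins; a trailing stop codon is tolerated.
#' @return List with `codons_a`, `codons_b` (equal-length codon vectors).
#' @export
backtranslate_codon_alignment <- function(paln, cds_a, cds_b) {
  ca <- validate_codon_sequence(.as_codon_vector(cds_a))
  cb <- validate_codon_sequence(.as_codon_vector(cds_b))
  expand <- function(gapped, codons, label) {
    res <- strsplit(gapped, "")[[1]]
    ungapped <- res[res != "-"]
    if (length(ungapped) != length(codons))
      .stopf("CDS of %s has %d codons but the aligned protein has %d residues",
             label, length(codons), length(ungapped))
    aa <- .codon_aa()[codons]
    mism <- which(aa != ungapped)
    if (length(mism))
      .stopf("translation mismatch for %s at codon %d: codon %s encodes %s, protein has %s",
             label, mism[1], codons[mism[1]], aa[mism[1]], ungapped[mism[1]])
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  list(codons_a = expand(paln$a, ca, "sequence a"),
       codons_b = expand(paln$b, cb, "sequence b"))
}

#' Ungapped protein identity between two equal-length sequences
#' @noRd
.protein_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- min(length(av), length(bv))
  sum(av[seq_len(n)] == bv[seq_len(n)]) / n
}
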