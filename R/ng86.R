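# Nei-Gojobori (1986) counting of synonymous and nonsynonymous sites and
# differences, with Jukes-Cantor multiple-hit correction.

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' @noRd
.codon_aa <- function() {
  if (is.null(.cucurbHLH_cache$codon_aa))
    .cucurbHLH_cache$codon_aa <- Biostrings::GENETIC_CODE
  .cucurbHLH_cache$codon_aa
}

#' @noRd
.nucs <- c("A", "C", "G", "T")

# Single-nucleotide neighbours of a codon at one position.
#' @noRd
.codon_neighbours <- function(codon, pos) {
  base <- substr(codon, pos, pos)
  vapply(setdiff(.nucs, base), function(n) {
    out <- codon
    substr(out, pos, pos) <- n
    out
  }, character(1), USE.NAMES = FALSE)
}

# Per-codon synonymous site count. At each of the three positions the three
# possible changes are classified; changes creating a stop codon are excluded
# and the synonymous fraction is taken over the remaining changes, so every
# position contributes exactly one site and S + N = 3 per codon.
#' @noRd
.ng86_site_table <- function() {
  if (!is.null(.cucurbHLH_cache$ng86_sites)) return(.cucurbHLH_cache$ng86_sites)
  aa <- .codon_aa()
  codons <- sense_codons()
  s <- vapply(codons, function(cd) {
    tot <- 0
    for (pos in 1:3) {
      nb <- .codon_neighbours(cd, pos)
      nb_aa <- aa[nb]
      valid <- nb_aa != "*"
      n_valid <- sum(valid)
      if (n_valid == 0L) next  # position contributes 0 syn (cannot occur in practice)
      tot <- tot + sum(nb_aa[valid] == aa[[cd]]) / n_valid
    }
    tot
  }, numeric(1))
  .cucurbHLH_cache$ng86_sites <- s
  s
}

# All orderings of k positions, k <= 3.
#' @noRd
.perms <- list(
  matrix(1L, 1, 1),
  matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE),
  matrix(c(1L, 2L, 3L, 1L, 3L, 2L, 2L, 1L, 3L,
           2L, 3L, 1L, 3L, 1L, 2L, 3L, 2L, 1L), 6, 3, byrow = TRUE)
)

# Average synonymous/nonsynonymous difference counts between two sense codons
# over all minimal mutational pathways, excluding pathways that pass through a
# stop codon (all pathways are used if every one is blocked, which cannot
# happen with <= 2 differences).
#' @noRd
.ng86_pair_diff <- function(c1, c2) {
  aa <- .codon_aa()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- .perms[[k]]
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  sd_all <- 0; nd_all <- 0
  for (r in seq_len(nrow(perms))) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in pos[perms[r, ]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (aa[[nxt]] == "*") blocked <- TRUE
      if (aa[[nxt]] == aa[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    sd_all <- sd_all + sd; nd_all <- nd_all + nd
    if (!blocked) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_valid <- n_valid + 1L
    }
  }
  if (n_valid > 0L) c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
  else c(sd = sd_all / nrow(perms), nd = nd_all / nrow(perms))
}

# Cached 61 x 61 Sd and Nd matrices over sense codons.
#' @noRd
.ng86_diff_tables <- function() {
  if (!is.null(.cucurbHLH_cache$ng86_diff)) return(.cucurbHLH_cache$ng86_diff)
  codons <- sense_codons()
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- .ng86_pair_diff(codons[i], codons[j])
    sd[i, j] <- d[["sd"]]
    nd[i, j] <- d[["nd"]]
  }
  .cucurbHLH_cache$ng86_diff <- list(sd = sd, nd = nd)
  .cucurbHLH_cache$ng86_diff
}

#' NG86 substitution-rate estimates for a pairwise codon alignment
#'
#' Implements the Nei-Gojobori (1986) method: per-codon synonymous site
#' fractions from single-mutation enumeration averaged over the two sequences,
#' difference counts averaged with equal weight over all minimal mutational
#' pathways (pathways through stop codons excluded), and the Jukes-Cantor
#' correction `d = -(3/4) log(1 - (4/3) p)`. Proportions `pS >= 3/4` or
#' `pN >= 3/4` cannot be corrected and set the saturation flag.
#'
#' @param aln A codon alignment as returned by
#'   [backtranslate_codon_alignment()]: a list with character vectors
#'   `codons_a` and `codons_b` of equal length, entries either sense codons or
#'   the gap `"---"`.
#' @return An object of class `ng86`: list with `S`, `N` (site counts), `Sd`,
#'   `Nd` (difference counts), `pS`, `pN`, `Ks`, `Ka`, `ratio` (`Ka/Ks`,
#'   `NA` when `Ks` is 0 or undefined), `saturated`, and `codons` (number of
#'   ungapped codon columns).
#' @export
compute_ng86 <- function(aln) {
  a <- aln$codons_a
  b <- aln$codons_b
  if (length(a) != length(b))
    .stopf("codon alignment rows have different lengths (%d vs %d)", length(a), length(b))
  keep <- a != "---" & b != "---"
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L)
    .stopf("codon alignment has no ungapped columns")
  codons <- sense_codons()
  ia <- match(a, codons); ib <- match(b, codons)
  if (anyNA(ia) || anyNA(ib))
    .stopf("codon alignment contains non-sense codons: %s",
           paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  sites <- .ng86_site_table()
  diffs <- .ng86_diff_tables()
  L <- length(a)
  S <- sum((sites[ia] + sites[ib]) / 2)
  N <- 3 * L - S
  Sd <- sum(diffs$sd[cbind(ia, ib)])
  Nd <- sum(diffs$nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  sat <- pS >= 0.75 || pN >= 0.75
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio, saturated = sat, codons = L),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf("NG86 over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ka=%s Ks=%s Ka/Ks=%s%s\n",
              x$codons, x$S, x$N, x$Sd, x$Nd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Validate a codon sequence
#'
#' @param codons Character vector of codons.
#' @param allow_final_stop Accept a trailing stop codon (stripped from the
#'   returned value).
#' @return The validated (possibly stop-stripped) codon vector.
#' @export
validate_codon_sequence <- function(codons, allow_final_stop = TRUE) {
  if (length(codons) < 1L) .stopf("codon sequence is empty")
  if (any(nchar(codons) != 3L)) .stopf("codon sequence contains non-triplet entries")
  aa <- .codon_aa()
  unknown <- setdiff(codons, names(aa))
  if (length(unknown)) .stopf("unknown codons: %s", paste(unknown, collapse = ", "))
  is_stop <- aa[codons] == "*"
  if (allow_final_stop && length(codons) > 1L && is_stop[length(codons)]) {
    codons <- codons[-length(codons)]
    is_stop <- is_stop[-length(is_stop)]
  }
  if (any(is_stop))
    .stopf("codon sequence contains an internal stop codon at position %d", which(is_stop)[1])
  codons
}

#' Translate a codon vector to an amino-acid string
#' @param codons Character vector of sense codons.
#' @return Single amino-acid string.
#' @export
translate_codons <- function(codons) {
  paste(.codon_aa()[codons], collapse = "")
}

#' Split a CDS nucleotide string into codons
#' @param cds Nucleotide string; length must be divisible by 3.
#' @return Character vector of codons.
#' @export
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) .stopf("CDS length %d is not divisible by 3", n)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}
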