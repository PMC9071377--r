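# Position-specific scoring profile for the bHLH domain, and profile-to-
# protein search. The domain search is a semi-global affine-gap alignment:
# every profile column is consumed (gaps allowed), protein flanks are free.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Packaged seed alignment of bHLH domain sequences
#'
#' A small synthetic alignment (60 columns) used to build the default domain
#' profile. Column layout: basic region (1-15), helix 1 (16-30), loop (31-44),
#' helix 2 (45-60). The rule-bearing positions (H/K-1, E-2, R-4, R-5) sit at
#' columns 5, 9, 12 and 13. The rows are constructed, not transcribed from any
#' curated family alignment.
#'
#' @return Named character vector of equal-length aligned sequences.
#' @export
bhlh_seed_alignment <- function() {
  c(seed1 = "ANRAHERNERLRRERLREAIQYIKSLQELLPGASSDKASNSGTLVESAIEYIKELQNQNR",
    seed2 = "ANRSHERNERLRRERLKEAIQYIKSLQELLPGASTDKASNSGSLVESAIEYIKELQNQNR",
    seed3 = "SNRAHERSERLRRERLREALQYIKSLQDLLPGGSSDKASNAGTLVESAVEYIKELQNQNR",
    seed4 = "ANRAHERNERLRKERLREAIQYVKSLQELLPSASSDKASNSGTLIESAIEYIKELQKQNR",
    seed5 = "ANKAHERNERLRRERMREAIQYIKSLQELLPGASSDRASNSGTLVESAIEYIRELQNQNR",
    seed6 = "ANRAHERNERLRRERLREAIQYIKNLQELLPGTSSDKASNSGTLVESAIEYIKELQNQSR",
    seed7 = "TNRAHERNDRLRRERLREAIQYIKSLEELLPGASSDKATNSGTLVESAIEYIKELQNQNR",
    seed8 = "ANRAHERNERLRRERLREAIHYIKSLQELLPGASSDKASNSGTLVDSAIEYIKELQNQNR")
}

#' Default region layout of the packaged profile
#' @return Named list of column index vectors (basic, helix1, loop, helix2).
#' @export
default_region_spec <- function() {
  list(basic = 1:15, helix1 = 16:30, loop = 31:44, helix2 = 45:60)
}

#' Default rule-bearing profile columns
#'
#' Column indices of the residues consulted by the DNA-binding cascade. These
#' ship as configurable defaults on the packaged seed alignment.
#' @return Named integer vector with entries `H/K-1`, `E-2`, `R-4`, `R-5`.
#' @export
default_named_positions <- function() {
  c(`H/K-1` = 5L, `E-2` = 9L, `R-4` = 12L, `R-5` = 13L)
}

#' Build a domain profile from a seed alignment
#'
#' Per-column residue+gap frequencies and log-odds scores against a uniform
#' background.
#'
#' @param alignment Character vector (>= 2 rows) of equal-length aligned
#'   sequences; `-` marks gaps.
#' @param region_spec Named list of disjoint, ordered column ranges covering
#'   the profile (see [default_region_spec()]).
#' @param named_positions Named integer vector of rule-bearing columns; each
#'   must fall inside a region.
#' @param score_threshold Minimum alignment score for [find_bhlh_domain()] to
#'   report a hit. If `NULL`, calibrated as the 99th percentile of the scores
#'   of shuffled consensus sequences (deterministic internal seed).
#' @param pseudocount Added to frequencies before log-odds scoring.
#' @return Object of class `bhlh_profile`.
#' @export
build_domain_profile <- function(alignment,
                                 region_spec = default_region_spec(),
                                 named_positions = default_named_positions(),
                                 score_threshold = NULL,
                                 pseudocount = 0.02) {
  if (length(alignment) < 2L) .stopf("seed alignment needs at least 2 rows")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    .stopf("ragged seed alignment: row widths %s", paste(unique(widths), collapse = ", "))
  L <- widths[1]
  cols <- sort(as.integer(unname(unlist(region_spec))))
  if (!identical(cols, seq_len(L)))
    .stopf("region_spec must cover profile columns 1..%d disjointly", L)
  if (any(named_positions < 1L | named_positions > L))
    .stopf("named position outside profile columns: %s",
           paste(names(named_positions)[named_positions < 1L | named_positions > L],
                 collapse = ", "))
  mat <- do.call(rbind, strsplit(alignment, ""))
  bad <- setdiff(unique(as.vector(mat)), c(.AA20, "X", "-"))
  if (length(bad)) .stopf("seed alignment contains invalid characters: %s",
                          paste(bad, collapse = ", "))
  alpha <- c(.AA20, "-")
  freq <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = alpha))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- alpha
  bg <- 1 / length(.AA20)
  scores <- log2((freq[.AA20, , drop = FALSE] + pseudocount) / (bg + pseudocount))
  consensus <- paste(.AA20[apply(freq[.AA20, , drop = FALSE], 2, which.max)],
                     collapse = "")
  prof <- structure(list(freq = freq, scores = scores, consensus = consensus,
                         region_spec = region_spec,
                         named_positions = named_positions,
                         score_threshold = score_threshold),
                    class = "bhlh_profile")
  if (is.null(score_threshold))
    prof$score_threshold <- calibrate_profile_threshold(prof)
  prof
}

#' Calibrate the profile score threshold by shuffle scoring
#'
#' Scores `n` residue shuffles of the profile consensus and returns the
#' requested quantile. Uses an internal fixed seed so the packaged default is
#' reproducible; the caller's RNG stream is left untouched.
#'
#' @param profile A `bhlh_profile`.
#' @param n Number of shuffles.
#' @param quantile Score quantile to return.
#' @param seed Internal RNG seed.
#' @return Numeric threshold.
#' @export
calibrate_profile_threshold <- function(profile, n = 300, quantile = 0.99, seed = 20260101) {
  cons <- strsplit(profile$consensus, "")[[1]]
  .with_seed(seed, {
    sc <- vapply(seq_len(n), function(i) {
      shuf <- paste(sample(cons), collapse = "")
      .profile_align(profile, shuf)$score
    }, numeric(1))
    as.numeric(stats::quantile(sc, quantile, names = FALSE))
  })
}

#' The packaged default bHLH domain profile
#'
#' Built once per session from [bhlh_seed_alignment()] and cached.
#' @return A `bhlh_profile`.
#' @export
default_domain_profile <- function() {
  if (is.null(.cucurbHLH_cache$default_profile))
    .cucurbHLH_cache$default_profile <- build_domain_profile(bhlh_seed_alignment())
  .cucurbHLH_cache$default_profile
}

#' Construct a protein record
#' @param id Gene/protein identifier.
#' @param species Species label.
#' @param sequence Amino-acid string (20 standard residues plus `X`).
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(id, species, sequence) {
  if (!nzchar(sequence)) .stopf("protein %s has an empty sequence", id)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(.AA20, "X"))
  if (length(bad)) .stopf("protein %s contains invalid residues: %s",
                          id, paste(bad, collapse = ", "))
  structure(list(id = id, species = species, sequence = sequence),
            class = "protein_record")
}

# Semi-global alignment of all profile columns against a protein substring.
# Returns score, 0-based [start, end) protein coordinates and the per-column
# map to 0-based protein positions (NA where the column is gapped).
#' @noRd
.profile_align <- function(profile, sequence, gap_open = 6, gap_extend = 0.5) {
  sv <- strsplit(sequence, "")[[1]]
  P <- ncol(profile$scores)
  m <- length(sv)
  known <- sv %in% .AA20
  # profile$scores is residues x columns; emit is columns x protein positions
  emit <- t(profile$scores[ifelse(known, sv, "A"), , drop = FALSE])
  emit[, !known] <- 0  # unknown residue (X) scores neutrally
  NEG <- -1e18
  M <- matrix(NEG, P + 1, m + 1)
  Ix <- matrix(NEG, P + 1, m + 1)
  Iy <- matrix(NEG, P + 1, m + 1)
  M[1, ] <- 0  # free protein prefix
  jj <- seq_len(m) + 1L
  for (i in seq_len(P) + 1L) {
    best_prev <- pmax(M[i - 1L, jj - 1L], Ix[i - 1L, jj - 1L], Iy[i - 1L, jj - 1L])
    M[i, jj] <- emit[i - 1L, ] + best_prev
    Ix[i, jj] <- pmax(pmax(M[i - 1L, ], Iy[i - 1L, ])[jj] - gap_open - gap_extend,
                      Ix[i - 1L, jj] - gap_extend)
    Ix[i, 1] <- max(M[i - 1L, 1] - gap_open - gap_extend, Ix[i - 1L, 1] - gap_extend)
    Bk <- pmax(M[i, ], Ix[i, ]) + (0:m) * gap_extend
    run <- cummax(Bk)
    Iy[i, jj] <- run[jj - 1L] - gap_open - (jj - 1L) * gap_extend
  }
  fin <- pmax(M[P + 1, ], Ix[P + 1, ])
  j <- which.max(fin)  # smallest protein end on ties
  score <- fin[j]
  # traceback
  eps <- 1e-9
  state <- if (M[P + 1, j] >= Ix[P + 1, j]) "M" else "Ix"
  i <- P + 1L
  cmap <- rep(NA_integer_, P)
  while (i > 1L) {
    if (state == "M") {
      cmap[i - 1L] <- j - 2L  # 0-based protein position
      prev <- c(M = M[i - 1L, j - 1L], Ix = Ix[i - 1L, j - 1L], Iy = Iy[i - 1L, j - 1L])
      state <- names(prev)[which.max(prev + c(2, 1, 0) * eps)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {
      cand <- c(M = M[i - 1L, j] - gap_open - gap_extend,
                Iy = Iy[i - 1L, j] - gap_open - gap_extend,
                Ix = Ix[i - 1L, j] - gap_extend)
      state <- names(cand)[which.max(cand + c(2, 1, 0) * eps)]
      i <- i - 1L
    } else {
      cand <- c(M = M[i, j - 1L] - gap_open - gap_extend,
                Ix = Ix[i, j - 1L] - gap_open - gap_extend,
                Iy = Iy[i, j - 1L] - gap_extend)
      state <- names(cand)[which.max(cand + c(2, 0, 1) * eps)]
      j <- j - 1L
    }
  }
  matched <- cmap[!is.na(cmap)]
  list(score = score, column_map = cmap,
       start = if (length(matched)) min(matched) else NA_integer_,
       end = if (length(matched)) max(matched) + 1L else NA_integer_)
}

#' Locate the bHLH domain in a protein
#'
#' Best-scoring semi-global alignment of the profile against the protein.
#' Returns `NULL` (absence is a value, not an error) when the best score falls
#' below `profile$score_threshold`.
#'
#' @param protein A [protein_record()] or a plain amino-acid string.
#' @param profile A `bhlh_profile`.
#' @param gap_open,gap_extend Affine gap penalties of the search.
#' @return A `domain_annotation` (list with `id`, `start`, `end` in 0-based
#'   half-open protein coordinates, `score`, `column_map`) or `NULL`.
#' @export
find_bhlh_domain <- function(protein, profile = default_domain_profile(),
                             gap_open = 6, gap_extend = 0.5) {
  seq <- if (inherits(protein, "protein_record")) protein$sequence else protein
  id <- if (inherits(protein, "protein_record")) protein$id else NA_character_
  res <- .profile_align(profile, seq, gap_open, gap_extend)
  if (res$score < profile$score_threshold || is.na(res$start)) return(NULL)
  structure(list(id = id, start = res$start, end = res$end, score = res$score,
                 column_map = res$column_map, regions = NULL),
            class = "domain_annotation")
}

#' Map profile regions onto protein coordinates
#'
#' Pushes the basic/helix1/loop/helix2 column ranges through the annotation's
#' column map. A region whose columns are all gapped in the protein is flagged
#' empty rather than raising an error.
#'
#' @param annotation A `domain_annotation` from [find_bhlh_domain()].
#' @param profile The profile the annotation was produced from.
#' @return The annotation with a `regions` data frame (region, start, end in
#'   0-based half-open protein coordinates, length, empty flag).
#' @export
partition_regions <- function(annotation, profile = default_domain_profile()) {
  stopifnot(inherits(annotation, "domain_annotation"))
  rows <- lapply(names(profile$region_spec), function(rn) {
    pos <- annotation$column_map[profile$region_spec[[rn]]]
    pos <- pos[!is.na(pos)]
    if (!length(pos))
      data.frame(region = rn, start = NA_integer_, end = NA_integer_,
                 length = 0L, empty = TRUE)
    else
      data.frame(region = rn, start = min(pos), end = max(pos) + 1L,
                 length = length(pos), empty = FALSE)
  })
  annotation$regions <- do.call(rbind, rows)
  annotation
}
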