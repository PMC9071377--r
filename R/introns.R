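# Gene models, intron positions in CDS coordinate space, and typing of
# intron-distribution patterns within the domain-encoding region.

#' Construct a gene model
#'
#' Coordinates are 0-based half-open genomic intervals. Exons are given in
#' transcript (5' to 3') order; for minus-strand genes that is descending
#' genomic order. Introns are derived in CDS coordinate space (nucleotides
#' from the CDS start).
#'
#' @param gene Gene id.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`, `end` (0-based half-open) in
#'   transcript order. Treated as CDS segments (no UTR model).
#' @param phase Phase of the first CDS segment (leading incomplete codon
#'   nucleotides, 0-2).
#' @return Object of class `gene_model` with derived `introns_cds`.
#' @export
gene_model <- function(gene, chrom, strand = "+", exons, phase = 0L) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (any(exons$end <= exons$start)) .stopf("gene %s: exon with end <= start", gene)
  if (!strand %in% c("+", "-")) .stopf("gene %s: invalid strand %s", gene, strand)
  g_sorted <- exons[order(exons$start), , drop = FALSE]
  if (nrow(g_sorted) > 1L && any(g_sorted$start[-1] < g_sorted$end[-nrow(g_sorted)]))
    .stopf("gene %s: overlapping exons", gene)
  expected <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(expected, seq_len(nrow(exons))))
    .stopf("gene %s: exons not in transcript order for strand %s", gene, strand)
  lens <- exons$end - exons$start
  cds_len <- as.integer(sum(lens) - phase)
  if (cds_len %% 3L != 0L)
    .stopf("gene %s: CDS length %d not divisible by 3 after phase", gene, cds_len)
  introns <- if (nrow(exons) > 1L) cumsum(lens)[-nrow(exons)] - phase else integer(0)
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 exons = exons, phase = as.integer(phase),
                 cds_length = cds_len, introns_cds = as.integer(introns)),
            class = "gene_model")
}

#' Intron events inside the domain-encoding CDS region
#'
#' Converts the domain's protein coordinates to CDS nucleotides (x3) and
#' returns the introns falling in `[domain_start*3, domain_end*3)`, with
#' positions relative to the domain CDS start and phase `position %% 3`.
#'
#' @param model A [gene_model()].
#' @param annotation The protein's `domain_annotation`.
#' @param cds The gene's codon vector (or CDS string); used to cross-check
#'   lengths against the gene model.
#' @return Data frame with `position` (domain-relative nt) and `phase`.
#' @export
map_introns_to_domain <- function(model, annotation, cds) {
  stopifnot(inherits(model, "gene_model"), inherits(annotation, "domain_annotation"))
  codons <- .as_codon_vector(cds)
  n_nt <- 3L * length(codons)
  if (!model$cds_length %in% c(n_nt, n_nt + 3L))  # model may include the stop codon
    .stopf("gene %s: CDS length mismatch (model %d nt, sequence %d nt)",
           model$gene, model$cds_length, n_nt)
  lo <- 3L * annotation$start
  hi <- 3L * annotation$end
  pos <- model$introns_cds[model$introns_cds >= lo & model$introns_cds < hi]
  data.frame(position = pos - lo, phase = pos %% 3L)
}

#' Canonical intron positions of the domain-encoding region
#'
#' Domain-relative CDS nucleotide offsets of the three conserved intron
#' positions (basic region, loop, helix 2) used for pattern typing.
#' @return Integer vector of length 3.
#' @export
canonical_intron_positions <- function() c(27L, 105L, 150L)

#' Packaged intron-pattern definition table
#'
#' Maps occupancy signatures over the three canonical positions, plus the
#' presence of non-canonical introns, to the twelve pattern codes. Patterns I
#' (all three positions), IX (loop position only) and XI (no intron) are fixed
#' by the family literature; the remaining assignments are the packaged,
#' editable convention. Any signature not listed types as `O`.
#'
#' @return Data frame with `code`, `positions` (comma-joined canonical
#'   positions) and `noncanonical` (logical).
#' @export
default_pattern_table <- function() {
  data.frame(
    code = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X", "XI"),
    positions = c("1,2,3", "2,3", "1,2", "1,3", "1", "3", "2", "", "2", "1,2,3", ""),
    noncanonical = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                     FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Type the intron-distribution pattern of a domain
#'
#' Each intron event is assigned to the nearest canonical position within the
#' tolerance window, otherwise it counts as non-canonical. A canonical
#' position claimed by two or more events is treated as unoccupied and those
#' events count as non-canonical. The resulting occupancy signature is looked
#' up in the pattern table; unmatched signatures type as `O`.
#'
#' @param events Data frame from [map_introns_to_domain()] (column
#'   `position`).
#' @param canonical Canonical position offsets (ordered).
#' @param tolerance Assignment window in nucleotides (>= 0).
#' @param pattern_table Pattern definition table (see
#'   [default_pattern_table()]).
#' @return A single pattern code.
#' @export
type_intron_pattern <- function(events,
                                canonical = canonical_intron_positions(),
                                tolerance = 6L,
                                pattern_table = default_pattern_table()) {
  if (is.unsorted(canonical)) .stopf("canonical positions must be ordered")
  if (tolerance < 0) .stopf("tolerance must be >= 0")
  pos <- if (is.data.frame(events)) events$position else events
  assigned <- integer(0)
  n_noncanon <- 0L
  for (p in pos) {
    d <- abs(canonical - p)
    if (min(d) <= tolerance) assigned <- c(assigned, which.min(d))
    else n_noncanon <- n_noncanon + 1L
  }
  tab <- table(factor(assigned, levels = seq_along(canonical)))
  occupied <- which(tab == 1L)
  n_noncanon <- n_noncanon + sum(tab[tab > 1L])
  sig_pos <- paste(occupied, collapse = ",")
  hit <- pattern_table$code[pattern_table$positions == sig_pos &
                              pattern_table$noncanonical == (n_noncanon > 0L)]
  if (length(hit) >= 1L) hit[1] else "O"
}

#' All defined intron pattern codes
#' @return Character vector (I..XI plus the catch-all O).
#' @export
intron_pattern_codes <- function() c(default_pattern_table()$code, "O")
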