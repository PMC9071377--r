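# Collinear-block chaining by sparse dynamic programming, and the synteny-
# derived comparative units: ortholog pairs/groups, paralog pairs and
# tandem-duplicate clusters.

#' @noRd
.anchor_loci <- function(anchors, loci) {
  ia <- match(anchors$gene_a, loci$gene)
  ib <- match(anchors$gene_b, loci$gene)
  if (anyNA(ia) || anyNA(ib))
    .stopf("anchor references unknown locus: %s",
           paste(unique(c(anchors$gene_a[is.na(ia)], anchors$gene_b[is.na(ib)])),
                 collapse = ", "))
  cbind(anchors,
        species_a = loci$species[ia], chrom_a = loci$chrom[ia],
        rank_a = loci$rank[ia],
        species_b = loci$species[ib], chrom_b = loci$chrom[ib],
        rank_b = loci$rank[ib])
}

# Best chain (score, members) among anchors of one chromosome pair, one
# orientation. ranks must be strictly monotone on both sides; consecutive
# anchors may skip at most `max_gap_ranks` intervening ranks per side; the
# chain scores sum(match_score) - gap_penalty * sum(intervening ranks).
#' @noRd
.best_chain <- function(ra, rb, orientation, match_score, gap_penalty, max_gap_ranks) {
  n <- length(ra)
  ord <- order(ra, if (orientation > 0) rb else -rb)
  ra <- ra[ord]; rb <- rb[ord]
  dp <- rep(match_score, n)
  pred <- rep(NA_integer_, n)
  start_rank <- ra
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- (rb[i] - rb[j]) * orientation
      if (da < 1L || db < 1L) next
      if (da - 1L > max_gap_ranks || db - 1L > max_gap_ranks) next
      cand <- dp[j] + match_score - gap_penalty * ((da - 1L) + (db - 1L))
      if (cand > dp[i] + 1e-12 ||
          (abs(cand - dp[i]) <= 1e-12 && start_rank[j] < start_rank[i])) {
        dp[i] <- cand
        pred[i] <- j
        start_rank[i] <- start_rank[j]
      }
    }
  }
  best <- order(-dp, start_rank, ra)[1]
  chain <- integer(0)
  k <- best
  while (!is.na(k)) { chain <- c(k, chain); k <- pred[k] }
  list(score = dp[best], members = ord[chain], start_rank = start_rank[best])
}

#' Chain homology anchors into collinear blocks
#'
#' Per chromosome pair and orientation, maximal-score chains are found by
#' sparse dynamic programming over anchors sorted by a-side rank
#' (`score = sum(match_score) - gap_penalty * intervening ranks`); chains are
#' extracted greedily by score (ties to the smaller starting a-rank), each
#' anchor enters at most one block, and chains below `min_block_size` anchors
#' are discarded.
#'
#' @param anchors Data frame with `gene_a`, `gene_b` and optionally
#'   `similarity`.
#' @param loci Locus table (`gene`, `species`, `chrom`, `rank`, `start`,
#'   `end`, `strand`).
#' @param min_block_size Minimum anchors per reported block.
#' @param max_gap_ranks Maximum intervening gene ranks between consecutive
#'   anchors, per side.
#' @param match_score,gap_penalty Chain scoring parameters.
#' @param min_similarity Anchors below this similarity are ignored.
#' @return List of blocks; each block is a list with `species_a`, `chrom_a`,
#'   `species_b`, `chrom_b`, `orientation` (`"same"`/`"inverted"`), `score`,
#'   `size` and the member `anchors` data frame (rank-annotated).
#' @export
chain_collinear_blocks <- function(anchors, loci, min_block_size = 5L,
                                   max_gap_ranks = 25L, match_score = 1,
                                   gap_penalty = 0.05, min_similarity = 0) {
  if (nrow(anchors) == 0L) return(list())
  anc <- .anchor_loci(anchors, loci)
  anc <- anc[anc$gene_a != anc$gene_b, , drop = FALSE]
  if (!is.null(anc$similarity) && min_similarity > 0)
    anc <- anc[anc$similarity >= min_similarity, , drop = FALSE]
  if (nrow(anc) == 0L) return(list())
  # canonical side order: (species, chrom, rank) so each unordered pair maps
  # to one chromosome-pair group
  swap <- with(anc, species_a > species_b |
                 (species_a == species_b & .chrom_order(chrom_a) > .chrom_order(chrom_b)) |
                 (species_a == species_b & chrom_a == chrom_b & rank_a > rank_b))
  if (any(swap)) {
    tmp <- anc[swap, ]
    anc[swap, c("gene_a", "species_a", "chrom_a", "rank_a",
                "gene_b", "species_b", "chrom_b", "rank_b")] <-
      tmp[, c("gene_b", "species_b", "chrom_b", "rank_b",
              "gene_a", "species_a", "chrom_a", "rank_a")]
  }
  key <- with(anc, paste(species_a, chrom_a, species_b, chrom_b, sep = "\r"))
  blocks <- list()
  for (grp in split(seq_len(nrow(anc)), key)) {
    pool <- grp
    repeat {
      if (length(pool) < min_block_size) break
      ra <- anc$rank_a[pool]; rb <- anc$rank_b[pool]
      fwd <- .best_chain(ra, rb, 1L, match_score, gap_penalty, max_gap_ranks)
      rev <- .best_chain(ra, rb, -1L, match_score, gap_penalty, max_gap_ranks)
      pick <- if (fwd$score >= rev$score) fwd else rev
      orientation <- if (fwd$score >= rev$score) "same" else "inverted"
      if (length(pick$members) < min_block_size) break
      idx <- pool[pick$members]
      blocks[[length(blocks) + 1L]] <- list(
        species_a = anc$species_a[idx[1]], chrom_a = anc$chrom_a[idx[1]],
        species_b = anc$species_b[idx[1]], chrom_b = anc$chrom_b[idx[1]],
        orientation = orientation, score = pick$score,
        size = length(idx), anchors = anc[idx, , drop = FALSE])
      pool <- setdiff(pool, idx)
    }
  }
  ord <- order(vapply(blocks, function(b) -b$score, numeric(1)))
  blocks <- blocks[ord]
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- i
  blocks
}

#' @noRd
.block_anchor_table <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      species_a = character(0), species_b = character(0),
                      block = integer(0)))
  }
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(gene_a = b$anchors$gene_a, gene_b = b$anchors$gene_b,
               species_a = b$anchors$species_a, species_b = b$anchors$species_b,
               block = b$block_id)
  }))
}

#' Inter-genomic ortholog pairs from collinear blocks
#'
#' Returns block anchors whose two genes both belong to the analyzed family
#' and come from different species.
#'
#' @param blocks Blocks from [chain_collinear_blocks()].
#' @param family_genes Character vector of family gene ids.
#' @return Data frame (`gene_a`, `gene_b`, `species_a`, `species_b`, `block`).
#' @export
derive_ortholog_pairs <- function(blocks, family_genes) {
  tab <- .block_anchor_table(blocks)
  tab[tab$species_a != tab$species_b &
        tab$gene_a %in% family_genes & tab$gene_b %in% family_genes, ,
      drop = FALSE]
}

#' Intra-genomic paralog pairs from collinear blocks
#'
#' As [derive_ortholog_pairs()] but within one species; self-pairs are
#' excluded.
#' @inheritParams derive_ortholog_pairs
#' @return Data frame (`gene_a`, `gene_b`, `species`, `block`).
#' @export
find_paralog_pairs <- function(blocks, family_genes) {
  tab <- .block_anchor_table(blocks)
  tab <- tab[tab$species_a == tab$species_b & tab$gene_a != tab$gene_b &
               tab$gene_a %in% family_genes & tab$gene_b %in% family_genes, ,
             drop = FALSE]
  if (nrow(tab)) data.frame(gene_a = tab$gene_a, gene_b = tab$gene_b,
                            species = tab$species_a, block = tab$block)
  else data.frame(gene_a = character(0), gene_b = character(0),
                  species = character(0), block = integer(0))
}

#' Merge ortholog pairs into ortholog groups
#'
#' Groups are the connected components of the pair graph over the family.
#' Family genes in no pair form species-specific singleton OGs, unless linked
#' to same-species genes by the optional `intra_pairs` (e.g. tandem-cluster
#' pairs), in which case they join that component. OG ids are zero-padded and
#' ordered by descending species count, then genomic coordinates.
#'
#' @param pairs Cross-species pair data frame (`gene_a`, `gene_b`).
#' @param loci Locus table covering all family genes.
#' @param intra_pairs Optional intra-species pair data frame used only to
#'   attach unplaced same-species homologs.
#' @return List with `membership` (gene, og, species) and `summary`
#'   (og, size, species_count, cross_species).
#' @export
merge_ortholog_groups <- function(pairs, loci, intra_pairs = NULL) {
  genes <- loci$gene
  edges <- rbind(
    if (nrow(pairs)) data.frame(a = pairs$gene_a, b = pairs$gene_b),
    if (!is.null(intra_pairs) && nrow(intra_pairs))
      data.frame(a = intra_pairs$gene_a, b = intra_pairs$gene_b)
  )
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$a, genes), match(edges$b, genes)))
  comp <- igraph::components(g)$membership
  mem <- data.frame(gene = genes, comp = comp,
                    species = loci$species, chrom = loci$chrom,
                    start = loci$start, stringsAsFactors = FALSE)
  stats <- do.call(rbind, lapply(split(mem, mem$comp), function(d) {
    data.frame(comp = d$comp[1], size = nrow(d),
               species_count = length(unique(d$species)),
               chrom_ord = min(.chrom_order(d$chrom)),
               start = min(d$start))
  }))
  stats <- stats[order(-stats$species_count, stats$chrom_ord, stats$start), ]
  stats$og <- sprintf("OG%03d", seq_len(nrow(stats)))
  mem$og <- stats$og[match(mem$comp, stats$comp)]
  list(membership = data.frame(gene = mem$gene, og = mem$og,
                               species = mem$species, stringsAsFactors = FALSE),
       summary = data.frame(og = stats$og, size = stats$size,
                            species_count = stats$species_count,
                            cross_species = stats$species_count >= 2L,
                            stringsAsFactors = FALSE))
}

#' Detect tandem-duplicate clusters
#'
#' Clusters are connected components of the relation "homologous AND on the
#' same chromosome AND rank distance <= max_gap + 1". Clusters are named per
#' species (`T1`, `T2`, ...) in genomic coordinate order.
#'
#' @param loci Locus table.
#' @param anchors Intra-species homology pairs (`gene_a`, `gene_b`).
#' @param max_gap Maximum intervening (non-homologous) genes between cluster
#'   members.
#' @return Data frame (`species`, `cluster`, `chrom`, `gene`, `rank`,
#'   `start`), ordered by cluster and rank; zero rows when nothing clusters.
#' @export
detect_tandem_clusters <- function(loci, anchors, max_gap = 1L) {
  empty <- data.frame(species = character(0), cluster = character(0),
                      chrom = character(0), gene = character(0),
                      rank = integer(0), start = numeric(0))
  if (nrow(anchors) == 0L) return(empty)
  anc <- .anchor_loci(anchors, loci)
  keep <- anc$gene_a != anc$gene_b &
    anc$species_a == anc$species_b & anc$chrom_a == anc$chrom_b &
    abs(anc$rank_a - anc$rank_b) <= max_gap + 1L
  anc <- anc[keep, , drop = FALSE]
  if (nrow(anc) == 0L) return(empty)
  genes <- loci$gene
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  g <- igraph::add_edges(g, rbind(match(anc$gene_a, genes), match(anc$gene_b, genes)))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  in_cluster <- comp %in% as.integer(names(sizes)[sizes >= 2L])
  d <- data.frame(gene = genes[in_cluster], comp = comp[in_cluster],
                  species = loci$species[in_cluster],
                  chrom = loci$chrom[in_cluster],
                  rank = loci$rank[in_cluster], start = loci$start[in_cluster],
                  stringsAsFactors = FALSE)
  out <- list()
  for (sp in sort(unique(d$species))) {
    ds <- d[d$species == sp, , drop = FALSE]
    firsts <- do.call(rbind, lapply(split(ds, ds$comp), function(x) {
      data.frame(comp = x$comp[1], chrom_ord = min(.chrom_order(x$chrom)),
                 start = min(x$start))
    }))
    firsts <- firsts[order(firsts$chrom_ord, firsts$start), ]
    label <- setNames(paste0("T", seq_len(nrow(firsts))), firsts$comp)
    ds$cluster <- label[as.character(ds$comp)]
    ds <- ds[order(as.integer(sub("^T", "", ds$cluster)), ds$rank), ]
    out[[sp]] <- data.frame(species = ds$species, cluster = ds$cluster,
                            chrom = ds$chrom, gene = ds$gene,
                            rank = ds$rank, start = ds$start,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter inter-genomic anchors to near-best hits per gene
#'
#' For each gene and each target species, anchors within `delta` of the
#' gene's best similarity to that species are kept (in either direction).
#' This emulates the top-hit lists that collinearity tools consume and keeps
#' ancient outparalog anchors from chaining into spurious cross-species
#' blocks.
#'
#' @param anchors Anchor data frame with `similarity`.
#' @param loci Locus table.
#' @param delta Similarity slack below the per-gene best hit.
#' @return Filtered anchor data frame.
#' @export
filter_best_hits <- function(anchors, loci, delta = 0.03) {
  if (nrow(anchors) == 0L) return(anchors)
  anc <- .anchor_loci(anchors, loci)
  key_a <- paste(anc$gene_a, anc$species_b, sep = "\r")
  key_b <- paste(anc$gene_b, anc$species_a, sep = "\r")
  best_a <- tapply(anc$similarity, key_a, max)
  best_b <- tapply(anc$similarity, key_b, max)
  keep <- anc$similarity >= best_a[key_a] - delta |
    anc$similarity >= best_b[key_b] - delta
  anchors[keep, , drop = FALSE]
}
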