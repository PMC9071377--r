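# Protein distance matrices with partial deletion, neighbor-joining tree
# construction, bootstrap support, clade assignment, and Ks-based inference of
# lineage-specific cluster expansions.

#' Pairwise protein distances from a multiple alignment
#'
#' Columns with non-gap coverage below `coverage` are removed first (partial
#' deletion). For each pair, the p-distance is the mismatch fraction over
#' columns where both rows are ungapped; the Poisson correction is
#' `-log(1 - p)`. Pairs with no comparable column (or `p >= 1` under Poisson)
#' get an infinite, flagged distance.
#'
#' @param alignment Named character vector of equal-length gapped sequences
#'   (>= 3 rows).
#' @param method `"poisson"` (default) or `"p-distance"`.
#' @param coverage Partial-deletion column coverage threshold.
#' @return Symmetric distance matrix with zero diagonal; attribute `flagged`
#'   lists non-finite pairs.
#' @export
protein_distance_matrix <- function(alignment, method = c("poisson", "p-distance"),
                                    coverage = 0.8) {
  method <- match.arg(method)
  if (length(alignment) < 3L) .stopf("distance matrix requires >= 3 sequences")
  if (length(unique(nchar(alignment))) != 1L) .stopf("ragged alignment")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  nongap <- mat != "-"
  keep <- colMeans(nongap) >= coverage
  mat <- mat[, keep, drop = FALSE]
  nongap <- nongap[, keep, drop = FALSE]
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  flagged <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- nongap[i, ] & nongap[j, ]
    if (!any(both)) {
      D[i, j] <- D[j, i] <- Inf
      flagged <- c(flagged, paste(rownames(mat)[c(i, j)], collapse = "|"))
      next
    }
    p <- sum(mat[i, both] != mat[j, both]) / sum(both)
    d <- if (method == "p-distance") p else if (p < 1) -log(1 - p) else Inf
    if (!is.finite(d)) flagged <- c(flagged, paste(rownames(mat)[c(i, j)], collapse = "|"))
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "flagged") <- flagged
  attr(D, "method") <- method
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q criterion. Ties are broken by the
#' lexicographically smallest pair of subtree labels (each subtree labelled by
#' its smallest tip label). Negative branch estimates are clamped to zero and
#' flagged in the `clamped` attribute. The result is an unrooted `phylo`
#' object (trifurcating root node).
#'
#' @param d Symmetric distance matrix with row/column names (>= 3 labels).
#' @return An [ape::read.tree()]-compatible `phylo` object.
#' @export
build_nj_tree <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) .stopf("neighbor joining requires >= 3 labels")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (any(!is.finite(D)))
    .stopf("distance matrix contains non-finite entries (flagged pairs?)")
  if (max(abs(D - t(D))) > 1e-8) .stopf("distance matrix is not symmetric")
  labels <- rownames(D)
  active <- seq_len(n)                 # node ids of active lineages
  node_label <- labels                 # smallest tip label per active lineage
  next_id <- n + 1L
  edges <- list()
  clamped <- character(0)
  Dm <- D
  ids <- active
  clamp <- function(x, child) {
    if (x < 0) { clamped <<- c(clamped, child); 0 } else x
  }
  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- apply(cand, 1, function(ij) {
      paste(sort(node_label[ij]), collapse = "\r")
    })
    pick <- cand[order(pair_lab)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    u <- next_id; next_id <- next_id + 1L
    edges[[length(edges) + 1L]] <- c(u, ids[i], clamp(bi, node_label[i]))
    edges[[length(edges) + 1L]] <- c(u, ids[j], clamp(bj, node_label[j]))
    du <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    new_lab <- min(node_label[c(i, j)])
    ids <- c(ids[keep], u)
    node_label <- c(node_label[keep], new_lab)
    rownames(Dm) <- colnames(Dm) <- node_label
  }
  # final three lineages join at the (unrooted) central node
  cn <- next_id
  b1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  b2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  b3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  for (k in 1:3)
    edges[[length(edges) + 1L]] <- c(cn, ids[k], clamp(c(b1, b2, b3)[k], node_label[k]))
  emat <- do.call(rbind, edges)
  # renumber internal nodes: root (central node) = n + 1, then breadth-first
  n_internal <- next_id - n
  new_id <- integer(next_id)
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n + 1L
  queue <- cn
  children <- split(seq_len(nrow(emat)), emat[, 1])
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    new_id[nd] <- counter; counter <- counter + 1L
    kids <- emat[children[[as.character(nd)]], 2]
    queue <- c(queue, kids[kids > n])
  }
  phy <- list(edge = cbind(new_id[emat[, 1]], new_id[emat[, 2]]),
              edge.length = emat[, 3],
              tip.label = labels,
              Nnode = n_internal)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "clamped") <- unique(clamped)
  phy
}

#' Bootstrap support for the internal edges of an alignment's NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate, and reports for each internal node of the original tree the
#' fraction of replicates containing the corresponding bipartition
#' (counted with [ape::prop.clades()]). Seed-deterministic.
#'
#' @param alignment Named character vector of equal-length gapped sequences.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed for the resampling stream.
#' @param builder Function mapping an alignment to a `phylo`; defaults to
#'   NJ on [protein_distance_matrix()].
#' @param ... Passed to [protein_distance_matrix()] by the default builder.
#' @return List with `tree` (the original-alignment tree) and `support`
#'   (numeric in `[0, 1]` per internal node; empty when `n_reps = 0`).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L,
                              builder = NULL, ...) {
  if (is.null(builder))
    builder <- function(aln) build_nj_tree(protein_distance_matrix(aln, ...))
  tree <- builder(alignment)
  if (n_reps == 0L) return(list(tree = tree, support = numeric(0)))
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  trees <- .with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      builder(sub)
    })
  })
  counts <- ape::prop.clades(tree, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = tree, support = counts / n_reps)
}

#' Cut a tree into k clades
#'
#' Partitions the leaves at the tree's k-1 deepest splits: clades are the
#' k groups obtained by single-linkage clustering of the leaf-to-leaf path
#' distances, which on a tree is equivalent to removing the k-1 internal
#' edges bounding the deepest divergences (for `k = 2` on a clean tree this
#' is the cut at the longest internal edge). When anchors are given, edges
#' are instead chosen greedily by length subject to separating all anchors.
#' Labels follow anchor identity where given; otherwise Roman numerals in
#' order of each clade's first tip.
#'
#' @param tree A `phylo` object.
#' @param k Number of clades (`1 <= k <=` leaf count).
#' @param anchors Optional named character vector `clade label -> leaf name`.
#' @return Data frame (`gene`, `clade`).
#' @export
assign_clades <- function(tree, k, anchors = NULL) {
  ntip <- length(tree$tip.label)
  if (k < 1L || k > ntip) .stopf("k must be between 1 and the leaf count (%d)", ntip)
  if (!is.null(anchors)) {
    miss <- setdiff(anchors, tree$tip.label)
    if (length(miss)) .stopf("anchor leaves not in tree: %s", paste(miss, collapse = ", "))
    if (length(anchors) > k) .stopf("more anchors (%d) than clades (%d)", length(anchors), k)
  }
  internal <- which(tree$edge[, 2] > ntip)
  ord <- internal[order(-tree$edge.length[internal], internal)]
  n_nodes <- ntip + tree$Nnode
  comp_of <- function(cuts) {
    keep <- setdiff(seq_len(nrow(tree$edge)), cuts)
    g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
    if (length(keep)) g <- igraph::add_edges(g, t(tree$edge[keep, , drop = FALSE]))
    igraph::components(g)$membership
  }
  if (is.null(anchors)) {
    coph <- ape::cophenetic.phylo(tree)
    coph <- coph[tree$tip.label, tree$tip.label]
    grp <- stats::cutree(stats::hclust(stats::as.dist(coph), method = "single"), k = k)
    tip_comp <- grp[tree$tip.label]
    comp_order <- unique(tip_comp)
    labels <- stats::setNames(.roman_labels(length(comp_order)), comp_order)
    return(data.frame(gene = tree$tip.label,
                      clade = unname(labels[as.character(tip_comp)]),
                      stringsAsFactors = FALSE))
  }
  cuts <- integer(0)
  {
    anchor_idx <- match(anchors, tree$tip.label)
    membership <- comp_of(cuts)
    for (e in ord) {
      if (length(cuts) >= k - 1L) break
      trial <- c(cuts, e)
      mtrial <- comp_of(trial)
      sep_now <- length(unique(mtrial[anchor_idx]))
      sep_before <- length(unique(membership[anchor_idx]))
      # accept a cut if it separates anchors, or anchors are already apart
      if (sep_now > sep_before || sep_before == length(anchors)) {
        cuts <- trial
        membership <- mtrial
      }
    }
    if (length(unique(comp_of(cuts)[anchor_idx])) < length(anchors)) {
      tab <- split(names(anchors), comp_of(cuts)[anchor_idx])
      conflict <- tab[vapply(tab, length, 1L) > 1L]
      .stopf("anchors cannot be separated into distinct clades: %s",
             paste(vapply(conflict, paste, "", collapse = "+"), collapse = "; "))
    }
  }
  membership <- comp_of(cuts)
  tip_comp <- membership[seq_len(ntip)]
  comp_order <- unique(tip_comp)          # order of first tip occurrence
  labels <- setNames(rep(NA_character_, length(comp_order)), comp_order)
  if (!is.null(anchors)) {
    for (a in seq_along(anchors))
      labels[as.character(tip_comp[match(anchors[a], tree$tip.label)])] <- names(anchors)[a]
  }
  free <- setdiff(.roman_labels(max(k, length(comp_order))), labels)
  labels[is.na(labels)] <- free[seq_len(sum(is.na(labels)))]
  data.frame(gene = tree$tip.label, clade = unname(labels[as.character(tip_comp)]),
             stringsAsFactors = FALSE)
}

#' Infer lineage-specific expansions and losses within clades
#'
#' Within each clade, a species' genes are called a post-speciation expansion
#' iff the maximum intra-species Ks among them is smaller than the minimum
#' inter-species Ks from that species to clade members elsewhere. A species
#' with one gene in the clade is an ancestral retention; a species absent from
#' the clade is a loss. Saturated pairs are excluded with a warning. When a
#' clade has no inter-species comparison, `recent_dup_threshold` substitutes
#' for the inter-species minimum.
#'
#' @param members Data frame (`gene`, `species`, `clade`).
#' @param ks Data frame (`gene_a`, `gene_b`, `ks`, optional `saturated`).
#' @param recent_dup_threshold Ks bound treated as "recent" when no
#'   inter-species Ks is available.
#' @param species Species universe; defaults to those present in `members`.
#' @return Data frame, one row per clade x species: `clade`, `species`,
#'   `n_genes`, `genes`, `max_intra_ks`, `min_inter_ks`, `verdict`.
#' @export
infer_lineage_expansion <- function(members, ks, recent_dup_threshold = 0.32,
                                    species = NULL) {
  if (is.null(species)) species <- sort(unique(members$species))
  sat <- if (!is.null(ks$saturated)) ks$saturated else rep(FALSE, nrow(ks))
  if (any(sat))
    .warnf("%d saturated pair(s) excluded from expansion inference", sum(sat))
  ks_ok <- ks[!sat & !is.na(ks$ks), , drop = FALSE]
  lut <- setNames(ks_ok$ks, .pair_key(ks_ok$gene_a, ks_ok$gene_b))
  pair_ks <- function(ga, gb) {
    v <- lut[.pair_key(rep(ga, each = length(gb)), rep(gb, length(ga)))]
    v[!is.na(v)]
  }
  rows <- list()
  for (cl in sort(unique(members$clade))) {
    mc <- members[members$clade == cl, , drop = FALSE]
    for (sp in species) {
      g_in <- mc$gene[mc$species == sp]
      g_out <- mc$gene[mc$species != sp]
      if (length(g_in) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          clade = cl, species = sp, n_genes = 0L, genes = "",
          max_intra_ks = NA_real_, min_inter_ks = NA_real_, verdict = "loss")
        next
      }
      inter <- pair_ks(g_in, g_out)
      min_inter <- if (length(inter)) min(inter) else NA_real_
      if (length(g_in) == 1L) {
        verdict <- "ancestral_retention"
        max_intra <- NA_real_
      } else {
        cmb <- utils::combn(g_in, 2)
        intra <- lut[.pair_key(cmb[1, ], cmb[2, ])]
        intra <- intra[!is.na(intra)]
        max_intra <- if (length(intra)) max(intra) else NA_real_
        bound <- if (!is.na(min_inter)) min_inter else recent_dup_threshold
        verdict <- if (!is.na(max_intra) && max_intra < bound)
          "post_speciation_expansion" else "ancestral_retention"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, species = sp, n_genes = length(g_in),
        genes = paste(sort(g_in), collapse = ","),
        max_intra_ks = max_intra, min_inter_ks = min_inter, verdict = verdict)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
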