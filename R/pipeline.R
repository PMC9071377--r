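# End-to-end orchestration: load standard files, locate and classify domains,
# run synteny/orthology/tandem analysis, Ka/Ks, cluster phylogeny and
# expression, and assemble the report.

#' Coordinate-ordered gene names
#'
#' Sorts loci by (chromosome natural order, start) and assigns zero-padded
#' indices from 001. Duplicate coordinates are broken deterministically by
#' input id, with a warning.
#'
#' @param loci Locus table for one species.
#' @param prefix Species prefix (e.g. `Csa`).
#' @param family_tag Family tag inserted between prefix and index.
#' @return Named character vector, gene id -> name.
#' @export
name_genes <- function(loci, prefix, family_tag = "bHLH") {
  if (nrow(loci) == 0L) return(stats::setNames(character(0), character(0)))
  key <- paste(loci$chrom, loci$start)
  if (anyDuplicated(key))
    .warnf("duplicate coordinates among %s loci; breaking ties by gene id", prefix)
  ord <- order(.chrom_order(loci$chrom), loci$start, loci$gene)
  stats::setNames(sprintf("%s%s%03d", prefix, family_tag, seq_len(nrow(loci))),
                  loci$gene[ord])
}

#' Per-species percentages over the binding categories
#'
#' @param gene_table Data frame with `species` and `category`.
#' @return Data frame (`species`, `category`, `count`, `percent`); percents
#'   are exact (format to 0.1 for display) and sum to 100 per species.
#' @export
summarize_categories <- function(gene_table) {
  rows <- list()
  for (sp in sort(unique(gene_table$species))) {
    d <- gene_table[gene_table$species == sp, ]
    for (cat in binding_categories()) {
      cnt <- sum(d$category == cat)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, category = cat, count = cnt,
        percent = 100 * cnt / nrow(d), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag root-expressed candidates in a paralogous cluster
#'
#' Candidates are the cluster genes that are tissue-predominant in the target
#' tissue and (when a clade assignment is supplied) fall in the target clade
#' (default: the clade holding most predominant cluster genes). One candidate
#' per species is expected; deviations are reported with a warning. Cluster
#' genes without an expression record are skipped with a warning.
#'
#' @param cluster_genes Character vector of paralogous-cluster gene ids.
#' @param calls Output of [call_tissue_predominance()].
#' @param clades Optional clade assignment (`gene`, `clade`).
#' @param target_clade Optional clade label restricting candidates.
#' @param loci Optional locus table used for the per-species expectation.
#' @return Character vector of candidate gene ids.
#' @export
flag_brp_candidates <- function(cluster_genes, calls, clades = NULL,
                                target_clade = NULL, loci = NULL) {
  missing <- setdiff(cluster_genes, calls$gene)
  if (length(missing))
    .warnf("no expression record for cluster gene(s) %s; skipped",
           paste(missing, collapse = ", "))
  present <- intersect(cluster_genes, calls$gene)
  pred <- calls$gene[calls$verdict & calls$gene %in% present]
  if (!is.null(clades)) {
    if (is.null(target_clade)) {
      in_cluster <- clades[clades$gene %in% cluster_genes, , drop = FALSE]
      tab <- table(in_cluster$clade[in_cluster$gene %in% pred])
      if (length(tab)) target_clade <- names(tab)[which.max(tab)]
    }
    if (!is.null(target_clade))
      pred <- intersect(pred, clades$gene[clades$clade == target_clade])
  }
  if (!length(pred)) {
    .warnf("no %s candidate found in the paralogous cluster", "tissue-predominant")
    return(character(0))
  }
  if (!is.null(loci)) {
    sp <- loci$species[match(pred, loci$gene)]
    per <- table(sp)
    if (any(per != 1L))
      .warnf("expected one candidate per species; got: %s",
             paste(sprintf("%s=%d", names(per), per), collapse = ", "))
  }
  sort(pred)
}

#' Full-analysis configuration
#'
#' @param input_dir Directory of per-species FASTA/GFF3/TSV inputs (the
#'   layout written by [emit_files()]).
#' @param species Species labels; inferred from the directory when `NULL`.
#' @param profile Domain profile; defaults to the packaged one.
#' @param rules Binding rules.
#' @param min_block_size,max_gap_ranks,match_score,gap_penalty Collinearity
#'   chaining parameters.
#' @param best_hit_delta Per-gene best-hit slack for inter-genomic anchors
#'   (see [filter_best_hits()]).
#' @param recent_paralog_min_similarity Intra-species anchors at or above
#'   this protein identity count as recent duplicates and keep both copies in
#'   one OG during merging.
#' @param max_tandem_gap Maximum intervening genes inside a tandem cluster.
#' @param target_tissue Tissue for predominance calls and candidate flagging.
#' @param fold_threshold,min_expression Predominance parameters.
#' @param n_clades Clade count for the cluster phylogeny.
#' @param recent_dup_threshold Ks bound for "recent" duplications.
#' @param bt_anchor_genes Known members of the tandem regulator cluster used
#'   to seed the cluster/candidate analysis (`NULL` disables that stage).
#' @param distance_method,partial_deletion Distance-matrix options.
#' @param bootstrap_reps Bootstrap replicates for the cluster tree.
#' @param seed Seed for the pipeline's stochastic steps (bootstrap).
#' @param out_dir Optional directory for TSV/Newick outputs.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(input_dir, species = NULL, profile = NULL,
                            rules = binding_rules(),
                            min_block_size = 5L, max_gap_ranks = 25L,
                            match_score = 1, gap_penalty = 0.05,
                            best_hit_delta = 0.03,
                            recent_paralog_min_similarity = 0.8,
                            max_tandem_gap = 1L,
                            target_tissue = "root", fold_threshold = 2,
                            min_expression = 1, n_clades = 5L,
                            recent_dup_threshold = 0.32,
                            bt_anchor_genes = NULL,
                            distance_method = "poisson",
                            partial_deletion = 0.8,
                            bootstrap_reps = 0L, seed = 1L, out_dir = NULL) {
  if (!dir.exists(input_dir)) .stopf("input_dir does not exist: %s", input_dir)
  structure(as.list(environment()), class = "analysis_config")
}

#' @noRd
.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' @noRd
.stage_error <- function(stage, e) {
  .stopf("stage '%s' failed: %s", stage, conditionMessage(e))
}

# Ka/Ks for a set of gene pairs via protein alignment -> codon alignment ->
# NG86.
#' @noRd
.kaks_for_pairs <- function(pairs, proteins, cds) {
  if (!nrow(pairs)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      S = numeric(0), N = numeric(0), Sd = numeric(0),
                      Nd = numeric(0), ka = numeric(0), ks = numeric(0),
                      ratio = numeric(0), saturated = logical(0)))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    paln <- align_proteins_global(proteins[[ga]], proteins[[gb]])
    caln <- backtranslate_codon_alignment(paln, cds[[ga]], cds[[gb]])
    r <- compute_ng86(caln)
    data.frame(gene_a = ga, gene_b = gb, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               ka = r$Ka, ks = r$Ks, ratio = r$ratio, saturated = r$saturated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full comparative analysis
#'
#' Stages: load -> domain -> classify -> synteny -> OG/paralog/tandem ->
#' Ka/Ks -> cluster tree/clades/expansion -> expression -> report. Each stage
#' logs record counts to stderr; a failure aborts with the stage name.
#'
#' @param config An [analysis_config()].
#' @return Object of class `report_bundle` (see the components in the
#'   Details).
#' @details The report contains: `gene_table` (per-gene name, domain, binding
#'   category, intron pattern), `category_percent`, `blocks_inter`,
#'   `blocks_intra`, `ortholog_pairs`, `ogs`, `paralog_pairs`, `kaks`,
#'   `tandem`, `cluster` (tree, clades, Ks table, expansion calls),
#'   `expression_calls` and `brp_candidates`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config
  profile <- if (is.null(cfg$profile)) default_domain_profile() else cfg$profile

  bundle <- tryCatch(load_bundle(cfg$input_dir, cfg$species),
                     error = function(e) .stage_error("load", e))
  .stage_log("load", "%d species, %d loci, %d anchors",
             length(bundle$species), nrow(bundle$loci), nrow(bundle$anchors))

  # ---- domain location + classification ------------------------------------
  gene_rows <- list()
  tryCatch({
    for (sp in bundle$species) {
      d <- bundle$data[[sp]]
      name_map <- name_genes(d$loci, sp)
      for (gid in d$loci$gene) {
        ann <- find_bhlh_domain(d$proteins[[gid]], profile)
        if (is.null(ann)) next
        ann$id <- gid
        ann <- partition_regions(ann, profile)
        category <- classify_binding(d$proteins[[gid]], ann, profile, cfg$rules)
        nb <- count_basic_residues(d$proteins[[gid]], ann, profile, cfg$rules)
        events <- map_introns_to_domain(d$models[[gid]], ann, d$cds[[gid]])
        pattern <- type_intron_pattern(events)
        lo <- d$loci[d$loci$gene == gid, ]
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene = gid, name = unname(name_map[gid]), species = sp,
          chrom = lo$chrom, start = lo$start,
          domain_start = ann$start, domain_end = ann$end,
          domain_score = ann$score, basic_count = nb,
          category = category, pattern = pattern,
          n_domain_introns = nrow(events), stringsAsFactors = FALSE)
      }
    }
  }, error = function(e) .stage_error("domain", e))
  gene_table <- do.call(rbind, gene_rows)
  if (is.null(gene_table)) .stopf("stage 'domain' failed: no domain found in any protein")
  .stage_log("domain", "%d family genes with located domains", nrow(gene_table))
  family_genes <- gene_table$gene
  category_percent <- summarize_categories(gene_table)

  # ---- synteny -------------------------------------------------------------
  loci <- bundle$loci
  sp_of <- stats::setNames(loci$species, loci$gene)
  anc <- bundle$anchors
  is_inter <- sp_of[anc$gene_a] != sp_of[anc$gene_b]
  res <- tryCatch({
    inter <- filter_best_hits(anc[is_inter, , drop = FALSE], loci, cfg$best_hit_delta)
    blocks_inter <- chain_collinear_blocks(inter, loci, cfg$min_block_size,
                                           cfg$max_gap_ranks, cfg$match_score,
                                           cfg$gap_penalty)
    blocks_intra <- chain_collinear_blocks(anc[!is_inter, , drop = FALSE], loci,
                                           cfg$min_block_size, cfg$max_gap_ranks,
                                           cfg$match_score, cfg$gap_penalty)
    list(inter = blocks_inter, intra = blocks_intra)
  }, error = function(e) .stage_error("synteny", e))
  .stage_log("synteny", "%d inter-genomic and %d intra-genomic blocks",
             length(res$inter), length(res$intra))

  ortho_pairs <- derive_ortholog_pairs(res$inter, family_genes)
  paralog_pairs <- find_paralog_pairs(res$intra, family_genes)
  tandem <- detect_tandem_clusters(loci, anc[!is_inter, , drop = FALSE],
                                   cfg$max_tandem_gap)
  tandem <- tandem[tandem$gene %in% family_genes, , drop = FALSE]
  tandem_edges <- do.call(rbind, lapply(
    split(tandem, paste(tandem$species, tandem$cluster)), function(cl) {
      if (nrow(cl) < 2L) return(NULL)
      data.frame(gene_a = cl$gene[-nrow(cl)], gene_b = cl$gene[-1])
    }))
  # recent same-species duplicates (near-identical proteins, e.g. fresh WGD
  # copies) stay with their parent's OG; ancient paralogs do not qualify
  recent <- anc[!is_inter &
                  anc$similarity >= cfg$recent_paralog_min_similarity &
                  anc$gene_a %in% family_genes & anc$gene_b %in% family_genes,
                c("gene_a", "gene_b"), drop = FALSE]
  intra_edges <- rbind(tandem_edges, recent)
  ogs <- merge_ortholog_groups(ortho_pairs, loci[loci$gene %in% family_genes, ],
                               intra_pairs = intra_edges)
  .stage_log("orthology", "%d ortholog pairs, %d OGs (%d cross-species), %d tandem clusters",
             nrow(ortho_pairs), nrow(ogs$summary), sum(ogs$summary$cross_species),
             length(unique(paste(tandem$species, tandem$cluster))))

  # ---- Ka/Ks ---------------------------------------------------------------
  proteins <- unlist(lapply(bundle$data, `[[`, "proteins"))
  names(proteins) <- unlist(lapply(bundle$data, function(x) names(x$proteins)))
  cds <- unlist(lapply(bundle$data, `[[`, "cds"))
  names(cds) <- unlist(lapply(bundle$data, function(x) names(x$cds)))
  kaks_pairs <- unique(rbind(
    if (nrow(paralog_pairs)) data.frame(gene_a = paralog_pairs$gene_a,
                                        gene_b = paralog_pairs$gene_b,
                                        source = "paralog"),
    if (!is.null(tandem_edges) && nrow(tandem_edges) > 0L)
      do.call(rbind, lapply(split(tandem, paste(tandem$species, tandem$cluster)),
                            function(cl) {
                              cmb <- utils::combn(cl$gene, 2)
                              data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                                         source = "tandem")
                            }))
  ))
  kaks <- tryCatch({
    if (!is.null(kaks_pairs) && nrow(kaks_pairs)) {
      key <- .pair_key(kaks_pairs$gene_a, kaks_pairs$gene_b)
      kaks_pairs <- kaks_pairs[!duplicated(key), , drop = FALSE]
      cbind(.kaks_for_pairs(kaks_pairs, proteins, cds),
            source = kaks_pairs$source)
    } else .kaks_for_pairs(data.frame(gene_a = character(0), gene_b = character(0)),
                           proteins, cds)
  }, error = function(e) .stage_error("kaks", e))
  .stage_log("kaks", "%d pairs (%d saturated)", nrow(kaks), sum(kaks$saturated))

  # ---- designated cluster analysis -----------------------------------------
  cluster <- NULL
  brp_candidates <- character(0)
  # ---- expression ----------------------------------------------------------
  expr <- tryCatch({
    m <- log_transform_matrix(bundle$fpkm)
    call_tissue_predominance(m, cfg$target_tissue, cfg$fold_threshold,
                             cfg$min_expression)
  }, error = function(e) .stage_error("expression", e))
  .stage_log("expression", "%d genes, %d predominant in %s",
             nrow(expr), sum(expr$verdict), cfg$target_tissue)

  if (!is.null(cfg$bt_anchor_genes)) {
    cluster <- tryCatch(
      .cluster_analysis(cfg, gene_table, ogs, paralog_pairs, proteins, cds, loci),
      error = function(e) .stage_error("cluster", e))
    if (!is.null(cluster)) {
      brp_candidates <- flag_brp_candidates(cluster$paralog_og_members, expr,
                                            clades = cluster$clades, loci = loci)
      .stage_log("cluster", "%d cluster genes, %d clades, %d candidate(s)",
                 length(cluster$members), length(unique(cluster$clades$clade)),
                 length(brp_candidates))
    }
  }

  out <- structure(list(
    gene_table = gene_table, category_percent = category_percent,
    blocks_inter = res$inter, blocks_intra = res$intra,
    ortholog_pairs = ortho_pairs, ogs = ogs, paralog_pairs = paralog_pairs,
    tandem = tandem, kaks = kaks, cluster = cluster,
    expression_calls = expr, brp_candidates = brp_candidates,
    config = cfg), class = "report_bundle")
  if (!is.null(cfg$out_dir)) .write_report(out, cfg$out_dir)
  out
}

# Cluster phylogeny around the designated tandem regulator cluster: find its
# OG, the paralogous OG most linked to it, build an NJ tree over the members'
# full-length proteins, assign clades and infer expansions/losses from Ks.
#' @noRd
.cluster_analysis <- function(cfg, gene_table, ogs, paralog_pairs, proteins, cds, loci) {
  mem <- ogs$membership
  anchor_ogs <- mem$og[mem$gene %in% cfg$bt_anchor_genes]
  if (!length(anchor_ogs)) .stopf("none of the bt_anchor_genes are in an OG")
  bt_og <- names(sort(table(anchor_ogs), decreasing = TRUE))[1]
  bt_members <- mem$gene[mem$og == bt_og]
  og_of <- stats::setNames(mem$og, mem$gene)
  partner <- c(og_of[paralog_pairs$gene_b][og_of[paralog_pairs$gene_a] == bt_og],
               og_of[paralog_pairs$gene_a][og_of[paralog_pairs$gene_b] == bt_og])
  partner <- partner[!is.na(partner) & partner != bt_og]
  if (!length(partner))
    .stopf("no paralogous OG linked to the designated cluster OG %s", bt_og)
  brp_og <- names(sort(table(partner), decreasing = TRUE))[1]
  brp_members <- mem$gene[mem$og == brp_og]
  members <- c(bt_members, brp_members)
  seqs <- proteins[members]
  width <- max(nchar(seqs))
  aln <- vapply(seqs, function(s)
    paste0(s, strrep("-", width - nchar(s))), character(1))
  D <- protein_distance_matrix(aln, method = cfg$distance_method,
                               coverage = cfg$partial_deletion)
  tree <- build_nj_tree(D)
  support <- NULL
  if (cfg$bootstrap_reps > 0L)
    support <- bootstrap_support(aln, cfg$bootstrap_reps, cfg$seed,
                                 method = cfg$distance_method,
                                 coverage = cfg$partial_deletion)$support
  k <- min(cfg$n_clades, length(members))
  clades <- assign_clades(tree, k)
  cmb <- utils::combn(members, 2)
  ks <- .kaks_for_pairs(data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ]),
                        proteins, cds)
  ks_tab <- data.frame(gene_a = ks$gene_a, gene_b = ks$gene_b, ks = ks$ks,
                       saturated = ks$saturated)
  members_df <- data.frame(gene = members,
                           species = loci$species[match(members, loci$gene)])
  members_df <- merge(members_df, clades, by = "gene")
  expansion <- infer_lineage_expansion(members_df, ks_tab,
                                       cfg$recent_dup_threshold)
  list(bt_og = bt_og, brp_og = brp_og, members = members,
       bt_og_members = bt_members, paralog_og_members = brp_members,
       tree = tree, support = support, clades = clades, ks = ks_tab,
       expansion = expansion)
}

#' @noRd
.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(report$gene_table, file.path(out_dir, "gene_table.tsv"))
  .write_tsv(report$category_percent, file.path(out_dir, "category_percent.tsv"))
  .write_tsv(report$ogs$membership, file.path(out_dir, "ortholog_groups.tsv"))
  .write_tsv(report$paralog_pairs, file.path(out_dir, "paralog_pairs.tsv"))
  .write_tsv(report$kaks, file.path(out_dir, "kaks.tsv"))
  .write_tsv(report$tandem, file.path(out_dir, "tandem_clusters.tsv"))
  .write_tsv(report$expression_calls, file.path(out_dir, "expression_calls.tsv"))
  if (!is.null(report$cluster)) {
    ape::write.tree(report$cluster$tree, file.path(out_dir, "cluster_tree.nwk"))
    .write_tsv(report$cluster$clades, file.path(out_dir, "cluster_clades.tsv"))
    .write_tsv(report$cluster$expansion, file.path(out_dir, "cluster_expansion.tsv"))
  }
  writeLines(report$brp_candidates, file.path(out_dir, "brp_candidates.txt"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(paste0("report_bundle: %d genes, %d OGs, %d paralog pairs, ",
                     "%d tandem clusters, %d Ka/Ks pairs, %d candidate(s)\n"),
              nrow(x$gene_table), nrow(x$ogs$summary), nrow(x$paralog_pairs),
              length(unique(paste(x$tandem$species, x$tandem$cluster))),
              nrow(x$kaks), length(x$brp_candidates)))
  invisible(x)
}
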