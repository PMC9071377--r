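# Conversion of simulated tip genomes into the emitted bundle: coordinates,
# gene models, sequences, homology anchors, expression and ground truth.

#' @noRd
.exons_from_introns <- function(gstart, cds_len, introns, strand, intron_len = 200L) {
  bounds <- c(0L, introns, cds_len)
  seg <- diff(bounds)
  k <- length(seg)
  total <- cds_len + intron_len * (k - 1L)
  if (strand == "+") {
    starts <- gstart + cumsum(c(0L, utils::head(seg, -1L) + intron_len))
    data.frame(start = starts, end = starts + seg)
  } else {
    cum <- cumsum(seg)
    starts <- gstart + total - cum - intron_len * (seq_len(k) - 1L)
    data.frame(start = starts, end = starts + seg)
  }
}

#' @noRd
.finalize_species <- function(genome, sp) {
  if (!length(genome)) {
    empty_loci <- data.frame(gene = character(0), species = character(0),
                             chrom = character(0), rank = integer(0),
                             start = numeric(0), end = numeric(0),
                             strand = character(0))
    empty_info <- data.frame(gene = character(0), species = character(0),
                             family = integer(0), lineage = character(0),
                             uid = character(0), role = character(0),
                             clade_copy = integer(0), category = character(0),
                             pattern = character(0), tissue = character(0),
                             base_mean = numeric(0))
    return(list(loci = empty_loci, models = list(),
                proteins = stats::setNames(character(0), character(0)),
                cds = stats::setNames(character(0), character(0)),
                info = empty_info))
  }
  ord <- order(vapply(genome, `[[`, 0L, "chrom"),
               vapply(genome, `[[`, 0, "pos"))
  genome <- genome[ord]
  n <- length(genome)
  ids <- sprintf("%s_%03d", sp, seq_len(n))
  chroms <- vapply(genome, `[[`, 0L, "chrom")
  loci <- data.frame(gene = ids, species = sp,
                     chrom = paste0("chr", chroms),
                     rank = NA_integer_, start = NA_real_, end = NA_real_,
                     strand = vapply(genome, `[[`, "", "strand"),
                     stringsAsFactors = FALSE)
  models <- vector("list", n)
  proteins <- character(n)
  cds <- character(n)
  intron_len <- 200L
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    cur <- 1000L
    for (r in seq_along(idx)) {
      i <- idx[r]
      g <- genome[[i]]
      cds_len <- 3L * length(g$codons)
      total <- cds_len + intron_len * length(g$introns)
      loci$rank[i] <- r
      loci$start[i] <- cur
      loci$end[i] <- cur + total
      exons <- .exons_from_introns(cur, cds_len, g$introns, g$strand, intron_len)
      models[[i]] <- gene_model(ids[i], paste0("chr", ch), g$strand, exons)
      proteins[i] <- translate_codons(g$codons)
      cds[i] <- paste(g$codons, collapse = "")
      cur <- cur + total + 2000L
    }
  }
  names(models) <- names(proteins) <- names(cds) <- ids
  info <- data.frame(gene = ids, species = sp,
                     family = vapply(genome, `[[`, 0L, "family"),
                     lineage = vapply(genome, `[[`, "", "lineage"),
                     uid = vapply(genome, `[[`, "", "uid"),
                     role = vapply(genome, `[[`, "", "role"),
                     clade_copy = vapply(genome, `[[`, 0L, "clade_copy"),
                     category = vapply(genome, `[[`, "", "category"),
                     pattern = vapply(genome, `[[`, "", "pattern"),
                     tissue = vapply(genome, `[[`, "", "tissue"),
                     base_mean = vapply(genome, `[[`, 0, "base_mean"),
                     stringsAsFactors = FALSE)
  list(loci = loci, models = models, proteins = proteins, cds = cds, info = info)
}

#' @noRd
.truth_tandem_clusters <- function(info, loci) {
  d <- merge(info[, c("gene", "family")], loci, by = "gene")
  out <- list()
  for (sp in sort(unique(d$species))) {
    ds <- d[d$species == sp, ]
    ds <- ds[order(.chrom_order(ds$chrom), ds$rank), ]
    runs <- list()
    for (ch in unique(ds$chrom)) {
      dc <- ds[ds$chrom == ch, ]
      if (nrow(dc) < 2L) next
      grp <- cumsum(c(TRUE, diff(dc$rank) != 1L | diff(dc$family) != 0L))
      for (g in split(dc, grp)) if (nrow(g) >= 2L) runs[[length(runs) + 1L]] <- g
    }
    if (!length(runs)) next
    starts <- vapply(runs, function(g) min(g$start), numeric(1))
    chord <- vapply(runs, function(g) min(.chrom_order(g$chrom)), numeric(1))
    runs <- runs[order(chord, starts)]
    for (k in seq_along(runs)) {
      g <- runs[[k]]
      out[[length(out) + 1L]] <- data.frame(
        species = sp, cluster = paste0("T", k), chrom = g$chrom,
        gene = g$gene, rank = g$rank, start = g$start, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(species = character(0), cluster = character(0),
                      chrom = character(0), gene = character(0),
                      rank = integer(0), start = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @noRd
.finalize_bundle <- function(tips, cfg, env) {
  sp_data <- lapply(names(tips), function(sp) .finalize_species(tips[[sp]], sp))
  names(sp_data) <- names(tips)
  loci <- do.call(rbind, lapply(sp_data, `[[`, "loci"))
  info <- do.call(rbind, lapply(sp_data, `[[`, "info"))
  rownames(loci) <- rownames(info) <- NULL
  proteins <- unlist(lapply(sp_data, `[[`, "proteins"))
  names(proteins) <- unlist(lapply(sp_data, function(x) names(x$proteins)))
  # homology anchors: all gene pairs sharing a pre-tetraploidy family
  anchors <- list()
  for (fam in split(info, info$family)) {
    if (nrow(fam) < 2L) next
    cmb <- utils::combn(seq_len(nrow(fam)), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      anchors[[length(anchors) + 1L]] <- data.frame(
        gene_a = fam$gene[i], gene_b = fam$gene[j],
        similarity = .protein_identity(proteins[[fam$gene[i]]],
                                       proteins[[fam$gene[j]]]),
        type = if (fam$species[i] == fam$species[j]) "intra" else "inter",
        stringsAsFactors = FALSE)
    }
  }
  anchors <- if (length(anchors)) do.call(rbind, anchors)
  else data.frame(gene_a = character(0), gene_b = character(0),
                  similarity = numeric(0), type = character(0))
  # FPKM matrix with log-normal noise around planted per-tissue means
  tp <- cfg$tissue_profiles
  fpkm <- matrix(NA_real_, nrow(info), length(tp$tissues),
                 dimnames = list(info$gene, tp$tissues))
  for (i in seq_len(nrow(info))) {
    mu <- rep(info$base_mean[i], length(tp$tissues))
    if (!is.na(info$tissue[i]))
      mu[match(info$tissue[i], tp$tissues)] <- info$base_mean[i] * tp$fold
    fpkm[i, ] <- stats::rlnorm(length(mu), meanlog = log(mu), sdlog = tp$noise_sdlog)
  }
  events <- if (length(env$events)) do.call(rbind, env$events)
  else data.frame(type = character(0), time = numeric(0), branch = character(0),
                  parent = character(0), child = character(0),
                  lineage = character(0))
  uid2id <- setNames(info$gene, info$uid)
  events$parent_gene <- unname(uid2id[events$parent])
  events$child_gene <- unname(uid2id[events$child])
  ground_truth <- list(
    og = data.frame(gene = info$gene, og = info$lineage, species = info$species,
                    stringsAsFactors = FALSE),
    tdg_clusters = .truth_tandem_clusters(info, loci),
    binding = data.frame(gene = info$gene, category = info$category,
                         stringsAsFactors = FALSE),
    introns = data.frame(gene = info$gene, pattern = info$pattern,
                         stringsAsFactors = FALSE),
    branch_omega = cfg$omega_by_branch,
    duplication_events = events,
    bt_genes = info$gene[info$role == "bt" & !is.na(info$role)],
    brp_genes = info$gene[info$role == "brp" & !is.na(info$role)],
    brp_sibling_genes = info$gene[info$role == "brp_sib" & !is.na(info$role)],
    cluster_copies = info[!is.na(info$role),
                          c("gene", "species", "role", "clade_copy")],
    tissue_bias = data.frame(gene = info$gene, tissue = info$tissue,
                             stringsAsFactors = FALSE)
  )
  structure(list(
    species = names(tips),
    data = lapply(sp_data, function(x) x[c("loci", "models", "proteins", "cds")]),
    loci = loci,
    anchors = anchors,
    fpkm = expression_matrix(fpkm),
    ground_truth = ground_truth,
    config = cfg
  ), class = "pangenome_bundle")
}

#' @export
print.pangenome_bundle <- function(x, ...) {
  counts <- vapply(x$data, function(d) nrow(d$loci), integer(1))
  cat(sprintf("pangenome_bundle: %d species (%s), %d genes, %d anchors, %d OGs\n",
              length(x$species),
              paste(sprintf("%s:%d", names(counts), counts), collapse = ", "),
              nrow(x$loci), nrow(x$anchors),
              length(unique(x$ground_truth$og$og))))
  invisible(x)
}
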