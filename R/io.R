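# Standard-format I/O: FASTA via Biostrings, GFF3 via rtracklayer, TSV
# tables. Internal coordinates are 0-based half-open; GFF3 is converted on
# read and write.

#' @noRd
.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(d)
}

#' @noRd
.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @noRd
.models_to_gff <- function(models, loci) {
  rows <- list()
  add <- function(chrom, start0, end0, strand, type, id, parent, phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start0 + 1L, end = end0, strand = strand,
      type = type, ID = id, Parent = parent, phase = phase,
      stringsAsFactors = FALSE)
  }
  for (gid in loci$gene) {
    m <- models[[gid]]
    lo <- loci[loci$gene == gid, ]
    add(lo$chrom, lo$start, lo$end, lo$strand, "gene", gid, NA_character_)
    tid <- paste0(gid, ".t1")
    add(lo$chrom, lo$start, lo$end, lo$strand, "mRNA", tid, gid)
    lens <- m$exons$end - m$exons$start
    cumprev <- c(0L, cumsum(lens)[-length(lens)])
    phases <- (3L - cumprev %% 3L) %% 3L
    for (k in seq_len(nrow(m$exons))) {
      add(lo$chrom, m$exons$start[k], m$exons$end[k], lo$strand, "exon",
          sprintf("%s.exon%d", tid, k), tid)
      add(lo$chrom, m$exons$start[k], m$exons$end[k], lo$strand, "CDS",
          sprintf("%s.cds%d", tid, k), tid, phases[k])
    }
  }
  do.call(rbind, rows)
}

#' @noRd
.write_gff3 <- function(models, loci, path) {
  tab <- .models_to_gff(models, loci)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  parent <- ifelse(is.na(tab$Parent), list(character(0)), as.list(tab$Parent))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(parent)
  S4Vectors::mcols(gr)$phase <- tab$phase
  rtracklayer::export(gr, path, format = "gff3")
  length(unique(tab$ID[tab$type == "gene"]))
}

#' Emit a pangenome bundle to standard files
#'
#' Writes per-species protein/CDS FASTA and GFF3, inter/intra anchor TSVs, an
#' FPKM TSV and ground-truth TSVs under `out_dir`, and returns a manifest of
#' files with record counts.
#'
#' @param bundle A `pangenome_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest (`file`, `records`).
#' @export
emit_files <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) .stopf("cannot create output directory %s", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE)))
    .stopf("output directory %s is not writable", out_dir)
  unlink(probe)
  manifest <- list()
  note <- function(file, records)
    manifest[[length(manifest) + 1L]] <<- data.frame(file = file, records = records)
  for (sp in bundle$species) {
    d <- bundle$data[[sp]]
    pf <- file.path(out_dir, paste0(sp, "_proteins.fasta"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(d$proteins), pf)
    note(basename(pf), length(d$proteins))
    cf <- file.path(out_dir, paste0(sp, "_cds.fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(d$cds), cf)
    note(basename(cf), length(d$cds))
    gf <- file.path(out_dir, paste0(sp, ".gff3"))
    n <- if (nrow(d$loci)) .write_gff3(d$models, d$loci, gf) else {
      writeLines("##gff-version 3", gf); 0L
    }
    note(basename(gf), n)
  }
  for (ty in c("inter", "intra")) {
    anc <- bundle$anchors[bundle$anchors$type == ty, , drop = FALSE]
    f <- file.path(out_dir, paste0("anchors_", ty, ".tsv"))
    note(basename(f), .write_tsv(anc, f))
  }
  fp <- data.frame(gene = rownames(bundle$fpkm$values),
                   bundle$fpkm$values, check.names = FALSE)
  f <- file.path(out_dir, "fpkm.tsv")
  note(basename(f), .write_tsv(fp, f))
  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  gt <- bundle$ground_truth
  for (nm in c("og", "tdg_clusters", "binding", "introns", "duplication_events",
               "cluster_copies", "tissue_bias")) {
    f <- file.path(gt_dir, paste0(nm, ".tsv"))
    note(file.path("ground_truth", paste0(nm, ".tsv")), .write_tsv(gt[[nm]], f))
  }
  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  out
}

#' Load gene models and loci from a GFF3 file
#'
#' Imports gene/mRNA/CDS features, converts 1-based GFF3 coordinates to the
#' package's 0-based half-open convention, selects one representative
#' transcript per gene (longest CDS), honors CDS phase, and derives per-
#' chromosome gene ranks. Genes whose CDS length is not a codon multiple
#' after phase handling are excluded with a warning.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param species Species label recorded in the locus table.
#' @return List with `loci` (data frame) and `models` (named list of
#'   [gene_model()]s).
#' @export
load_gene_models <- function(gff3_path, species) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gr) == 0L)
    return(list(loci = data.frame(gene = character(0), species = character(0),
                                  chrom = character(0), rank = integer(0),
                                  start = numeric(0), end = numeric(0),
                                  strand = character(0)),
                models = list()))
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  gene_idx <- which(type == "gene")
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  cds_idx <- which(type == "CDS")
  models <- list()
  loci_rows <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    mr <- mrna_idx[parents[mrna_idx] == gid]
    if (!length(mr)) next
    best <- NULL; best_len <- -1L
    for (mi in mr) {
      tid <- ids[mi]
      ci <- cds_idx[parents[cds_idx] == tid]
      if (!length(ci)) next
      len <- sum(GenomicRanges::width(gr[ci]))
      if (len > best_len) { best <- ci; best_len <- len }
    }
    if (is.null(best)) next
    strand <- as.character(GenomicRanges::strand(gr[gi]))
    starts <- GenomicRanges::start(gr[best]) - 1L  # to 0-based
    ends <- GenomicRanges::end(gr[best])
    ord <- if (strand == "-") order(-starts) else order(starts)
    exons <- data.frame(start = starts[ord], end = ends[ord])
    ph <- gr$phase[best][ord][1]
    ph <- if (is.na(ph)) 0L else as.integer(ph)
    m <- tryCatch(gene_model(gid, as.character(GenomicRanges::seqnames(gr[gi])),
                             strand, exons, phase = ph),
                  error = function(e) {
                    .warnf("gene %s excluded: %s", gid, conditionMessage(e))
                    NULL
                  })
    if (is.null(m)) next
    models[[gid]] <- m
    loci_rows[[length(loci_rows) + 1L]] <- data.frame(
      gene = gid, species = species, chrom = m$chrom, rank = NA_integer_,
      start = GenomicRanges::start(gr[gi]) - 1L,
      end = as.numeric(GenomicRanges::end(gr[gi])),
      strand = strand, stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci_rows)
  loci <- loci[order(.chrom_order(loci$chrom), loci$start), ]
  for (ch in unique(loci$chrom))
    loci$rank[loci$chrom == ch] <- seq_len(sum(loci$chrom == ch))
  rownames(loci) <- NULL
  list(loci = loci, models = models[loci$gene])
}

#' Read a protein FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
load_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a CDS FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of nucleotide sequences.
#' @export
load_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a homology anchor TSV
#' @param path TSV with columns `gene_a`, `gene_b`, `similarity`, `type`.
#' @return Data frame.
#' @export
load_anchor_table <- function(path) .read_tsv(path)

#' Read an FPKM TSV into an [expression_matrix()]
#' @param path TSV whose first column is the gene id, remaining columns
#'   tissues.
#' @return An `expression_matrix` (untransformed).
#' @export
load_fpkm_matrix <- function(path) {
  d <- .read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  expression_matrix(m)
}

#' Reload an emitted bundle directory
#'
#' Inverse of [emit_files()] minus the ground truth: per-species sequences,
#' gene models and loci, the combined anchor table and the FPKM matrix.
#'
#' @param dir Directory written by [emit_files()].
#' @param species Species labels; defaults to those inferred from the
#'   `*_proteins.fasta` files present.
#' @return List shaped like the corresponding `pangenome_bundle` fields.
#' @export
load_bundle <- function(dir, species = NULL) {
  if (is.null(species)) {
    species <- sort(sub("_proteins\\.fasta$", "",
                        basename(Sys.glob(file.path(dir, "*_proteins.fasta")))))
  }
  data <- lapply(species, function(sp) {
    gm <- load_gene_models(file.path(dir, paste0(sp, ".gff3")), sp)
    list(loci = gm$loci, models = gm$models,
         proteins = load_protein_fasta(file.path(dir, paste0(sp, "_proteins.fasta"))),
         cds = load_cds_fasta(file.path(dir, paste0(sp, "_cds.fasta"))))
  })
  names(data) <- species
  anchors <- rbind(load_anchor_table(file.path(dir, "anchors_inter.tsv")),
                   load_anchor_table(file.path(dir, "anchors_intra.tsv")))
  loci <- do.call(rbind, lapply(data, `[[`, "loci"))
  rownames(loci) <- NULL
  list(species = species, data = data, loci = loci, anchors = anchors,
       fpkm = load_fpkm_matrix(file.path(dir, "fpkm.tsv")))
}
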