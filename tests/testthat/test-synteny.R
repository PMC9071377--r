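# Collinear-block chaining, ortholog/paralog derivation, OG merging and
# tandem-cluster detection.

toy_loci <- function(n_a = 10, n_b = 10) {
  mk <- function(p, n, sp) {
    if (n == 0) return(NULL)
    data.frame(gene = sprintf("%s%02d", p, seq_len(n)), species = sp,
               chrom = "chr1", rank = seq_len(n), start = seq_len(n) * 1000,
               end = seq_len(n) * 1000 + 500, strand = "+")
  }
  rbind(mk("a", n_a, "A"), mk("b", n_b, "B"))
}

test_that("a perfectly collinear run chains into one block, size cutoff applies", {
  loci <- toy_loci()
  anc5 <- data.frame(gene_a = sprintf("a%02d", 1:5),
                     gene_b = sprintf("b%02d", 1:5), similarity = 0.9)
  blocks <- chain_collinear_blocks(anc5, loci, min_block_size = 5)
  expect_length(blocks, 1L)
  expect_identical(blocks[[1]]$size, 5L)
  expect_equal(blocks[[1]]$score, 5)
  expect_identical(blocks[[1]]$orientation, "same")
  anc4 <- anc5[1:4, ]
  expect_length(chain_collinear_blocks(anc4, loci, min_block_size = 5), 0L)
  expect_error(chain_collinear_blocks(
    data.frame(gene_a = "a01", gene_b = "zz", similarity = 1), loci),
    "unknown locus")
})

test_that("inverted runs are chained with decreasing b-ranks", {
  loci <- toy_loci()
  anc <- data.frame(gene_a = sprintf("a%02d", 1:6),
                    gene_b = sprintf("b%02d", 6:1), similarity = 0.9)
  blocks <- chain_collinear_blocks(anc, loci, min_block_size = 5)
  expect_length(blocks, 1L)
  expect_identical(blocks[[1]]$orientation, "inverted")
  expect_identical(blocks[[1]]$size, 6L)
})

test_that("emitted blocks always satisfy the rank-monotonicity invariant", {
  set.seed(31)
  loci <- toy_loci(30, 30)
  for (rep in 1:20) {
    anc <- data.frame(gene_a = sprintf("a%02d", sample(30, 12)),
                      gene_b = sprintf("b%02d", sample(30, 12)),
                      similarity = runif(12, 0.5, 1))
    blocks <- chain_collinear_blocks(anc, loci, min_block_size = 2)
    for (b in blocks) {
      expect_true(all(diff(b$anchors$rank_a) >= 1))
      db <- diff(b$anchors$rank_b)
      expect_true(all(db >= 1) || all(db <= -1))
    }
  }
})

test_that("top chain scores equal the brute-force subset maximum", {
  set.seed(97)
  loci <- toy_loci(40, 40)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    anc <- data.frame(gene_a = sprintf("a%02d", sample(40, n)),
                      gene_b = sprintf("b%02d", sample(40, n)),
                      similarity = 1)
    gp <- sample(c(0.05, 0.2), 1)
    mg <- sample(c(5L, 25L), 1)
    blocks <- chain_collinear_blocks(anc, loci, min_block_size = 1,
                                     max_gap_ranks = mg, gap_penalty = gp)
    got <- max(vapply(blocks, `[[`, 0, "score"))
    ra <- match(anc$gene_a, loci$gene[loci$species == "A"])
    rb <- match(anc$gene_b, loci$gene[loci$species == "B"])
    want <- oracle_best_chain_score(ra, rb, gap_penalty = gp, max_gap_ranks = mg)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("instance %d (n=%d gp=%.2f mg=%d)", rep, n, gp, mg))
  }
})

test_that("ortholog pairs are the family anchors inside blocks", {
  loci <- toy_loci()
  anc <- data.frame(gene_a = sprintf("a%02d", 1:5),
                    gene_b = sprintf("b%02d", 1:5), similarity = 0.9)
  blocks <- chain_collinear_blocks(anc, loci, min_block_size = 5)
  fam1 <- c("a03", "b03")
  p <- derive_ortholog_pairs(blocks, fam1)
  expect_identical(nrow(p), 1L)
  expect_setequal(c(p$gene_a, p$gene_b), fam1)
  expect_identical(nrow(derive_ortholog_pairs(blocks, character(0))), 0L)
  # a family anchor outside any block is excluded
  anc_extra <- rbind(anc, data.frame(gene_a = "a09", gene_b = "b01",
                                     similarity = 0.9))
  blocks2 <- chain_collinear_blocks(anc_extra, loci, min_block_size = 5)
  p2 <- derive_ortholog_pairs(blocks2, c("a09", "b01"))
  expect_identical(nrow(p2), 0L)
})

test_that("paralog pairs stay within one species and exclude self-pairs", {
  loci <- rbind(toy_loci(10, 0),
                data.frame(gene = sprintf("a2%02d", 1:10), species = "A",
                           chrom = "chr2", rank = 1:10, start = 1:10 * 1000,
                           end = 1:10 * 1000 + 500, strand = "+"))
  anc <- data.frame(gene_a = sprintf("a%02d", 1:5),
                    gene_b = sprintf("a2%02d", 1:5), similarity = 0.8)
  blocks <- chain_collinear_blocks(anc, loci, min_block_size = 5)
  pp <- find_paralog_pairs(blocks, loci$gene)
  expect_identical(nrow(pp), 5L)
  expect_true(all(pp$species == "A"))
  expect_true(all(pp$gene_a != pp$gene_b))
})

test_that("OG merging equals transitive closure and singles become specific OGs", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    genes <- sprintf("g%02d", seq_len(n))
    loci <- data.frame(gene = genes,
                       species = sample(c("A", "B", "C"), n, replace = TRUE),
                       chrom = "chr1", rank = seq_len(n),
                       start = seq_len(n) * 100, end = seq_len(n) * 100 + 50,
                       strand = "+")
    m <- sample(0:10, 1)
    pairs <- data.frame(gene_a = sample(genes, m, replace = TRUE),
                        gene_b = sample(genes, m, replace = TRUE))
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    ogs <- merge_ortholog_groups(pairs, loci)
    got <- sort(vapply(split(ogs$membership$gene, ogs$membership$og),
                       function(g) paste(sort(g), collapse = "|"), character(1)))
    want <- oracle_components(genes, pairs)
    expect_identical(unname(got), want)
    # disjointness and conservation of the family size
    expect_identical(sum(ogs$summary$size), n)
    expect_false(anyDuplicated(ogs$membership$gene) > 0)
  }
})

test_that("explicit pair chains merge transitively and isolated genes stand alone", {
  loci <- data.frame(gene = c("a", "b", "c", "d", "e", "f"),
                     species = c("A", "B", "C", "A", "B", "C"),
                     chrom = "chr1", rank = 1:6, start = 1:6 * 100,
                     end = 1:6 * 100 + 50, strand = "+")
  pairs <- data.frame(gene_a = c("a", "b", "d"), gene_b = c("b", "c", "e"))
  ogs <- merge_ortholog_groups(pairs, loci)
  sets <- split(ogs$membership$gene, ogs$membership$og)
  expect_setequal(vapply(sets, function(g) paste(sort(g), collapse = ""), ""),
                  c("abc", "de", "f"))
  expect_identical(sum(!ogs$summary$cross_species), 1L)
  # ids are zero-padded in descending species-count order
  expect_identical(ogs$summary$og, sprintf("OG%03d", 1:3))
})

test_that("tandem clusters follow the rank-distance relation", {
  loci <- data.frame(gene = sprintf("g%d", 1:10), species = "A", chrom = "chr1",
                     rank = 1:10, start = 1:10 * 1000, end = 1:10 * 1000 + 10,
                     strand = "+")
  anc <- data.frame(gene_a = c("g5", "g6"), gene_b = c("g6", "g7"),
                    similarity = 0.9)
  cl <- detect_tandem_clusters(loci, anc, max_gap = 1)
  expect_identical(sort(cl$gene), c("g5", "g6", "g7"))
  expect_identical(unique(cl$cluster), "T1")
  # rank distance above the cutoff does not cluster
  far <- data.frame(gene_a = "g5", gene_b = "g9", similarity = 0.9)
  expect_identical(nrow(detect_tandem_clusters(loci, far, max_gap = 1)), 0L)
  # one intervening gene is allowed at max_gap 1
  near <- data.frame(gene_a = "g5", gene_b = "g7", similarity = 0.9)
  expect_identical(nrow(detect_tandem_clusters(loci, near, max_gap = 1)), 2L)
})

test_that("tandem detection matches exhaustive pairwise clustering", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    loci <- data.frame(gene = sprintf("g%02d", 1:n),
                       species = sample(c("A", "B"), n, replace = TRUE),
                       chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                       rank = NA_integer_, start = NA_real_, end = NA_real_,
                       strand = "+")
    for (key in unique(paste(loci$species, loci$chrom))) {
      idx <- paste(loci$species, loci$chrom) == key
      loci$rank[idx] <- seq_len(sum(idx))
      loci$start[idx] <- seq_len(sum(idx)) * 1000
      loci$end[idx] <- loci$start[idx] + 10
    }
    m <- sample(1:12, 1)
    anc <- data.frame(gene_a = sample(loci$gene, m, replace = TRUE),
                      gene_b = sample(loci$gene, m, replace = TRUE),
                      similarity = 1)
    anc <- anc[anc$gene_a != anc$gene_b, , drop = FALSE]
    if (!nrow(anc)) next
    cl <- detect_tandem_clusters(loci, anc, max_gap = 1)
    got <- sort(unique(vapply(split(cl$gene, paste(cl$species, cl$cluster)),
                              function(g) paste(sort(g), collapse = "|"), character(1))))
    want <- oracle_tandem_sets(loci, anc, max_gap = 1)
    expect_identical(unname(got), want)
  }
})

test_that("best-hit filtering keeps each gene's top hit per target species", {
  loci <- toy_loci()
  anc <- data.frame(gene_a = c("a01", "a01", "a03", "a02"),
                    gene_b = c("b01", "b05", "b05", "b02"),
                    similarity = c(0.9, 0.7, 0.9, 0.8))
  # (a01, b05) is the best hit for neither side -> dropped
  kept <- filter_best_hits(anc, loci, delta = 0.05)
  expect_identical(nrow(kept), 3L)
  expect_false(any(kept$gene_a == "a01" & kept$gene_b == "b05"))
  # a weaker anchor survives while one side's best hit is within delta
  kept2 <- filter_best_hits(anc, loci, delta = 0.25)
  expect_identical(nrow(kept2), 4L)
})
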