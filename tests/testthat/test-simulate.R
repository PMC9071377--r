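# Pangenome simulator: configuration contracts, event bookkeeping, sequence
# evolution and file round-trips.

no_event_config <- function(seed = 3L, n = 20L, loss_rate = 0, ...) {
  simulation_config(tree = species_tree_spec(), n_ancestral_genes = n,
                    tandem_rate = 0, loss_rate = loss_rate, cluster_spec = NULL,
                    seed = seed, ...)
}

test_that("invalid configurations are rejected with the field named", {
  expect_error(simulation_config(tandem_rate = -1), "tandem_rate")
  expect_error(simulation_config(loss_rate = 2), "loss_rate")
  expect_error(simulation_config(binding_category_mix = c(GBOX = 0.6,
                                                          NON_BINDING = 0.3)),
               "binding_category_mix")
  expect_error(simulation_config(intron_pattern_mix = c(ZZ = 1)),
               "intron pattern")
  expect_error(species_tree_spec(wgd_events = list(list(branch = "nope",
                                                        time = 5, retention = 1))),
               "terminal branch")
  expect_error(species_tree_spec(shared_polyploidy_time = 10), "predate")
})

test_that("the no-event genome is copied unchanged to every species", {
  b <- simulate_pangenome(no_event_config())
  counts <- vapply(b$data, function(d) nrow(d$loci), integer(1))
  expect_true(all(counts == 20L))
  og_sizes <- table(b$ground_truth$og$og)
  expect_identical(length(og_sizes), 20L)
  expect_true(all(og_sizes == 3L))
  expect_identical(nrow(b$ground_truth$tdg_clusters), 0L)
})

test_that("a forced WGD doubles exactly the carrying species", {
  cfg <- simulation_config(
    tree = species_tree_spec(wgd_events = list(list(branch = "SpC", time = 10,
                                                    retention = 1.0))),
    n_ancestral_genes = 20L, tandem_rate = 0, loss_rate = 0,
    cluster_spec = NULL, seed = 3L)
  b <- simulate_pangenome(cfg)
  counts <- vapply(b$data, function(d) nrow(d$loci), integer(1))
  expect_identical(unname(counts[c("SpA", "SpB", "SpC")]), c(20L, 20L, 40L))
})

test_that("identical config and seed reproduce the bundle exactly", {
  b1 <- simulate_pangenome(simulation_config(seed = 11L))
  b2 <- simulate_pangenome(simulation_config(seed = 11L))
  expect_identical(b1, b2)
  b3 <- simulate_pangenome(simulation_config(seed = 12L))
  expect_false(identical(b1$anchors, b3$anchors))
})

test_that("gene counts reconcile with the logged duplication and loss events", {
  b <- default_test_bundle()
  ev <- b$ground_truth$duplication_events
  n0 <- b$config$n_ancestral_genes
  # each tip genome = ancestral count + gains - losses along its root path
  path_branches <- list(SpA = c("ancestral", "internal", "SpA"),
                        SpB = c("ancestral", "internal", "SpB"),
                        SpC = c("ancestral", "SpC"))
  for (sp in b$species) {
    gains <- sum(ev$type %in% c("tandem", "wgd") & ev$branch %in% path_branches[[sp]])
    losses <- sum(ev$type == "loss" & ev$branch %in% path_branches[[sp]])
    expect_identical(nrow(b$data[[sp]]$loci), n0 + gains - losses,
                     label = sprintf("%s conservation", sp))
  }
})

test_that("every CDS translates to its protein and models match sequences", {
  b <- default_test_bundle()
  for (sp in b$species) {
    d <- b$data[[sp]]
    for (g in d$loci$gene) {
      expect_identical(translate_codons(split_codons(d$cds[[g]])), d$proteins[[g]])
      expect_identical(d$models[[g]]$cds_length, nchar(d$cds[[g]]))
    }
  }
})

test_that("anchors connect only genes of one ground-truth family", {
  b <- default_test_bundle()
  og <- b$ground_truth$og
  fam <- setNames(sub("[ab]$", "", og$og), og$gene)  # pre-tetraploidy family
  expect_true(all(fam[b$anchors$gene_a] == fam[b$anchors$gene_b]))
})

test_that("ground-truth tandem clusters are adjacent same-family runs", {
  b <- default_test_bundle()
  tc <- b$ground_truth$tdg_clusters
  for (key in unique(paste(tc$species, tc$cluster))) {
    cl <- tc[paste(tc$species, tc$cluster) == key, ]
    expect_identical(length(unique(cl$chrom)), 1L)
    expect_true(all(diff(sort(cl$rank)) == 1L))
  }
})

test_that("zero-branch evolution is the identity and omega 0 forbids amino-acid change", {
  anc <- validate_codon_sequence(sample(sense_codons(), 400, replace = TRUE))
  expect_identical(evolve_codon_sequence(anc, 0, 0.5, seed = 1), anc)
  ev <- evolve_codon_sequence(anc, 0.8, 0, seed = 2)
  expect_identical(translate_codons(ev), translate_codons(anc))
  expect_false(identical(ev, anc))  # synonymous changes did occur
  expect_error(evolve_codon_sequence(c("ATG", "TAA", "AAA"), 0.1, 1), "stop")
  # constrained codons never change their amino acid
  ev2 <- evolve_codon_sequence(anc, 0.8, 1, seed = 3, constrained = 1:50)
  expect_identical(translate_codons(ev2[1:50]), translate_codons(anc[1:50]))
})

test_that("evolution under omega recovers the simulated dN/dS on average", {
  set.seed(21)
  anc <- validate_codon_sequence(sample(sense_codons(), 500, replace = TRUE))
  ratios <- vapply(1:30, function(i) {
    der <- evolve_codon_sequence(anc, 0.3, 0.5)
    compute_ng86(list(codons_a = anc, codons_b = der))$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.1)
})

test_that("emitted files round-trip through the pipeline loaders", {
  b <- simulate_pangenome(no_event_config(seed = 8L, n = 12L))
  dir <- withr::local_tempdir()
  manifest <- emit_files(b, dir)
  fa <- manifest$records[manifest$file == "SpA_proteins.fasta"]
  expect_identical(fa, nrow(b$data$SpA$loci))
  re <- load_bundle(dir)
  expect_identical(sort(re$species), sort(b$species))
  for (sp in b$species) {
    expect_identical(re$data[[sp]]$proteins, b$data[[sp]]$proteins)
    expect_identical(re$data[[sp]]$cds, b$data[[sp]]$cds)
    expect_identical(re$data[[sp]]$loci$gene, b$data[[sp]]$loci$gene)
    expect_identical(re$data[[sp]]$loci$rank, b$data[[sp]]$loci$rank)
    for (g in b$data[[sp]]$loci$gene)
      expect_identical(re$data[[sp]]$models[[g]]$introns_cds,
                       b$data[[sp]]$models[[g]]$introns_cds)
  }
  expect_equal(re$fpkm$values, b$fpkm$values, tolerance = 1e-6)
  got_anc <- re$anchors[order(re$anchors$gene_a, re$anchors$gene_b), ]
  want_anc <- b$anchors[order(b$anchors$gene_a, b$anchors$gene_b), ]
  expect_identical(got_anc$gene_a, want_anc$gene_a)
  expect_equal(got_anc$similarity, want_anc$similarity, tolerance = 1e-6)
})

test_that("an empty bundle emits valid empty files", {
  cfg <- no_event_config(seed = 5L, n = 1L, loss_rate = 1)
  b <- simulate_pangenome(cfg)  # certain loss empties every genome
  expect_identical(nrow(b$loci), 0L)
  dir <- withr::local_tempdir()
  manifest <- emit_files(b, dir)
  expect_true(all(manifest$records[grepl("fasta", manifest$file)] == 0))
})
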