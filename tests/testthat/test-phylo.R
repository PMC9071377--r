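# Distance matrices, neighbor joining, bootstrap, clades and expansion calls.

test_that("partial deletion and p-distances follow their definitions", {
  aln <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAACC", s3 = "AAAAAAAAAA")
  D <- protein_distance_matrix(aln, method = "p-distance", coverage = 0.8)
  expect_equal(D["s1", "s2"], 0.2)
  expect_equal(D["s1", "s3"], 0)
  # a column gapped in 1 of 3 rows (coverage 2/3 < 0.8) is removed
  aln2 <- c(s1 = "AAAAAAAAAA", s2 = "-AAAAAAACC", s3 = "AAAAAAAAAA")
  D2 <- protein_distance_matrix(aln2, method = "p-distance", coverage = 0.8)
  expect_equal(D2["s1", "s2"], 2 / 9)
  # Poisson correction of the same proportion
  D3 <- protein_distance_matrix(aln, method = "poisson")
  expect_equal(D3["s1", "s2"], -log(1 - 0.2))
  expect_true(isSymmetric(unname(D3)))
})

test_that("three-taxon NJ solves the closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3")
  Dn <- D; Dn[1, 2] <- 5
  expect_error(build_nj_tree(Dn), "not symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    phy <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(phy)
    got <- build_nj_tree(D)
    Dhat <- ape::cophenetic.phylo(got)[rownames(D), colnames(D)]
    expect_lt(max(abs(Dhat - D)), 1e-9)
    # cross-check topology against the independent ape implementation
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(ref))[1], 0)
  }
})

test_that("star-like equal distances yield zero internal branches", {
  n <- 6
  D <- matrix(2, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(D) <- 0
  tr <- build_nj_tree(D)
  internal <- tr$edge[, 2] > n
  expect_true(all(abs(tr$edge.length[internal]) < 1e-9))
})

test_that("bootstrap support is seed-deterministic and certain for invariant splits", {
  aln <- c(a = "AAAAAAGGGG", b = "AAAAAAGGGG", c = "TTTTTTGGGG", d = "TTTTTTGGGG")
  bs1 <- bootstrap_support(aln, n_reps = 50, seed = 9, method = "p-distance")
  bs2 <- bootstrap_support(aln, n_reps = 50, seed = 9, method = "p-distance")
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support >= 0 & bs1$support <= 1))
  # every column induces the same bipartition -> full support
  expect_true(all(bs1$support == 1))
  bs0 <- bootstrap_support(aln, n_reps = 0)
  expect_length(bs0$support, 0L)
})

test_that("clade cutting respects k, anchors and conflicts", {
  phy <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):3,((e:1,f:1):1,(g:1,h:1):1):3);")
  cl2 <- assign_clades(phy, 2)
  sets <- split(cl2$gene, cl2$clade)
  expect_setequal(vapply(sets, function(g) paste(sort(g), collapse = ""), ""),
                  c("abcd", "efgh"))
  cl4 <- assign_clades(phy, 4)
  expect_identical(length(unique(cl4$clade)), 4L)
  expect_setequal(unique(cl4$clade), c("I", "II", "III", "IV"))
  # k equal to the leaf count puts every leaf in its own clade
  cl8 <- assign_clades(phy, 8)
  expect_identical(anyDuplicated(cl8$clade), 0L)
  # anchors name their clades
  cla <- assign_clades(phy, 2, anchors = c(left = "a", right = "g"))
  expect_identical(cla$clade[cla$gene == "b"], "left")
  expect_identical(cla$clade[cla$gene == "h"], "right")
  expect_error(assign_clades(phy, 2, anchors = c(x = "a", y = "zz")), "not in tree")
})

test_that("a caterpillar tree with one long internal edge splits there", {
  phy <- ape::read.tree(
    text = "(a:0.1,(b:0.1,(c:0.1,(d:0.1,(e:0.1,f:0.1):0.2):5):0.2):0.2);")
  cl <- assign_clades(phy, 2)
  sets <- split(cl$gene, cl$clade)
  expect_setequal(vapply(sets, function(g) paste(sort(g), collapse = ""), ""),
                  c("abc", "def"))
})

test_that("expansion calls apply the intra-vs-inter Ks rule", {
  members <- data.frame(gene = c("m1", "m2", "m3", "c1", "w1"),
                        species = c("Me", "Me", "Me", "Cu", "Wa"),
                        clade = "I")
  ks <- data.frame(gene_a = c("m1", "m1", "m2", "m1", "m2", "m3", "c1"),
                   gene_b = c("m2", "m3", "m3", "c1", "c1", "c1", "w1"),
                   ks = c(0.10, 0.15, 0.12, 0.40, 0.45, 0.42, 0.50),
                   saturated = FALSE)
  calls <- infer_lineage_expansion(members, ks)
  me <- calls[calls$species == "Me", ]
  expect_identical(me$verdict, "post_speciation_expansion")
  expect_equal(me$max_intra_ks, 0.15)
  expect_equal(me$min_inter_ks, 0.40)
  expect_identical(calls$verdict[calls$species == "Cu"], "ancestral_retention")
  # a species with genes in no clade member is a loss
  members2 <- rbind(members, data.frame(gene = "x1", species = "Ex", clade = "II"))
  calls2 <- infer_lineage_expansion(members2, ks)
  expect_identical(calls2$verdict[calls2$clade == "I" & calls2$species == "Ex"],
                   "loss")
  # saturated pairs are excluded with a warning
  ks_sat <- ks
  ks_sat$saturated[4:7] <- TRUE
  expect_warning(infer_lineage_expansion(members, ks_sat), "saturated")
})
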