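# Nei-Gojobori counting, codon utilities and the alignment back-translation.

test_that("single-codon site counts follow single-mutation enumeration", {
  # TTT: of its 9 single-nucleotide changes only TTT->TTC is synonymous
  aln <- list(codons_a = "TTT", codons_b = "TTT")
  r <- compute_ng86(aln)
  expect_equal(r$S, 1 / 3, tolerance = 1e-12)
  expect_equal(r$N, 3 - 1 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
})

test_that("identical sequences give zero rates and no saturation", {
  cds <- c("ATG", "CTT", "GGA", "AAA", "TGG")
  r <- compute_ng86(list(codons_a = cds, codons_b = cds))
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_false(r$saturated)
  expect_equal(r$S + r$N, 3 * length(cds))
})

test_that("NG86 is symmetric and S+N equals three sites per codon", {
  set.seed(11)
  codons <- sense_codons()
  for (rep in 1:20) {
    a <- sample(codons, 30, replace = TRUE)
    b <- sample(codons, 30, replace = TRUE)
    r1 <- compute_ng86(list(codons_a = a, codons_b = b))
    r2 <- compute_ng86(list(codons_a = b, codons_b = a))
    expect_identical(r1$Sd, r2$Sd)
    expect_identical(r1$Nd, r2$Nd)
    expect_identical(r1$S, r2$S)
    expect_equal(r1$S + r1$N, 90, tolerance = 1e-10)
  }
})

test_that("gapped columns are excluded and empty alignments error", {
  r <- compute_ng86(list(codons_a = c("ATG", "---", "AAA"),
                         codons_b = c("ATG", "CCC", "AAG")))
  expect_equal(r$codons, 2L)
  expect_error(compute_ng86(list(codons_a = "---", codons_b = "ATG")),
               "no ungapped")
})

test_that("saturation flags high difference proportions", {
  # maximally different codons at every position drive pS/pN to saturation
  a <- rep("TTT", 30)
  b <- rep("AGG", 30)
  r <- compute_ng86(list(codons_a = a, codons_b = b))
  expect_true(r$saturated)
  expect_true(is.na(r$ratio))
})

test_that("codon validation catches internal stops and ragged input", {
  expect_error(validate_codon_sequence(c("ATG", "TAA", "AAA"),
                                       allow_final_stop = FALSE), "stop codon")
  expect_identical(validate_codon_sequence(c("ATG", "AAA", "TAA")),
                   c("ATG", "AAA"))
  expect_error(split_codons("ATGC"), "divisible by 3")
})

test_that("back-translation expands gaps and reports mismatch positions", {
  cds_a <- c("ATG", "GCT", "GAA", "TTC")
  cds_b <- c("ATG", "GAA", "TTC")
  paln <- align_proteins_global(translate_codons(cds_a), translate_codons(cds_b))
  caln <- backtranslate_codon_alignment(paln, cds_a, cds_b)
  expect_equal(length(caln$codons_a), length(caln$codons_b))
  expect_identical(caln$codons_a[caln$codons_a != "---"], cds_a)
  expect_identical(caln$codons_b[caln$codons_b != "---"], cds_b)
  # gapless alignment reproduces both CDS verbatim
  paln2 <- align_proteins_global(translate_codons(cds_a), translate_codons(cds_a))
  caln2 <- backtranslate_codon_alignment(paln2, cds_a, cds_a)
  expect_identical(caln2$codons_a, cds_a)
  expect_identical(caln2$codons_b, cds_a)
  # a planted translation mismatch is reported with its codon position
  bad <- cds_a
  bad[2] <- "CCC"  # Pro, protein says Ala
  expect_error(backtranslate_codon_alignment(paln2, cds_a, bad), "codon 2")
})

test_that("global alignment scores match exhaustive enumeration on small cases", {
  sub <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "D", "E"),
                                          c("A", "C", "D", "E")))
  diag(sub) <- 2
  set.seed(5)
  for (case in 1:150) {
    la <- sample(1:5, 1); lb <- sample(1:5, 1)
    a <- paste(sample(c("A", "C", "D", "E"), la, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "E"), lb, replace = TRUE), collapse = "")
    go <- sample(c(1, 2, 4), 1); ge <- sample(c(0.5, 1), 1)
    got <- align_proteins_global(a, b, substitution = sub,
                                 gap_open = go, gap_extend = ge)
    want <- oracle_align_score(a, b, sub, go, ge)
    expect_equal(got$score, want, tolerance = 1e-9,
                 label = sprintf("%s vs %s (open %g ext %g)", a, b, go, ge))
    # the emitted alignment must realize the reported score
    expect_equal(nchar(got$a), nchar(got$b))
  }
})

test_that("identical sequences align gapless with the diagonal score", {
  s <- "MKVLAE"
  r <- align_proteins_global(s, s)
  expect_identical(r$a, s)
  expect_identical(r$b, s)
  b62 <- cucurbHLH:::.default_substitution()
  expect_equal(r$score, sum(diag(b62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))
  r2 <- align_proteins_global("A", "G")
  expect_identical(r2$a, "A")
  expect_identical(r2$b, "G")
  expect_error(align_proteins_global("A", ""), "non-empty")
  expect_error(align_proteins_global("A1", "G"), "invalid residues")
})
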