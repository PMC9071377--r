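# Profile construction, domain search, region partition and the binding
# cascade.

test_that("profile frequencies are direct column counts", {
  aln <- c("EEQA", "EEQA")
  prof <- build_domain_profile(aln, region_spec = list(basic = 1:2, helix1 = 3L,
                                                       loop = integer(0), helix2 = 4L),
                               named_positions = c(`H/K-1` = 1L, `E-2` = 2L,
                                                   `R-4` = 3L, `R-5` = 4L),
                               score_threshold = 0)
  expect_true(all(prof$freq["E", 1:2] == 1))
  expect_true(all(colSums(prof$freq) == 1))
  aln2 <- c("E", "E", "Q", "-")
  prof2 <- build_domain_profile(aln2, region_spec = list(basic = 1L, helix1 = integer(0),
                                                         loop = integer(0), helix2 = integer(0)),
                                named_positions = c(`H/K-1` = 1L, `E-2` = 1L,
                                                    `R-4` = 1L, `R-5` = 1L),
                                score_threshold = 0)
  expect_equal(unname(prof2$freq["E", 1]), 0.5)
  expect_equal(unname(prof2$freq["-", 1]), 0.25)
})

test_that("ragged alignments and out-of-range named positions are rejected", {
  expect_error(build_domain_profile(c("AA", "AAA")), "ragged")
  expect_error(build_domain_profile(c("AAAA", "AAAA"),
                                    region_spec = list(basic = 1:4),
                                    named_positions = c(`E-2` = 9L)),
               "named position")
})

test_that("the consensus attains the maximal profile score at every column", {
  prof <- default_domain_profile()
  cons <- strsplit(prof$consensus, "")[[1]]
  for (j in seq_along(cons))
    expect_equal(unname(prof$scores[cons[j], j]), max(prof$scores[, j]))
})

test_that("a planted consensus is recovered at its offset with no gaps", {
  prof <- default_domain_profile()
  for (pad in c(0, 7, 40)) {
    prot <- paste0(strrep("M", pad), prof$consensus, strrep("W", 15))
    ann <- find_bhlh_domain(prot, prof)
    expect_false(is.null(ann))
    expect_identical(ann$start, as.integer(pad))
    expect_identical(ann$end, as.integer(pad + nchar(prof$consensus)))
    expect_false(anyNA(ann$column_map))
  }
})

test_that("low-complexity sequence scores below the shuffle-calibrated threshold", {
  prof <- default_domain_profile()
  expect_null(find_bhlh_domain(strrep("A", 150), prof))
})

test_that("of two planted copies the first is returned on equal score", {
  prof <- default_domain_profile()
  prot <- paste0("MM", prof$consensus, strrep("P", 10), prof$consensus, "MM")
  ann <- find_bhlh_domain(prot, prof)
  expect_identical(ann$start, 2L)
})

test_that("region partition maps column ranges through the alignment", {
  prof <- default_domain_profile()
  prot <- paste0(strrep("M", 12), prof$consensus, strrep("W", 12))
  ann <- partition_regions(find_bhlh_domain(prot, prof), prof)
  spec_lens <- vapply(prof$region_spec, length, 1L)
  expect_identical(ann$regions$length, unname(spec_lens))
  expect_false(any(ann$regions$empty))
  # regions are ordered and non-overlapping
  expect_true(all(diff(as.vector(rbind(ann$regions$start, ann$regions$end))) >= 0))
})

test_that("a fully gapped basic region is flagged empty and classifies NON_BINDING", {
  prof <- default_domain_profile()
  prot <- paste0(strrep("M", 12), prof$consensus, strrep("W", 12))
  ann <- find_bhlh_domain(prot, prof)
  ann$column_map[prof$region_spec$basic] <- NA_integer_
  ann <- partition_regions(ann, prof)
  expect_true(ann$regions$empty[ann$regions$region == "basic"])
  expect_identical(classify_binding(prot, ann, prof), "NON_BINDING")
})

test_that("the binding cascade matches a brute-force transcription of its rules", {
  prof <- default_domain_profile()
  rules <- binding_rules()
  dom0 <- strsplit(prof$consensus, "")[[1]]
  np <- prof$named_positions
  other_basic_cols <- setdiff(prof$region_spec$basic, np)
  states <- list(hk1 = c("H", "A", NA), e2 = c("E", "Q", NA),
                 r4 = c("R", "L", NA), r5 = c("R", "G", NA))
  grid <- expand.grid(hk1 = 1:3, e2 = 1:3, r4 = 1:3, r5 = 1:3,
                      n_other = c(0L, 3L, 5L, 7L, 11L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    dom <- dom0
    # controlled count of basic residues outside the named positions
    dom[other_basic_cols] <- "S"
    dom[other_basic_cols[seq_len(g$n_other)]] <- "R"
    res <- list(hk1 = states$hk1[g$hk1], e2 = states$e2[g$e2],
                r4 = states$r4[g$r4], r5 = states$r5[g$r5])
    for (nm in names(res)) {
      col <- np[[c(hk1 = "H/K-1", e2 = "E-2", r4 = "R-4", r5 = "R-5")[nm]]]
      dom[col] <- if (is.na(res[[nm]])) "A" else res[[nm]]  # placeholder for gap
    }
    pad <- 10L
    prot <- paste0(strrep("M", pad), paste(dom, collapse = ""), strrep("W", 10))
    # fixed identity annotation so the constructed states are read verbatim
    ann <- structure(list(id = "t", start = pad, end = pad + length(dom),
                          score = 100, column_map = pad + 0:(length(dom) - 1L),
                          regions = NULL), class = "domain_annotation")
    gapped <- names(res)[vapply(res, is.na, TRUE)]
    for (nm in gapped) {
      col <- np[[c(hk1 = "H/K-1", e2 = "E-2", r4 = "R-4", r5 = "R-5")[nm]]]
      ann$column_map[col] <- NA_integer_
    }
    # expected basic count from the construction itself
    basic_cols <- prof$region_spec$basic
    visible <- basic_cols[!is.na(ann$column_map[basic_cols])]
    expect_count <- sum(dom[visible] %in% rules$basic_residues)
    got <- classify_binding(prot, ann, prof, rules)
    want <- oracle_binding_cascade(expect_count, res$hk1, res$e2, res$r4, res$r5,
                                   rules$basic_min_count)
    expect_identical(got, want,
                     label = sprintf("row %d (n_other=%d hk1=%s e2=%s r4=%s r5=%s)",
                                     i, g$n_other, res$hk1, res$e2, res$r4, res$r5))
  }
})

test_that("adding basic residues never demotes a binding domain", {
  prof <- default_domain_profile()
  rules <- binding_rules()
  dom0 <- strsplit(prof$consensus, "")[[1]]
  other_basic_cols <- setdiff(prof$region_spec$basic, prof$named_positions)
  prev_binding <- FALSE
  for (n in 0:11) {
    dom <- dom0
    dom[other_basic_cols] <- "S"
    if (n > 0) dom[other_basic_cols[seq_len(n)]] <- "K"
    prot <- paste0(strrep("M", 10), paste(dom, collapse = ""), strrep("W", 10))
    ann <- structure(list(id = "t", start = 10L, end = 10L + length(dom),
                          score = 100, column_map = 10L + 0:(length(dom) - 1L),
                          regions = NULL), class = "domain_annotation")
    cat_n <- classify_binding(prot, ann, prof, rules)
    if (prev_binding) expect_true(cat_n != "NON_BINDING")
    prev_binding <- prev_binding || cat_n != "NON_BINDING"
  }
})
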