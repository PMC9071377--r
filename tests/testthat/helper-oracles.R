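# Independent oracle implementations used to validate the package's
# algorithmic cores. These deliberately use different mechanisms (recursive
# enumeration, boolean matrix closure) than the implementations they check.

.oracle_gc <- Biostrings::GENETIC_CODE

oracle_translate1 <- function(codon) .oracle_gc[[codon]]

# NG86 synonymous site count of one codon: per position, the synonymous
# fraction among non-stop single-nucleotide changes.
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (oracle_translate1(mut) == "*") next
      valid <- valid + 1L
      if (oracle_translate1(mut) == oracle_translate1(codon)) syn <- syn + 1L
    }
    if (valid > 0L) total <- total + syn / valid
  }
  total
}

# NG86 difference counts between two codons: depth-first enumeration of all
# substitution orders; paths through stop codons are excluded (all paths used
# if every one is blocked).
oracle_diff_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd, blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      b2 <- blocked || oracle_translate1(nxt) == "*"
      s <- oracle_translate1(nxt) != "*" &&
        oracle_translate1(nxt) == oracle_translate1(cur)
      # a step into a stop codon is neither; treat as nonsynonymous on the
      # all-blocked fallback, matching the averaged-over-all-paths convention
      syn_step <- oracle_translate1(nxt) == oracle_translate1(cur)
      walk(nxt, setdiff(remaining, p), sd + syn_step, nd + !syn_step, b2)
    }
  }
  walk(c1, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, "blocked"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

# Best collinear-chain score by exhaustive subset enumeration: a subset is a
# valid chain if, ordered by a-rank, both rank sequences are strictly
# monotone (b increasing or decreasing) with per-side gaps <= max_gap_ranks.
oracle_best_chain_score <- function(ra, rb, match_score = 1, gap_penalty = 0.05,
                                    max_gap_ranks = 25) {
  n <- length(ra)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    o <- idx[order(ra[idx])]
    m <- length(o)
    if (m == 1L) { best <- max(best, match_score); next }
    da <- diff(ra[o])
    db <- diff(rb[o])
    if (any(da < 1L)) next
    inc <- all(db >= 1L); dec <- all(db <= -1L)
    if (!inc && !dec) next
    adb <- abs(db)
    if (any(da - 1L > max_gap_ranks) || any(adb - 1L > max_gap_ranks)) next
    sc <- m * match_score - gap_penalty * sum((da - 1L) + (adb - 1L))
    best <- max(best, sc)
  }
  best
}

# The binding cascade transcribed directly from its rule text.
oracle_binding_cascade <- function(basic_count, hk1, e2, r4, r5, min_count = 6L) {
  req <- function(res, allowed) !is.na(res) && res %in% allowed
  if (basic_count < min_count) return("NON_BINDING")
  if (!(req(e2, "E") && req(r4, "R"))) return("NON_EBOX")
  if (req(hk1, c("H", "K")) && req(e2, "E") && req(r5, "R")) "GBOX"
  else "EBOX_NON_GBOX"
}

# Optimal global affine-gap alignment score by exhaustive enumeration of all
# alignments (column-by-column recursion; gap runs cost open + L * extend).
oracle_align_score <- function(a, b, sub, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= n)
      best <- max(best, -(if (prev == "X") gap_extend else gap_open + gap_extend) +
                    rec(i + 1L, j, "X"))
    if (j <= m)
      best <- max(best, -(if (prev == "Y") gap_extend else gap_open + gap_extend) +
                    rec(i, j + 1L, "Y"))
    best
  }
  rec(1L, 1L, "start")
}

# Connected components by boolean transitive closure (repeated squaring).
oracle_components <- function(genes, pairs) {
  n <- length(genes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(genes, genes)
  for (k in seq_len(nrow(pairs))) {
    A[pairs$gene_a[k], pairs$gene_b[k]] <- TRUE
    A[pairs$gene_b[k], pairs$gene_a[k]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comps <- unique(apply(A, 1, function(r) paste(sort(genes[r]), collapse = "|")))
  sort(comps)
}

# Tandem clustering by exhaustive pairwise closure over the defining relation.
oracle_tandem_sets <- function(loci, anchors, max_gap = 1L) {
  rel <- data.frame(gene_a = character(0), gene_b = character(0))
  for (k in seq_len(nrow(anchors))) {
    ia <- match(anchors$gene_a[k], loci$gene)
    ib <- match(anchors$gene_b[k], loci$gene)
    if (loci$species[ia] == loci$species[ib] &&
        loci$chrom[ia] == loci$chrom[ib] &&
        abs(loci$rank[ia] - loci$rank[ib]) <= max_gap + 1L &&
        anchors$gene_a[k] != anchors$gene_b[k])
      rel <- rbind(rel, anchors[k, c("gene_a", "gene_b")])
  }
  comps <- oracle_components(loci$gene, rel)
  sort(comps[vapply(strsplit(comps, "\\|"), length, 1L) >= 2L])
}

# A small bundle shared by slower tests (simulated once per test run).
default_test_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_pangenome(simulation_config(seed = 42L))
    cache
  }
})
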