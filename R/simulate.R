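# Multi-species pangenome simulator with full ground truth: a shared ancient
# tetraploidy (two collinear chromosome copies, one fractionated), optional
# lineage-specific WGD, tandem duplication, gene loss, codon evolution under
# branch-specific dN/dS with the domain held under purifying constraint, and
# tissue-biased expression. Every downstream stage of the package can be
# validated against the emitted ground truth.

#' Species tree specification
#'
#' @param taxa Tip labels.
#' @param newick Rooted binary topology with branch lengths in million years.
#' @param wgd_events List of lineage-specific whole-genome duplications, each
#'   `list(branch = <tip label>, time = <MYA>, retention = <(0,1]>)`.
#' @param shared_polyploidy_time Age (MYA) of the family-wide shared
#'   tetraploidy predating the root.
#' @param shared_retention Fraction of ancestral genes whose second
#'   tetraploidy copy survives fractionation (duplicate-retained families).
#' @return Object of class `species_tree_spec`.
#' @export
species_tree_spec <- function(taxa = c("SpA", "SpB", "SpC"),
                              newick = "((SpA:35,SpB:35):20,SpC:55);",
                              wgd_events = list(),
                              shared_polyploidy_time = 90,
                              shared_retention = 1 / 3) {
  phy <- ape::read.tree(text = newick)
  if (is.null(phy)) .stopf("invalid configuration: 'newick' did not parse")
  if (!setequal(phy$tip.label, taxa))
    .stopf("invalid configuration: 'taxa' do not match the newick tips")
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_along(phy$tip.label)])
  ages <- root_age - depth
  if (any(abs(ages[seq_along(phy$tip.label)]) > 1e-8))
    .stopf("invalid configuration: tree must be ultrametric (tips at age 0)")
  if (shared_polyploidy_time <= root_age)
    .stopf("invalid configuration: 'shared_polyploidy_time' must predate the root age (%.1f)",
           root_age)
  if (shared_retention <= 0 || shared_retention > 1)
    .stopf("invalid configuration: 'shared_retention' must be in (0,1]")
  for (ev in wgd_events) {
    if (!ev$branch %in% phy$tip.label)
      .stopf("invalid configuration: wgd branch '%s' is not a terminal branch", ev$branch)
    parent_age <- ages[phy$edge[match(match(ev$branch, phy$tip.label),
                                      phy$edge[, 2]), 1]]
    if (ev$time <= 0 || ev$time >= parent_age)
      .stopf("invalid configuration: wgd time %.1f outside branch '%s' (0, %.1f)",
             ev$time, ev$branch, parent_age)
    if (ev$retention <= 0 || ev$retention > 1)
      .stopf("invalid configuration: wgd retention must be in (0,1]")
  }
  structure(list(taxa = taxa, phylo = phy, ages = ages, root_age = root_age,
                 wgd_events = wgd_events,
                 shared_polyploidy_time = shared_polyploidy_time,
                 shared_retention = shared_retention),
            class = "species_tree_spec")
}

#' Default designated regulator-cluster specification
#'
#' Plants a tandem cluster of fruit-biased genes (three ancestral copies, the
#' Bt-cluster analog) on the main chromosome, a conserved paralogous two-gene
#' cluster on the duplicate-retained chromosome whose first copy (the Brp
#' analog) is root-predominant and whose sibling is leaf-biased, a
#' post-speciation tandem expansion of copy 1 in one species, and a loss of
#' copy 3 in another.
#'
#' @param expansions,losses Planted post-speciation events (terminal-branch
#'   species, ancestral copy index, and for expansions the number of extra
#'   copies and the event age in MYA).
#' @return List consumed by [simulation_config()].
#' @export
default_cluster_spec <- function(expansions = list(list(species = "SpB", copy = 1L,
                                                        n = 2L, time = 20)),
                                 losses = list(list(species = "SpC", copy = 3L))) {
  list(bt_dup_times = c(80, 70), brp_dup_time = 75,
       bt_tissue = "fruit", brp_tissue = "root", brp_sibling_tissue = "leaf",
       expansions = expansions, losses = losses)
}

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a three-species
#' ultrametric tree (root 55 MYA, sister split 35 MYA) under a 90-MYA shared
#' tetraploidy, one lineage WGD (SpC, 10 MYA, retention 0.7), 40 ancestral
#' (post-tetraploidy) genes, and plant-typical rates.
#'
#' @param tree A [species_tree_spec()].
#' @param n_ancestral_genes Post-tetraploidy ancestral gene count.
#' @param tandem_rate Expected tandem duplications per gene per branch.
#' @param loss_rate Per-gene per-branch loss probability.
#' @param codon_length Codons per gene.
#' @param omega_by_branch dN/dS; either a single value or a named vector by
#'   branch label (tips, `"ancestral"`, `"internal"`), with `.default`.
#' @param mutation_rate Nucleotide proposals per site per million years.
#' @param kappa Transition/transversion proposal bias (1 = unbiased).
#' @param binding_category_mix Named proportions over
#'   [binding_categories()]; must sum to 1.
#' @param intron_pattern_mix Named proportions over pattern codes; must sum
#'   to 1.
#' @param tissue_profiles Tissue set, fraction of genes with a biased tissue,
#'   linear fold of the bias, log mean of baseline FPKM and log-normal noise
#'   sd.
#' @param cluster_spec A [default_cluster_spec()] list, or `NULL` to plant no
#'   designated cluster.
#' @param seed Integer; fully determines the bundle.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(tree = species_tree_spec(
                                wgd_events = list(list(branch = "SpC", time = 10,
                                                       retention = 0.7))),
                              n_ancestral_genes = 40L,
                              tandem_rate = 0.05,
                              loss_rate = 0.03,
                              codon_length = 300L,
                              omega_by_branch = c(.default = 0.2),
                              mutation_rate = 0.0055,
                              kappa = 1,
                              binding_category_mix = c(GBOX = 0.50,
                                                       NON_BINDING = 0.29,
                                                       EBOX_NON_GBOX = 0.12,
                                                       NON_EBOX = 0.09),
                              intron_pattern_mix = c(IX = 0.38, I = 0.25,
                                                     XI = 0.17, II = 0.06,
                                                     IV = 0.05, V = 0.04,
                                                     VI = 0.03, VIII = 0.02),
                              tissue_profiles = list(
                                tissues = c("root", "stem", "leaf", "flower", "fruit"),
                                biased_fraction = 0.3, fold = 8,
                                base_log_mean = log(8), noise_sdlog = 0.25),
                              cluster_spec = default_cluster_spec(),
                              seed = 42L) {
  cfg <- structure(list(tree = tree, n_ancestral_genes = as.integer(n_ancestral_genes),
                        tandem_rate = tandem_rate, loss_rate = loss_rate,
                        codon_length = as.integer(codon_length),
                        omega_by_branch = omega_by_branch,
                        mutation_rate = mutation_rate, kappa = kappa,
                        binding_category_mix = binding_category_mix,
                        intron_pattern_mix = intron_pattern_mix,
                        tissue_profiles = tissue_profiles,
                        cluster_spec = cluster_spec, seed = as.integer(seed)),
                   class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param config A `simulation_config`.
#' @return The config, invisibly; errors name the offending field.
#' @export
validate_simulation_config <- function(config) {
  if (!inherits(config$tree, "species_tree_spec"))
    .stopf("invalid configuration: 'tree' must be a species_tree_spec")
  .assert_scalar_number(config$n_ancestral_genes, "n_ancestral_genes", min = 1)
  .assert_scalar_number(config$tandem_rate, "tandem_rate", min = 0)
  .assert_scalar_number(config$loss_rate, "loss_rate", min = 0)
  if (config$loss_rate > 1) .stopf("invalid configuration: 'loss_rate' must be <= 1")
  .assert_scalar_number(config$codon_length, "codon_length", min = 80)
  .assert_scalar_number(config$mutation_rate, "mutation_rate", min = 0)
  .assert_scalar_number(config$kappa, "kappa", min = 0)
  if (any(config$omega_by_branch < 0))
    .stopf("invalid configuration: 'omega_by_branch' must be >= 0")
  for (mix_name in c("binding_category_mix", "intron_pattern_mix")) {
    mix <- config[[mix_name]]
    if (abs(sum(mix) - 1) > 1e-9)
      .stopf("invalid configuration: '%s' must sum to 1 (got %.12f)", mix_name, sum(mix))
    if (any(mix < 0)) .stopf("invalid configuration: '%s' has negative entries", mix_name)
  }
  if (!all(names(config$binding_category_mix) %in% binding_categories()))
    .stopf("invalid configuration: unknown binding category in mix")
  if (!all(names(config$intron_pattern_mix) %in% intron_pattern_codes()))
    .stopf("invalid configuration: unknown intron pattern code in mix")
  invisible(config)
}

#' @noRd
.aa_codons <- function() {
  if (is.null(.cucurbHLH_cache$aa_codons)) {
    gc <- Biostrings::GENETIC_CODE
    .cucurbHLH_cache$aa_codons <- split(names(gc)[gc != "*"], gc[gc != "*"])
  }
  .cucurbHLH_cache$aa_codons
}

#' Evolve a codon sequence along a branch
#'
#' Proposal/rejection codon process: nucleotide proposals arrive at rate
#' `branch_length` per site (Poisson total count), with transition bias
#' `kappa`; proposals creating a stop codon are redrawn; nonsynonymous
#' proposals are accepted at relative rate `omega` (synonymous at 1; for
#' `omega > 1` the synonymous acceptance is scaled down instead). Codons in
#' `constrained` reject every nonsynonymous change (used to hold the domain
#' under purifying constraint).
#'
#' @param ancestor Codon vector (or CDS string); no internal stops.
#' @param branch_length Expected nucleotide proposals per site (>= 0).
#' @param omega dN/dS acceptance ratio (>= 0).
#' @param seed Optional integer; when `NULL` the ambient RNG stream is used.
#' @param kappa Transition/transversion proposal bias.
#' @param constrained 1-based codon indices evolving only synonymously.
#' @return Codon vector of the same length.
#' @export
evolve_codon_sequence <- function(ancestor, branch_length, omega, seed = NULL,
                                  kappa = 1, constrained = integer(0)) {
  codons <- validate_codon_sequence(.as_codon_vector(ancestor),
                                    allow_final_stop = FALSE)
  if (branch_length < 0) .stopf("branch_length must be >= 0")
  if (omega < 0) .stopf("omega must be >= 0")
  run <- function() .evolve_impl(codons, branch_length, omega, kappa, constrained)
  if (!is.null(seed)) .with_seed(seed, run()) else run()
}

#' @noRd
.transitions <- c(A = "G", G = "A", C = "T", T = "C")

#' @noRd
.evolve_impl <- function(codons, branch_length, omega, kappa, constrained) {
  aa <- .codon_aa()
  L <- length(codons)
  n_sites <- 3L * L
  n_prop <- stats::rpois(1L, branch_length * n_sites)
  if (n_prop == 0L) return(codons)
  p_syn <- if (omega <= 1) 1 else 1 / omega
  p_non <- if (omega <= 1) omega else 1
  is_constrained <- logical(L)
  is_constrained[constrained] <- TRUE
  for (k in seq_len(n_prop)) {
    for (try in 1:10) {  # stop-creating proposals are redrawn
      site <- sample.int(n_sites, 1L)
      ci <- (site - 1L) %/% 3L + 1L
      pos <- (site - 1L) %% 3L + 1L
      cur <- codons[ci]
      base <- substr(cur, pos, pos)
      alts <- setdiff(c("A", "C", "G", "T"), base)
      w <- ifelse(alts == .transitions[[base]], kappa, 1)
      nt <- sample(alts, 1L, prob = w)
      prop <- cur
      substr(prop, pos, pos) <- nt
      if (aa[[prop]] == "*") next
      syn <- aa[[prop]] == aa[[cur]]
      if (!syn && is_constrained[ci]) break
      p_acc <- if (syn) p_syn else p_non
      if (p_acc >= 1 || stats::runif(1L) < p_acc) codons[ci] <- prop
      break
    }
  }
  codons
}

# ---- internal genome representation ----------------------------------------

#' @noRd
.new_uid <- function(env) {
  env$uid <- env$uid + 1L
  sprintf("u%05d", env$uid)
}

#' @noRd
.record_event <- function(env, type, time, branch, parent, child, lineage) {
  env$events[[length(env$events) + 1L]] <-
    data.frame(type = type, time = time, branch = branch,
               parent = parent, child = child, lineage = lineage,
               stringsAsFactors = FALSE)
}

# Sample a synonymous back-translation of an amino-acid string.
#' @noRd
.sample_codons_for_protein <- function(aa_string) {
  tab <- .aa_codons()
  vapply(strsplit(aa_string, "")[[1]], function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

# Domain amino-acid sequence realizing a binding category, derived from the
# packaged profile consensus (columns 5/9/12/13 carry the rules; columns 3
# and 10 adjust the basic-residue count).
#' @noRd
.domain_for_category <- function(category) {
  cons <- strsplit(default_domain_profile()$consensus, "")[[1]]
  switch(category,
         GBOX = cons,
         EBOX_NON_GBOX = { cons[5] <- "A"; cons },
         NON_EBOX = { cons[9] <- "Q"; cons },
         NON_BINDING = { cons[3] <- "S"; cons[10] <- "S"; cons },
         .stopf("unknown binding category %s", category)) -> out
  paste(out, collapse = "")
}

# Intron CDS offsets (absolute, nt) realizing a pattern for a domain starting
# at codon `domain_start` (0-based). A non-canonical intron sits at domain
# offset 60; half the genes also carry one flank intron at CDS nt 9.
#' @noRd
.introns_for_pattern <- function(pattern, domain_start, with_flank_intron) {
  canon <- canonical_intron_positions()
  tab <- default_pattern_table()
  row <- tab[tab$code == pattern, ]
  if (nrow(row) != 1L) .stopf("pattern %s has no definition row", pattern)
  occ <- if (nzchar(row$positions)) as.integer(strsplit(row$positions, ",")[[1]]) else integer(0)
  off <- canon[occ]
  if (row$noncanonical) off <- c(off, 60L)
  abs_off <- sort(3L * domain_start + off)
  if (with_flank_intron) abs_off <- c(9L, abs_off)
  as.integer(abs_off)
}

#' @noRd
.make_ancestral_gene <- function(family, lineage, chrom, pos, cfg, env,
                                 category, pattern, tissue, base_mean) {
  L <- cfg$codon_length
  domain_len <- nchar(default_domain_profile()$consensus)
  domain_start <- sample(40:(L - domain_len - 40), 1L)
  domain_aa <- .domain_for_category(category)
  flank1 <- replicate(domain_start, {
    s <- sense_codons(); s[sample.int(length(s), 1L)]
  })
  flank2 <- replicate(L - domain_start - domain_len, {
    s <- sense_codons(); s[sample.int(length(s), 1L)]
  })
  codons <- c(flank1, .sample_codons_for_protein(domain_aa), flank2)
  list(uid = .new_uid(env), family = family, lineage = lineage,
       chrom = chrom, pos = pos, codons = codons,
       domain_start = domain_start, category = category, pattern = pattern,
       introns = .introns_for_pattern(pattern, domain_start,
                                      stats::runif(1) < 0.5),
       strand = sample(c("+", "-"), 1L),
       tissue = tissue, base_mean = base_mean,
       role = NA_character_, clade_copy = NA_integer_)
}

#' @noRd
.branch_omega <- function(cfg, branch) {
  ob <- cfg$omega_by_branch
  if (length(ob) == 1L && is.null(names(ob))) return(unname(ob))
  if (branch %in% names(ob)) return(unname(ob[[branch]]))
  if (".default" %in% names(ob)) return(unname(ob[[".default"]]))
  unname(ob[[1]])
}

#' @noRd
.evolve_genome <- function(genome, dt, omega, cfg) {
  if (dt <= 0) return(genome)
  bl <- cfg$mutation_rate * dt
  domain_len <- nchar(default_domain_profile()$consensus)
  lapply(genome, function(g) {
    g$codons <- .evolve_impl(g$codons, bl, omega, cfg$kappa,
                             constrained = (g$domain_start + 1L):(g$domain_start + domain_len))
    g
  })
}

# Insert a tandem copy of genome[[idx]] immediately after it on its
# chromosome (fractional position between parent and the next gene).
#' @noRd
.tandem_copy <- function(genome, idx, time, branch, env, role = NULL) {
  parent <- genome[[idx]]
  same_chrom <- vapply(genome, function(g) g$chrom == parent$chrom, logical(1))
  pos_all <- vapply(genome[same_chrom], function(g) g$pos, numeric(1))
  nxt <- pos_all[pos_all > parent$pos]
  child <- parent
  child$uid <- .new_uid(env)
  child$pos <- if (length(nxt)) (parent$pos + min(nxt)) / 2 else parent$pos + 1000
  if (!is.null(role)) child$role <- role
  .record_event(env, "tandem", time, branch, parent$uid, child$uid, parent$lineage)
  c(genome, list(child))
}

#' @noRd
.sim_branch <- function(genome, age_from, age_to, branch, cfg, env, is_tip) {
  omega <- .branch_omega(cfg, branch)
  cs <- cfg$cluster_spec
  protected <- !is.na(vapply(genome, function(g) g$role, character(1)))
  # random losses (uniform times; applied up front, timing does not affect
  # surviving sequences)
  if (cfg$loss_rate > 0 && length(genome)) {
    lose <- stats::runif(length(genome)) < cfg$loss_rate & !protected
    for (g in genome[lose])
      .record_event(env, "loss", age_from, branch, g$uid, NA_character_, g$lineage)
    genome <- genome[!lose]
  }
  # collect timed events on this branch
  evs <- list()
  if (cfg$tandem_rate > 0) {
    for (i in seq_along(genome)) {
      if (!is.na(genome[[i]]$role)) next  # cluster history is fully planted
      n <- stats::rpois(1L, cfg$tandem_rate)
      if (n > 0L) for (tm in stats::runif(n, age_to, age_from))
        evs[[length(evs) + 1L]] <- list(time = tm, type = "tandem",
                                        uid = genome[[i]]$uid)
    }
  }
  if (!is.null(cs)) {
    if (branch == "ancestral") {
      for (j in seq_along(cs$bt_dup_times))
        evs[[length(evs) + 1L]] <- list(time = cs$bt_dup_times[j], type = "bt_dup",
                                        copy = j + 1L)
      evs[[length(evs) + 1L]] <- list(time = cs$brp_dup_time, type = "brp_dup")
    }
    if (is_tip) {
      for (ex in cs$expansions) if (ex$species == branch)
        for (j in seq_len(ex$n))
          evs[[length(evs) + 1L]] <- list(time = ex$time - (j - 1L) * 0.5,
                                          type = "cluster_expansion", copy = ex$copy)
      for (lo in cs$losses) if (lo$species == branch)
        evs[[length(evs) + 1L]] <- list(time = age_from, type = "cluster_loss",
                                        copy = lo$copy)
    }
  }
  if (is_tip) {
    for (w in cfg$tree$wgd_events) if (w$branch == branch)
      evs[[length(evs) + 1L]] <- list(time = w$time, type = "wgd",
                                      retention = w$retention)
  }
  times <- vapply(evs, function(e) e$time, numeric(1))
  bad <- times > age_from + 1e-9 | times < age_to - 1e-9
  if (any(bad))
    .stopf("invalid configuration: event time %.2f outside branch '%s' [%.2f, %.2f]",
           times[bad][1], branch, age_to, age_from)
  evs <- evs[order(-times)]
  cur <- age_from
  find_role <- function(role, copy = NULL) {
    which(vapply(genome, function(g) {
      identical(g$role, role) && (is.null(copy) || identical(g$clade_copy, copy))
    }, logical(1)))
  }
  for (e in evs) {
    genome <- .evolve_genome(genome, cur - e$time, omega, cfg)
    cur <- e$time
    if (e$type == "tandem") {
      idx <- which(vapply(genome, function(g) g$uid == e$uid, logical(1)))
      if (length(idx)) genome <- .tandem_copy(genome, idx, e$time, branch, env)
    } else if (e$type == "bt_dup") {
      idx <- find_role("bt", 1L)[1]
      genome <- .tandem_copy(genome, idx, e$time, branch, env, role = "bt")
      genome[[length(genome)]]$clade_copy <- e$copy
    } else if (e$type == "brp_dup") {
      idx <- find_role("brp", 1L)[1]
      genome <- .tandem_copy(genome, idx, e$time, branch, env, role = "brp_sib")
      genome[[length(genome)]]$clade_copy <- 2L
      genome[[length(genome)]]$tissue <- cfg$cluster_spec$brp_sibling_tissue
    } else if (e$type == "cluster_expansion") {
      idx <- find_role("bt", e$copy)
      if (length(idx)) {
        genome <- .tandem_copy(genome, idx[1], e$time, branch, env, role = "bt")
        genome[[length(genome)]]$clade_copy <- e$copy
      }
    } else if (e$type == "cluster_loss") {
      idx <- find_role("bt", e$copy)
      if (length(idx)) {
        .record_event(env, "loss", e$time, branch, genome[[idx[1]]]$uid,
                      NA_character_, genome[[idx[1]]]$lineage)
        genome <- genome[-idx[1]]
      }
    } else if (e$type == "wgd") {
      keep <- stats::runif(length(genome)) < e$retention
      for (i in which(keep)) {
        child <- genome[[i]]
        child$uid <- .new_uid(env)
        child$chrom <- child$chrom + 2L
        .record_event(env, "wgd", e$time, branch, genome[[i]]$uid, child$uid,
                      child$lineage)
        genome <- c(genome, list(child))
      }
    }
  }
  .evolve_genome(genome, cur - age_to, omega, cfg)
}

#' @noRd
.sim_node <- function(genome, node, phy, ages, cfg, env) {
  ntip <- length(phy$tip.label)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  out <- list()
  for (child in kids) {
    is_tip <- child <= ntip
    label <- if (is_tip) phy$tip.label[child] else "internal"
    g2 <- .sim_branch(genome, ages[node], ages[child], label, cfg, env, is_tip)
    if (is_tip) out[[label]] <- g2
    else out <- c(out, .sim_node(g2, child, phy, ages, cfg, env))
  }
  out
}

#' Simulate a pangenome bundle with ground truth
#'
#' See [simulation_config()] for the study conditions. The returned bundle
#' holds per-species sequences, gene models and loci, inter/intra-genomic
#' homology anchors with identity scores, an FPKM matrix, and the complete
#' ground truth (OG membership, tandem clusters, binding categories, intron
#' patterns, duplication/loss events, branch dN/dS, designated cluster
#' genes).
#'
#' @param config A [simulation_config()].
#' @return Object of class `pangenome_bundle`.
#' @export
simulate_pangenome <- function(config) {
  validate_simulation_config(config)
  .with_seed(config$seed, .simulate_impl(config))
}

#' @noRd
.simulate_impl <- function(cfg) {
  tree <- cfg$tree
  env <- new.env(parent = emptyenv())
  env$uid <- 0L
  env$events <- list()
  n <- cfg$n_ancestral_genes
  r <- tree$shared_retention
  n_chr2 <- max(0L, round(n * r / (1 + r)))
  n_fam <- n - n_chr2
  if (n_chr2 > n_fam) .stopf("invalid configuration: shared_retention too high for n_ancestral_genes")
  retained <- sort(sample.int(n_fam, n_chr2))
  cluster_family <- NA_integer_
  if (!is.null(cfg$cluster_spec)) {
    if (n_chr2 == 0L) .stopf("invalid configuration: cluster_spec requires retained duplicate families")
    cluster_family <- retained[ceiling(length(retained) / 2)]
  }
  tissues <- cfg$tissue_profiles$tissues
  genome <- list()
  for (f in seq_len(n_fam)) {
    category <- sample(names(cfg$binding_category_mix), 1L,
                       prob = cfg$binding_category_mix)
    pattern <- sample(names(cfg$intron_pattern_mix), 1L,
                      prob = cfg$intron_pattern_mix)
    tissue <- if (stats::runif(1) < cfg$tissue_profiles$biased_fraction)
      sample(tissues, 1L) else NA_character_
    base_mean <- exp(stats::rnorm(1, cfg$tissue_profiles$base_log_mean, 0.5))
    g1 <- .make_ancestral_gene(f, sprintf("F%02da", f), 1L, f * 1000, cfg, env,
                               category, pattern, tissue, base_mean)
    genome <- c(genome, list(g1))
    if (f %in% retained) {
      g2 <- g1
      g2$uid <- .new_uid(env)
      g2$lineage <- sprintf("F%02db", f)
      g2$chrom <- 2L
      g2$pos <- f * 1000
      genome <- c(genome, list(g2))
    }
  }
  if (!is.na(cluster_family)) {
    for (i in seq_along(genome)) {
      g <- genome[[i]]
      if (g$family == cluster_family) {
        if (g$chrom == 1L) {
          genome[[i]]$role <- "bt"
          genome[[i]]$clade_copy <- 1L
          genome[[i]]$tissue <- cfg$cluster_spec$bt_tissue
        } else {
          genome[[i]]$role <- "brp"
          genome[[i]]$clade_copy <- 1L
          genome[[i]]$tissue <- cfg$cluster_spec$brp_tissue
        }
      }
    }
  }
  # shared (pre-root) lineage: tetraploidy age down to the root
  genome <- .sim_branch(genome, tree$shared_polyploidy_time, tree$root_age,
                        "ancestral", cfg, env, is_tip = FALSE)
  root_node <- length(tree$phylo$tip.label) + 1L
  tips <- .sim_node(genome, root_node, tree$phylo, tree$ages, cfg, env)
  .finalize_bundle(tips, cfg, env)
}
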