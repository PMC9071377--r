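---
title: "Comparative genomics of a bHLH transcription-factor family: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of a bHLH transcription-factor family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cucurbHLH)
```

# Scope

cucurbHLH re-implements, as a tested pipeline, a family-wide comparative
analysis of basic helix–loop–helix (bHLH) transcription factors across a set
of related plant genomes: domain location and region partition, rule-based
DNA-binding classification, intron-distribution typing, synteny-based
orthology/paralogy/tandem-duplication analysis, Ka/Ks estimation,
neighbor-joining phylogenetics with clade-based inference of cluster
evolution, and expression-based tissue-predominance calling. Because the real
inputs of such studies are multi-gigabyte genome assemblies, validation rests
on a pangenome simulator that plants a complete, recoverable ground truth.
This vignette explains each model, its parameters, and the design decisions
that were genuinely open.

# Domain location and region partition

Proteins are searched with a position-specific scoring profile built from a
packaged 60-column seed alignment (`bhlh_seed_alignment()`); the alignment is
synthetic — constructed to carry the canonical architecture (basic region,
columns 1–15; helix 1, 16–30; loop, 31–44; helix 2, 45–60) — not a
transcription of any curated family alignment. Scores are per-column log-odds
against a uniform background with a pseudocount of 0.02. The search
(`find_bhlh_domain()`) is a semi-global affine-gap alignment: every profile
column must be consumed (gaps allowed, open 6, extend 0.5 in log2 units),
protein flanks are free. We chose deterministic profile alignment over a full
HMM forward pass because the decision rules downstream consume a hard
column-to-residue map, and a Viterbi-style best path is what they need; the
packaged threshold is calibrated as the 99th percentile of scores of 300
shuffles of the profile consensus, so a hit must beat the profile's own
composition. Absence of a domain is a value (`NULL`), not an error, and is
how the pipeline decides family membership.

Two details matter for reproducibility: ties in the final score resolve to
the earliest protein position (so of two identical planted copies the first
is annotated), and the traceback prefers match over a gap in the profile over
a gap in the protein. All coordinates are 0-based half-open internally; GFF3
is converted on read and write.

# DNA-binding classification

The classifier (`classify_binding()`) is a three-step cascade over the
annotated basic region:

1. fewer than `basic_min_count` basic residues (default 6, reading "more
   than five" literally; residue set defaults to K/R/H) → non-binding;
2. otherwise E at the E-2 column and R at R-4 → E-box binder, else
   non-E-box;
3. an E-box binder with H or K at H/K-1, E at E-2 and R at R-5 → G-box
   binder, else E-box-non-G-box.

The rule-bearing column indices ship as configuration
(`default_named_positions()`: columns 5, 9, 12, 13 of the packaged profile)
because the defining supplementary material of the source analyses is not
reproduced here; users aligning to their own seed alignment should override
them. A rule position that is gapped in the protein counts as a failed
requirement — the conservative choice, since the evidence for the contact
residue is absent. The cascade is validated against an independent
transcription of the rule text over the full grid of basic counts and
residue/gap states.

# Intron patterns

Intron positions are derived from gene models in CDS coordinate space and
mapped into the domain window (`[3*start, 3*end)`, half-open). Three
canonical positions are fixed at domain-CDS offsets 27, 105 and 150
(basic region, loop, helix 2) with a ±6 nt assignment tolerance. The
occupancy signature (which canonical positions hold exactly one intron,
plus whether any non-canonical intron is present) is looked up in a packaged
table of twelve codes. Codes I (all three positions), IX (loop only) and XI
(no intron) are fixed by the family literature; the assignments of II–VIII
and X to the remaining signatures are the package's own convention, shipped
as an editable table (`default_pattern_table()`), and any signature outside
the table types as the catch-all `O`. A canonical position claimed by two
introns is treated as unoccupied and those introns count as non-canonical;
this keeps the signature a total function of the event configuration.

# Synteny, orthology, paralogy, tandem duplication

Homology anchors (gene pairs with a similarity score) are consumed as input,
mirroring practice where a BLAST-derived pair list feeds a collinearity
tool. Blocks are maximal-score chains under sparse dynamic programming per
chromosome pair and orientation: anchors sorted by a-side rank, strict rank
monotonicity on both sides, score `matches − 0.05 × intervening ranks`, at
most 25 intervening ranks per side, minimum 5 anchors per block — the
defaults of the widely used collinearity scanner this step re-implements.
Chains are extracted greedily by score (ties to the smaller starting a-rank)
and each anchor enters at most one block. The chain optimum is
property-tested against exhaustive subset enumeration.

Two filters shape what enters the comparative units:

* **Best-hit filtering of inter-genomic anchors** (`filter_best_hits()`,
  slack 0.03): only anchors within 0.03 identity of a gene's best hit in the
  target species (in either direction) are chained. Real anchor lists are
  already top-hit truncated; without this, anchors between ancient
  (tetraploidy-era) homeologs can chain into spurious cross-species blocks
  that fuse distinct ortholog groups. Each gene's best hit per target
  species always survives, which guarantees that true ortholog links are
  never filtered away.
* **Recent-duplicate merging** (`recent_paralog_min_similarity`, default
  0.8 identity): intra-species anchors at or above this identity (fresh WGD
  or tandem copies) keep both copies in one ortholog group during
  connected-component merging. Ancient paralogous clusters stay separate
  because tetraploidy-era pairs sit far below this identity at any plausible
  divergence.

Ortholog groups are connected components of the syntenic ortholog-pair graph
over the family, with tandem-cluster edges and recent-duplicate edges
attached; genes in no pair form species-specific singleton groups. IDs are
zero-padded in descending species-count order. Tandem clusters are connected
components of "homologous ∧ same chromosome ∧ rank distance ≤ max_gap+1"
(default one intervening gene), named `T1, T2, …` per species in coordinate
order.

# Ka/Ks

Pairs are aligned at the protein level (Needleman–Wunsch–Gotoh, BLOSUM62,
gap open 10 / extend 1, deterministic tie-breaks), back-translated to a
codon alignment, and scored with the Nei–Gojobori (1986) counting method:
synonymous site fractions from single-mutation enumeration averaged over the
two sequences; difference counts averaged with equal weight over all minimal
mutational pathways, pathways through stop codons excluded (all pathways are
used in the impossible case that every one is blocked); Jukes–Cantor
correction `d = −(3/4)·ln(1 − (4/3)p)`. We fixed the method to NG86 — the
classic counting mode of the commonly cited calculators — because the model
choice is rarely stated in the analyses this package emulates; the output
records the method. One convention deserves note: at each codon position,
mutational targets that are stop codons are excluded and the synonymous
fraction is computed among the remaining changes, which preserves
`S + N = 3 × codons` exactly. Proportions at or above 3/4 cannot be
corrected; such pairs carry a saturation flag and are excluded from
downstream Ks comparisons. The full 61×61 sense-codon table is checked
against an independent pathway-enumeration oracle at 10⁻¹².

# Trees, clades, expansions

Distances come from a multiple alignment after partial deletion (columns
with non-gap coverage < 0.8 removed), as p-distance or Poisson-corrected
distance (default). JTT maximum-likelihood distances are not implemented;
the topology-level conclusions the pipeline draws are insensitive to that
choice on data of this divergence, and the divergence from the
JTT-distance convention of the emulated analyses is deliberate and
documented. Neighbor joining follows Saitou–Nei on the Q criterion with
ties broken by the lexicographically smallest pair of subtree labels;
negative branch estimates are clamped to zero and flagged. NJ is
property-tested to reproduce random additive trees exactly (residual
< 10⁻⁹). Bootstrap support resamples alignment columns with a
caller-supplied seed; support is the fraction of replicate trees containing
each original bipartition.

`assign_clades()` partitions leaves at the tree's k−1 deepest splits. The
default implementation is single-linkage clustering of leaf-to-leaf path
distances, which on a tree equals removing the k−1 internal edges bounding
the deepest divergences (and coincides with cutting the longest internal
edge for k = 2 on a clean tree). We chose depth over raw edge length after
observing that on unrooted trees of duplicated clusters, long within-clade
species-divergence edges rival the between-copy edges and make longest-edge
cutting unstable. With anchors, edges are cut greedily by length subject to
separating all anchors, and conflicts raise an error.

For a designated tandem regulator cluster, the pipeline finds the cluster's
ortholog group from user-supplied known members, finds its most-linked
paralogous group via intra-genomic pairs, builds an NJ tree over the
members' **full-length proteins** — within a single cluster the domain is
too conserved to resolve lineages — assigns clades (default k = 5), and
calls per-species evolution from Ks: a species' genes in a clade are a
post-speciation expansion iff their maximum intra-species Ks is below the
minimum inter-species Ks to clade members elsewhere; a species absent from
a clade is a loss; single genes are ancestral retentions. The default
recent-duplication Ks bound of 0.32 (used when no inter-species comparison
exists) is the empirical post-divergence cutoff of the emulated analyses
and is configurable. Root-predominant candidates in the paralogous cluster
are the members that are tissue-predominant in the target tissue and fall
in the clade holding most such members.

# Expression

FPKM matrices are transformed elementwise as log2(FPKM+1); missing samples
stay missing and transforming twice is a state error. "Predominantly
expressed" is never quantified in the emulated analyses; we operationalize
it as: the tissue attains the unique row maximum, the maximum is at least
FPKM 1, and exceeds twice the runner-up on the linear scale. Both the fold
margin and the floor are configurable. Under exchangeable log-normal noise
(σ_log = 0.25, five tissues) the false-positive rate of this rule is below
5%, which the test suite checks on 1,000 simulated genes.

# The pangenome simulator

`simulate_pangenome()` generates the reference study conditions: a
three-species ultrametric tree (`((SpA:35,SpB:35):20,SpC:55)` in million
years) beneath a shared tetraploidy at 90 MYA, with one lineage-specific WGD
on SpC (10 MYA, retention 0.7). The tetraploidy is modelled as two collinear
chromosomes: chr1 carries all ancestral families, chr2 the duplicate-
retained subset (one third of genes, order preserved); the SpC WGD copies
chr1/chr2 onto chr3/chr4. Sequences are 300 codons with the 60-codon domain
at a per-family random offset; codon evolution is a proposal–rejection
process (uniform nucleotide proposals at `mutation_rate` = 0.0055
proposals/site/MY, a plant-typical synonymous rate; stop-creating proposals
redrawn; nonsynonymous acceptance ω = 0.2 per branch). The domain evolves
under full purifying constraint (synonymous changes only), which keeps the
planted binding category and intron pattern exactly recoverable and is the
strong-conservation limit of a real domain. The proposal kernel accepts a
transition/transversion bias `kappa`, but its default is 1: the NG86
estimator assumes unbiased substitution, and the simulator's own
recovery property (mean estimated Ka/Ks within ±0.1 of ω at 500 codons ×
100 replicates, proposal density 0.3/site) is only well posed there.

A designated regulator-cluster specification plants the study system: three
ancestral tandem copies of a fruit-biased family on chr1 (duplicated at 80
and 70 MYA), a conserved two-gene paralogous cluster on chr2 (75 MYA) whose
first copy is root-predominant (8-fold linear bias over log-normal noise,
σ_log = 0.25) and whose sibling is leaf-biased, a post-speciation tandem
expansion of copy 1 in SpB (20 MYA) and a loss of copy 3 in SpC. Random
tandem duplication (0.05/gene/branch) and loss (0.03/gene/branch) act on all
other genes. Divergence times and rates are configurable constants; the tree
ages are arbitrary defaults of this package, chosen so that ortholog,
recent-duplicate and tetraploidy-era identities occupy well-separated bands.

Ground truth records OG membership (one OG per post-tetraploidy lineage),
tandem clusters (adjacent same-family runs), binding categories, intron
patterns, per-branch ω, every duplication/loss event with its time, and the
planted root-predominant genes. Anchors are emitted for every gene pair
sharing a pre-tetraploidy family, with protein identity as the similarity
score.

What the simulator deliberately does **not** emulate: indels (so real
domain alignments can gap where synthetic ones cannot), base-composition
and codon-usage bias, annotation errors and split gene models,
rearrangements and translocations (gene order is perfectly preserved), and
assembly-specific artifacts. Passing the recovery suite therefore
demonstrates correctness of the algorithms under clean, well-separated
conditions — not robustness to noisy annotation, which real analyses handle
by manual re-annotation upstream of this pipeline.

# Validation problem sizes

The packaged validation uses: the full 61×61 sense-codon table (exact
oracle match at 10⁻¹²); 500 random chaining instances of ≤ 10 anchors
against exhaustive subset enumeration; 200 random additive matrices of
≤ 12 leaves for NJ; the full rule grid (11 basic counts × 3⁴ residue/gap
states) for the binding cascade; 100 replicates × 500 codons per ω level
for Ka/Ks recovery; and the seed-42 reference bundle (40 ancestral genes,
three species, ~170 genes total) for end-to-end ground-truth recovery.
These sizes were chosen as the package's own validation conditions — small
enough to run routinely, large enough that every code path and tie-break is
exercised.

# Known limitations

* The domain search is profile alignment, not a calibrated HMM; its
  threshold is composition-based and should be re-calibrated when users
  supply their own seed alignment.
* Distance-based trees only; no ML/Bayesian inference, no ML codon models,
  no divergence-time estimation.
* The cluster phylogeny assumes the member proteins are alignable
  end-to-end (equal length in the synthetic setting); real analyses should
  supply a curated multiple alignment.
* Subfamily classification against an external reference family set is out
  of scope; `assign_clades()` provides the generic machinery.
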