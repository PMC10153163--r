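---
title: "Mining and validating isocyanide synthase gene clusters with icsmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating isocyanide synthase gene clusters with icsmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Isocyanide synthases (ICSs) are non-canonical backbone enzymes of fungal
specialized metabolism. Because genome-mining tools key on well-characterised
synthase classes (NRPS, PKS, terpene synthases), ICS biosynthetic gene
clusters (BGCs) are invisible to them. `icsmine` implements a mining and
comparative-evolution workflow for this class: it detects ICS backbones from
protein-domain tables, calls cluster borders from shared promoter motifs,
groups clusters into gene cluster families (GCFs), extracts conserved
biosynthetic cores, validates families with a microsynteny-conservation
statistic against a BUSCO-anchored null, censuses dit1/dit2 loci, and
compares gene trees with species trees.

The package deliberately *consumes* the outputs of the heavy external tools a
practitioner already runs — HMMER domain tables, Orthofinder orthogroup
tables, BUSCO anchor tables, alignments and ML trees — and re-implements only
the decision logic built on top of them.

## Detection model

An ICS anchor is any gene whose protein carries the DIT1_PvcA domain
(Pfam PF05141) with a per-domain independent e-value at or below `1e-4`. We
threshold the i-Evalue rather than the full-sequence e-value because the
per-domain evidence is what identifies the ICS region; the same ceiling is
applied wherever domain evidence is consumed downstream. Backbone variants
follow domain co-occurrence on the anchor protein: NRPS-associated domains
(AMP-binding, PP-loading, condensation) give `ICS_NRPS_LIKE`, otherwise TauD
gives `ICS_TAUD`, otherwise `MONO`. When NRPS and TauD domains co-occur the
NRPS-like call wins; this precedence is a package decision (the architecture
is the most derived) — the case is vanishingly rare in practice.

The curated list of specialized-metabolism domains used to flag genes as
biosynthetic (and to mark CDSs in GenBank exports) ships as an editable TSV
(`inst/extdata/sm_biosynthetic_domains.tsv`) with a separate
transport/regulation category; the shipped defaults are a condensed,
antiSMASH-style selection (p450s, oxidoreductases, methyltransferases,
isocyanide hydratase, MFS transporters, fungal Zn-cluster factors, ...), not
a reproduction of any particular supplementary table.

## Border prediction from shared promoter motifs

Genes of a co-regulated fungal BGC tend to share a cluster-specific promoter
motif. The border predictor turns that principle into an exact, dependency-free
test:

* A gene's **promoter** is up to `L_up` = 1000 bp upstream of its start
  (strand-aware), truncated at the neighbouring gene boundary and the contig
  edge, plus `L_down` = 50 bp into the gene. Divergently transcribed adjacent
  pairs share their intergenic region, and that sharing matters below.
* **Candidate motifs** are the canonical `k` = 8 bp k-mers of the anchor
  promoter whose genome-wide promoter background frequency `p0` is at most
  `q_max` = 0.10 (ubiquitous motifs are uninformative). Canonical means a
  k-mer and its reverse complement are one motif.
* **Candidate ranges** are all contiguous gene intervals containing the
  anchor within `K` = 10 genes on each side.
* Each (motif, range) pair is scored by the upper-tail binomial probability
  of the observed number of motif-containing promoters given `p0`
  (`score_candidate()`), and the minimising pair is selected; ties prefer the
  smaller range (conservative borders), then the lexicographically smaller
  motif. The selected probability is Bonferroni-corrected over the number of
  candidate motifs, and the anchor is a BGC (`is_bgc`) when the selected
  range contains at least one neighbour and the corrected probability is at
  most `alpha` = 0.05.

Two counting rules keep the binomial honest, and both were fixed at design
time after analysing the test's operating characteristics:

1. **The anchor is not evidence.** Candidate motifs are drawn from the anchor
   promoter, so the anchor contains every candidate by construction; counting
   it would condition on its own occurrence. `n` and `m` therefore range over
   the anchor's neighbours only.
2. **Trials are promoter regions, not genes.** A divergent gene pair shares
   one intergenic region, so one chance k-mer occurrence there would count as
   two independent promoter hits. Such a pair inside the evidence set is one
   observation (success if the motif is in either promoter), and the anchor's
   own divergent partner — which shares the anchor promoter — is excluded
   from the evidence. Without these rules, simulated random genes produce
   spurious cluster calls at rates far above `alpha`; with them the empirical
   false-call rate on planted-free genes is about 2%.

All parameters are exposed in `predictor_config()`; the published
MEME/FIMO-based border tools do not document a single canonical
parameterisation, so these defaults are package decisions reported with every
output.

## Family clustering

Pairs of clusters are compared with an anchor-weighted composite distance
`d = 1 − (wJ·J + wD·DSS + wA·AI)` over thresholded domain annotations:

* `J` — Jaccard index of domain-type sets;
* `AI` — Jaccard index of unordered adjacent domain-type pairs along each
  cluster's gene-order domain string (0 if either cluster has fewer than two
  domain positions);
* `DSS` — per-type sequence similarity: copies of a shared type are paired
  greedily by unit-cost global-alignment identity (matches / alignment
  columns), summed identities divided by the larger copy number, unshared
  types scoring 0; anchor-resident domain types (the ICS domain and
  co-resident backbone domains) are up-weighted by `anchor_boost` = 4.

Weights default to `wJ` = 0.2, `wD` = 0.75, `wA` = 0.05, following the
conventions of the established BGC-family tool this distance is modelled on;
only the 0.3 family cutoff and the anchor treatment are fixed by the method
itself. Alignment identities are computed with the two sequences in a
canonical order, making the distance exactly symmetric despite traceback ties.
Families are connected components of the graph with edges `d ≤ cutoff` —
deterministic and parameter-light compared with affinity-propagation
refinement; the 13-point cutoff sweep (0.2–0.8 by 0.05) exposes the
granularity trade-off and its merge events instead.

## Cores, superfamilies and dit status

For each family (one representative cluster per species, smallest anchor
ordinal winning within a species) the conservation fraction `c(O)` of an
orthogroup is the fraction of species whose cluster contains it. Orthogroups
with `c(O) ≥ τ` (default 0.8 — the literature describes cores qualitatively,
so τ is a package decision reported in output) form the biosynthetic core,
and the anchor orthogroup is always core. Families sharing an *identical*
core signature collapse into a superfamily whose original families become
clans. Families spanning fewer than five species are flagged low-confidence
rather than refused.

The dit1 (ICS) / dit2 (p450) locus of a genome is `COLOCALIZED` when genes of
the two seed orthogroups lie within `D` = 3 ordinals on one contig in the
expected relative orientation, `FRAGMENTED` when both orthogroups occur but
never co-localize, and `ABSENT` otherwise. In *S. cerevisiae* DIT2 sits
immediately left of DIT1 on the opposite strand — a divergent, head-to-head
pair — so `"divergent"` is the default expected orientation, and it is
configurable because assembly or annotation conventions can flip it.
Fragmentation is reported as observed; no attempt is made to correct for
assembly-driven fragmentation.

## The conservation ("LD") statistic

The validation statistic asks whether the gene neighbourhood around a
family's ICS anchors is more conserved across species than neighbourhoods
around universal single-copy genes. "LD" here is cross-species microsynteny
conservation — a selection signal — not population-genetic r².

* `window_orthogroups()` collects the orthogroups of genes within `w` = 5
  ordinals of an anchor (anchor's own orthogroup excluded; truncated at
  contig ends). The window size is a package decision.
* `conservation_score()` aggregates windows across species as the mean
  pairwise Jaccard index — symmetric, bounded, size-robust; pairs with an
  empty window contribute 0. The aggregation had to be chosen here; mean
  pairwise Jaccard was selected once and is reported in output.
* The null distribution is the same score computed around every BUSCO anchor
  present in all of the family's representative genomes; the empirical
  p-value is the pseudocount percentile rank `(1 + #{null ≥ obs}) / (1 + n)`,
  which can never be exactly zero. Verdicts: `SIGNIFICANT` below 0.05,
  `STRONG` below 0.07.

Fewer than two usable species or fewer than 20 usable BUSCO anchors is an
error — a null that small cannot support a percentile rank.

## Tree comparison

Trees are `ape` objects; ML inference, alignment and trimming belong to
upstream tools. `rf_distance()` compares non-trivial unrooted bipartitions
and normalizes by their total count, also returning the shared and
conflicting splits; congruence verdicts are reported as normalized values
without a hard-coded threshold. `concatenate_alignments()` builds a
gap-filled supermatrix with a partition table. `expansion_scan()` walks a
species tree and compares sister-clade BGC-count distributions (both clades
at least `min_clade` = 4 leaves) with an exact two-sided rank-sum test by
full enumeration of rank assignments (midranks for ties; normal approximation
beyond 2×10^5 assignments), followed by Benjamini–Hochberg correction. The
scan procedure is a declared stand-in — published expansion analyses of this
kind do not document their exact test — and is labelled as such in output.

## The synthetic pangenome generator

`simulate_dataset()` is first-class, tested code and the substrate for the
whole validation suite. It emulates exactly the statistical structure the
pipeline assumes: contiguous co-regulated clusters whose genes share a
planted promoter 8-mer; orthologous families derived from master proteins by
per-site substitution at rate μ; BUSCO-like universal single-copy genes in
per-species randomized neighbourhoods; filler genes drawing orthogroups from
a shared pool; and planted dit1/dit2 loci (divergent adjacent pair,
fragmented across contigs, or absent). Domain annotations are emitted as
table rows tied to the planted genes so tests need no profile database; a
real HMM scan can be routed in instead.

Defaults, chosen once as realistic for compact fungal genomes and not
revisited: intergenic lengths uniform on 200–800 bp, GC 0.5, master protein
lengths uniform on 120–300 aa, two contigs per genome, planted cluster genes
on the plus strand. Two constructions keep the planted truth exact: the
motif is inserted just inside each cluster gene's start (within the `L_down`
promoter stretch, which belongs to that gene's promoter alone — an insertion
in the upstream intergenic would leak into a divergent neighbour's promoter),
and chance occurrences of planted motifs elsewhere on a contig are resampled
away, because a chance occurrence adjacent to a planted span makes the true
border genuinely ambiguous.

What the generator does **not** emulate: codon structure, introns, repeats,
gene gain/loss along a phylogeny (the species are a star), promoter motif
degeneracy, or annotation errors. Passing the suite therefore demonstrates
the correctness of the decision logic under the model's assumptions, not
robustness to real-genome noise; on real data the promoter model in
particular will be weaker than on fixtures with exact planted 8-mers.

## Problem sizes and numerical choices

The test and acceptance fixtures use 8–10 species at 120–200 genes per
genome, six planted families for border recovery, five for family recovery
(μ = 0.05), a 50-anchor BUSCO null for the conservation test and 30 genomes
for dit classification — sizes at which every planted signal is
comfortably identifiable while the whole suite stays fast. Binomial tails
come from `pbinom`, alignments from `Biostrings::pairwiseAlignment` with a
unit substitution matrix (gap opening 0, extension 1), empirical p-values use
the pseudocount form, and all generator randomness flows from a single
mandatory seed, restoring the caller's RNG state afterwards.

## Known limitations

* The promoter model is an exact k-mer model; degenerate motifs are out of
  scope, so real clusters regulated by variable motifs will be called
  standalone more often than in motif-profile approaches.
* RBH orthology (`build_orthogroups(mode = "rbh")`) is all-vs-all global
  alignment and intended for fixture-scale data; real runs should ingest an
  Orthofinder-style table.
* Whether seed-orthogroup dit2 membership reproduces the p450 clade boundary
  on real genomes is untested here; the seed orthogroups delegate that
  decision to the user's orthology run.
* Species dereplication implements only the representative-selection rule
  (fewest contigs, then assembly length, then id); no manual curation step is
  reproduced.
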