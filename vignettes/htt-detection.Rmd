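---
title: "Detecting horizontal transposon transfer from TE-TE similarity hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transposon transfer from TE-TE similarity hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httscan)
```

## The inference problem

Transposable elements (TEs) move between reproductively isolated host
lineages by horizontal transfer (HTT). The signature of a transfer is a pair
of TE copies, one in each of two host lineages, whose nucleotide divergence
is far below what vertical inheritance since the hosts' common ancestor
would produce. Because neutral divergence accumulates at a roughly clock-like
rate at synonymous coding positions, the synonymous divergence (Ks) of a
TE-TE alignment can be compared against the Ks distribution of core
orthologous genes of the same two lineages: core genes started diverging when
the hosts did, so a TE pair with Ks far below essentially all core-gene Ks
values cannot be vertically inherited.

`httscan` implements that inference as a pipeline over four kinds of input:
a dated ultrametric species tree (node ages in My), TE copy records (sequence
plus species, superfamily, and protein-anchored coding frames), pairwise
TE-TE similarity hits in BLAST tabular form, and per-gene core ortholog Ks
records. A forward simulator generates all four kinds of input with planted
transfers and ground truth, so every stage of the pipeline is testable
without any external data.

## Pairwise Ka/Ks on degraded coding regions

TE copies decay by frameshifts and nonsense mutations, which rules out
multiple alignment and codon-model fitting at scale. The pipeline therefore
scores pairwise alignments with Li's (1993) degeneracy-class method:

* every position of every sense codon is classified nondegenerate, twofold
  or fourfold degenerate by counting its synonymous single-base changes in
  the standard genetic code (0 synonymous → nondegenerate, 3 → fourfold,
  otherwise twofold; changes creating stops count as nonsynonymous);
* for a codon pair, the class of a site is the average of the two codons'
  classes (half weight to each when they disagree), and each differing
  position contributes a transitional or transversional difference to those
  classes;
* the proportions \(P_i, Q_i\) at class-\(i\) sites are corrected with
  Kimura's two-parameter formulas
  \(A_i = \tfrac12\ln\frac{1}{1-2P_i-Q_i} - \tfrac14\ln\frac{1}{1-2Q_i}\),
  \(B_i = \tfrac12\ln\frac{1}{1-2Q_i}\), and combined into
  \(K_s = (L_2A_2+L_4A_4)/(L_2+L_4) + B_4\) and
  \(K_a = A_0 + (L_0B_0+L_2B_2)/(L_0+L_2)\).

The standard deviation of Ks, used by the hit filter, is a delta-method
propagation of the multinomial sampling variance of \((P_i, Q_i)\); any
consistent variance works here because it only enters one filter inequality.
When a logarithm argument is non-positive the estimate is flagged saturated
and treated downstream as failing the Ks filter. Conventions differ in
small details between published implementations (site-class tables for the
serine/arginine irregularities, for example); the package pins the
convention above, verifies it against an independently written brute-force
oracle to 1e-10, and cross-checks against `seqinr::kaks()` within ~0.01 on
realistic divergences.

One estimator artifact is worth knowing: a synonymous **transversion** at an
arginine-type twofold site (AGA↔CGA first positions) is booked into the
transversional nonsynonymous-class distance, so even a process that makes
exclusively synonymous changes yields a tiny positive Ka.

Codon alignments are rebuilt from nucleotide alignments plus each copy's own
protein-anchored frame segments (`codon_project()`): a codon survives only
if all three of its columns align coding positions whose within-codon phases
agree between the two copies, with no gap, ambiguity or stop. Phases are
re-derived from the frame map after every disruption, never continued
naively, because frame-disrupting damage is the norm in TE copies.

## Selecting hits incompatible with vertical inheritance

Thresholds live in one record, `htt_config()`, with the published
screening values as defaults:
alignments ≥ 300 bp, identity ≥ 75%, score ≥ 200, same superfamily;
species pairs diverged < 120 My excluded outright (strict inequality: a pair
at exactly the boundary is kept); a global-identity prefilter discarding
hits whose divergence proxy \(1 - pID/100\) exceeds the 0.5% quantile of the
relevant core-gene Ks distribution (dimensionally this compares a nucleotide
divergence with a Ks quantile — it is intentionally loose, purely an
optimization, and provably a superset of the Ks filter on simulated data);
and the Ks filter itself: keep iff \(K_s + 2\,\mathrm{sd}(K_s)\) is at most
that 0.5% quantile, \(K_s < 0.5\), and at least 100 codons support the
estimate.

Core-gene distributions are built per sister-clade pair (the two descendant
groups of the MRCA of the hit's species; at a polytomy the child containing
the first species versus all other children): alignments ≥ 600 bp, longest
alignment per gene, and for pairs older than 250 My one genome per subclade
younger than 30 My (the genome with most annotated genes). Empirical
quantiles use linear interpolation (R's default type 7).

## Clustering hits into communities and hit groups

One transfer yields many hits, because the transferred TE keeps transposing
and its hosts keep speciating. Hits are reduced to events in two
iterations, separately per superfamily, with species collapsed into clades
younger than 40 My:

1. **Communities.** Within each pair of young clades, two hits may reflect
   the same transfer (criterion 1) when in at least one clade the
   within-clade identity between the hits' copies exceeds the between-clade
   identity, taken conservatively as `min(pID(h1), pID(h2))` — the looser
   reading merges more, which errs toward undercounting transfers. Hits are
   first preclustered by single linkage on shared copies (at most 200 hits
   per cluster per species pair, favoring the longest coding coverage), then
   community detection runs on the criterion-1 graph: greedy agglomerative
   modularity maximization, with the merge dendrogram cut at the level of
   maximal modularity and ties broken toward fewer communities, which makes
   the partition deterministic and never splits a clique.
2. **Hit groups.** Pairs of communities are merged when ≥ 5% of their
   cross-community hit pairs pass criterion 1 (or, for copy sets with no
   nucleotide homology and < 100 bp of shared protein-anchored region, the
   fragmentation fallback applies), **and** criterion 2 holds: on every side
   where the two communities involve different host lineages, both
   communities' mean hit Ks must be at least the 0.5% core-gene Ks quantile
   of the sister-clade pair spanning those lineages — the transfer must
   predate the speciations it straddles. Merging is complete-linkage
   (every within-group pair must pass), attempted in order of decreasing
   mean hit identity with ties broken by community id. Side orientation
   between two communities is chosen to minimize the summed MRCA ages of the
   paired side unions, and sides must stay disjoint.

Criterion 2 is reconstructed from the logic of the two-clade divergence
diagram (TE divergence between clades must not postdate within-clade host
divergence); it is isolated behind a single predicate so the inequality
form can be revised independently.

## Group evaluation and independent-event counting

Each group is then audited:

* **Retrieval.** Copies discarded upstream are re-attributed: a candidate
  copy joins clade A when its mean recorded identity (alignments ≥ 100 bp)
  to the group's clade-A copies strictly exceeds the group's mean
  cross-clade hit identity.
* **Copy counts** (anti-contamination): ≥ 5 copies per clade including
  retrieved ones and ≥ 2 per clade excluding them; a contaminant inserted
  as a single foreign copy can never pass.
* **Ks truncation** (anti-vertical-inheritance): Ks classes are delineated
  by `hist()` (Sturges count on pretty breaks; verified against an
  independent construction); the modal class must hold at least 20 more
  hits than the rightmost non-empty class, and the maximum Ks must be at
  most the selection threshold minus 0.2. A slowly diverging vertical tail
  sneaking under the Ks threshold produces a flat, right-truncated
  distribution and fails here; a genuine transfer gives a star-like young
  distribution that passes.

Finally, groups are reduced to a minimal set of independent events.
Groups are processed in increasing order of a reliability score (per copy,
the best hit pID; summed per clade; the lower sum), ties by group id. A
focal group is *explained* when every one of its species has a copy that is
better matched by a compatible clade of some other pool group (equal,
nested or encompassing species set) than by at least one cross-clade partner
in the focal group, with at least two distinct explanatory groups overall;
explanatory groups whose removal would break this are flagged *required* and
can no longer be explained themselves. Explained groups leave the pool;
everything never explained is an independent transfer. "Similarity" is the
maximum pID over all recorded evidence (hits plus identity tables). The
procedure is greedy, not optimal: the test suite checks it against a
literal independently coded oracle on all small instances and against an
exhaustive minimum-support bound (within one), and probes order sensitivity
by processing in reverse (a few percent change in aggregate counts).

## Permutation nulls and selection regimes

Transfer distribution across clades is tested by constrained species
permutation: each transfer is represented by the species pair of its
highest-identity hit; a permutation is a bijection on the involved species
applied consistently everywhere (preserving per-species transfer counts);
permutations creating any pair diverged < 120 My are rejected and redrawn
until 1000 legal ones accumulate (attempt budget 1e7, after which the
function advises permuting subsets). Superfamilies with < 20 transfers are
pooled per TE class; units above 120 transfers are split after a seeded
shuffle into balanced contiguous chunks. Verdicts are reported as
outside-all (empirical p < 1/n_perm), within, or outside the central 95%,
plus the observed/null-mean ratio. The habitat test permutes
aquatic/terrestrial labels (amphibious counted aquatic) across the tetrapod
species involved in fish-tetrapod hit groups.

Selection regimes compare two Ka/Ks distributions per superfamily:
horizontally transferred pairs (the retained hits) versus within-genome
pairs (same community and genome, ≥ 300 coding bp — pairs that diverged by
transposition alone). Each distribution is tested against neutrality with a
one-sample Wilcoxon signed-rank test of the ratios against 1 (the standard
one-sample reading of a "one-sample Mann-Whitney" test), one-sided toward
purifying selection, exact for ≤ 25 values; ratios exactly 1 are dropped per
the classical procedure, and pairs with Ks = 0 carry no ratio and are
excluded with a logged count. No multiple-testing correction is applied by
default, matching the per-superfamily reporting convention; `p.adjust` can
be applied downstream. Pseudo-replication from copies appearing in many
pairs is not corrected either — the distributions mirror the pair lists as
computed.

## The forward simulator

`simulate_dataset()` emits every input the pipeline consumes. Design:

* **Substitution process.** Proposals arrive at `mu_s` (default 3.1e-9 per
  site per year, the vertebrate synonymous rate scale) uniformly over the
  three alternative bases; synonymous proposals are always accepted,
  nonsynonymous ones with probability `omega`; a proposal creating a stop is
  rerouted to a uniformly chosen valid nonsynonymous alternative of the same
  site and then subjected to the same `omega` acceptance. The rerouting
  matters: the estimator's site counts include the stop-bound directions a
  simulation can never realize, so plain rejection would depress realized
  Ka/Ks by ~4-5% and any calibrated neutrality test would flag the bias.
  With rerouting, a pair split `t` years ago has expected Ks `2*mu_s*t` and
  expected Ka/Ks `omega` under the estimator.
* **Gapless TE families.** Copies of a family are gapless homologs, so a
  "search hit" is a positional comparison: pID is the percent of matching
  positions, the score is `2*matches - 3*mismatches` (the default
  nucleotide-search weights; only threshold behavior matters), and the
  best-scoring comparison per query copy per target species is reported in
  both directions, then deduplicated per unordered pair. Indel robustness
  is the codon projector's job and is tested with hand-built gapped
  fixtures instead.
* **Transposition.** Bursts arrive per family per lineage (default 0.02/My)
  and duplicate one random active copy into `1 + Poisson(2)` new copies;
  for 20 My after a family enters a lineage (its origin, or a horizontal
  arrival) the rate is multiplied by 30 — the invasion burst that gives
  both vertical families and fresh transfers their star-like within-genome
  structure. An optional per-copy deactivation rate switches copies to
  neutral evolution, the handle for probing selection-regime change.
* **Planted transfers.** An event copies one active donor-lineage copy into
  the recipient lineage at the stated time, where it diversifies under the
  same rules; descendants are labelled in a truth table. Family origins can
  be placed on a specific lineage at a specific age: recently active donor
  families are the kind that mediate detectable transfer.
* **Reproducibility.** One master seed; each stage derives its own stream
  deterministically, so identical configs give byte-identical datasets.

`demo_sim_config(K, seed)` packages the standard verification arena: a
16-species tree (two 430-My-diverged major clades, eight clades younger
than 40 My), `K` planted transfers, each in its own superfamily originating
on its donor lineage 24 My ago and crossing 18 My ago, over a vertical
background superfamily spanning the whole tree. These ages follow from the
detection window that the thresholds define: the truncation margin caps
usable cross-clade Ks at 0.3 (≈ 48 My of divergence at the default clock),
identity ≥ 75% caps total divergence, and the modal-class rule needs
of order 150 hits per group, hence the invasion-amplified copy numbers
(roughly 20-40 copies per species and side).

What the generator does **not** emulate: indels and fragment decay,
assembly artifacts, contamination (contamination behavior is exercised with
hand-built single-copy fixtures), base-composition non-stationarity, rate
variation across sites, and LTR/LINE mechanistic detail. Passing tests
demonstrate the pipeline's logic under clock-like, gapless, composition-
stationary evolution; they do not certify performance on real genomes,
where annotation quality and saturation dominate the error budget.

## Numerical and scale choices

Ultrametricity is enforced within a relative tolerance of 1e-6 of tree
height and trees are never rescaled. Age comparisons are strict
("younger than" means `<`). All stage thresholds are read from
`htt_config()`; a configuration with `min_age = 0` is refused because the
HTT-versus-vertical decision is undefined without a divergence floor. The
test suite runs its heaviest property — exact recovery of K ∈ {1, 3, 5, 8}
planted transfers over 50 seeds each — on the 16-species arena with 60
core genes per genome, and the simulation-backed calibration checks use
150-200-codon alignments with a few hundred replicates; these sizes were
chosen to make the Monte-Carlo error small relative to each tolerance band
while keeping the suite light enough for routine runs.

## Known limitations

* Criterion 2's exact inequality is a reconstruction (the source describes
  it only diagrammatically); it is deliberately one predicate.
* The greedy explanatory-transfer procedure bounds, but does not minimize,
  the number of independent events.
* Detection is blind to transfers whose cross-clade Ks exceeds ~0.3 at the
  default clock — equivalently, transfers older than roughly 48 My — and to
  anything between hosts diverged < 120 My; this is a property of the
  thresholds, not of the implementation.
* Saturated Ka/Ks estimates are discarded rather than corrected, so deep
  divergences contribute no rate information.
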