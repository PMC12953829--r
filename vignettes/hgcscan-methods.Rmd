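---
title: "hgcscan: methods, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hgcscan: methods, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgcscan)
```

## The problem

Microbial mercury methylation requires the tandem gene pair *hgcAB*. In a
redox-stratified water column the carriers are expected to concentrate in
the anoxic, sulfidic deep layer, and their distribution may further differ
between free-living (FL) cells and cells attached to sinking particles
(PA). Quantifying this from shotgun metagenomes raises three separable
methodological problems, each handled by one part of this package:

1. deciding which predicted proteins are genuine HgcA (homology search
   alone admits corrinoid-protein paralogs such as the CdhD family);
2. turning read coverage of a gene into an interpretable community
   fraction ("percent of genomes carrying the gene");
3. summarizing the result along the depth/redox and FL/PA axes, on a gene
   tree, and against reference protein structure.

## Validation cascade

`screen()` composes four deterministic filters.

* **E-value gate** (default 1e−25). The profile-HMM search itself is
  delegated: the module consumes a hit table (plain TSV or HMMER tblout).
  This mirrors standard marker-database protocols where the search is a
  fixed tool run and the scientifically contested step is everything
  after it. When no hit table is supplied, all proteins proceed to
  motif-anchored discovery. Which tblout e-value column is gated (full
  sequence vs best domain) is a configuration choice
  (`read_hits_table(evalue_column=)`); the default is the full-sequence
  column.
* **Cap-helix motif** N-(V/I)-W-C-(A/S)-(A/G)-G-K. Exactly 8 eight-mers
  are accepted (degeneracy 1·2·1·1·2·2·1·1). The ambiguity residue X never
  matches a constrained position — a conservative choice: an X at the
  catalytic cysteine position should not validate a sequence.
* **Length filter**, strictly below 100 aa discarded; a 100-aa sequence is
  retained. Fragments shorter than this cannot be distinguished reliably
  from truncated paralogs, and 100 aa is also the approximate size of
  HgcB, so shorter motif-bearing ORFs are likely assembly fragments.
* **Deduplication** at 100 % identity with containment: two sequences
  share a cluster when identical or when one is an exact substring of the
  other (the behaviour of word-indexed clustering at identity 1.0). The
  representative is the longest member; ties break on the
  lexicographically smallest gene id, making the output independent of
  input order.

Filter order between the motif and length checks does not affect the
result (both are per-sequence predicates); this is asserted by a test.

For structure-modelling picks, `select_representatives()` implements
greedy longest-first clustering at 50 % global identity. The identity of
two sequences is defined as aligned matches divided by the length of the
shorter sequence under a Needleman–Wunsch global alignment (match +1,
mismatch −1, gap open 10, gap extension 0.5). The definition had to be
fixed somewhere: clustering tools use the shorter-sequence convention, and
stating it explicitly makes the 50 % threshold reproducible.

The tandem-pair check accepts a downstream neighbour on the same strand
within 500 bp of the *hgcA* stop (strand-aware), shorter than 100 aa, with
at least two non-overlapping CX₂CX₂CX₃C matches. 500 bp is a generous
ceiling for an intra-operon gap; the generator plants the pair at 20 bp.

## Abundance model

For gene *g* in sample *s*,

> rel_abundance(g, s) = mean_depth(g, s) / GE(s) × 100

where `mean_depth` is aligned bases overlapping the gene interval divided
by gene length (CIGAR M/=/X blocks of primary alignments only — secondary
and supplementary records are excluded so each read is counted once), and
GE(s), the *genome equivalent*, is the estimated number of genome copies
the sample's reads represent. The statistic is scale-invariant: doubling
sequencing effort doubles numerator and denominator alike.

GE is estimated as the **median** aggregate coverage of universal
single-copy marker gene families. A read-sampling estimator
(MicrobeCensus-style) is deliberately replaced by this transparent
statistic: it has the same contract (each single-copy family's summed
depth across community members equals the genome count), is fully
testable offline, and the median makes it robust to one collapsed or
mismapped family. Externally computed genome equivalents can be supplied
(`ge_override`) when fidelity to another estimator is required. At least
3 marker families are required; fewer is an error that advises explicit
input rather than a silent fallback.

## Ecology conventions

* **Zones**: surface ≤ 50 m, intermediate 50–100 m, deep > 100 m. The
  sampled depth groups are 0–50, 60–100 and 105–190 m; the unsampled
  50–60 and 100–105 m gaps are closed by extending surface down to 50 m
  and deep up to 100 m, because oxygen is undetectable below 100 m (the
  anoxic regime starts there) while 50 m is still grouped with surface.
  The classifier therefore partitions \[0, 300\] with no gaps or overlaps,
  and the seven canonical sampling depths {0, 30, 50, 90, 120, 140, 170}
  map to 3 surface, 1 intermediate and 3 deep samples.
* **Lifestyles**: sequential filtration; the 3 µm retentate is PA, the
  0.22 µm retentate is FL. Any other pore size is an error, not a guess.
* **Habitat preference**: `log2((pa + ε)/(fl + ε))`. The pseudocount ε
  engages *only when one of the pair is zero* — a ratio of two positive
  percentages needs no regularization, and an always-on ε would visibly
  bias small ratios (2 %/1 % must score exactly +1). When scoring a whole
  sample pair, ε is shared: half the smallest nonzero abundance across
  both samples. The policy is symmetric, so the score is antisymmetric
  under swapping PA and FL. Both-zero features score 0 and are flagged
  `"absent"` rather than dropped.

## Tree operations

Rerooting places the root on the branch separating the outgroup's MRCA
from the ingroup, at the **midpoint** of that branch. Interactive tree
editors do not document their placement; the midpoint is deterministic and
preserves the unrooted metric exactly (the two root-child edges sum to the
original branch length, so all leaf-to-leaf path lengths are unchanged —
asserted against a distance-matrix oracle). A non-monophyletic outgroup
triggers a warning and rooting on the MRCA edge anyway, with the result
flagged. Support labels travel with their child nodes (`edgelabel = TRUE`)
and are never averaged.

Monophyly is defined on the unrooted topology: a leaf set is monophyletic
iff some edge bipartitions exactly that set from the rest. Pendant edges
count, so a single leaf (and the complement of one) is monophyletic —
matching the common convention. Tests compare this against an independent
edge-removal/graph-traversal oracle.

Clade delimitation is an *input* (a name → leaf-ids table), not an
inference: how the published Delta-1/2/3 clades were drawn is not
algorithmically specified anywhere, so the package summarizes clades it is
given (per-sample abundance sums, mean root-to-tip lengths, longest-first
ranking) rather than inventing a delimitation rule.

## Structure comparison

Superposition is Cα-only (reported pruned atom pairs in this field are Cα
pairs) via the Kabsch SVD solution with the determinant correction, so
reflections are never returned: a mirror-image decoy cannot score an
artificially low RMSD. Degenerate (collinear) point sets are an error.
Outlier pruning iterates fit → drop all pairs beyond the cutoff → refit,
until convergence, 100 iterations, or when a drop would leave fewer than
3 pairs (the drop is then not applied). The 2.0 Å default cutoff is the
documented default of the interactive matchmaker tool this emulates; the
iteration always reports both retained and pruned counts so results are
comparable to published "RMSD over N pruned pairs" figures. Pruning can
only lower the RMSD (the refit minimizes over a subset chosen to exclude
the worst residuals); this is asserted over random fixtures rather than
assumed.

Residue pairing comes from an explicit table or a two-sequence gapped
alignment (gap columns excluded); the package does not compute structural
alignments itself — the upstream matchmaker settings are not reproducible
from any published description, so pairing is an explicit, auditable
input. Per-residue confidence is read from the PDB temperature-factor
column (where prediction tools store pLDDT); the global confidence flag
uses a 0.73 floor, the lowest pTM observed across accepted models in the
motivating analysis.

## The synthetic generator: what it emulates, and what it does not

`build_community()` states a world:

* **Design**: 7 depths {0, 30, 50, 90, 120, 140, 170} m × {FL, PA}
  (14 samples), genome equivalents 50 per sample, coverage noise CV 0.1
  by default.
* **Carrier fractions** default to surface 0.2 %, intermediate 1.5 %,
  deep 30 % — the redoxcline shape reported for stratified anoxic sites
  (trace carriers in oxic water, ~1.5 % at the suboxic transition, ~30 %
  in anoxic deep water). Within the carrier and non-carrier groups,
  per-taxon shares follow zone-affinity weights and a lifestyle bias
  multiplier `exp(±bias)`.
* **Genomes**: each taxon contributes one contig with 10 single-copy
  marker genes of 900 bp; carriers add an hgcA (200–330 aa, motif at a
  random internal position, so every planted hgcA is ≥ 150 aa) and an
  hgcB (90 aa, two tandem CX₂CX₂CX₃C motifs) 20 bp downstream on the same
  strand. Alternating carriers use the minus strand so the strand-aware
  pair check is exercised. Protein backbones are random over the 20-letter
  alphabet (re-drawn in the vanishingly rare event a spurious cap-helix
  motif appears): only motif, length and identity properties matter
  downstream, so no attempt is made at realistic composition.
* **Coverage noise** is multiplicative lognormal with unit mean and the
  stated CV, drawn independently per gene and sample: strictly positive,
  heavy-tailed, and simple to reason about. No error model for coverage
  is published for the motivating data; this is a stand-in, not an
  inference. Marker-family depth rows are aggregates over taxa (the sum
  of per-taxon copies is the genome-equivalent signal), so their
  effective CV shrinks with community size, as real universal-marker
  coverage does.
* **Decoys**: paralogs break the motif at one constrained position but
  keep hgcA-like length; fragments carry a genuine motif truncated to
  60–99 aa. Both receive background coverage and are marked non-hgcA in
  the truth tables.

What the generator does **not** emulate — so a green test does not
establish robustness to it: read-level errors (no FASTQ simulation),
assembly chimera and fragmentation, strain microdiversity, compositional
biases of real proteins, correlated coverage along contigs, and
inter-sample correlation structure beyond the planted depth profile.
Recovery results on this generator validate the arithmetic and the
filtering logic, not performance on low-quality assemblies.

Determinism is part of the contract: a fixed seed yields byte-identical
fixture files, and every pipeline stage is a pure function of its inputs
(internal sorts make outputs independent of input row order). The RNG
state of the caller is saved and restored around all seeded operations.

## Numerical choices and degenerate inputs

* E-value gate boundary: `evalue <= threshold` retained; negative
  e-values reject the input. Candidates without an e-value pass the gate
  (discovery mode) — absence of evidence is not treated as failure.
* Length boundary: `>= 100` retained ("shorter than 100" is strict).
* Dedup tie-breaks: length descending, then gene id; cluster id is the
  representative's gene id.
* Genome equivalents: ≥ 3 markers or error; zero/negative GE rejects.
* `habitat_preference`: both-zero → 0 + `"absent"`; ε only rescues zeros.
* Kabsch: < 3 pairs or collinear sets are errors; orthonormality of the
  returned rotation is within 1e−8 with det +1.
* Zone classifier: depths outside \[0, 300\] are errors, not clamped.

## Known limitations

* The HMM search itself is out of scope; sensitivity is bounded by the
  supplied hit table (or, in discovery mode, by exact motif matching,
  which cannot recover a sequencing error inside the motif).
* The 50 %-identity clustering is greedy and order-dependent by design
  (longest first); it reproduces the convention of the standard tool but
  is not a globally optimal clustering.
* Genome-equivalent estimation assumes the marker families are truly
  single-copy and completely assembled; systematic marker dropout would
  inflate relative abundances.
* Structural comparison requires an externally supplied residue pairing;
  disagreement with a structure-aware aligner's pairing will change RMSD.
* Fused hgcAB ORFs are not specially handled: a fusion long enough to
  pass the length filter validates as hgcA and its hgcB check then
  depends on annotation having split the ORF.
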