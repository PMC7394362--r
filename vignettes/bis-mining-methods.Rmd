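---
title: "Mining Bacteroidales injection system loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining Bacteroidales injection system loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisminer)
```

## The system and the questions

Gut *Bacteroidales* encode a contractile injection system (BIS) — a
phage-tail-derived syringe assembled from sheath and inner-tube proteins on
a baseplate of gp25, gp27 and gp6, with an FtsH/ATPase, LysM, Spike, Tip,
two DUF-domain proteins (DUF4255, DUF4157) and five hypothetical proteins
completing an 18-gene roster (`bis_roster()`). Ten of the genes form a core
that cooccurs at high frequency in gut metagenomes. The package answers
three questions about this system:

1. Where are BIS loci encoded in genomes, and in which of the three
   conserved architectures?
2. How prevalent are the roster genes in metagenome samples and donors?
3. Do donors from different health groups (healthy, IBD, prediabetes) carry
   different numbers of BIS genes?

## Locus discovery

`find_bis_loci()` implements neighborhood mining around sheath anchors:

* **Anchoring.** Profile hits against the sheath family are kept when the
  bit score exceeds 31.4 **and** the E-value is below 1e-9 (both strict).
  These gathering thresholds make anchoring conservative: a sheath is the
  most recognisable CIS component, and every true locus contains one.
* **Neighborhoods.** Twenty proteins are taken on each side of an anchor
  (clipped at replicon ends, overlapping windows merged). The widest
  architecture spans 18 genes, so a ±20 window always contains the full
  locus with margin, while staying small enough that unrelated genes
  dominate neither the clustering pool nor the trimmed locus.
* **Clustering.** All neighborhood proteins from all genomes are pooled and
  clustered greedily, longest first, at ≥50% identity to the cluster
  centroid (UCLUST-style). Identity is computed from a global
  Needleman–Wunsch alignment (match +2, mismatch −1, gap −2) as identical
  aligned pairs divided by the shorter sequence length. Clusters with fewer
  than 4 members are discarded — a real BIS gene family recurs across
  genomes, a spurious ORF does not. Consequently the finder is meant to run
  on pooled genome sets, not single genomes.
* **Annotation.** Cluster representatives are aligned to the 18 roster
  references; a representative takes the role of its best reference at
  identity ≥0.45 over ≥50% coverage, and members inherit the role.
* **Trimming and classification.** Each neighborhood is trimmed to the span
  bounded by the outermost DUF4255 and FtsH/ATPase calls (the flanking genes
  of every architecture), falling back to the first-to-last annotated gene
  when a boundary is missing. A locus is *complete* when all six core
  structural roles are present (three baseplate genes, sheath, tube,
  FtsH/ATPase). Complete loci are classified: architecture 3 if FtsH/ATPase
  precedes DUF4157 (the compact arrangement's inverted pair, which also
  carries shortened gp27/gp6), else architecture 1 with ≥2 sheath and
  ≥2 tube calls, else architecture 2 with exactly one sheath.

### Why the annotation floor is 0.45, not lower

The identity statistic divides by the *shorter* sequence length. For
unrelated random proteins this statistic grows as lengths diverge: a random
60-residue peptide aligned to a 245-residue protein reaches a median
"identity" above 0.6 purely by chance, because most of its residues can be
matched somewhere. Within a 200–250 residue band the chance identity stays
around 0.36–0.40. The annotation threshold of 0.45 therefore sits above the
in-band chance ceiling and far below the identity of true homologs (≥0.8 at
the generator's mutation rates), so random proteins stay unannotated while
diverged family members are still recognised. The 50% *clustering* threshold
is a separate, deliberately stricter, family-definition parameter.

### The alignment kernel

The Needleman–Wunsch DP is implemented in C++ (two-row, linear memory).
Among tied optimal alignments it deterministically prefers more identical
pairs, then more aligned pairs, so identity never depends on traceback
order. Clustering additionally prescreens each candidate-centroid pair with
a bit-parallel longest-common-subsequence length: LCS is an upper bound on
the identical pairs of any alignment, so when `LCS / shorter < threshold`
the exact DP can be skipped without changing any decision. This makes
clustering pools of ~1,000 neighborhood proteins run in seconds.

## Metagenome screening

Per-sample read hits in the standard 12-column tabular alignment layout are
filtered at E ≤ 0.001 (inclusive) and tallied per roster gene without
best-hit selection — in a metagenome many strains contribute reads, and the
screen asks which gene families are present, not which gene each read came
from. The per-sample, per-gene heat value is the coverage score
`log10(1e6 · hits / total_reads + 1)`: hits per million reads, log-damped,
zero hits mapping to exactly 0.

In metatranscriptome mode (`expression_profile()`) the opposite choice is
made: each read keeps only its best hit (lowest E, then highest bit score,
then subject name), because expression is quantified per gene and double
counting would bias long, conserved genes. Counts are normalized as
`1e9 · count / (total_reads · gene_length_nt)`.

## Cooccurrence and prevalence

The cooccurrence weight of two genes is the sum over samples of the smaller
of their two hit counts — the count of "shared" observations. It is
symmetric, bounded by either gene's total, and zero whenever the genes never
appear in the same sample.

Donor-level analysis averages each gene's counts over a donor's samples
(donors are sequenced 1–5 times; averaging prevents re-sequenced donors from
dominating), then counts genes with nonzero mean — the donor's *presence
count* (0–18). `prevalence_distribution()` reports the fraction of donors
at or above each presence count. Bacteroidetes relative abundance is parsed
from standard clade/abundance taxonomic profiles (phylum-rank rows).

## Group comparison

The difference in group medians of presence counts is estimated with a
percentile bootstrap: both groups are resampled independently with
replacement at their original sizes, the median difference recorded, and the
2.5%/97.5% quantiles of 10,000 replicates reported; the difference is
*significant* when the interval excludes zero. Medians (not means) because
presence counts are bounded, discrete and skewed; percentile intervals (not
normal-theory) because the bootstrap distribution of a median difference on
discrete data is lumpy and asymmetric. All resampling runs under an
explicit seed through `with_seed()`, which restores the caller's RNG state,
so results are bit-reproducible and never perturb other code's random
streams.

Each bootstrap call is validated by the asymptotic Wilcoxon rank-sum test
(midranks, tie-corrected variance, continuity correction). The continuity
correction matters: without it, the normal approximation deviates from the
exact permutation p-value by up to 0.125 already at group sizes of 3;
with it, the worst deviation over thousands of tie-free instances at sizes
2–7 is 0.088. With *heavily tied* tiny samples (e.g. `a = (0,2,2,0)` vs
`b = (0,0)`) the deviation can reach ~0.4 regardless of correction — an
intrinsic limit of the normal approximation, not of the implementation.
The package's comparisons operate on ≥28 donors per group, where the
approximation is accurate even with ties; the test suite validates the
approximation in its supported (tie-free) regime and treats the tied
small-sample case as a documented limitation.

`compare_all_groups()` runs four pairs — healthy vs IBD (pooling Crohn's
disease and ulcerative colitis), healthy vs prediabetes, prediabetes vs
IBD, Crohn's vs colitis — with pair-specific derived seeds, skipping pairs
with fewer than two donors.

## Synthetic data: realism and limits

The generators are the package's ground truth, and their defaults are the
study conditions of the test suite; none of their parameters are tuned to
any particular test outcome.

**Genomes** (`generate_genome()`): planted locus genes are derived from
fixed-seed roster references by substituting 5–12% of residues, so
within-family identity (≥0.8) clears the clustering and annotation
thresholds with a wide margin, as real orthologs would. Architecture 3
truncates gp27/gp6 to 85%. Flanking genes are random proteins. All protein
lengths — roster and flanks — are confined to 200–250 residues so that the
chance-identity inflation described above cannot create spurious clusters;
this is the generator's main concession to the identity statistic and its
main departure from real genomes, where neighboring ORFs vary widely in
length. Other simplifications: substitutions only (no indels, domain
shuffling or paralogs), single replicon, uniform residue frequencies.
`generate_anchor_hits()` emulates a profile search: every sheath gets a
passing hit; a few random proteins get hits failing exactly one threshold.

**Cohorts** (`generate_cohort()`): each donor carries a number of roster
genes drawn around 13 (SD 2, clipped to 0–18), reduced by `median_shift`
(default 2) for the IBD groups — the planted effect. Carried genes are
sampled with 3:1 preference for the ten core genes, reproducing the
core/accessory prevalence split. Per-sample hits for carried genes are
negative binomial (mean 5, dispersion 2): over-dispersed with occasional
zeros, like real per-gene read recruitment; genes not carried give
structural zeros. Read depths are log-normal around 1e6; Bacteroidetes
abundance is Beta-distributed per group with a lower mean in IBD, and
per-sample taxonomic profiles jitter around the donor value. Limits: no
strain mixtures, no compositional coupling between BIS carriage and
taxonomy beyond the group means, body site fixed to gut.

## Problem sizes

The package's own validation runs at desk scale, chosen so the full suite
completes in minutes on one CPU: 20 genomes per architecture (plus 20
locus-free and 20 decoy genomes) for recovery, cohorts of 200–345 donors
(~1,000 samples) for the statistical pipeline, 500 simulated cohorts of
n = 100 per group at 1,000 replicates for bootstrap calibration, and 50
seeded end-to-end runs for effect detection. Production-scale inputs
(thousands of genomes or metagenomes) pass through the same code paths; the
LCS-prescreened clustering is the only stage whose cost grows quadratically
in the pooled neighborhood size.

## Determinism

Every stochastic function takes an explicit seed and derives per-task seeds
by small integer offsets (all far below 2^31). The CLI writes a
`manifest.json` (command, options, package version, input MD5 checksums —
deliberately no timestamps) from which any run can be re-executed; the test
suite asserts byte-identical outputs for every subcommand.
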