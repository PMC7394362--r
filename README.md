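# bisminer

Tools for mining **Bacteroidales injection system (BIS)** gene clusters from
genomes and metagenomes, and for testing how the system's carriage differs
between human health groups.

The BIS is a contractile injection system (CIS) — a phage-tail-like molecular
syringe built from a sheath, an inner tube and a baseplate (gp25, gp27, gp6)
— encoded by gut *Bacteroidales* as a conserved cluster of 18 genes. The
package implements the complete computational workflow around that cluster:

1. **Locus discovery** (`find_bis_loci`) — anchor proteins matching the
   phage-sheath profile above gathering thresholds (bit score > 31.4,
   E < 1e-9) seed the extraction of ±20-protein genome neighborhoods; pooled
   neighborhood proteins are greedily clustered at 50% global-alignment
   identity (UCLUST-style, clusters of ≥4 kept); cluster representatives are
   annotated against the 18-gene roster; each neighborhood is trimmed between
   the DUF4255 and FtsH/ATPase boundary genes, assessed for completeness
   (baseplate + sheath + tube + ATPase) and classified into one of three
   conserved architectures (double sheath; single sheath; compact form with
   the FtsH/DUF4157 pair inverted and shortened gp27/gp6).
2. **Metagenome screening** (`count_hits`, `coverage_score`) — per-sample
   read hits against the roster are filtered at E ≤ 0.001 and summarized as
   `log10(1e6·hits/reads + 1)` coverage scores.
3. **Cooccurrence network** (`build_network`) — edge weight between two genes
   is the sum over samples of the smaller of their hit counts.
4. **Donor prevalence** (`aggregate_by_donor`, `prevalence_distribution`) —
   per-gene counts are averaged over each donor's samples; a donor's
   *presence count* is the number of roster genes with nonzero mean.
5. **Group comparison** (`bootstrap_median_ci`, `compare_all_groups`) —
   percentile bootstrap (10,000 replicates) for the difference in group
   medians, validated by the asymptotic Wilcoxon rank-sum test.
6. **Metatranscriptome screening** (`expression_profile`) — best hit per
   read, counts normalized by read depth and gene length.
7. **Synthetic data generators** (`generate_genome`, `generate_cohort`) —
   seeded genomes with planted loci and seeded donor cohorts with a planted
   group effect, used as ground truth throughout the test suite.

A command-line interface (`bis_main()`, wrapper in `inst/cli/bisminer`)
chains the stages as `simulate`, `find-clusters`, `screen`, `cooccur`,
`prevalence`, `compare` and `transcribe` subcommands; every run writes a
`manifest.json` from which it can be reproduced byte-identically.

## Worked example

Recover planted loci from five synthetic genomes:

```r
library(bisminer)

genomes <- lapply(1:5, function(i) generate_genome("2", flank_genes = 15, seed = i))
anchors <- do.call(rbind, lapply(1:5, function(i)
  generate_anchor_hits(genomes[[i]], seed = 100 + i)))
res <- find_bis_loci(genomes, anchors)
res$summary[, c("replicon_id", "n_genes", "complete", "architecture")]
#>    replicon_id n_genes complete architecture
#> 1 syn_arch2_s1      15     TRUE            2
#> 2 syn_arch2_s2      15     TRUE            2
#> 3 syn_arch2_s3      15     TRUE            2
#> 4 syn_arch2_s4      15     TRUE            2
#> 5 syn_arch2_s5      15     TRUE            2

res$loci[[1]]
#> BIS locus on syn_arch2_s1: 15 genes, complete, architecture 2
#>  roles: duf4255 hypothetical sheath tube baseplate_gp25 baseplate_gp27
#>  hypothetical baseplate_gp6 spike tip tube lysm hypothetical duf4157
#>  ftsh_atpase
```

Compare health groups in a synthetic cohort (214 healthy, 103 IBD,
28 prediabetes donors, with a planted two-gene reduction of carried BIS
genes in IBD):

```r
spec   <- cohort_spec(seed = 42)
cohort <- generate_cohort(spec)
prof   <- aggregate_by_donor(cohort$counts, cohort$samples)
compare_all_groups(prof, n_replicates = 10000, seed = 42)
#>       group_a     group_b estimate ci_low ci_high significant   wilcoxon_p
#> 1     healthy         ibd        2    1.0     3.0        TRUE 4.188110e-12
#> 2     healthy prediabetes        0   -1.0     0.5       FALSE 4.675666e-01
#> 3 prediabetes         ibd        2    1.0     3.0        TRUE 2.174173e-06
#> 4      ibd_cd      ibd_uc        0   -1.5     1.5       FALSE 8.154796e-01
```

The healthy-vs-IBD interval excludes zero (planted effect recovered, at its
planted size of 2) while the Crohn's-vs-colitis interval covers zero, and

```r
prev <- prevalence_distribution(prof$donors$presence_count)
prev[prev$k == 9, ]
#>    k   pct_eq   pct_ge
#> 10 9 4.927536 93.62319

coverage_score(10, 1e6)
#> [1] 1.041393   # log10(11)
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "bisminer",
                   load_package = "installed")
```

The suite validates the alignment, clustering and counting primitives
against brute-force oracles, recovers planted loci across all three
architectures with zero false positives, checks bootstrap calibration and
the Wilcoxon normal approximation, and verifies byte-level determinism of
every CLI subcommand. See `vignettes/bis-mining-methods.Rmd` for the methods
and the reasoning behind thresholds and generator design.
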