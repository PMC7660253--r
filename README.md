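# karyoshift

Aneuploidy pattern analysis for unstable hybrid yeast genomes.

Interspecific *Saccharomyces* hybrids -- e.g. allotriploid
*S. cerevisiae* x *S. kudriavzevii* wine strains, diploid for one sub-genome
and haploid for the other -- can have remarkably unstable karyotypes: whole
chromosomes of the haploid sub-genome drop to low frequency in the cell
population within a few generations. karyoshift is for geneticists asking
the questions that follow from that observation:

* **How much of the population still carries a chromosome?** From windowed
  read depth, the population frequency of chromosome *c* is estimated as
  `phi_hat(c) = mean_depth(c) / E`, where `E = 2RL / G` is the expected
  coverage per haploid copy from `R` read pairs of length `L` over a model
  genome of `G` bp (one haploid copy of each sub-genome). Chromosomes are
  classified `present` / `low_frequency` / `lost` with configurable
  thresholds, with bootstrap confidence intervals over windows.
* **Which chromosomes are aneuploid most often in a strain panel?** Within
  the aneuploid strains of a strain x chromosome copy-number matrix, the
  per-chromosome frequency statistic is the odds
  `f(c) = n_abnormal(c) / n_normal(c)`, counting gains and losses
  identically, plus the Pearson correlation of `f` with chromosome size.
* **Are a chromosome's genes collectively unusual?** For each chromosome
  (n_c genes) and each of 17 gene features (physical/genetic interaction
  counts split by partition and sign, complex membership, stress
  up-regulation), a bootstrap null is built from random n_c-gene sets drawn
  without replacement from the genome (default 10,000 replicates) and the
  observed mean is reported as a CDF value,
  `pnorm((actual - null_mean) / null_sd)` -- near 0 depleted, near 1
  enriched -- arranged with 1-minus-correlation average-linkage clustering.
* **Which chromosome can change copy number with the least epistatic
  consequence?** Signed genetic-interaction scores are summed between each
  chromosome pair (positive compensating negative) into `S(i, j)`, and a
  directed network draws one arrow per chromosome to the partner with
  `|S(i, j)|` nearest to zero; high in-degree nodes are the network's hubs.

A seeded generator suite (`simulate_*`) produces every input type with
planted, recoverable structure, so the whole pipeline runs and is tested
without any external download.

## Worked example

Simulate a panel and a sequencing run in which two small chromosomes have
nearly left the population, then run the analyses:

```r
library(karyoshift)

cfg <- simulation_config(seed = 42, phi = c(rep(1, 14), 0.01, 0.004))
map <- simulate_genome_map(cfg)
map
#> genome_map: 16 chromosomes (12.07 Mb), 6023 genes

cn <- simulate_copy_number_matrix(map, cfg)
length(detect_aneuploid_strains(cn))
#> [1] 222

f <- aneuploidy_frequency(cn)          # abnormal/normal, aneuploid strains
head(f[order(-f$f), ], 3)
#>         chrom n_abnormal n_normal         f undefined
#> chrI     chrI         38      184 0.2065217     FALSE
#> chrVI   chrVI         28      194 0.1443299     FALSE
#> chrIII chrIII         22      200 0.1100000     FALSE

size_frequency_correlation(f, map)
#> Pearson r = -0.868, P = 1.29e-05 (n = 16 chromosomes)
```

Of 1011 simulated strains, 222 are aneuploid somewhere; the smallest
chromosomes (I, VI, III) are aneuploid most often, and `f` correlates
negatively with chromosome size. On the coverage side:

```r
expected_subgenome_coverage(116062916, 100, rep(12e6, 3))
#> expected coverage: 644.8x per haploid copy (2.32e+10 bases / 3.6e+07 bp model genome)

depth <- simulate_depth(map, cfg)
est <- estimate_chromosome_frequency(chromosome_depth_summary(depth, map),
                                     list(expected_per_copy = 100))
tail(est[, c("chrom", "phi_hat", "state")], 3)
#>     chrom     phi_hat         state
#> 14 chrXIV 0.999990935       present
#> 15  chrXV 0.009999780 low_frequency
#> 16 chrXVI 0.004002242 low_frequency
```

A 116M-pair 100 bp library over a ~36 Mb triploid model genome yields
~645x per haploid copy; chromosomes sequenced at ~1% of that are carried by
~1% of cells -- present at low frequency, not absent. `enrichment_matrix()`
and `pairwise_interaction_sums()` + `least_epistasis_network()` complete the
picture from interaction/expression tables, and `run_pipeline()` (or the
`exec/karyoshift` command-line wrapper) orchestrates all stages from a YAML
config into TSV outputs, a markdown report and a `summary.json`.

Recipes for validating against the published external datasets (the
1011-genomes copy-number panel, the hybrid resequencing run) are in
`inst/extdata/external-checks.md`; they need downloads and are not part of
the test suite.

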