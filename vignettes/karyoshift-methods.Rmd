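---
title: "Methods: aneuploidy pattern analysis with karyoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aneuploidy pattern analysis with karyoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoshift)
```

karyoshift studies chromosome copy-number instability in yeast, with two
settings in mind: an interspecific hybrid (e.g. an allotriploid
*S. cerevisiae* x *S. kudriavzevii* wine strain, diploid for one sub-genome
and haploid for the other) whose population is losing chromosomes of the
haploid sub-genome, and a large panel of sequenced strains in which some
chromosomes turn out to be aneuploid far more often than others. The package
chains four statistical components; this vignette states each model, its
assumptions, the tunable parameters, and the numerical choices made where the
design was genuinely open.

## 1. Chromosome population frequency from read depth

When a sequencing library is made from a *population* of cells and only a
fraction $\varphi_c$ of cells carries chromosome $c$, the chromosome's mean
mapped depth is proportional to $\varphi_c$. With a library of $R$ read pairs
of length $L$ over a model genome of total haploid-copy size $G$ (the sum of
one haploid copy of each sub-genome), the expected coverage per haploid copy
is

$$E = \frac{2RL}{G},$$

and the frequency estimate for chromosome $c$ with observed length-weighted
mean depth $\bar d_c$ is $\hat\varphi_c = \bar d_c / E$. The estimator is
exactly linear in depth and, under the Poisson sampling model, unbiased; a
nonparametric bootstrap over depth windows (default 1000 resamples, seeded)
gives a percentile confidence interval without distributional claims.

Assumptions: mapping is unique and unbiased across chromosomes (no GC or
mappability correction is applied), carriers hold the chromosome at the
sub-genome's baseline copy number, and events are whole-chromosome.
$\hat\varphi$ is reported unclipped -- values slightly below 0 or above 1 are
informative about noise -- together with a companion clipped to
$[0, \texttt{max\_copies}]$ (default 4, a generous cap above a triploid's
three copies).

State labels are qualitative in origin, so the thresholds are exposed as
configuration: `lost` below 0.002 (about the level of index hopping and
mismapping noise), `present` above 0.5, `low_frequency` between, and
`no_data` for chromosomes without windows. As a worked magnitude: a
116,062,916-pair, 100 bp library over a ~36 Mb triploid model genome gives
$E \approx 645\times$; a chromosome observed at $5.6\times$ then has
$\hat\varphi \approx 0.0087$ -- carried by roughly 1 cell in 115, clearly
`low_frequency` rather than absent. The model genome size is a required user
input: the coverage arithmetic fixes only the total, not the per-sub-genome
split.

Positions absent from per-base (`samtools depth`-style) input are counted as
depth 0 when windowing, otherwise means on lost chromosomes would be biased
upward; windows are 0-based half-open, and the length-weighted mean is
invariant to re-partitioning the same per-base field.

## 2. Per-chromosome aneuploidy frequency in a strain panel

Within a panel, the *aneuploid strains* are those whose copy number deviates
from their baseline ploidy on at least one chromosome. For chromosome $c$,
counting over aneuploid strains only,

$$f_c = \frac{\#\{\text{strains abnormal at } c\}}
             {\#\{\text{strains normal at } c\}},$$

where "abnormal" ignores the direction of the deviation: a gain and a loss
count identically. $f$ is an abnormal:normal odds, not a proportion -- it
can exceed 1, and it is undefined (flagged, not silently dropped) when every
aneuploid strain is abnormal at $c$. Missing copy-number calls are excluded
from numerator and denominator alike.

The restriction to aneuploid strains and the abnormal/normal denominator are
two descriptions that do not pin each other down, so both alternative
denominators are available behind the `denominator` flag (`"aneuploid"`:
aneuploid strains with a call at $c$; `"all"`: every strain with a call).
The default combines both readings: aneuploid subset, abnormal/normal ratio.

The size association is summarized by the Pearson correlation between
chromosome length and $f$, with the two-sided $p$-value from the $t$
distribution on $n-2$ degrees of freedom. Under the package's
panel-emulating simulation defaults (below) this correlation is strongly
negative, matching the observation that small chromosomes are aneuploid more
often.

Baseline ploidy, when not shipped with the panel file, is inferred per
strain as the mode of its chromosome copies with ties broken toward the
smaller value -- a deliberate bias-to-parsimony for near-balanced karyotypes.

## 3. Bootstrap enrichment of gene features per chromosome

For each chromosome $c$ with $n_c$ genes and each gene-level feature (17 in
the standard catalogue: physical-interaction counts split all/intra/inter,
genetic-interaction counts further split by score sign, protein-complex
membership, and binary up-regulation under four stress conditions), the
question is whether the chromosome's genes are collectively unusual. The
null is built by resampling: draw $n_c$ genes *without replacement* from the
whole genome, record the mean feature value, repeat (default 10,000 times),
and place the chromosome's observed mean on that null as a CDF value --
`pnorm((actual - null_mean) / null_sd)` with the normal method. Values near
0 mean depleted, near 1 enriched.

Design choices worth stating:

* **Feature values are frozen before resampling.** Each gene's
  intra/inter-chromosomal counts are defined with respect to its true
  chromosome; a random gene set does not redefine "intra". This keeps the
  null well-defined and matches the gene-sampling description of the
  procedure.
* **Sum versus mean is immaterial.** The chromosome sum is the mean times
  $n_c$ and every null replicate has the same set size, so the CDF is
  computed on the mean scale and is *identical* replicate-for-replicate
  under either statistic (`statistic = "sum"` only rescales the reported
  magnitudes). This is asserted, not assumed, in the tests.
* **Degenerate nulls.** When the null sd is 0 (constant feature, or set size
  equal to the universe), the CDF is 0.5 at equality and 0/1 by sign
  otherwise.
* **Normal versus empirical.** The default follows the normal-CDF
  convention; an empirical method (proportion of replicate means below the
  observed value, ties at half weight) is retained for skewed count
  features. At large replicate counts the two agree within 0.02 on
  non-pathological features.
* **Seeding.** One seed governs the whole matrix; each (chromosome, feature)
  cell derives a deterministic substream
  (`seed + 100003*i + 101*j mod 2^31-1`), so the full heatmap is
  reproducible and any single cell can be recomputed in isolation.
* **No multiple-testing correction** is applied: the matrix is descriptive,
  a map of which chromosomes look unusual, not a set of significance calls.

The heatmap ordering uses hierarchical clustering with distance
$1 - r$ (Pearson) and average linkage; zero-variance rows or columns have no
defined correlation and are assigned the maximal distance 2 with a warning.
Only the ordering is computed -- values are not re-normalized before
clustering, since the CDF scale is already comparable across features.

Calibration: when feature values are assigned to genes independently of
chromosome, the matrix entries are uniform on $[0,1]$ (checked by a
Kolmogorov-Smirnov test in the suite), and the resampling engine reproduces
the exact hypergeometric distribution on an enumerable toy (universe
$\{0,0,1,1\}$, sets of size 2: means 0, 0.5, 1 with probabilities 1/6, 4/6,
1/6).

## 4. The least-epistasis chromosome network

Genetic-interaction (epistasis) scores are signed; summing them lets
positive interactions compensate negative ones. For chromosomes $i \ne j$,

$$S(i,j) = \sum_{\substack{(a,b)\ \text{retained pairs} \\ a \in i,\ b \in j}} w_{ab},$$

with intra-chromosomal pairs excluded and duplicate unordered gene pairs
mean-collapsed at load time (symmetric and order-independent, so $S$ is
exactly symmetric). Scores are summed unfiltered by default -- no
significance or magnitude threshold -- because the construction is a plain
summation; a filter can be applied upstream when desired.

The directed network draws, for every chromosome $i$, one arrow to
$\arg\min_{j \ne i} |S(i,j)|$: the partner whose net epistatic coupling with
$i$ is nearest to zero, i.e. the chromosome whose copy-number change
perturbs $i$'s interaction balance least. Ties (exactly equal $|S|$) break
toward the lexicographically smallest target id, purely for determinism.
Mutual pairs ($i \to j$ and $j \to i$) are flagged, and hubs are the nodes
of highest in-degree (ordering stable: in-degree descending, then id). The
implementation is verified against a brute-force argmin oracle on random
instances, and is invariant to positive rescaling of all scores but -- by
design -- not to additive shifts, which move different sums toward zero.

## 5. What the synthetic data emulates

All generators are pure functions of their configuration and seed
(Mersenne-Twister, inversion, rejection sampling fixed explicitly), so fixed
seeds give identical fixtures across runs and platforms. The defaults were
chosen once to emulate the study conditions of a large natural-isolate panel
on a budding-yeast karyotype and are not tuned thereafter:

* 16 chromosomes with reference-like lengths (230 kb to 1.53 Mb, ~12.07 Mb
  total) and ~50 genes per 100 kb (~6000 genes), gene counts Poisson in
  length.
* 1011 diploid strains; per-chromosome aneuploidy probability inversely
  proportional to chromosome length with mean 0.015, which yields roughly a
  fifth of strains aneuploid for at least one chromosome -- the order
  observed in panel data -- and a negative size-frequency correlation.
* Gains twice as likely as losses given an aneuploidy (gains are reported to
  be more frequent; the exact odds are not established, so 2:1 is a
  configurable default).
* Interaction pairs uniform over gene pairs at 2 expected pairs per gene;
  scores Normal with per-chromosome-pair planted block means (default 0) and
  sd 0.1, the scale of epsilon epistasis scores.
* Stress up-regulation Bernoulli(0.1) per gene, multiplied by a planted
  enrichment factor (default 3, clipped to probability 1) on designated
  chromosomes; complex membership Bernoulli(0.27), about the fraction of
  yeast genes in curated complexes.
* Depth per window Poisson with mean `lambda * copies * phi * width`
  (default 100x per haploid copy); optional gamma mixing gives a negative
  binomial-like marginal for overdispersed libraries. Poisson is the minimal
  coverage noise model; nothing in the estimators depends on it beyond the
  mean.
* Population frequencies `phi` act on whole chromosomes only; segmental
  events, recombination breakpoints and read-level artefacts (GC bias,
  mappability, duplicates) are deliberately not simulated.

Passing tests on these fixtures therefore demonstrate that the estimators
recover planted whole-chromosome structure under clean sampling noise; they
do not demonstrate robustness to mapping artefacts, segmental aneuploidy, or
reference bias in real libraries, which must be handled upstream.

## 6. Problem sizes, tolerances and degenerate inputs

The test suite and the acceptance script run at reduced but honest sizes,
chosen as the package's own trade-off between statistical resolution and a
fast default run: calibration at a ~2400-gene genome with 2000 bootstrap
replicates per cell (the KS uniformity check pools 16 x 17 entries),
frequency recovery at 1000 windows x 20 seeds per $\varphi$, planted-rank
recovery at 2000 strains, oracle equivalence over 100 random network
instances. Production runs would use the full 10,000 replicates -- the
default -- and whatever panel is at hand.

Numerical edge cases are handled explicitly rather than by accident: empty
chromosomes are flagged rows, a chromosome abnormal in every aneuploid
strain yields an undefined (not infinite) $f$, constant features produce the
0.5/0/1 degenerate CDF, window re-partitioning cannot change coverage means,
and scores are serialized at 17 significant digits so write/load round-trips
are exact. Known limitations: the estimator suite treats chromosomes
independently (no joint karyotype model), the bootstrap ignores gene-gene
correlation within chromosomes (neighbouring genes share complexes and
interactions, so real nulls are slightly wider than the resampled ones), and
the network is a descriptive argmin construction -- it has no associated
uncertainty measure.
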