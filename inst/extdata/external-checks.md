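# Validating against the published external datasets

The test suite runs entirely on synthetic data. The checks below reproduce
the published panel-scale numbers from the original external sources; they
require network access and (for the coverage check) a read mapper, so they
are shipped as a recipe rather than as tests.

## 1. Aneuploidy frequencies from the 1011-genomes panel

Download the chromosome copy-number calls of the 1011 *S. cerevisiae*
genomes panel from <http://1002genomes.u-strasbg.fr/files/> and reshape them
into the package's copy-number TSV dialect: one row per strain, a `ploidy`
column with the strain's overall ploidy, and one column per chromosome
(`chrI` ... `chrXVI`) holding the called copy number. Whole-chromosome calls
only; collapse segmental calls to the chromosome's modal copy first.

```r
library(karyoshift)
cn  <- load_copy_number_matrix("1011_copy_numbers.tsv")
length(detect_aneuploid_strains(cn))        # expected: 217 aneuploid strains
f   <- aneuploidy_frequency(cn)             # denominator = "normal"
# expected per-chromosome f (abnormal/normal within aneuploid strains):
# chrI 0.33, chrIX 0.27, chrIII 0.15, chrVIII 0.14, chrXI 0.13,
# chrVI 0.06, chrIV 0.05 (lowest)
map <- load_genome_map("s288c_map.tsv")     # S288C chromosome lengths
size_frequency_correlation(f, map)          # expected: r = -0.79, P = 0.00028
```

An S288C genome map can be built from the reference chromosome lengths (the
same values as `karyoshift:::YEAST_CHROM_LENGTHS`) plus any gene annotation
(e.g. SGD's `saccharomyces_cerevisiae.gff`).

## 2. Sub-genome chromosome coverages from the hybrid resequencing run

Fetch the Illumina run SRR9925222 (BioProject PRJNA611499) and the
*S. kudriavzevii* IFO1802 reference, map uniquely, and summarize depth:

```sh
fasterq-dump SRR9925222
bowtie2 -x IFO1802 -1 SRR9925222_1.fastq -2 SRR9925222_2.fastq \
  | samtools view -b -q 10 - | samtools sort -o vin7.bam
samtools depth -a vin7.bam > vin7.depth.tsv
```

```r
dp <- load_samtools_depth("vin7.depth.tsv", map_ifo1802, window_size = 1000)
cs <- chromosome_depth_summary(dp, map_ifo1802)
# expected mean depths: chrIII 5.6x, chrVI 10.4x, chrXI 2.5x
ec <- expected_subgenome_coverage(116062916, 100, rep(12e6, 3))  # ~645x
estimate_chromosome_frequency(cs, ec)   # chrIII/VI/XI -> low_frequency
```

## 3. Interaction and expression inputs

* Genetic interactions: pair/score exports from
  <http://thecellmap.org/costanzo2016/>; keep columns query ORF, array ORF
  and the epsilon score as `gene_a`, `gene_b`, `score`.
* Physical interactions: SGD `interaction_data.tab`; keep rows labelled
  `physical interactions`, columns 1 and 3 as `gene_a`, `gene_b`.
* Complexes: the CYC2008 complex table (ORF, complex name) as `gene`,
  `complex`.
* Expression flags: binary up-regulation calls per gene for the glycerol,
  lactate, ethanol and oxidative-stress conditions (SRA SRP074821), coded 1
  for up-regulated and 0 otherwise.

With those four tables, `enrichment_matrix()` at `reps = 10000` and
`pairwise_interaction_sums()` + `least_epistasis_network()` reproduce the
published CDF heatmap and the hub structure of the chromosome network
(principal hubs on chromosomes I and III, connected in both directions).
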