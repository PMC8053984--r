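# vitiSDR

Haplotyping and flower-sex prediction for the grapevine sex-determining
region (SDR).

## The problem

Wild grapevines (*Vitis* spp.) are dioecious: females are f/f at the
~145.5 kb SDR on chromosome 2, males are M/f, with dominance
M > H > f. Cultivated hermaphrodites carry one of two recombinant
haplotypes — H1 (a single crossover) or H2 (a double crossover) — that
are chimeras of M and f. The three crossover sites partition the SDR
into four gene regions A–D: A holds the female-sterility candidate
VviYABBY3, C holds the male-sterility candidate VviINP1 (whose f allele
carries a frameshifting 8 bp deletion), B is the recombination hotspot
with no sex-linked SNPs, and D holds VviAPT3.

Coding each region's genotype as 0/1/2 (homozygous f / heterozygous /
homozygous M) gives a four-digit **numeric genotype**. The ten unordered
diploid combinations of {f, M, H1, H2} have pairwise distinct numeric
genotypes, e.g. f/f = (0,0,0,0), M/f = (1,1,1,1), H1/f = (0,0,1,1),
H1/H2 = (0,1,2,1); region calls therefore identify the haplotype
combination, and flower sex follows from two factors:

- female-sterile ⇔ region A carries ≥ 1 M-derived haplotype (state 1 or 2),
- male-sterile ⇔ region C carries none (state 0),

with male = female-sterile, female = male-sterile, hermaphrodite =
neither.

`vitiSDR` is for geneticists and breeders working with this locus: it
models the haplotype structure, simulates the data types used to
characterise it (genotype panels, allele read depths, bulked-pool window
depths, INP1 spanning reads, allele-specific expression counts), and
implements the analyses that operate on them:

- **sex-linked SNP scan** — cosegregation, minor allele frequency, exact
  Hardy–Weinberg test, composite LD r², boundary detection;
- **bulk-segregant depth delineation** — pooled female/male unique-mapping
  depth per 500 bp window on a two-haplotype assembly (2×/0×/1×/1× SDR
  pattern) normalized to 2-unit flanks;
- **chromosome painting** — per-site 0/1/2 states, per-region modal
  calls, classification into the ten combinations, recombination
  breakpoint detection;
- **Bayes-factor prediction** — per-region comparison of the
  all-homozygous-f / all-heterozygous / all-homozygous-M models on read
  depths (region call requires ln BF ≥ ln 100), for DNA or RNA input,
  plus the VviINP1 8 bp indel marker;
- **ASE association** — permutation test of M-allele expression fraction
  against the flower-sex factors.

The per-site model behind the predictor: with `e` the per-read error,
reads at a site are binomial with alt-read probability `e`, 0.5 or
`1 − e` under genotype 0, 1 or 2; per-region log Bayes factors are sums
of per-site log-likelihood differences (a fully informative site at
depth d contributes ≈ d·ln 1.98 ≈ 0.68·d towards the true model).

## Worked example

```r
library(vitiSDR)
library(SummarizedExperiment)

model <- buildSDRModel()   # 145.5 kb SDR, regions A-D, 1,066 sex-linked sites
panel <- simulatePanel(model, c("f/f" = 2, "M/f" = 2, "H1/f" = 1, "H1/H2" = 1),
                       errorRate = 0.005, missingRate = 0.02, seed = 42)
depths <- simulateAlleleDepths(panel, model, meanDepth = 20, seed = 43)
calls <- predictPanel(depths, model)
as.data.frame(calls)[, c("id", "A", "B", "C", "D", "class", "phenotype")]
#>       id A B C D class     phenotype
#> 1 acc001 0 0 0 0   f/f        female
#> 2 acc002 0 0 0 0   f/f        female
#> 3 acc003 1 1 1 1   M/f          male
#> 4 acc004 1 1 1 1   M/f          male
#> 5 acc005 0 0 1 1  H1/f hermaphrodite
#> 6 acc006 0 1 2 1 H1/H2 hermaphrodite
```

Each row is one accession: columns A–D are the region numeric genotypes
called by the Bayes-factor predictor from ~20× read depths (0.5%
genotyping error and 2% missingness in the underlying panel), `class` is
the haplotype combination they imply, and `phenotype` the flower sex from
the two-factor rule — here all six match the simulation truth.

Bulk-segregant delineation recovers the SDR span from pooled window
depths:

```r
tracks <- simulateBulkDepths(model, unitCoverage = 30, seed = 44)
delineateSDR(tracks)
#> GRanges object with 2 ranges and 1 metadata column:
#>       seqnames          ranges strand |   haplotype
#>          <Rle>       <IRanges>  <Rle> | <character>
#>   [1]     chr2 1000001-1145500      * |       f-hap
#>   [2]     chr2 1000001-1145500      * |       M-hap
```

Both intervals equal the model's true SDR span (chr2:1,000,001–1,145,500).

A command-line predictor for allele-depth TSVs ships in
`inst/scripts/predict_flower_sex.R` (JSON-lines output, `--rna` for
transcriptome input).

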