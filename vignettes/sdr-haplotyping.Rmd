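---
title: "Modelling and genotyping the grapevine sex-determining region"
author: "vitiSDR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and genotyping the grapevine sex-determining region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitiSDR)
library(SummarizedExperiment)
```

## The locus and its model

Wild grapevines are dioecious: females carry two copies of the f haplotype
of the sex-determining region (SDR) on chromosome 2, males carry M/f, with
dominance M > H > f. Cultivated hermaphrodites carry one of two
recombinant H haplotypes: H1, produced by a single crossover, and H2,
produced by a double crossover. The three crossover sites partition the
locus into four gene regions:

* **A** — the female-sterility region (VviYABBY3, VviSKU5); every
  hermaphrodite is f-like here.
* **B** — the recombination hotspot (beta-fructofuranosidase,
  transaldolase); it carries no sex-linked SNPs because the two H
  haplotypes differ here (H1 f-like, H2 M-like), so no site is fixed
  between the f and M classes of chromosomes found in hermaphrodites.
* **C** — the male-sterility region, eleven genes including VviINP1 whose
  f allele carries an 8 bp frameshifting deletion.
* **D** — VviAPT3 alone; M-like in H1, f-like in H2, which is what
  excludes VviAPT3 as the female-sterility gene.

`buildSDRModel()` encodes this geometry. The f-reference span is 145.5 kb;
the default breakpoints put A at 25 kb, B at 20 kb, C at 45 kb and D at
55.5 kb, with the C/D breakpoint exactly 47 kb upstream of VviAPT3. The
transaldolase gene is modelled on the minus strand so that its 5' end
abuts the B/C boundary (the H1 crossover) while its 3' side faces the A/B
boundary (the first H2 crossover), matching the locus narrative. Gene
coordinates are otherwise synthetic: only counts per region, order, strand
of transaldolase and the 47 kb offset are constrained.

```{r}
model <- buildSDRModel()
model
```

Marker sites are placed uniformly at random *within* regions and then
frozen by the model seed, because only their count (1,066 sex-linked
sites) is known, not their positions; the A/C/D allocation is proportional
to region width. Region B receives 30 H-diagnostic markers — sites whose
allele tracks haplotype ancestry — as a desk-scale proxy for the sequence-
similarity evidence that distinguishes H1 from H2 there; real panels would
genotype B by alignment, not by SNPs, and this is the one place where the
simulator is deliberately more convenient than nature.

## The ten diploid classes and the two-factor phenotype rule

Each haplotype has a per-region ancestry signature; summing two signatures
gives the per-region numeric genotype (0 = homozygous f, 1 =
heterozygous, 2 = homozygous M). The ten unordered pairs of {f, M, H1,
H2} give ten pairwise-distinct signatures, so region genotyping inverts
into a haplotype-combination call:

```{r}
classSignatures()
```

Phenotype decomposes into two factors: female-sterile iff region A
carries at least one M-derived haplotype, male-sterile iff region C
carries none. Male = female-sterile only; female = male-sterile only;
hermaphrodite = neither. `phenotypeOf()` implements the dominance rule
M > H > f and the test suite verifies the two formulations agree on all
ten classes. The combination A ∈ {1,2} with C = 0 is produced by no
haplotype pair and is reported as `"inconsistent"` rather than forced
into a class.

## Simulators

The simulators generate every input the analyses consume, under stated
conditions chosen to mirror the study design rather than tuned to any
outcome:

* **Genotype panels** (`simulatePanel()`): template composition plus a
  symmetric error model (a call flips to one of the two other states with
  probability `errorRate`; the direction is not biased because nothing is
  known about the error structure) and uniform missingness. Validation
  panels use 0.5% error and 2% missingness — conservative for modern
  short-read genotyping.
* **Allele depths** (`simulateAlleleDepths()`): total depth is
  Poisson(`meanDepth`) — the simplest count model with the stated mean;
  real shotgun panels ranged roughly 3–50×, and the validation panels use
  the 20× midpoint. Alt reads are binomial with probability `baseError`,
  0.5 or 1−`baseError` by genotype. RNA mode restricts depth to sites
  inside genes, scales it with the expressed allele dose and applies
  per-gene M-allele multipliers (`aseEffectSpec()`): by default the
  VviYABBY3 M copy is expressed only in female-sterile samples, the
  regulatory pattern implicating that gene in female sterility.
* **Bulk pools** (`simulateBulkDepths()`): 13 + 13 accessions pooled, raw
  unique-mapping depth per 500 bp window Poisson around
  `unitCoverage × fold`, where the expected fold is 2/0/1/1 for
  (female,f-hap)/(female,M-hap)/(male,f-hap)/(male,M-hap) inside the SDR
  and 2 on the collapsed flanks; a 1% mismapping background keeps the 0×
  tracks realistic rather than identically zero.
* **INP1 spanning reads** (`simulateInp1Reads()`): reads drawn uniformly
  from the two alleles, 8 bp shorter on a deleted allele, with a 0.5%
  per-read length error.
* **ASE counts** (`simulateAseCounts()`): the RNA depth model applied to
  in-gene sites with per-sample phenotype factors attached.

What the simulators do *not* emulate: linked-read correlation along a
chromosome, mapping bias toward the reference allele, TE-driven
mappability loss, population structure within the sexes, and real
recombination elsewhere in the genome. Passing tests therefore establish
the correctness and calibration of the algorithms under their stated
models, not performance on any particular sequencing run.

## Scans

`cosegregationScan()` flags a site as sex-linked when the fraction of
accessions violating the dioecious expectation (females homozygous
reference, males heterozygous) is at most `maxMismatchFrac` (default
0.02, sized to tolerate realistic genotyping error without admitting
sex-blind sites, whose expected mismatch fraction is ≈ 0.5).
Hermaphroditic accessions must be excluded: their recombinant haplotypes
violate the wild-panel pattern by construction and are interpreted by the
painter instead. `hweExact()` is the exact conditional test (sum of
tables no more probable than the observed one, no mid-p — the plain
two-sided convention); `ldR2()` is the squared dosage correlation
(composite LD, no phasing needed). `sdrBoundaries()` takes the largest
gap-limited run of flagged sites (`maxGapBp` 10 kb, comfortably above
typical inter-site spacing but below the flank distance).

## Bulk-depth delineation

`normalizeTrack()` anchors the flanking median at 2.0 units, so fold
class is directly readable: `classifyFold()` cuts at 0.5 and 1.5, the
midpoints between the expected 0/1/2 levels. `delineateSDR()` looks for
the longest window run matching (female 2×, male 1×) on the f-hap and
(female 0×, male 1×) on the M-hap, after a 5-window majority smoothing
that absorbs isolated Poisson outliers; `minRunWindows = 20` (10 kb)
prevents spurious short runs. At 30 reads per unit per window, boundary
recovery is within two 500 bp windows in ≥95% of seeded replicates, and
exact on noise-free expectations.

## Painting, breakpoints, classification

`paintSites()` re-expresses genotypes as 0/1/2 states relative to the
f-allele. `regionNumeric()` calls each region's modal state, requiring
`minSites = 5` supporting sites and `minConcordance = 0.8` — strict
enough that a region torn by a rare crossover or by clustered errors
degrades to a no-call instead of a wrong call. `classifyGenotype()`
matches against the ten signatures; with one no-call region it accepts a
unique consistent completion, otherwise returns `"unknown"` with
diagnostics. `detectBreakpoints()` places a breakpoint at the midpoint
between flanking informative sites of each state transition (ties floored
toward the lower coordinate); H1 yields one breakpoint, H2 two, and their
union is the three recombination sites that define the A–D partition.

## Bayes-factor genotyping and phenotype prediction

For a region's sites the predictor compares three models — all sites
homozygous f, all heterozygous, all homozygous M — by summed per-site
binomial log-likelihoods (the binomial coefficient cancels). The
two-model comparison (homozygous reference vs heterozygous) suffices for
wild material, but homozygous-M regions (H1/H1, H1/H2 in C) require the
third model, so the package runs a three-way comparison with equal
priors. A region is called only when the best model beats its closest
rival by ln BF ≥ ln 100 (defaults: `baseError` 0.01, `minDepth` 3) —
"decisive" on the conventional evidence scale, yet easily reached by a
handful of sites at 20×, since each fully informative site contributes
about depth × ln 1.98 ≈ 0.68 × depth. For RNA input, sites in genes
subject to allele-specific silencing (the `aseEffectSpec()` genes) are
excluded before summation: the silenced M copy of VviYABBY3 would
otherwise make heterozygous A regions look homozygous-f — which is
invisible for phenotype (A = 0 vs 1 both come from f-like A haplotypes
only in fertile-female material) but wrong for class calls in males.

`inp1IndelGenotype()` genotypes the VviINP1 8 bp indel either from two
resolved allele sequences (motif presence, length difference 8) or from a
spanning-read length histogram (modes may differ by 0 or 8 bp; ±1 bp
sequencing-indel noise is collapsed onto the stronger mode; anything else
is reported ambiguous rather than guessed). Male sterility is implied iff
both alleles are deleted, and the linked C-region Bayes-factor state is
used as a cross-check: a conflict yields no confident call.

## Validation studies and problem sizes

`validateDnaPrediction()`, `validateInp1Marker()` and
`validateRnaPrediction()` re-run the three validation designs end to end
(193 DNA-genotyped accessions, 167 indel-marker accessions, 29 + 19 RNA
samples; `referencePanelDesigns()` fixes the class mixtures, with H1
dominant among cultivated classes and H2/H2 absent, as in nature). Each
driver returns the achieved accuracy; `scripts/acceptance.R` prints them
as percentages. The test suite uses the full 1,066-site model for these
studies and a 120-site model for fast unit tests; the bulk-depth
calibration uses 200 replicates of the 491-window default track set.
These sizes keep the whole suite under a few minutes on one core while
leaving every statistical margin wide.

## ASE association

`aseSiteTest()` tests, per transcribed site, the difference in mean
M-allele read fraction between the two levels of a flower-sex factor, with
a label-permutation p-value under the add-one rule (p = (1 + #extreme) /
(1 + n~perm~)) — chosen over a parametric correlation because the group
sizes are small, fractions are bounded, and depth varies per sample.
Samples below `minDepth = 10` are dropped; a result needs two samples per
group to be flagged valid. `aseScan()` applies Benjamini–Hochberg across
sites for flagging while reporting raw permutation p-values, and
`rankSites()` orders by −log10 p with positional tie-breaks. Under the
default effect specification the top-ranked site falls in VviYABBY3 when
female-sterile samples are contrasted against the rest.

## Numerical and degenerate-input choices

* Monomorphic sites: HWE p = 1; LD r² undefined (`NA`), never 0.
* All-missing sites are errors in `siteMAF()` and skipped by region
  callers; a depth-filtered empty region is a no-call, not an error.
* Probability ties in the HWE tail sum use a 1 + 1e−9 relative tolerance
  so floating-point noise cannot drop the observed table itself.
* Breakpoint midpoints are floored (ties toward the lower coordinate).
* Coordinates are 1-based closed throughout (IRanges/GRanges
  conventions); BED and bedGraph exports are 0-based half-open via
  rtracklayer, VCF is 1-based.
* Every stochastic function takes an explicit seed and is reproducible
  byte for byte.

## Known limitations

Region B calls rest on simulated H-diagnostic markers; on real data that
region must be typed by sequence similarity or targeted markers. The
predictor assumes sites are independent given the region state — true
under the simulator, optimistic under linked sequencing errors. The
painter does not phase: a genuinely novel recombinant that is
heterozygous in a region it "should" not be surfaces only as a no-call or
`"unknown"`. The ASE test conditions on total depth and ignores
overdispersion between biological replicates beyond what permutation
absorbs.
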