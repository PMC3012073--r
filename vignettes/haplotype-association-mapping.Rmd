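---
title: "Haplotype association mapping on inbred strain panels: methods and design"
author: "strainHAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype association mapping on inbred strain panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainHAM)
```

# The problem

A panel of fully inbred laboratory strains is a reusable mapping
population: every animal of a strain is genetically identical, so strain
means estimate genetic values, and the mosaic of ancestral haplotypes that
classical strains inherit lets local haplotype sharing stand in for
genotype at untyped variants.  Haplotype association mapping (HAM) scans
the genome by sliding a short SNP window along each chromosome, grouping
strains by their local allele string, and asking whether group membership
predicts the strain-level phenotype.  strainHAM implements this scan
together with the phenotype summarization that feeds it (exclusion
handling, strain means, broad-sense heritability) and the permutation
machinery that calibrates genome-wide significance.

# Phenotype summarization and heritability

Per-animal trait values arrive as long-form records
(`strain, animal_id, trait, value, excluded, reason`).  Records flagged
for exclusion — in tail-suspension data typically tail-climbing, which
invalidates the immobility measurement for that test only — are removed
by `applyExclusions()`, which logs per-strain counts so survey bookkeeping
(how many animals entered, how many scored) stays auditable.  For
activity-logger input, `percentImmobility()` scores the percentage of
immobile 200 ms bins over the final six minutes of a seven-minute
session; the first minute is excluded because animals are uniformly
active while settling.

Broad-sense heritability is estimated as the adjusted variance explained
by strain in a one-way fixed-effect ANOVA,

$$ R^2_{adj} \;=\; 1 - \frac{SSE/(N-g)}{SST/(N-1)}, $$

with $N$ animal scores over $g$ strains.  Because strain members are
clones, all within-strain variance is environmental and $R^2_{adj}$
estimates $H^2$.  `heritabilityANOVA()` follows the survey procedure of
balancing the design by subsampling a fixed number of scores per strain
(8–16, default 14) and computing the estimate twice on disjoint animals
as an outlier guard: each strain's retained animals are split at random
into two pools and each replicate subsamples from its own pool, so the
two estimates never share an animal even for strains with fewer than
twice the subsample size (such strains simply contribute their whole
pool).  Strains with fewer than 8 retained animals are dropped with a
warning.  The headline value is the mean of the two replicates.

Strain-level trait correlations use the Pearson product-moment
coefficient on strain means with a two-sided $t$ test on $n-2$ degrees of
freedom, matching the convention of strain surveys (the correlation is a
property of the strain panel, not of individual animals).

# The genome scan

`genomeScan()` proceeds window by window:

1. **Windows.** Every run of `windowSize` (default 3) consecutive SNPs
   within a chromosome, stepping one SNP, never spanning chromosome
   boundaries.
2. **Haplotype inference.** Strains are grouped by exact identity of
   their window allele string; a missing call (`N`) excludes the strain
   from that window.
3. **Filter.** A window is scored only if at least `minHaplotypes`
   (default 2) groups have at least `minMembers` (default 5) strains.
   Undersized groups are set aside for that window, not pooled — pooling
   would manufacture artificial haplotypes.
4. **Weighted ANOVA.** The scored statistic is a one-way ANOVA F of the
   (log-transformed) strain means across haplotype groups, weighted to
   reduce the influence of clusters of closely related strains.  With
   weights $w_s$, group means and sums of squares are weighted while the
   degrees of freedom count strains: $F = (SSB/(h-1)) / (SSW/(n-h))$ for
   $h$ groups over $n$ scored strains.  The score is
   $-\log_{10} p$ from the $F(h-1,\,n-h)$ distribution.

**Weights.** The genome-wide similarity of two strains is the fraction of
SNPs (both calls present) at which they agree.  Under the default
`estimate3` scheme, $w_s = 1/\sum_t \mathrm{sim}(s,t)^e$ with integer
exponent $e = 3$, normalized to mean 1.  Cubing sharpens the
down-weighting of near-duplicate strains while leaving unrelated strains
near weight 1.  The scheme sits behind a single interface
(`strainWeights()`), with `uniform` reducing the scan to a textbook
unweighted ANOVA; we do not claim numerical identity with any particular
historical implementation of relatedness weighting, whose exact estimator
was never published.

**Phenotype observations are strain means** — one observation per strain —
matching the strain-level nature of the inference; animal-level ANOVA
inside windows is out of scope.  The default transform is $\log_{10}$
(selectable: natural log, or none for simulated traits on an arbitrary
scale); nonpositive values under a log transform are an error naming the
offending strain.

**Degeneracies.** If the within-group sum of squares is numerically zero
while groups differ, the score is capped at `logPCap` (default 50) and
flagged rather than reported as infinite.  Windows with no within-group
degrees of freedom are left unscored.

# Significance: permutation gFWER

With thousands of overlapping, correlated windows, per-window p values
need a genome-wide calibration.  strainHAM controls the *generalized*
family-wise error rate: the probability of $k$ or more false-positive
windows (default $k = 10$, acknowledging that a handful of spurious
windows among thousands is tolerable while an excess is not).

`calibrateGfwer()` shuffles the strain phenotype vector across strain
labels $B$ times (default 1000), rescans the genome each time, and
records the $k$-th largest $-\log_{10}p$.  Because haplotype groupings,
the filter and the weights do not depend on the phenotype, they are
computed once and shared across permutations.  The raw threshold for
level $\alpha$ is the $\lceil (1-\alpha) B \rceil$-th order statistic of
these $B$ values (upper interpolation — conservative), and the adjusted p
value of a score $s$ is the add-one estimator
$(1 + \#\{b : \text{null}_b \ge s\})/(B+1)$, which is never exactly zero
and is monotone in $s$.  Ties count as exceedances.  If a permutation
scores fewer than $k$ windows its statistic falls back to the smallest
scored value and the calibration flags it.

Windows at or above a chosen threshold are merged into loci by
`mergeLoci()`: windows sharing at least one SNP merge, and the locus
interval runs from the first to the last member SNP (1-based inclusive
internally; BED export converts to 0-based half-open).  `sdpMatch()` then
searches for individual SNPs whose strain distribution pattern — the
bipartition induced by their alleles — equals the carrier pattern driving
a locus, the standard follow-up for nominating candidate variants.

# The synthetic panel generator

`simulatePanel()` and `simulatePhenotypes()` generate data with exactly
the structure the scan assumes, so every stage is testable without
external data:

* **Mosaic blocks.** Each chromosome is tiled into blocks with geometric
  lengths (mean `blockLengthMean`, default 60 kb — about ten SNPs at the
  default spacing), truncated at chromosome ends.  Within a block every
  strain carries one of `nAncestralHaplotypes` (default 4) random binary
  allele strings.  A one-strain minor-allele floor is enforced by
  redrawing patterns of SNPs that come out monomorphic, so windows stay
  informative unless monomorphism is configured deliberately (one
  ancestral haplotype).
* **Clades.** Strains belong to clades (default 5, echoing the handful of
  ancestral lineages behind the classical strains); a clade member reuses
  its clade founder's block assignment with probability `cladeShareProb`
  (default 0.9), producing the excess within-clade genotype identity that
  motivates relatedness weighting.  The clade model is a deliberately
  simple stand-in for real strain genealogy, not a reconstruction of it.
* **SNP density.** Inter-SNP gaps are exponential with mean
  `meanSnpSpacing` (default 6 kb, the density of the SNP maps used for
  this kind of scan, at a desk-scale SNP count).
* **Planted QTLs.** A planted QTL rewrites the three SNPs of its target
  window so carriers share one allele string and non-carriers the
  complementary one; the carrier bipartition is therefore exactly
  recoverable, and the window can pass the 2-groups-of-5 filter whenever
  the carrier set and its complement both have five strains.
* **Phenotypes.** The generator inverts the heritability model: animal
  value = strain genetic value (baseline 30 + strain random effect with
  SD `strainSD`, default 1, + planted effects for carriers) + residual
  noise with variance chosen so the between-strain share of total
  variance equals `targetH2` (default 0.64, the level typical of
  tail-suspension immobility).  The realized components are recorded in
  the truth record.  Animals per strain default to the survey-like range
  8–49; tail-climb exclusion flags are Bernoulli with per-strain
  probabilities (default 0).
* **Determinism.** One master seed; the genotype and phenotype stages
  draw from sub-streams derived deterministically from it, so identical
  configurations give bit-identical panels and tables.

What the generator does *not* emulate: coalescent-realistic linkage
disequilibrium, recombination hot spots, mutation processes, sex
chromosomes, or heterozygosity (inbred strains are fully homozygous by
assumption).  Passing tests on this generator therefore demonstrate the
statistical machinery — filter bookkeeping, F computation, error-rate
control, parameter recovery — not performance on real strain genealogies.

# Numerical and design choices

* Sums of squares use the standard sample conventions ($SST$ on $N-1$
  degrees of freedom), so the heritability estimator is the familiar
  adjusted $R^2$; the implementation is cross-checked in the test suite
  against `lm()` at $10^{-10}$ relative tolerance.
* Two-sided p values throughout.
* The reporting floor ($-\log_{10}p = 2.5$) controls output verbosity
  only; it never affects which windows are scored.
* Window scores are invariant to allele relabeling, strain order, and
  uniform weight rescaling (all property-tested).
* Coordinates are 1-based inclusive internally; BED export is 0-based
  half-open; locus tables display Mb to two decimals while keeping bp
  exact.
* Problem sizes in the test suite are chosen to exercise the statistics
  at survey scale while staying quick: heritability recovery uses 33
  strains × 14 animals over 200 replicates per level; QTL recovery uses
  40 strains × 5000 SNPs over 100 replicates; error-rate control uses
  200 permutations and 200 independent null scans on a 40 × 2000 panel.

# Known limitations

* The relatedness weight estimator is this package's own
  similarity-power scheme; published full-scale thresholds (raw
  $-\log_{10}p$ of 7 and 5.65 for adjusted p of 0.05 and 0.1 on a
  ~140,000-SNP map) are properties of the original data and tool and are
  not reproduced at desk scale.
* A planted effect of +1.5 strain-level SD in 7 of 40 strains sits near
  the edge of detectability against ~5000 correlated windows: the
  planted window is the genome-wide peak in roughly four of five
  replicates, not always.  Reliable top-ranking requires effects around
  2.5 SD — consistent with the large separations that real mapped loci
  show.
* Strain-level correlations and heritabilities of the published survey
  can be recomputed only from its deposited per-strain tables, which are
  not redistributable with the package (see
  `inst/extdata/deposited/README`).

# A worked example

```{r example, eval = FALSE}
cfg <- SimConfig(nStrains = 40, cladeSizes = rep(8, 5), nChromosomes = 1,
                 snpsPerChromosome = 500,
                 qtlSpecs = list(list(chromosome = 1, windowIndex = 200,
                                      carrierStrains = c(1, 9, 17, 25, 33,
                                                         34, 2),
                                      effectSize = 1.5)),
                 targetH2 = 0.6, seed = 42)
sim <- simulatePanel(cfg)
ph  <- simulatePhenotypes(sim$panel, sim$truth, cfg)
mv  <- strainMeans(applyExclusions(ph$phenotypes), "TST")
prm <- ScanParams(logTransform = "none")
scan <- genomeScan(sim$panel, mv, prm)
cal  <- calibrateGfwer(sim$panel, mv, prm,
                       GfwerParams(B = 100, k = 10, seed = 7))
loci <- mergeLoci(scan, gfwerThresholds(cal)[["0.05"]], cal, prm)
sdpMatch(sim$panel, sim$truth@plantedQtls[[1]]$carrierStrains)
```

On this seed the planted window is the scan peak ($-\log_{10}p = 4.51$,
adjusted p = 0.0099), merges into a single locus, and the SDP matcher
returns exactly the three planted SNPs.
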