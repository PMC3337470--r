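---
title: "Simulating sequence, SNP and phenotype data by coalescent plus gene drop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sequence, SNP and phenotype data by coalescent plus gene drop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaldrop)
```

## The simulation model

`coaldrop` builds benchmark data sets for genomic selection and GWAS
method development in two stages.

**Backward stage (coalescent).** For each chromosome, a sample of
haplotypes is drawn from a neutral coalescent with recombination under a
piecewise-linear effective-population-size history $N_e(t)$.  The
genealogy at the left chromosome end is simulated exactly: with $k$
lineages the coalescence hazard at time $t$ is
$\binom{k}{2} / (2 N_e(t))$, and waiting times are obtained by inverting
the integrated hazard in closed form on each linear segment of the
trajectory (for a segment with slope $m$,
$\int dt / N_e = \log(N_e(t_1)/N_e(t_0)) / m$).  The simulator then
walks left to right in the sequentially Markovian approximation (SMC′):
the distance to the next recombination breakpoint is exponential with
rate (total branch length × per-bp recombination rate); at a breakpoint
a recombination point is chosen uniformly on the tree, the lineage below
it is detached and re-coalesces with the old tree at hazard
$k(t) / (2 N_e(t))$, where $k(t)$ counts old-tree branches crossing
time $t$.  Re-coalescence onto the detached branch itself leaves the
tree unchanged (the "invisible event" that distinguishes SMC′ from
SMC; the plain-SMC variant is available via `smc_prime = FALSE` for
comparison).  Mutations fall on each marginal tree at rate $\mu$ per
site per generation over the non-recombining segment, each creating one
segregating site at a uniform integer coordinate with the derived allele
coded 1.  The full ancestral recombination graph is never materialised;
memory is linear in the sample size.

**Forward stage (gene drop).** A pedigree is generated (or read) with
discrete generations; generation 0 is the base layer and stands at the
most recent generation of the ancestral population.  Each base gamete is
a mosaic of the coalescent haplotypes: crossovers are Poisson along the
genetic map and each inter-crossover segment is copied from an
independently, uniformly (with replacement) chosen panel haplotype.
Later generations receive gametes by Mendelian inheritance: per meiosis,
crossover count $\sim$ Poisson(rate × map length) with no interference
(Haldane model), positions uniform in cM, mapped to site indices through
the uniform cM–bp map.  No mutation occurs during the drop, so alleles
can only fix or be lost after the base generation.

**Markers, QTL and traits.** SNP chips are uniform samples without
replacement of segregating sites at configured densities, allocated
across chromosomes by largest-remainder rounding.  Two candidate-QTL
sets of equal size are drawn: one unrestricted, one restricted to sites
whose base-generation minor allele frequency does not exceed a threshold
(inclusive rule, MAF ≤ threshold; the restriction lets QTL be rarer than
chip SNP).  Four additive traits are built in a fixed order —
`PolyUnres`, `GammaUnres`, `PolyRes`, `GammaRes`: the `Poly` traits give
every candidate locus a N(0, 1) allele-substitution effect; the `Gamma`
traits give a random subset (default 900 of 9000) an effect with
magnitude $\sim$ Gamma(shape, scale) and a fair sign flip.  Breeding
values are $a_i = \sum_j x_{ij} \beta_j$ with $x$ the derived-allele
dosage.  The residual standard deviation is set once per trait against
the base generation, $\sigma_e = \sqrt{\sigma_a^2 (1 - h^2) / h^2}$
with $\sigma_a^2 = \mathbf{a}'\mathbf{a}/(n-1)$ over base-generation
breeding values, so the configured heritability
$\sigma_a^2 / (\sigma_a^2 + \sigma_e^2) = h^2$ holds exactly;
phenotypes are $y_i = a_i + e_i$, $e_i \sim N(0, \sigma_e^2)$ with the
same $\sigma_e$ for every generation.

## Default scenario and its parameters

The shipped specification (`livestock_scenario.spec`) encodes a
ten-replicate livestock structure:

| parameter | value | meaning |
|---|---|---|
| chromosomes | 30 × 100 cM / $10^8$ bp | whole cattle-like genome |
| mutation rate | $2.5 \times 10^{-8}$ /site/generation | sequence mutation |
| $N_e$ anchors | 100 (now), 1256 (1k), 4350 (10k), 43,500 (100k) | Holstein-like decline, linear between anchors, constant beyond |
| base haplotypes | 4000 | coalescent sample per chromosome |
| pedigree | 10 generations × (50 sires × 10 dams × 2 offspring) | 1000/generation, 10,000 total, random mating |
| crossover rate | 0.01 /cM | 1 event per 100 cM per meiosis |
| chips | 60,000 and 300,000 SNP | independent uniform samples |
| candidate QTL | 9000 (+ 9000 with MAF ≤ 0.30) | trait loci pools |
| gamma effects | shape 0.4, scale 1.66, subset 900 | few loci, leptokurtic effects |
| heritability | 0.25 | all four traits |
| split | train = generations 4–5 (2000); validate = 500 each from 6, 8, 10 | by pedigree generation |

With these settings the expected genome-wide segregating-site count is
on the order of $1.5$–$1.7$ million (the quantity checked by the
acceptance suite on a scaled-down genome).

## Design choices where the design was open

* **Years vs generations.** The demography anchors are calendar-year
  estimates; no generation interval is stated for the scenario, so
  times are used directly as generations (`generation_interval = 1`).
  A cross-check against an independent coalescent simulator (piecewise-
  constant staircase) under this reading reproduces the target
  segregating-site count within the acceptance tolerance.  The
  `generation_interval` key rescales the anchors for users who prefer a
  cattle-like interval.
* **Generation labels.** Generations are 0-based with the base layer as
  generation 0; the scenario's 1-based "generations 4 and 5 / 6, 8, 10"
  become 3–4 and 5, 7, 9 in the shipped spec file.  All audited sizes
  (2000 training, 3 × 500 validation, 10,000 individuals) are
  unaffected.
* **Centering in the heritability scaling.** Breeding values are
  defined as deviations from the population mean, so
  $\mathbf{a}'\mathbf{a}/(n-1)$ is evaluated on base-generation
  mean-deviated breeding values — for which it *is* the sample
  variance.  Applying the formula to raw dosage-coded scores would add
  the squared mean $\big(\sum_j 2 p_j \beta_j\big)^2$, which for 9000
  neutral-spectrum loci is on average about twice the genetic variance;
  $\sigma_e$ would then be inflated ~2-fold and the realized base
  heritability would land near 0.1 instead of 0.25, with large
  seed-to-seed spread.  The uncentered variant remains available
  (`base_genetic_variance(..., centered = FALSE)`,
  `build_four_traits(center_bv_for_scaling = FALSE)`) and both variances
  are written to `trait_scaling.txt` so the convention stays visible.
* **Mating design.** The scenario states family sizes but not how dams
  are allocated: parents are drawn without replacement from the previous
  generation, mated in disjoint full-sib families, with no selection and
  no overlapping generations (external pedigree files cover other
  designs).  Offspring sexes are Bernoulli(0.5), redrawn if a generation
  cannot supply the next one's parents (negligible except in toy
  configurations).
* **Base-gamete sampling.** "Randomly sampled from the 4000 haplotypes"
  is read as sampling segments with replacement across gametes; nothing
  in the scenario pins down a without-replacement scheme.
* **MAF rule and reference population.** The restriction is inclusive
  (MAF ≤ 0.30) and evaluated in the base generation of the pedigree —
  the cohort the variance scaling sees — not in the coalescent panel;
  sites fixed during base-gamete sampling are excluded from the
  restricted pool (a fixed "QTL" would carry no variance).
* **Chip nesting.** The two chips are sampled independently by default
  (`nested = yes` makes lower-density chips subsets of the densest).
* **Breakpoint semantics.** The packed-storage layer uses 0-based,
  half-open site-index breakpoints (a breakpoint at `k` means sites
  `>= k` switch source); gene drop converts cM positions to site indices
  and cancels crossover pairs that land in the same inter-site gap.

## Numerical and degenerate-input behaviour

* Waiting-time draws are exact inversions of the piecewise closed-form
  integrated hazard — no time discretisation anywhere.
* Mutation coordinates are integers; collisions are redrawn (an
  effectively infinite-sites model on a finite grid), and a segment
  whose grid saturates simply drops the excess mutations.
* `mutation_rate = 0` gives an empty panel; `validation_size` equal to a
  generation's size returns the whole generation; a 1×1×1 pedigree is a
  single base individual.
* All randomness flows from one master seed through fixed per-stage
  derived seeds, so a rerun with the same spec and seed is
  byte-identical, and any stage can be regenerated in isolation.

## What the synthetic data does and does not emulate

The generator reproduces the *structure* the scenario stipulates:
realistic mutation/recombination rates, a declining-$N_e$ history, a
livestock pedigree shape, chip densities, QTL-effect distributions and
heritability.  It deliberately does not model gene conversion,
crossover interference, variable recombination or mutation maps,
selection or assortative mating, overlapping generations, sex
chromosomes, dominance/epistasis, genotyping error or chip
ascertainment bias.  A green test therefore certifies agreement with
the neutral-additive stated world, not with any particular real cattle
data set.

## Known limitations

* The SMC′ approximation slightly underestimates long-range linkage
  disequilibrium relative to the full ancestral recombination graph
  (the acceptance suite checks distributional agreement with a
  brute-force ARG at small sample sizes).
* The scenario-scale segregating-site count has a heavy-tailed
  replicate distribution (rare deep genealogies dominate), so
  scaled-down estimates carry Monte-Carlo error of order 10% at 10
  replicates.
* Runs at the full $30 \times 10^8$ bp scale are possible in principle
  but sized for cluster, not desk, hardware; `scale_spec()` (or the CLI
  `--scale` flag) shrinks physical lengths, genetic lengths (preserving
  the uniform 1 cM/Mb map and hence the per-bp recombination rate) and
  chip densities proportionally while preserving the pedigree and trait
  audit quantities.
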