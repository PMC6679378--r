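---
title: "Methods: eQTL mapping in a two-strain F2 intercross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping in a two-strain F2 intercross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlcross)
```

# Scope

`eqtlcross` maps expression quantitative trait loci (eQTLs) in an F2
intercross between two inbred strains — the design in which reciprocal
crosses between, say, a diabetic GK rat and a Brown Norway (BN) control
produce F2 animals whose genomes are mosaics of the two parental
haplotypes. Because real genotype data for such crosses are rarely
redistributable, the package treats its synthetic-data generator as a
first-class, tested component: every downstream stage is validated
against simulations whose true architecture is known exactly.

Throughout, the GK-like strain contributes the "B" allele: genotypes are
AA (BN/BN), AB, and BB (GK/GK), and all allelic-effect signs refer to
the GK allele.

# The generative and analysis model

For one transcript, expression in individual $i$ is modelled as

$$
y_i = m + b_c c_i + b_s s_i + b_g g_i + b_d h_i
      + g_s\, s_i g_i + g_c\, c_i g_i + e_i ,
\qquad e_i \sim N(0, \sigma^2),
$$

with $c_i \in \{0,1\}$ the reciprocal cross direction, $s_i \in \{0,1\}$
sex (1 = female), $g_i \in \{-1,0,1\}$ the signed GK-allele dosage at the
transcript's eQTL locus and $h_i$ the heterozygote indicator. The
simulator draws from exactly this model; the scan fits it by Haley–Knott
regression, replacing $(g_i, h_i)$ with their conditional expectations
$a_i = P(BB) - P(AA)$ and $h_i = P(AB)$ given the observed markers.

**Assumptions.** Residuals are Gaussian and homoscedastic on the scale
being scanned (hence log2 intensities after normalization); meiosis has
no crossover interference (Haldane map function), matching the Markov
chain used for genotype probabilities; autosomes only — the X chromosome
needs a dedicated HMM and is out of scope.

# Synthetic data

`sim_map()` places markers at fixed spacing with physical positions a
fixed Mb-per-cM multiple (default 2 Mb/cM, roughly the rat genome-wide
average). The deterministic cM–Mb relation is a deliberate
simplification: it makes the cis/trans geometry of every simulated gene
exactly known, so window-based classifications can be asserted, at the
cost of not emulating regional recombination-rate variation.

`sim_f2_cross()` builds each F2 genome as two independent gametes, each
a Markov walk along the chromosome with switch probability
$r = (1 - e^{-2d/100})/2$ between adjacent markers. Sex and cross labels
are assigned deterministically so the four sex-by-direction strata are as
balanced as integer counts allow. Random streams are split per
chromosome and per gene from the master seed, so regenerating a subset of
the data reproduces the original values.

Per-gene effect loci are snapped to the nearest map marker (a position on
an unknown chromosome or beyond the chromosome end is an error); the
truth table records the snapped position, which is what recovery tests
compare against.

The raw-intensity generator (`sim_raw_intensities()`) produces
`Normal(bg_mean, bg_sd) + Exponential(mean = signal_scale * 2^expr)`
draws plus detection scores computed against a per-array pool of
background-only draws, emulating negative-control beads. The probe
artifact generator (`inject_probe_artifacts()`) multiplies a probe's
linear-scale intensity by `attenuation` per GK allele at the probe's own
locus — the mechanism by which strain polymorphisms inside a probe's
target sequence create spurious cis-eQTLs, and the reason such probes
are excluded before mapping.

**What the simulator does not emulate:** bead-level array structure,
spatial artifacts, batch effects, heavy-tailed or heteroscedastic
expression noise, segregation distortion, genotyping errors beyond the
missing-at-random option, and correlated expression between genes.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every feature of
real array data.

# Genotype probabilities

`calc_genoprob()` runs a vectorized forward–backward pass over the
three-state genotype chain per chromosome. The grid is the union of
typed markers and pseudomarkers inserted so adjacent loci are at most
`step_cM` apart (default 2.5 cM, mirroring framework-marker maps
expanded to ~2.5 cM resolution); this "markers plus pseudomarkers"
choice, rather than a uniform grid, keeps typed markers exactly
representable so probabilities there are degenerate when the error rate
is zero. Emissions use a single global genotyping error rate
(default 0.002): $P(\text{obs}\mid\text{true})$ is $1-\varepsilon$ on a
match and $\varepsilon/2$ otherwise; missing observations emit
uniformly. The chain prior is the F2 segregation prior (¼, ½, ¼), which
is also the answer at fully untyped individuals and chromosome ends.
Rows are rescaled at every step to avoid underflow, and a row of
likelihood zero (only possible with $\varepsilon = 0$ and contradictory
flanking data) falls back to the uniform distribution. Correctness is
tested against exhaustive $3^L$ hidden-path enumeration.

# The scan engine

At each grid locus the design matrix is intercept + covariates +
$(a, h)$, plus $(s\,a, s\,h)$ or $(c\,a, c\,h)$ for interactive scans.
Each design is reduced once to an orthonormal basis $Q$ by QR (rank
deficiency, e.g. a monomorphic locus, silently drops redundant columns),
and for any phenotype matrix $Y$,
$\mathrm{RSS} = y'y - \lVert Q'y\rVert^2$. Stacking all per-locus bases
into one matrix turns a genome scan over a thousand permuted phenotypes
into a single BLAS product, which is what makes per-transcript
permutation testing affordable: a full 205-locus scan with 1000
permutations costs well under 0.1 s.

Numerical choices: LOD values are clamped to $[0, 300]$ (300 is the cap
reported for numerically perfect fits); an RSS that rounds to zero in
both models (constant phenotype) yields LOD 0; nested-model LODf is
clamped at 0. Peaks break ties toward the lowest chromosome, then the
lowest cM. Missing phenotype values drop the individual for that
transcript only, at the cost of re-deriving the per-locus bases for that
transcript.

# Significance

**Per-transcript permutation.** Phenotypes are permuted within the four
sex × cross-direction cells, keeping genotypes and covariates fixed, and
the genome-wide maximum LOD is recorded per permutation;
$p_\mathrm{adj} = (1 + \#\{\max_\pi \ge \max_\mathrm{obs}\})/(n_\mathrm{perm}+1)$.
Stratification is a design choice (the procedure description leaves it
open): it preserves the covariate structure so the permutation null
respects the additive-covariate model. The default 1000 permutations
give a p-value floor of 1/1001.

**Interaction scans.** The LODf null is generated by fixing the additive
fit at the additive-scan peak locus, permuting its residuals within
strata, adding them back to the fitted values, and rescanning LODf. This
preserves the genotype main effect under the null of no interaction;
fitting H\_add at the additive peak (rather than at every locus) is the
pragmatic choice, since the null must hold genome-wide for a single
permuted phenotype.

**Two-stage rule.** The literature convention states both a
"genome-scan adjusted P < 0.05" and an "FDR < 0.05" criterion without
the linking rule; here the reconciliation is explicit and configurable:
BH is applied across transcripts to the permutation-adjusted p-values,
and a transcript is declared at $q < 0.05$. Secondary (polygenic) eQTLs
are then reported on any other chromosome whose maximum LOD exceeds the
transcript's own 95% permutation threshold — within-chromosome secondary
peaks are not separable at F2 linkage-disequilibrium resolution and are
not reported.

The scan defaults to additive + dominance genotype terms (2 df), since
an F2 carries heterozygotes and the dominance deviation is estimable;
`dominance = FALSE` gives the 1-df additive-only scan.

# Architecture, conservation, enrichment

Declared eQTLs are classified by the distance between the peak's
interpolated Mb position and the gene's annotated position: different
chromosome → `trans`; within 5 Mb → `cis_5Mb`; within 10 Mb →
`cis_10Mb`; otherwise `same_chrom_distant`. Hotspots are 5 cM bins whose
count of non-local eQTLs (`trans` + `same_chrom_distant`) exceeds the
$1-\alpha/\#\text{bins}$ Poisson quantile at the genome-average rate —
a homogeneous-null with Bonferroni correction, chosen for strict
family-wise control because no published threshold exists for this
statistic; the detector's family-wise false-positive rate is verified
by simulation.

Cross-tissue conservation requires peaks within 15 cM on the same
chromosome *and* the same allelic-effect sign; cross-population
(F2 vs recombinant-inbred) conservation uses a 10 Mb physical window and
reports, rather than requires, direction agreement. Overlap enrichment
is the one-sided Fisher (hypergeometric upper-tail) test; the default
background universe is the set of transcripts scanned in both tables,
the most defensible choice where the original analyses leave the
universe unstated. Pathway enrichment is the hypergeometric upper tail
against the detected-expression background, with gene-level
deduplication before testing and BH correction over sets.

# Tunable parameters

| Parameter | Default | Units | Where |
|---|---|---|---|
| grid step | 2.5 | cM | `calc_genoprob(step_cM=)` |
| genotyping error rate | 0.002 | — | `calc_genoprob(error_rate=)` |
| permutations | 1000 | — | `scan_transcripts(n_perm=)` |
| transcript FDR | 0.05 | — | `declare_eqtls(fdr=)` |
| LOD cap | 300 | LOD | `scan_transcripts(cap=)` |
| cis windows | 5 / 10 | Mb | `classify_eqtls()` |
| hotspot bin / alpha | 5 / 0.001 | cM / — | `detect_hotspots()` |
| tissue window | 15 | cM | `conserved_crosstissue()` |
| cross-model window | 10 | Mb | `conserved_crossmodel()` |
| detection filter | 0.5 / 0.5 | score / fraction | `detection_filter()` |

The standard simulated study design used throughout the test suite is
123 individuals (balanced sexes and reciprocal directions) on five
100 cM chromosomes with markers every 10 cM — a desk-scale version of a
~20-chromosome cross that keeps the genome-wide multiplicity structure
(205 grid loci) while making thousands of full permutation scans cheap.
Null genes carry sex and cross main effects (0.5 and 0.25 residual sd)
so that calibration is tested in the presence of real covariate
structure, not in a vacuum.

# Known limitations

- Single-QTL model per scan: no multiple-QTL fitting, epistasis, or
  mixed-model relatedness correction.
- Autosomes only.
- The cM–Mb relation is linear by construction in simulations; with real
  annotation tables the interpolated peak Mb inherits whatever
  nonlinearity the map encodes, but the simulator cannot test that path.
- Conservation analyses compare records by gene identifier; orthology
  mapping across species or platforms is the user's responsibility.
- The hotspot null assumes exchangeable bins; strong variation in gene
  density or marker informativeness across the genome would call for a
  locally calibrated null.
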