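---
title: "Quantifying niche, morphological and genetic divergence with divaxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying niche, morphological and genetic divergence with divaxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divaxes)
```

## The problem

When a species comprises two phenotypically distinct groups of populations
in adjoining ranges — say two bird subspecies split across a climatic
transition — the question is where along the divergence continuum they sit.
divaxes addresses this with three coupled analyses: does the climatic niche
of the two groups differ more than random relabelling of their occurrence
sites would produce; does morphology track the climate gradient, and
linearly or only at its extremes; and how is sequence variation partitioned
within and between the groups. Each analysis is a small, well-defined
statistical procedure, and each is exercised end-to-end on synthetic data
whose generating process matches the assumptions of the method, so the
whole pipeline is testable without external data.

## Climatic niche divergence

Occurrence-site climate tables mix units (°C, mm), so the PCA runs on the
correlation matrix: every variable is centered and scaled before rotation.
Covariance-matrix PCA would let precipitation magnitudes dominate, and
standardized loadings are also the scale on which published loadings of
bioclimatic PCAs are usually reported. Eigenvector signs are arbitrary, so
each loading vector is flipped to make its largest-magnitude element
positive; published signed *Di* values may therefore differ from ours by a
per-axis sign, which affects nothing downstream because the default test is
two-sided.

The divergence statistic on axis *k* is the difference of group means of
the site scores, `Di = mean(A) − mean(B)`. The null distribution reshuffles
group labels over the pooled sites without replacement, preserving group
sizes — a permutation scheme, not a bootstrap. Two tail policies are
offered. The literal one-sided count `#(Di_null ≥ Di_obs)/n` has the defect
that any negative observed *Di* yields p near 1 even under extreme
divergence; since divergence on an axis is a two-sided question, the
default counts `|Di_null| ≥ |Di_obs|`. The plain count/n ratio is the
default estimator (so a value farther out than every permutation prints
p = 0); the (count+1)/(n+1) correction, which cannot return 0, is a flag.
An `exhaustive = TRUE` mode enumerates all `choose(n, nA)` allocations for
small site sets and is used in the tests as its own oracle.

The multivariate confirmation is a Wilks' Λ MANOVA on the leading axes:
`Λ = det(E)/det(E + H)` from the within- and between-group cross-product
matrices, with Rao's F approximation (exact for two groups, where it
reduces to Hotelling's T²; for one response axis it reduces to the one-way
ANOVA F — both reductions are tested).

## Morphology and climate

Traits (mass in g, wing and tarsus in mm) are log10-transformed before
modelling; the structural-size index is the pooled OLS residual of
log-wing on log-tarsus, which is orthogonal to log-tarsus by construction.
The factorial ANOVA (geography × sex) defaults to Type II sums of squares:
the design is unbalanced, main effects are the quantities of interest and
the interaction is expected to be negligible, which is the setting Type II
serves; Type I and Type III remain available because the choice is
genuinely open and published F values rarely state it. The group-level
contrast can be run with geography set to the group factor, with sex kept
in the model or not — both variants are one call apart, because collapsing
the two silently would mismatch someone else's model without notice.

The climate–morphology suite fits four OLS models per trait — PC1,
PC1+PC1², PC2, PC2+PC2² with site scores broadcast to the individuals of
each site — and ranks them by AICc in the least-squares form
`n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)`, where k counts the intercept, the
slope(s) and the residual variance: 3 for the linear and 4 for the
quadratic models. Akaike weights are `exp(−Δ/2)`, normalized. Adding the
quadratic term can never increase RSS, but the AICc penalty can still
prefer the linear model; the tests exercise both directions.

## Sequence statistics

A `LocusAlignment` holds equal-length sequences plus an analyzed-site mask.
The default site policy is complete deletion — any column containing `-`
or `N` is excluded everywhere — matching the common practice of removing
indel regions before computing diversity statistics; pairwise deletion is
available and only affects the pairwise quantities. All statistics are
invariant to sequence input order, and the frequency-spectrum
implementations of S and π are property-tested against an O(n²L)
brute-force oracle.

Watterson's θ per site is `S/(a1·L)`; its SE uses the neutral sampling
variance `Var(S) = a1·θ_L + a2·θ_L²` with the locus-scale estimate plugged
in, divided by `(a1·L)²`. Published per-locus SEs vary with the exact
variance variant implemented, so comparisons to other software should allow
for that. Tajima's D uses the 1989 constants and is reported as an explicit
`NA` when S = 0 rather than 0 — an undefined statistic should not look like
a neutral one.

Hudson's Kst is `1 − Ks/Kt` with the size-weighted `Ks = Σ n_j/n · K_j`
(the `(n_j−1)`-based weighting is a flag; the literature defines several
variants and the choice is documented rather than hidden). Significance
permutes sequence-to-population labels; p is `(count+1)/(n+1)`.

The AMOVA uses pairwise difference counts as squared distances, partitions
the sums of squared deviations into among-group / among-population /
within-population strata, and solves the expected mean squares with
unequal-sample-size coefficients. Negative variance components are reported
as estimated, with a warning, because clamping would silently distort the
percentages. The three F-statistics get three permutation schemes: whole
populations among groups (F_CT), sequences among populations within groups
(F_SC), sequences among all populations (F_ST). The F_CT scheme permutes
population labels, a much smaller space than sequence labels: with 5+5
populations there are only 126 distinct allocations, so the permutation
p-value has a floor near 1/126 from exact re-draws of the true split.
Resolving p-values near 0.01 therefore needs more permutations at that
level than the sequence-level schemes do, which is why `amova()` lets the
caller run a single scheme at a higher permutation count.

Amino-acid profiles translate protein-coding mtDNA under the vertebrate
mitochondrial genetic code, list codon positions at which more than one
amino acid segregates, and count positions whose amino-acid sets are
disjoint between the two groups (diagnostic positions). Internal stop
codons warn rather than fail: mitochondrial reading frames and incomplete
stop codons are messy in real data.

## The synthetic-data generators

**Climate.** Sites are drawn from a latent-factor model: `nVars`
(default 19, the bioclim set size) observed variables are fixed linear
combinations of a few standard-normal latent factors plus independent
noise, and the second group's latent means are offset by a shift vector.
This produces the collinearity that motivates a PCA reduction while keeping
the truth known: the population correlation matrix is
`cov2cor(L·Lᵀ + σ²I)`, whose eigenvalues the sample variance fractions must
approach — that is the test oracle. What it does not emulate: spatial
autocorrelation between nearby sites, non-Gaussian climate marginals, and
distribution-edge truncation; a real niche analysis inherits those, so a
passing calibration here shows correctness of the test under
exchangeability, not robustness to spatial structure.

**Morphology.** Individuals are drawn per site (at least 3 per site,
matching the minimum site size used in site-level analyses) with sex
assigned at a fixed ratio (default 52/81 male, a realistic field ratio for
mist-netted samples); each log10 trait is intercept + sex effect + linear
and quadratic terms in the site's climate-axis value + Gaussian noise, then
back-transformed. Defaults describe a ~31 g, 80 mm-wing, 27 mm-tarsus
passerine with mild male-biased dimorphism (0.01–0.03 log10 units) and
residual SDs of 0.012–0.025 log10 units, i.e. coefficients of variation of
3–6%.

**Sequences.** The isolation-with-migration simulator runs a structured
coalescent for two demes that exchange migrants backwards in time until the
split time, then coalesce in one ancestral deme whose relative size is a
parameter (default 1 — equal to the daughters — because the generative
model needs a value and equality is the neutral choice). Time is in
ms-style coalescent units: a deme of relative size x coalesces each lineage
pair at rate 1/x, each lineage migrates at rate M/2 with `M = 4N·m`, and
mutations fall as Poisson(θ/2 × total branch length), giving the standard
single-deme expectation E[S] = θ·a1 that the calibration tests check.
Conversion to years happens in exactly one place
(`convertDivergenceTime`), avoiding the 2N/4N ambiguity. Mutations follow
the infinite-sites model, mapped to distinct positions of the finite
alignment; if more mutations arise than sites exist the simulator raises an
error instead of silently collapsing to finite sites, so S always equals
the mutation count. The inheritance scalar (1 autosomal, 0.75 Z, 0.25
mtDNA) scales deme sizes, so within-deme diversity behaves as h·θ and the
effective population-scaled migration as h·M — the scalar acts through the
genealogy, as it does in nature, rather than through the mutation process.
The multilocus generator applies the phased-diploid ploidy convention: two
sequences per individual per autosomal locus, one for mtDNA, two for
Z-linked loci in males (ZZ) and one in females (ZW). Recombination within
loci, selection and spatial structure beyond two demes are out of scope.

## Numerical choices and degenerate inputs

* Permutation p-values: Di defaults to count/n (so 0 is reachable), Kst
  and AMOVA to (count+1)/(n+1); both conventions are stated in the
  respective results.
* PCA refuses constant columns by name and axis requests beyond the data
  rank; reconstruction of the standardized data from scores × loadingsᵀ is
  tested to 1e−8.
* AICc refuses RSS = 0 (degenerate criterion) and n ≤ k+1 (undefined
  correction).
* Tajima's D is `NA` at S = 0; Kst is `NA` at Kt = 0; AMOVA refuses
  all-identical sequences and single-group partitions, and F_SC is `NA`
  when each group holds a single population (F_ST then equals F_CT, which
  is tested).
* All stochastic functions accept a seed, record it in their result, and
  restore the caller's RNG state; pipeline reports are byte-identical
  under identical configs.

## Calibration problem sizes

The shipped calibration (tests and `scripts/acceptance.R`) uses 2000
single-deme replicates (n = 10, θ = 5) for E[S] = θ·a1 within 5%; 1000
replicates (n = 20, θ = 5) for mean Tajima's D within ±0.15 of 0; 500
exchangeable null climate datasets (14 + 14 sites, 999 permutations each)
for the Di type-I error at α = 0.05 within the exact binomial 99% interval;
and 100 deep-split replicates (θ = 5, split time 10, no migration,
10 + 10 samples) for recovery of Kst > 0.5 and F_CT > 0.5 at p ≤ 0.01 in at
least 95% of replicates, with 9999 population-level permutations for F_CT
for the resolution reason given above. These sizes keep every Monte-Carlo
standard error several times smaller than the corresponding tolerance.

## Known limitations

The niche test assumes site exchangeability under the null; spatially
autocorrelated occurrences violate this and make the test anti-conservative
— on real data, thinning or block permutations would be needed. The AMOVA
p-value floor at the population-permutation level is a property of the
method, not the implementation. Inference of IM parameters (migration
rates, divergence-time posteriors) is out of scope: the IM model here is
generative only. The amino-acid profiler assumes the supplied frame and
code; it does not scan frames.
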