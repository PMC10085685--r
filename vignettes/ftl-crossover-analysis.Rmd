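---
title: "Measuring meiotic crossover frequency with fluorescent-tagged lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meiotic crossover frequency with fluorescent-tagged lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftlmap)
```

## The measurement model

A fluorescent tagged line (FTL) carries two dominant fluorescent transgenes —
GFP and dsRed expressed in the seed — inserted in *cis* on one homolog,
bracketing a marker interval. A hemizygous parent transmits, per meiosis, the
four gamete classes

| gamete | frequency |
|---|---|
| GFP + dsRed (parental) | $(1-r)/2$ |
| neither (parental) | $(1-r)/2$ |
| GFP only (recombinant) | $r/2$ |
| dsRed only (recombinant) | $r/2$ |

where $r$ is the recombination fraction in the interval. Because the markers
are dominant, a seed's fluorescence phenotype is determined by the union of
its two gametes' markers. `expected_seed_class_probs()` gives the closed-form
seed-class probabilities for the three supported designs, and
`enumerate_zygotes()` recomputes them by brute-force enumeration of all
gamete pairings; the two agree to $10^{-12}$ over a dense $(r_f, r_m)$ grid in
the test suite, and the enumeration path is kept as a permanent oracle.

In a **backcross** the hemizygote is crossed to wild type, so seeds read the
scored parent's gametes directly and

$$\mathrm{cM} = 100\,\frac{N_G + N_R}{N_T},$$

with $N_G$, $N_R$ the green-only and red-only seed counts and $N_T$ the
total. In an **F2 self**, single-colour seeds arise from the combinations of
recombinant and non-recombinant gametes of both sexes; under equal female and
male fractions the single-colour probability is $(2r - r^2)/2$, and inverting
it gives the square-root formula

$$\mathrm{cM} = 100\left(1 - \left[1 - \frac{2(N_G+N_R)}{N_T}\right]^{1/2}\right).$$

### The F2 equal-sex assumption

The inversion above is only exact when $r_f = r_m$. Applied to expectations
with unequal rates it converges to
$100\,(1 - \sqrt{(1-r_f)(1-r_m)})$ — a geometric-mean-type blend — so the F2
design cannot separate the sexes, while the reciprocal backcrosses recover
each sex's rate exactly. Since recombination is strongly sex-dimorphic in
Arabidopsis (and the genotypes this assay targets can change the two sexes in
opposite directions), every F2 estimate carries the flag
`f2_assumes_equal_sex_rates` rather than silently presenting a blended
number.

### Uncertainty

The observed recombinant proportion $f$ is binomial, so
$\mathrm{SE}(f) = \sqrt{f(1-f)/N_T}$. The backcross estimate is a linear
rescaling ($\mathrm{SE}_{cM} = 100\,\mathrm{SE}(f)$); the F2 estimate passes
through the square-root inversion, and the delta method gives
$\mathrm{SE}_{cM} = 100\,\mathrm{SE}(f)/\sqrt{1-2f}$. Wald 95% intervals are
clipped to $[0, 100]$ cM. The delta-method SE is cross-checked in the tests
against the standard deviation of the estimator over 2000 multinomial
resamples (agreement within 5% at $N_T = 1000$). No analytic interval is
attempted at the F2 boundary $f = 1/2$: the estimate is returned as 100 cM
with infinite SE, interval $[0, 100]$ and a `f2_boundary` flag. An observed
F2 fraction *above* 0.5 is outside the model and raises an error — it is
evidence of mis-scoring or transmission distortion, not a number to cap.

### Genotype comparisons

Genotypes are compared on the proportion of recombinant seeds among all seeds
counted, as a 2×2 table (recombined / non-recombined × genotype):

* **chi-square**: Pearson's statistic on the 2×2 table, 1 df, *without* Yates
  continuity correction — counts in this assay are large (≥ 400 seeds per
  replicate), where the correction only biases;
* **Fisher**: exact two-sided test, with the "small-p" two-sided convention
  (the sum of probabilities of all fixed-margin tables no more probable than
  the observed one). Conventions for two-sided Fisher tests differ, so the
  choice is stated; the test suite verifies agreement with a full
  hypergeometric enumeration for an exhaustive family of small tables (row
  margins up to 16) plus a seeded random sample of tables with margins up to
  60 — the family is sampled rather than fully enumerated at the large end to
  keep the suite's runtime proportionate.

Replicates (plants) are kept separate for per-plant estimates and plotting,
and pooled for the genotype-level test; both behaviours are exposed in the
file pipeline (`pool_replicates`), pooled being the default. No
multiple-testing adjustment is applied across genotype comparisons.

## Seed classification

Per-seed measurements are two channel intensities (arbitrary units > 0).
Classification proceeds in three steps.

**Normalization.** Plants differ by multiplicative scale (illumination,
exposure). Two per-plant anchors are offered. `per_plant_median` divides each
channel by the plant's median — the obvious choice, but on a backcross each
channel is bimodal with the positive fraction near one half, so the median
falls in the near-empty gap between modes and can land on either side of it
from plant to plant, misaligning plants by more than the mode separation
itself. The default is therefore `per_plant_geomean`, the per-plant geometric
mean: it moves smoothly with the positive fraction (its sampling error is a
few hundredths of a log-unit at hundreds of seeds), and it is exactly
scale-equivariant, so classification is invariant under rescaling all of a
plant's intensities. Both anchors are tested for that invariance.

**Threshold fitting.** Thresholds are fitted per experiment batch (all plants
pooled after normalization; per-plant fits are unstable at a few hundred
seeds). Each channel's log-intensities are fitted with a Gaussian mixture by
EM (via mclust, whose deterministic hierarchical initialisation replaces
random restarts), letting BIC choose between one and two components. A
one-component win is the unimodality signal — a *forced* two-component fit on
unimodal data reports a deceptively large mean separation (splitting a
Gaussian at its mean yields two half-normals ~2.6 pooled-sd apart), so mean
separation alone cannot detect unimodality. With two components the threshold
is placed at the equal-posterior point between the component means (solved
numerically; the midpoint of the means is the fallback if the posterior
curves do not cross inside the interval). If the mixture path fails or
separates poorly (< 1 pooled-sd), the threshold falls back to the density
valley between the two dominant modes, accepted only if the valley is
prominent (minor mode ≥ 10% of the major mode's density, valley below half
the minor mode). A channel with no acceptable threshold raises an
`unclassifiable-channel` error naming the channel.

**Classification.** A seed is channel-positive iff its log intensity is at or
above the channel threshold; exact ties classify as positive (a deterministic,
documented rule, measure-zero under continuous intensities). Class tallies
conserve the seed count by construction. QC flags (never errors) mark counts
below 400 seeds (the assay's customary per-replicate minimum), backcross
parental classes deviating from 1:1 (chi-square p < 0.01; transmission
distortion), and F2 single-colour fractions above 0.5.

## Cytology and fertility

**Bivalent model.** Each of the $K = 5$ chromosome pairs independently
receives a Poisson($\lambda$) number of class II crossovers; when the class I
(obligate-crossover, ZMM-dependent) pathway is active every pair receives at
least one. A pair with ≥ 1 crossover appears at metaphase I as a bivalent, so
with class I inactive the bivalent count is Binomial($K$, $1 - e^{-\lambda}$).
This is the simplest model consistent with 0–5 bivalent tallies: pairs are
exchangeable with a single shared $\lambda$ (per-chromosome rates are not
separately identifiable from such tallies), and the obligate-CO switch is
all-or-nothing — partial phenotypes are produced by varying $\lambda$, not by
a partial class I efficiency. `estimate_co_rate()` inverts the model:
$\hat\lambda = -\ln(1 - \hat p)$ with $\hat p$ the mean bivalent fraction,
with a profile-likelihood CI on the binomial proportion transformed to the
$\lambda$ scale. A sample with all pairs bound (mean 5) leaves $\lambda$
unbounded and raises an error; a mean of 0 returns exactly 0.

**Comparisons.** Bivalent means are compared by Welch's $t$ (the pooled-vs-
Welch choice is not dictated by the field's convention here; Welch is the
robust default), with the statistic's sign following mean(a) − mean(b).
Constant groups are handled explicitly ($t = 0, p = 1$ when equal;
$|t| = \infty, p = 0$ when different) rather than erroring. A secondary
chi-square compares the full 0–5 distributions, merging bins with expected
counts below 1 into their neighbour (0–5 tables routinely have empty corner
bins); comparing full distributions rather than dichotomised counts is the
default, both are possible from the tallies. Fragmentation (a cell-level
with/without call, modelled as Bernoulli independent of bivalent count) is
compared by the two-sided Fisher exact test.

**Fertility.** Seed set is linked to segregation: each ovule draws a maternal
and a paternal meiosis; a meiosis with $u$ crossover-less (univalent) pairs
yields a euploid gamete with probability $2^{-u}$ (each achiasmate pair
segregates at random), and a seed requires both gametes euploid. With the
obligate crossover active the expected seed set equals the ovule number
(default 50 per fruit, the Arabidopsis ballpark); with five achiasmate pairs
per meiosis the viable-seed probability is $(1/32)^2 \approx 10^{-3}$ — the
near-sterility characteristic of crossover-deficient mutants. The analysis
unit is the **plant** (mean seeds per fruit over its fruits, matching the
one-dot-per-plant presentation of fertility data; the default design is five
plants × ten fruits): a one-way ANOVA on plant means is followed by pairwise
contrasts of each genotype against the designated control using the pooled
ANOVA error, Šidák-adjusted ($p_{adj} = 1-(1-p)^k$; the identity at $k = 1$).
The tests verify the pairwise machinery against emmeans' control contrasts
and check the family-wise error rate by simulation.

## The simulator: what it does and does not emulate

The generator produces every input the pipeline reads: multinomial seed-class
counts from the segregation model; per-seed log-normal intensities (positive
and autofluorescence populations per channel, per-plant multiplicative scale
noise, spectral crosstalk mixing the underlying signals); Poisson/obligate-CO
bivalent counts and Bernoulli fragmentation flags; and segregation-driven
seeds-per-fruit. Defaults describe a wild-type plant scored in a
sub-telomeric interval: $r_f = 0.14$, $r_m = 0.22$ (male recombination
exceeds female in such intervals), $K = 5$, $\lambda = 0.35$ (a
*zmm*-mutant-like residual class II rate, used when the obligate pathway is
switched off), no fragmentation; intensities with log-means 7.5/4.5 and
log-sd 0.35 per channel (~20× signal-to-background, ~8.6 pooled-sd
separation, a cleanly bimodal channel), plant scale sd 0.15, 2% crosstalk.

It deliberately does **not** model crossover interference,
chromosome-length-dependent crossover rates, gametophyte selection or
transmission distortion, seed-coat versus embryo expression (seeds are scored
by zygotic genotype with dominant markers — the only reading consistent with
the map-distance formulas), image segmentation artefacts, or non-log-normal
intensity populations. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under the stated model, not that real
seed images are free of the upstream issues the QC flags screen for.

All simulators take an explicit `rng_seed`, are bit-reproducible given it,
and leave the global RNG state untouched; file outputs embed the seed and a
hash of the full run configuration in `#` comment headers.

## Numerical choices and degenerate inputs

* Probabilities are validated to $[0,1]$; class probabilities sum to 1 within
  $10^{-12}$ by construction.
* Estimators accept fractional (expected) counts; contingency and per-seed
  operations require integers.
* Intensities must be finite and strictly positive (log scale, base $e$,
  throughout); non-positive values are rejected at parse time.
* Chi-square on a table with a zero margin raises a degenerate-table error
  (Fisher remains defined); QC's 1:1 chi-square never raises.
* Profile-likelihood bounds are found by `uniroot` on the likelihood-ratio
  scale with the proportion confined to $(10^{-12}, 1-10^{-12})$.
* The equal-posterior threshold is solved by `uniroot` between the component
  means, guaranteeing the fitted threshold lies strictly between them.

## Problem sizes used by the tests and acceptance script

Oracle grids use $r \in \{0, 0.05, \dots, 1\}$ (both sexes crossed, all three
designs). Estimator exactness uses expected counts at $N_T = 10^6$ and 50
values of $r$. Parameter recovery uses 500 F2 populations of 4000 seeds at
$r = 0.10$; test calibration uses 2000 null replicates of two 1000-seed
plants; classifier checks use 5000 seeds (accuracy) and 2000 seeds
(end-to-end cM); the cytology round trip uses 200 replicates of 200 cells
plus one draw of $10^5$ cells; the Fisher-vs-enumeration check enumerates all
tables with row margins ≤ 16 and samples 2000 further tables with margins up
to 60. These sizes keep the full suite around a minute on one CPU while
leaving Monte-Carlo error well inside the asserted bands.

## Known limitations

* The F2 design's sex blending is inherent to the printed formula; use
  reciprocal backcrosses for sex-specific rates.
* Map distances are direct recombinant-fraction rescalings per the assay's
  formulas; no Haldane/Kosambi multi-interval mapping, interference
  estimation, or trans-configured marker support.
* The λ estimator assumes the obligate pathway is inactive; applying it to a
  wild-type-like distribution (mean near 5) is rejected rather than
  extrapolated.
* Seeds with neither colour are counted as a class, not verified as
  transgene-free; the QC report exposes the class proportion but no
  correction is applied.
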