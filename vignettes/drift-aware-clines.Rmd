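---
title: "Drift-aware allele-frequency clines and 4C contact profiles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-aware allele-frequency clines and 4C contact profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ooadrift)
```

## The scientific question

During the human expansion out of Africa, populations that migrated
farther carried different allele frequencies at some behaviour-linked
loci. A naive regression of migratory distance on allele frequency
over ~40 populations is confounded: frequencies of related populations
are correlated because they share most of their drift history (the
serial founder effect), so "significant" clines arise even for neutral
markers. `ooadrift` implements the full analysis chain that addresses
this for the SIRPB1 copy-number variant and its tagging SNPs: a
variance-stabilized regression with a drift-derived correlation
structure, an AIC model search over marker interactions, an empirical
multiple-testing correction calibrated on null markers, and the
chromatin-level companion analyses (haplotype phasing by EM, 4C-seq
contact profiles, allele-specific 3C).

## The regression model

For population $i$ with migratory distance $y_i$ (km) and allele
proportion $p_{im}$ at marker $m$, the design uses the
variance-stabilizing transform $x_{im} = \arcsin\sqrt{p_{im}}$
(radians). The model is

$$ y = X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 R), $$

with $X$ containing an intercept, transformed main effects, and
interaction columns built as element-wise products of transformed
columns (the only transform the source analysis names). Estimation is
full maximum likelihood (not REML):
$\hat\beta = (X^\top R^{-1}X)^{-1}X^\top R^{-1}y$,
$\hat\sigma^2 = e^\top R^{-1}e/n$, and
$\ell = -\tfrac n2[\log(2\pi\hat\sigma^2)+1] - \tfrac12\log\det R$.
Conventions chosen where the source is silent:

* **p-values** are two-sided Wald $z$ (ML framework); with the ML
  $n$-denominator variance these run slightly hot at $n \approx 42$,
  which is part of what the inflation factor (below) absorbs.
* **AIC** $= -2\ell + 2(k+1)$, counting the variance as a parameter.
  Published AIC values for these data are not reproducible under this
  (or the constant-free) convention, so AIC is used strictly for
  internal ranking — which is invariant to the convention and, as the
  tests verify, to rescaling distances km→m.
* **Exact fits** (possible with noiseless synthetic data) return the
  well-defined coefficients with `loglik = Inf` rather than an error;
  the error is reserved for a constant response.
* **Complete cases** per model, requiring $n \ge k+2$.

### The drift correlation

The published correction derives a pseudo-correlation from a
microsatellite genetic-distance matrix $D^2$:
$R_{ij} = (\max D^2 - D^2_{ij})/\max D^2$, unit diagonal, zero at the
maximal distance. This transform does not guarantee positive
definiteness; if the smallest eigenvalue falls below $10^{-10}$ a
ridge of $10^{-8}$ is added and the matrix renormalized, with the
ridge recorded on the object. The original $D^2$ matrix is not
machine-readable anywhere, so the drift-adjusted column of the
published table cannot be reproduced numerically; the package instead
demonstrates the correction's effect on synthetic data where the true
structure is known (see below).

### Allele orientation

The bundled table stores frequencies exactly as printed, and the
printed source never states which allele is counted. One marker
(rs1535882) is printed in an orientation inconsistent with the
published regression output: its printed frequencies fall with
distance while the published slope is positive. Because
$\arcsin\sqrt{1-p} = \pi/2 - \arcsin\sqrt p$, switching allele simply
flips the slope sign without changing the fit. `build_design()` takes
a `complement` argument; the shipped analyses complement rs1535882
only, which reproduces the published sign pattern (+, −, +, +) and
magnitudes.

## Multiple testing: the empirical inflation factor

The model search fits many correlated models, and the Wald-z/ML
convention is itself slightly anticonservative. The published remedy
fits the same model to thousands of random genomic markers and defines
the inflation factor as (proportion of null fits with $p<0.05$)/0.05;
every observed p-value is multiplied by it and capped at 1.

What the null markers must carry matters. Real genomic SNPs share the
populations' drift history, so their p-value distribution reflects
both the small-sample inflation *and* the drift confounding.
`simulate_null_markers()` therefore offers two nulls:

* `method = "drift"` — redraws founder-chain markers with no cline;
  the faithful stand-in for random genomic SNPs. Used when the scan is
  run the way the published final analysis was (drift-adjusted fits):
  corrected type-I error lands near nominal (~0.057 measured over
  replicate scans).
* `method = "permute"` — permutes observed columns across populations;
  a distribution-free null under exchangeability, used as the
  calibration check (factor 0.99 on a large exchangeable table with
  10,000 draws).

A factor computed from *permuted* nulls cannot repair an *unadjusted*
fit on drift-structured data: permutation destroys exactly the
correlation that inflates the statistic, and the rescaling cannot fix
p-values that are orders of magnitude too small. This is a property of
the published design, not of the implementation, and is why the
package pairs the correction with the drift-adjusted fit.

## The synthetic drift world

`simulate_drift_frequencies()` states one world and keeps it: 42
populations on a serial-founder chain spanning 0–28,000 km (the range
of the bundled table), ancestral allele proportion 0.85 (typical of
the African rows), per-step drift of 0.05 radians on the arcsine
scale, and a cline of 15,000 km/radian (the magnitude of the published
univariate slopes). Drift is Brownian on the transform scale, so the
GLS model is exactly correct under the generator and type-I-error
statements are sharp. The implied squared distance between populations
is the drift variance accumulated between them ($|i-j|\,\sigma_d^2$);
the *true* error structure is the Brownian-sharing kernel
$\min(i,j)$ — note it is heteroskedastic (variance grows along the
chain), which is why the generator returns the kernel rather than its
correlation: conditioning on the correlation alone leaves the fit
misspecified.

Two caveats the generator makes explicit rather than hiding:

* **Saturation.** With the stated cline and origin, the arcsine scale
  reaches its boundary and frequencies pin at 0/1 — exactly as the
  real table's many 1.00 entries do. Values are clipped; tests that
  require the linear model to hold exactly use parameter settings
  where clipping has negligible probability.
* **Attenuation.** The analysis regresses a *fixed* distance on a
  *noisy* frequency, i.e., backwards relative to the generative
  direction. The slope estimator is therefore attenuated by the usual
  errors-in-variables factor and no test asserts unbiased recovery of
  the forward slope; what is testable, and tested, is exact recovery
  in the noiseless limit and unbiased recovery of the generative-
  direction coefficient $1/\beta$ when the true kernel is supplied.
  This caveat applies equally to the published effect sizes.

## Haplotypes, LD, Hardy-Weinberg

`em_haplotypes()` estimates the four CNV×SNP haplotype frequencies
(Sin-C, Sin-T, Dup-C, Dup-T) from unphased genotypes. Only the double
heterozygote is phase-ambiguous; the E-step splits it between the two
resolutions in proportion to the current gamete products.
Initialization is linkage equilibrium of the observed allele
frequencies with a single deterministic start (the two-locus
likelihood is well behaved at these sample sizes), stopping at
$\max|\Delta h| < 10^{-8}$ or 1000 iterations; the observed-data
log-likelihood is asserted non-decreasing at every update, and its
fixed point preserves the observed allele margins exactly. The tests
pin the estimator against an exhaustive grid maximization (coarse
0.01 full-simplex scan plus exhaustive 0.002 refinement) and verify
recovery at the reported South-East-Africa regime
(0.92/0.005/0.011/0.064) within 0.03 at $n=500$. LD statistics follow
the standard definitions ($D$, $D'$ with the sign-dependent
$D_{\max}$, $r^2$); the Hardy-Weinberg test is the 1-df Pearson
chi-square without continuity correction, matching the usual
haplotype-browser display the analysis emulated.

## The 4C-seq pipeline

Coordinates are 0-based half-open; BED in, bedGraph out. Choices:

* **Digestion** cuts before each occurrence of the primary motif
  (DpnII `GATC`; blunt-cut convention — overhangs are irrelevant to
  binning) and flags fragments lacking an internal secondary site
  (Csp6I `GTAC`) as blind.
* **Filtering** removes blind fragments, fragments shorter than 40 bp
  (strict inequality), and fragments overlapping viewpoint ± 10 kb;
  it is idempotent and reports per-rule counts.
* **Fragment ends**: each retained fragment contributes two ends,
  split at the midpoint; a read is counted on the end whose half
  contains its start. Reads outside retained fragments are discarded
  and counted, so reads are conserved.
* **Smoothing**: 30-end centered running mean (15 left + self + 14
  right); at the edges the window shrinks symmetrically to the
  available ends — no padding, so no signal is fabricated.
* **Normalization** divides by the total smoothed signal within
  ±2 Mb of the viewpoint, making in-window weights sum to 1.
* **Asymmetry**: fractions of in-window weight strictly upstream and
  downstream of the viewpoint, summing to 1. The Spearman trend with
  Dup dosage uses mid-rank ties and an exact permutation p-value over
  the distinct arrangements of the dosage vector when there are at
  most $10^5$ of them (the canonical 2+2+2 design has 90; full
  enumeration of all $10!$ raw permutations would be needlessly
  hostile for untied $n=9,10$, where the t approximation is used).
* **Mann-Whitney U** (allele-specific 3C) is exact for combined
  samples of at most 12 without ties, otherwise the tie-corrected
  normal approximation.

The 4C generator draws reads multinomially with end weights
$(1+|c-\text{vp}|)^{-\text{decay}}$, attenuated by $(1 - s\cdot
\text{dosage}/2)$ beyond an insulator 25 kb downstream of the
viewpoint — the simplest monotone encoding of a dosage-dependent CTCF
boundary. With strength tied to Dup dosage the pipeline reproduces the
published ordering of downstream contact fractions
(Sin/Sin > Dup/Sin > Dup/Dup) without targeting the published
percentages, which would require the unpublished raw reads. The
generated world omits much of real 4C data: no mappability or GC
structure, no self-ligation artefacts, no biological replicates of the
same donor, and a single chromosome-scale decay regime — a green test
establishes the pipeline's arithmetic and the qualitative insulator
effect, not concordance with any particular experiment.

## What a green suite does and does not establish

Reproduced from in-paper data: the four unadjusted univariate slopes
(two exactly within print precision, two within ~3% — consistent with
the source using unrounded frequencies and/or a 42-of-43 population
subset that the printed table cannot disambiguate), the rs2209313
standard error, and the published sign pattern. Established on
synthetic data only: everything involving the unpublished drift
matrix, cohort genotypes, or raw 4C reads. Established analytically:
the $2^{\Delta Ct}$ identity and the correction formulas.
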