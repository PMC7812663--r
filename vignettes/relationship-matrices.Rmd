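---
title: "Centering and scaling genomic relationship matrices without Hardy-Weinberg assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centering and scaling genomic relationship matrices without Hardy-Weinberg assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmforge)
```

## The model

GBLUP with additive and dominance effects in the biological
parameterization writes the phenotype of individual $i$ as

$$y_i = \mu + \sum_{j=1}^m z_{ij} a_j + \sum_{j=1}^m s_{ij} d_j + e_i,$$

where $z_{ij} \in \{1, 0, -1\}$ and $s_{ij} \in \{0, 1, 0\}$ code the
genotypes $AA$, $Aa$, $aa$ at marker $j$, and $a_j$, $d_j$ are the additive
and dominance genotypic effects. Treating the genetic effects as random
gives

$$\mathrm{Cov}(\mathbf a) = \frac{H_a H_a'}{SC_a}\,\sigma^2_a = G\sigma^2_a,
\qquad
\mathrm{Cov}(\mathbf d) = \frac{H_d H_d'}{SC_d}\,\sigma^2_d = D\sigma^2_d,$$

where the $n \times m$ matrices $H_a$, $H_d$ hold per-marker *scales*:
per-genotype coefficients, analogous to contrasts, that center each
marker's column so it contributes zero mean. The scalar denominators
$SC_a$, $SC_d$ bring the average diagonal of $G$ and $D$ to one. Everything
in this package is about the choice of those scales and denominators when
genotype frequencies $(p_{AA}, p_{Aa}, p_{aa})$ are *not* the
Hardy-Weinberg proportions $(p^2, 2pq, q^2)$ — the normal situation in
crossbred livestock, where F1 crosses between divergent parental lines
carry a genome-wide excess of heterozygotes.

## The six parameterizations

Writing $w_A = p_{AA} + p_{aa} - (p_{AA} - p_{aa})^2$ for the additive
genotypic variance weight of a marker (frequencies per marker, subscripts
dropped):

| method | additive triple $(AA, Aa, aa)$ | dominance triple | $SC$ convention |
|---|---|---|---|
| HW     | $(2-2p,\; 1-2p,\; -2p)$ | $(-2pq,\; 1-2pq,\; -2pq)$ | $\sum 2pq$, $\sum 2pq(1-2pq)$ |
| NO-HW  | $(1-\delta,\; -\delta,\; -1-\delta)$ with $\delta = p_{AA}-p_{aa}$ | $(-p_{Aa},\; 1-p_{Aa},\; -p_{Aa})$ | $\sum w_A$, $\sum p_{Aa}(1-p_{Aa})$ |
| NOIA   | = NO-HW | $(-2p_{Aa}p_{aa},\; 4p_{AA}p_{aa},\; -2p_{AA}p_{Aa})/w_A$ | realized $\mathrm{tr}(HH')/n$ |
| GSP-A  | = NO-HW | Gram-Schmidt: $v - \mathrm{proj}_u(v)$ | expected traces $\sum w_A$, $\sum 4p_{AA}p_{Aa}p_{aa}/w_A$ |
| GSP-D  | $(2p_{aa},\; 0,\; -2p_{AA})/(1-p_{Aa})$ | = NO-HW dominance | $\sum 4p_{AA}p_{aa}/(p_{AA}+p_{aa})$, $\sum p_{Aa}(1-p_{Aa})$ |
| GSP-N  | GSP-A $/\; \lVert\tau_A\rVert$ | GSP-A $/\; \lVert\tau_D\rVert$ | realized $\mathrm{tr}(HH')/n$ |

Key relationships, all of which are asserted by the test suite:

* The NO-HW additive triple reduces to the VanRaden (HW) triple because
  $p = p_{AA} + p_{Aa}/2$; the HW *dominance* centering, however, fails off
  HWE — its column mean is $p_{Aa} - 2pq$.
* GSP-A (Gram-Schmidt started from the additive vector) lands exactly on
  the NOIA dominance triple. The package deliberately implements GSP-A via
  the projection arithmetic and NOIA via its closed form, so this identity
  is a genuine cross-check of two independent code paths rather than a
  tautology.
* GSP-D keeps the biological dominance scale and orthogonalizes the
  additive vector against it; its heterozygote additive entry is exactly 0.
* GSP-N divides the GSP-A vectors by their norms
  $\lVert\tau_A\rVert = \sqrt{n\,w_A}$ and
  $\lVert\tau_D\rVert = \sqrt{n \cdot 4p_{AA}p_{Aa}p_{aa}/w_A}$, so every
  marker contributes equally regardless of its frequencies.
* At HWE frequencies the NOIA dominance triple reduces to the classical
  dominance-deviation coding $(-2q^2,\; 2pq,\; -2p^2)$ with per-marker
  weight $(2pq)^2$; it coincides with the biological HW triple only at
  $p = 1/2$. (It is the NO-HW dominance *variance* $p_{Aa} - p_{Aa}^2$ that
  reduces to $2pq(1-2pq)$.)

### Orthogonality and the angle diagnostic

A parameterization partitions variance orthogonally when, per marker, the
frequency-weighted mean of each scale and the frequency-weighted
cross-product of the two scales vanish. `verify_orthogonality()` reports
all three residuals; NOIA, GSP-A, GSP-D and GSP-N satisfy them to numerical
precision, NO-HW and HW do not.

For the non-orthogonal biological scales, the degree of non-orthogonality
of a marker is summarized by the angle between its $n$-dimensional additive
and dominance scale vectors:

$$\cos\theta_j = \frac{n(-p_{Aa})(p_{AA}-p_{aa})}
{\sqrt{n\,w_A}\;\sqrt{n\,p_{Aa}(1-p_{Aa})}},$$

so $\theta_j = 90^\circ$ exactly when the two homozygote frequencies are
equal (or no heterozygotes exist, in which case the dominance norm is zero
and the angle is undefined). The individual count cancels.
`marker_angle()` clips $\cos\theta$ to $[-1, 1]$ to absorb rounding and
reports degrees in $[0^\circ, 180^\circ]$.

```{r angle}
f <- data.frame(marker = "m1", pAA = 0.5, pAa = 0.3, paa = 0.2,
                p = 0.65, q = 0.35)
marker_angle(f, n = 903)
```

## Numerical and design choices

**Degenerate markers.** A marker is dropped from $H_a$ when its additive
variance weight falls below $10^{-12}$ (monomorphic, or all-heterozygous
for the NO-HW family; $p_{Aa} = 1$ for GSP-D) and from $H_d$ when its
method-specific dominance denominator does, with the excluded marker ids
recorded on the `scale_matrices` object. Dropped columns are all-zero and
do not enter the denominators.

**Missing genotypes.** Frequencies use pairwise-complete per-marker
denominators; a missing genotype's centered scale entry is 0, i.e. mean
imputation after centering, which keeps column sums exactly zero. Realized
traces are computed on the filled matrices, so trace-scaled methods keep an
average diagonal of exactly 1 with or without missing data.

**Denominator conventions** are fixed per method as in the table (NOIA and
GSP-N realized trace, the rest expected sums); `build_scale_matrices()`
takes a `denominator` override for experimentation, and the CLI exposes it
as `--denominator`. On complete data the expected and realized sums
coincide exactly because the expectations are taken over the observed
frequencies; the two conventions differ only under missingness or when
frequencies come from a different panel.

**Exact HWE test.** The Levene-Haldane conditional distribution of the
heterozygote count given the allele counts is fully enumerated;
the two-sided p-value sums all configurations no more probable than the one
observed (ties included, no mid-p correction — the convention of the
standard SNP exact test). The enumeration uses log-factorials and is exact
up to floating point for any sample size used here.

**KL divergence.** $G$ and $D$ are compared as zero-mean Gaussian
covariances, $D_{KL}(P\Vert Q) = \tfrac12[\mathrm{tr}(Q^{-1}P) - n +
\ln(|Q|/|P|)]$ in nats, via Cholesky log-determinants. Mean vectors are
zero by default (GBLUP effects are centered); explicit `mu_p`/`mu_q`
arguments restore the general quadratic term. Because a Gram matrix built
from $m < n$ markers is singular, a ridge (default $10^{-6}$) is added to
both diagonals; the ridge is *not* used for eigenvalue summaries.

**REML.** The mixed model $V = \sigma^2_a G + \sigma^2_d D + \sigma^2_e I$
is fitted by restricted maximum likelihood with the residual variance
profiled out analytically, leaving a two-dimensional derivative-free
(Nelder-Mead) search over the log variance ratios
$\gamma_a = \sigma^2_a/\sigma^2_e$, $\gamma_d = \sigma^2_d/\sigma^2_e$,
restarted from three points (equal split, additive-heavy, dominance-heavy)
with relative tolerance $10^{-8}$; profiling keeps every evaluation a
single Cholesky factorization and makes the search space two- rather than
three-dimensional. The log-likelihood carries the $\ln|X'X|$ correction,
so it is invariant to full-rank reparameterizations of the fixed effects.
Estimates below $10^{-6}\,\mathrm{var}(y)$ are reported as 0 (boundary
solutions). Identical $G$ and $D$ make the split non-identifiable; the fit
warns and clears its convergence flag. Standard errors, when requested,
come from the numerical Hessian of the unprofiled restricted likelihood and
are approximate.

## What the simulator emulates — and what it does not

`simulate_genotypes()` reproduces the two features of a crossbred panel
the methods are sensitive to: per-marker genotype frequencies that depart
from HWE, and a genome-wide heterozygote excess. Mode `"f1"` draws each
marker as a cross of two parental pools (heterozygote frequency
$p_1q_2 + p_2q_1 \ge$ HWE expectation); mode `"inbreeding"` uses a single
disequilibrium parameter $F$ (genotype probabilities
$p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq$), with $F = -0.047$ as the default —
a 4.7% average heterozygote excess, the magnitude reported for
Large-White × Landrace crossbreds. Optional per-marker jitter on $F$
reflects that real disequilibrium is locus-heterogeneous. Default panel
size is $n = 903$; allele frequencies are uniform on $[0.05, 0.95]$
(a post-QC SNP-chip spectrum). Infeasible $(p, F)$ draws are redrawn and
counted.

`simulate_phenotypes()` draws marker effects i.i.d. normal and rescales
them so the *realized* additive and dominance variances equal their targets
exactly, giving recovery tests a well-defined truth; residuals are left
unscaled. Trial groups, when requested, are random assignments with fixed
offsets (default spacing: one phenotypic SD, a deliberately strong batch
effect). Each logical stream (frequencies, genotypes, effects, trials,
noise) is seeded separately, so genotypes are unchanged when only trait
parameters vary.

The simulator does **not** model linkage or LD, pedigree structure,
selection, locus-specific ancestry, or the viremia-curve phenotypes of
disease-challenge studies. Passing tests therefore demonstrate the algebra
and the estimation machinery under independent markers; they do not certify
behavior under LD or family structure.

A note on the per-marker heterozygote-excess estimator
$(\hat p_{Aa} - 2\hat p\hat q)/(2\hat p\hat q)$: it is a ratio of
estimates, with the usual $O(1/n)$ small-sample bias; calibration checks
allow for it explicitly.

## Problem sizes and test design

The characterization suite runs at desk scale, chosen to make the
algebraic identities exact and the stochastic checks well-powered: panel
summaries on a complete $903 \times 1000$ F1 panel (average diagonals of
trace-scaled $G$ and $D$ equal 1.000, average off-diagonal $-1/902$),
orthogonality residuals over 1000 random frequency vectors, REML recovery
of $(\sigma^2_a, \sigma^2_d, \sigma^2_e) = (2, 1, 1)$ over 20 replicates at
$n = 800$, $m = 1000$ (each component's mean within 3 Monte-Carlo SEs),
null panels at $n = 500$, and simulator calibration at $m = 5000$ markers.
The NOIA/GSP-A convergence of relationship matrices (realized versus
expected trace) is asserted at $n = 2000$, $m = 500$.

Two aspects of the REML checks deserve emphasis. First, parameter
*recovery* is tested on HWE panels with $p = 1/2$, because that is the one
regime in which the biological simulation basis $(z, s)$ coincides with the
orthogonal model basis: on any other panel the orthogonal parameterization
reassigns the additive-dominance covariation of the biological coding to
the additive component, so the simulated biological variance targets are
*not* the estimands of the orthogonal model — different parameterizations
genuinely partition variance differently, which is the phenomenon the
package exists to expose, not an estimation error. Second, the null-panel
check uses few markers ($m = 30$) by design: among unrelated individuals
genomic relationships have variance $\approx 1/m$, making the null sampling
SD of $\hat h^2$ roughly $\sqrt{2m}/n$, and $m$ is chosen so three such
SDs sit below the 0.05 declaration threshold.

## Known limitations

* The additive-dominance *covariance* model (an explicit covariance term
  instead of orthogonalization) is out of scope, as are epistatic scales,
  breed-of-origin crossbred models, and the statistical (allele
  substitution) parameterization.
* Dense algebra throughout: $n$ in the low thousands is comfortable;
  APY-style approximations for very large $n$ are not provided.
* The exact-test enumeration is per marker and single-threaded; a
  32k-marker panel takes seconds, not milliseconds.
* KL divergences between near-singular relationship matrices depend
  visibly on the ridge; compare values only at a fixed ridge.
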