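---
title: "Functional regression tests for eQTL epistasis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional regression tests for eQTL epistasis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

RNA-seq measures expression of a gene not as one number but as a read-count
profile over genomic position: splicing, alternative transcription starts,
polyadenylation and RNA editing all leave positional signatures that a single
summary (RPKM, a normalized total) discards.  This package tests whether two
gene regions *interact* — epistasis — in shaping that profile, treating the
per-position read counts of a target gene as a function-valued trait
$y_i(\tau)$ and the genotype profiles of the two regions as functions
$x_i(t)$, $z_i(s)$ of genomic position.

Genotypes at a SNP with minor/major allele frequencies $P_m, P_M$ are encoded
by frequency:
$$
x_i(t) = \begin{cases} 2P_m(t) & \text{MM}\\ P_m(t)-P_M(t) & \text{Mm}\\
-2P_M(t) & \text{mm,}\end{cases}
$$
which has mean zero under Hardy–Weinberg proportions, so a genotype function
is automatically centered.  The regression is
$$
y_i(\tau) = \mu(\tau) + W_i^{\mathsf T}\omega(\tau)
 + \int x_i(t)\,\alpha(t,\tau)\,dt + \int z_i(s)\,\beta(s,\tau)\,ds
 + \iint x_i(t)\,z_i(s)\,\gamma(t,s,\tau)\,ds\,dt + \varepsilon_i(\tau),
$$
and the null hypothesis of no epistatic effect is $\gamma \equiv 0$.

Expanding $x_i$, $z_i$ and $y_i$ in functional principal components
($J$, $L$ and $K$ components; scores $\xi_{ij}$, $\eta_{il}$, $y_{ik}$)
collapses this to a multivariate multiple regression
$Y = E\mu + W\omega + \xi\alpha + \eta\beta + \Gamma\gamma + \varepsilon$
with interaction design $\Gamma$ whose $i$-th row is
$\xi_i^{\mathsf T} \otimes \eta_i^{\mathsf T}$.  Least squares gives
$\hat b = (A^{\mathsf T}A)^{-}A^{\mathsf T}Y$ for
$A = [E\;W\;\xi\;\eta\;\Gamma]$, and the interaction block
$\hat\gamma$ (last $JL$ rows of $\hat b$) is tested with the Wald statistic
$$
T_I = \mathrm{vec}(\hat\gamma)^{\mathsf T}\,\Lambda^{-1}\,
      \mathrm{vec}(\hat\gamma),
\qquad \Lambda = \hat\Sigma \otimes G,
$$
where $G$ is the trailing $JL\times JL$ block of $(A^{\mathsf T}A)^{-}$ and
$\hat\Sigma$ the residual covariance of the $K$ response score columns.
Under the null, $T_I$ is asymptotically $\chi^2$ with $JLK$ degrees of
freedom (or $\mathrm{rank}(\Lambda)$ when the design is deficient).

Two choices here deserve explanation:

* **vec ordering.**  "The last $JLK$ rows and columns of
  $\Sigma\otimes(A^{\mathsf T}A)^{-1}$" is ambiguous without fixing how
  $\hat b$ is vectorized.  We stack $\hat\gamma$ by columns (all $JL$
  interaction coefficients of response component 1, then component 2, …),
  under which the trailing block is exactly $\hat\Sigma\otimes G$.  The
  identity is asserted directly in the test suite by extracting the block
  from the full Kronecker covariance and comparing element-for-element; any
  consistent pairing of ordering and block gives the same $T_I$.
* **residual covariance denominator.**  $\hat\Sigma$ is the unbiased
  multivariate OLS estimate
  $(Y - A\hat b)^{\mathsf T}(Y - A\hat b)/(n - q)$ with
  $q = 1 + d + J + L + JL$.  Any extra scaling of $\hat\Sigma$ would rescale
  $T_I$ by the same factor and destroy the $\chi^2_{JLK}$ calibration that
  the null simulations verify.

## Functional machinery

All curves live on a common unit interval after the affine map
$(\text{pos} - a)/(b - a)$ of the region $[a, b]$.

* **Quadrature** is the trapezoid rule, on the uniform response grid and on
  the (generally non-uniform) SNP positions.  It is exact for piecewise
  linear integrands, which is the resolution at which the data exist.  A
  single-SNP "function" degenerates to a point mass of weight one.  Grids
  with fewer than 4 sub-intervals are refused.
* **Regridding** of raw per-position counts to the grid uses tricube local
  polynomial regression (degree 2, span 0.3 by default, both configurable).
  Because every sample shares the gene's positions, the smoother is one
  matrix applied to all samples; it reproduces a reference local-regression
  implementation (`stats::loess`, direct surface) to machine precision,
  which the test suite asserts at $10^{-6}$.  The default grid has
  $m = 256$ sub-intervals; $m = 2456$ (a median gene length) is available
  where fidelity to long genes matters more than speed.
* **FPCA** is the eigendecomposition of the quadrature-weighted sample
  covariance $W^{1/2}\,\hat C\,W^{1/2}$; eigenvectors are rescaled to
  eigenfunctions orthonormal under the quadrature rule and scores are
  quadrature inner products of centered curves with eigenfunctions, so the
  score variance of component $j$ equals its eigenvalue.  Eigenfunction
  signs are fixed by making the largest-magnitude element positive (first
  such element on ties), so output is deterministic.  Genotype functions are
  kept discrete — scores are computed at the SNP positions themselves with
  non-uniform weights — rather than smoothed, since a genotype profile is a
  step-like object with no sampling noise to remove.

## Component selection

$J$, $L$ and $K$ default to the smallest counts explaining 80% of the
variance of their block, subject to two caps: each count at most
`max_components` (default 8) and $J\cdot L\cdot K \le n/2$ (largest count
trimmed first).  The variance rule is the conventional one; the caps matter
more than usual here.  With many independent rare variants the encoded
genotype spectrum is nearly flat, so the 80% rule alone can retain ten or
more components per gene; the interaction block then has $J\cdot L \sim 100$
columns and the Wald test becomes visibly anticonservative at $n = 2000$.
Capping each block at 8 keeps the null rejection rate at its nominal level
(verified in the acceptance suite at $r = 0$) while retaining enough
directions to carry causal rare variants.

## Numerical safeguards

* $(A^{\mathsf T}A)^{-}$ and $\hat b$ come from the SVD of $A$; rank-deficient
  designs use the Moore–Penrose minimum-norm solution and the test degrees
  of freedom drop to $\mathrm{rank}(\Lambda)$ (flagged in the result).
* $\Lambda$ is inverted through its symmetric eigendecomposition with a
  relative eigenvalue cutoff of $10^{-10}$.
* Missing genotypes are mean-imputed per SNP (counts recorded); allele
  frequencies are estimated from the analysis sample itself, and columns are
  oriented so the minor-allele frequency never exceeds 0.5, which makes the
  whole pipeline invariant (up to sign) to which allele a VCF calls ALT.

## Quality control and normalization

* **Genotype QC** removes duplicated positions (first kept), singletons
  (minor allele seen exactly once), and SNPs failing an exact
  Hardy–Weinberg test at $p < 10^{-9}$.  The exact test enumerates the
  conditional distribution of heterozygote counts given allele counts; it is
  implemented here (no installed package provides it) and cross-checked
  against a closed-form oracle in the tests.
* **Expression summaries** for the scalar-response comparator: raw
  median-of-ratios size factors (no global rescaling; the convention is
  documented and tested), RPKM as
  $10^9\,c/(\ell\cdot N)$, an expressing-rate gene filter (fraction of
  samples with any read $\ge$ 30%, boundary inclusive), and the rank-based
  inverse normal transform with the Blom offset $c = 3/8$ (offset exposed).
  Whether per-position curves should be size-factor normalized before FPCA
  is not settled by the method itself; `run_bfgm()` accepts size factors and
  applies them by default when given (`normalize_curves`).

## The synthetic-data engine

Simulations are first-class code, built to mirror how the method was
evaluated.

**Null traits.**  A panel of template genes stands in for a random sample of
real RNA-seq genes: each template has a smooth positive mean (Gaussian-bump
mixture), a few random per-sample amplitude scores on additional smooth
shapes, and small white noise.  The null construction regrids every template
gene to the unit grid, averages the regridded matrices over genes per
sample, takes the FPCA mean (reconstructed from averaged scores — with
centered FPCA this collapses to the pointwise mean, and the test suite
asserts the collapse against a longhand rebuild), centers per position, and
uses the FPCA eigenfunctions and score covariance $\hat\Sigma$ of the
centered pool as the error process: $\varepsilon_i(\tau) = \sum_t
\varepsilon_{it}\,\phi_t(\tau)$ with
$\varepsilon_i \sim N(0, \hat\Sigma)$.  Model 1 adds nothing else; models 2
and 3 add additive marginal terms $\sum_j x_{ij}\,r_j\,\alpha(\tau)$ (and
the gene-2 analogue) with per-SNP multipliers $r_j, s_k \sim U(0.5, 1.5)$
and effect shapes taken from the leading error eigenfunctions.  No
interaction term is ever present.

**Genotypes** are independent SNPs sampled under Hardy–Weinberg at
minor-allele frequencies drawn from a rare spectrum $U(0.001, 0.05)$ or a
rare/common mixture; 10% of SNPs are flagged causal for the null models and
20% for the power models.

**Power traits** follow a two-locus penetrance design: for every causal SNP
pair, an individual receives $r\,\lambda[\text{class}]\cdot g(\tau)$
according to its genotype class at the pair, where $\lambda$ is a 3×3
indicator table over minor-allele counts.  The built-in tables — Dominant OR
Dominant, Dominant AND Dominant, Recessive OR Recessive, and Threshold
(total count $\ge 3$) — are the canonical patterns matching those model
names; the exact tables used in the original study are not published in its
main text, so these are declared substitutes and the table is an argument.
The signal shape $g(\tau)$ defaults to the leading error eigenfunction
centered to zero quadrature mean and scaled to norm $\sqrt{\lambda_1}$: a
positional signal with *no net change in overall expression*, the regime in
which a curve-level test should succeed and a scalar summary should not.
The generator also includes $\mu(\tau)$ so that $r = 0$ reproduces the null
generator draw for draw (the intercept absorbs $\mu$ in the test, so this
changes nothing else).

**Why power is averaged over genotype pairs.**  With independent rare SNPs
(no linkage disequilibrium — deliberately out of scope), how much of the
penetrance signal lands in the span of the leading genotype components is
dominated by the luck of the causal-MAF draw: the number of double carriers
at a causal pair varies by an order of magnitude across draws.  A power
curve conditioned on one simulated pair is therefore a property of the draw,
not of the design, and can even dip below the nominal level (the unexplained
signal inflates $\hat\Sigma$).  `power_experiment()` consequently averages
over several independently drawn gene pairs (default 4, 20 SNPs per gene),
the same averaging the type-1 design uses; the averaged curves rise in $r$
and preserve the method ordering at every seed we checked.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full suite completes in a few minutes without changing any method defaults:
type-1 error with 2000 replicates at $n = 1000$ on an $m = 128$ grid with a
10-gene template panel, averaged over 2 genotype pairs; $\chi^2$/uniformity
Kolmogorov–Smirnov checks with 2500 replicates at a fixed $n = 2000$ design;
power with 500 replicates at $n = 2000$ on an $m = 64$ grid averaged over 4
pairs; covariance recovery with 500 replicates at $n = 5000$.

## What passing these simulations does and does not show

The generator draws Gaussian component scores on smooth curves: it emulates
the low-rank correlated variation of real per-position profiles, but not
count-level overdispersion, zero inflation at silent positions, ragged exon
boundaries, library-size artefacts, or LD between SNPs.  Calibration and
power results under it therefore validate the statistical machinery — not
robustness to heteroscedastic counts or confounding (population structure,
batch), which the model does not attempt to address.  The homoscedastic
assumption $\mathrm{var}(\mathrm{vec}(\varepsilon)) = \Sigma \otimes I_n$ is
taken as given; no sandwich/robust variant is provided.  Real-data use at
genome scale (hundreds of millions of pairs) is out of scope for this
package's drivers, though the per-pair test itself is the same.
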