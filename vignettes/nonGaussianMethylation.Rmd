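---
title: "Non-Gaussian models for methylation beta-values: methods and design"
author: "methylNG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-Gaussian models for methylation beta-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylNG)
```

# The problem

DNA methylation at a CpG is measured as a beta-value: the estimated
fraction of cells in which that locus is methylated, bounded in [0, 1] and
naturally beta-distributed, typically bimodal (hypo- and hypermethylated
loci). Array cohorts pair tens of thousands of CpGs with on the order of a
hundred samples, and the salient biology — normal tissue versus several
heterogeneous cancer subgroups — lives in a much lower-dimensional space.
Gaussian-based reduction and clustering ignore both the bounded support of
beta-values and the unit-norm geometry of spectral features; this package
provides the matching non-Gaussian alternatives and a pipeline that keeps
each clusterer on the feature geometry it was built for.

# Models

## Bounded-support factorization (BG-NMF)

Each entry of the CpG-by-sample matrix is modeled as
$X_{pt} \sim \mathrm{Beta}(a_{pt}, b_{pt})$ with the two shape matrices
factorized through shared nonnegative loadings,
$a \approx AH$, $b \approx BH$, and independent gamma priors on every entry
of $A$, $B$ and $H$. The posterior-mean reconstruction is
$\bar X = \bar A\bar H \oslash (\bar A\bar H + \bar B\bar H)$, and the
*pseudo-basis* $\bar W = \bar A \oslash (\bar A + \bar B)$ keeps every
entry in (0, 1) — the same support as the data — so beta-mixture
clusterers can operate on the reduced representation directly. To reduce
samples the factorization is applied to the transposed matrix, giving a
samples-by-$K$ pseudo-basis.

Inference is extended variational Bayes with all factors gamma. Two
intractable expectations are bounded: the log-beta normalizer
$E[\ln\Gamma(a+b)-\ln\Gamma(a)-\ln\Gamma(b)]$ by a relative-convexity
(tangent in log space) lower bound anchored at the current posterior
means, and $E[\ln \sum_k A_{pk}H_{kt}]$ by a Jensen bound whose weights
are proportional to the mean summands. Both bounds are tight at the
anchor, so each sweep (update order $A$, $B$, $H$, anchors refreshed per
block) has closed-form shape/rate updates and the tracked ELBO surrogate
— the anchored likelihood bound minus the exact gamma KL terms — is
non-decreasing; the test suite asserts this at $10^{-8}$ relative
tolerance on every fit it runs.

Sparsity on the excitation columns is induced by a sub-unit prior shape on
$H$ (default $\rho_0 = 0.5$); the other gamma hyperparameters default
to 1. Defaults: tolerance $10^{-5}$ relative ELBO change, at most 500
sweeps, inputs clipped into $[10^{-6}, 1-10^{-6}]$ (the package-wide
constant — every model here evaluates $\ln x$ and $\ln(1-x)$).
Initialization is seeded: excitation means from scaled uniform draws
(column sums 1), basis means from moment-matched per-row beta fits.

## Directional and bounded densities

The von Mises–Fisher density on the unit $(K-1)$-sphere is
$c_K(\lambda)\exp(\lambda\mu^{\top}x)$ with
$c_K(\lambda)=\lambda^{K/2-1}/((2\pi)^{K/2}I_{K/2-1}(\lambda))$; the
Watson density for *axial* data ($x \equiv -x$) is
$\frac{\Gamma(p/2)}{2\pi^{p/2}}\,{}_1F_1(1/2,p/2,\kappa)^{-1}
e^{\kappa(\mu^{\top}x)^2}$, uniform at $\kappa \to 0$, concentrated on the
axis for $\kappa>0$ and on the orthogonal great circle for $\kappa<0$.
All special functions are evaluated in log space: exponentially scaled
Bessel functions for $c_K$, and a log-space ascending series for
$\ln{}_1F_1$ with the Kummer transformation
${}_1F_1(a,b,x)=e^x{}_1F_1(b-a,b,-x)$ handling negative arguments, stable
to concentrations of several hundred (the visualization-scale grid
$\{4, 40, 400\}$ is covered by normalization tests).

Sampling: vMF via the Wood/Ulrich rejection scheme (beta-enveloped
tangent component plus a uniform orthogonal direction). For the Watson
law we sample the polar angle from its exact marginal
$\propto e^{\kappa\cos^2\theta}\sin^{p-2}\theta$ by inverse-CDF lookup on
a dense trapezoid grid ($2^{14}+1$ nodes). A rejection sampler is the
classical choice here, but a tight envelope for the Watson marginal is
delicate for both signs of $\kappa$; the grid inverse-CDF is uniformly
valid, deterministic given the seed, and its accuracy is checked in the
suite by a Kolmogorov–Smirnov test against an independently integrated
CDF.

## Mixture models with automatic complexity

Five clusterers share one contract: start from `Minit` components, place a
sparse Dirichlet prior (concentration $10^{-3}$) on the weights, prune
components whose posterior weight falls below 0.01, refit once.

* **VBGMM** (baseline): full conjugate Gaussian–Wishart variational
  mixture for real-valued embeddings such as PCA scores.
* **VBBMM**: independent-dimension beta components with gamma posteriors
  on every shape, using the same extended-VI bound as the factorization.
* **VBvMM / VBWMM**: hybrid schemes — variational posteriors over labels
  and weights, point-mode estimates for each component's direction and
  concentration under a uniform prior on the sphere and a weak gamma
  prior on the concentration. The concentration update maximizes a
  concave 1-D objective exactly (Bessel-ratio root for vMF,
  Kummer-derivative ratio for Watson), and the Watson direction update is
  the leading eigenvector of the responsibility-weighted scatter, so
  every quantity depends on the data only through $xx^{\top}$ — label
  assignments are exactly invariant to sign flips of any input.
* **RPBMM** (benchmark): recursive binary partitioning; each node fits 1-
  and 2-component beta mixtures by EM with the node's responsibilities as
  observation weights and splits iff the weighted BIC
  ($-2\,\mathrm{wLL} + d\ln\sum w$) improves. Leaves carry split-path
  labels (`rL`, `rRL`, ...). Child EM runs are initialized from the
  node's own high-weight members; an unweighted initialization would
  rediscover the parent boundary and starve the tree.

**Initialization and model search.** Every variational fit starts from
seeded k-means++ responsibilities. Coordinate ascent cannot merge
symmetric redundant components on weakly structured data (e.g. a sphere
carved into ten caps on uniform data is a local optimum whose weights all
survive pruning), so besides three restarts at `Minit` the driver also
restarts from smaller initial counts (1, 2, `Minit`/2) and keeps the best
final ELBO. The ELBO comparison is what selects the parsimonious solution;
we verified it ranks the collapsed solutions above the overfit ones on
uniform-sphere, antipodal and two-axis constructions before adopting the
ladder. Convergence: relative ELBO change below $10^{-6}$ or 500
iterations.

## Embeddings and dimension estimation

* **Top-variance selection** keeps the n most variable CpGs, preserving
  row order; ties break by original order.
* **RMT**: rows standardized, eigenvalues of the $T\times T$ correlation
  matrix compared with the Marchenko–Pastur upper edge
  $(1+\sqrt{T/P})^2$; the count above the edge is the signal dimension.
  No Tracy–Widom refinement — the estimate is used as a reasonable
  working dimension, and on pure noise it returns 0 in $\ge 95\%$ of
  seeded runs.
* **PCA** mean-centers each CpG (no variance scaling) and projects on the
  leading covariance eigenvectors.
* **Spectral embedding**: Gaussian affinity
  $\exp(-\|x_i-x_j\|^2/(2\sigma^2))$ with zero diagonal, symmetric
  normalization $D^{-1/2}AD^{-1/2}$, top-$K$ eigenvectors stacked as rows,
  columns scaled to unit norm. The automatic kernel width follows the
  variance heuristic: $\sigma$ is the square root of the variance of the
  entries of the squared-distance matrix. The optimal width is an open
  question in the field; the heuristic is the documented default and an
  explicit `sigma` overrides it. Eigenvector signs are fixed so the
  largest-magnitude entry is positive, for reproducibility across linear
  algebra backends.

## Pipeline compatibility

Feature support decides the pairing, and the pipeline enforces it:
PCA scores (real-valued) go to VBGMM; the BG-NMF pseudo-basis (bounded)
goes to VBBMM or RPBMM; spectral features (unit-norm) go to VBvMM or
VBWMM. Scoring maps each cluster to its majority truth class (ties toward
the larger class), counts misclustered samples, and reports the error
rate as a percentage plus the two directional counts
(larger-class-to-smaller and vice versa — cancer-to-normal and
normal-to-cancer in the standard cohort setting).

# The synthetic cohort

The default generator profile emulates a 27k-array breast cohort: 136
samples — 23 normals plus cancer subgroups of 40, 40 and 33 — over a
configurable number of CpGs (1000 by default, desk-scale; 5000 matches
a full top-variance selection). Non-differential CpGs share one beta law
across groups; each cancer subgroup owns a disjoint subset of the
differential CpGs, whose means shift by `delta` (default 0.3) toward the
interval center, and entries are drawn with beta precision 30 (moderate
array-like noise) before clipping. What this does *not* emulate: probe
chemistry (type I/II), batch effects, missingness, or the long-range
correlation structure of real arrays — passing tests demonstrate
correctness of the algorithms under their own assumptions, not
performance on any particular real cohort. A second generator draws
exactly from the BG-NMF generative model (the factorization's own truth),
and a third plants directional mixtures with component axes at least 60
degrees apart.

# Numerical choices and degenerate inputs

* Single clipping constant $10^{-6}$ shared by readers, generators and
  fitters; exact 0/1 in files is clipped with a logged count, anything
  outside [0, 1] is rejected with coordinates.
* Unit-norm inputs are accepted within $10^{-8}$ and re-normalized;
  anything further off errors.
* Constant rows are dropped (with a warning) before RMT; a sample with a
  zero affinity row in the spectral embedding raises an error naming it.
* Concentrations are capped at 2000 in the directional fits (beyond the
  working range of the data the fits see); gamma shape/rate updates are
  positive by construction.
* Ties in top-variance selection and k-means seeding are resolved
  deterministically; all stochastic steps flow from a single integer
  seed, and identical configuration plus seed reproduces reports byte
  for byte.

# Problem sizes used in validation

The suite validates at desk scale, chosen to exercise every code path
with comfortable margins: factorization recovery at $200\times 60$ with
three latent components over five seeds; mixtures at 200–300
observations; RMT at $1000\times 100$ over 100 seeds; the end-to-end
profile at $1000\times 136$. These match or shrink the study conditions
without changing any model constant.

# Known limitations

* The directional mixtures use point-mode component parameters rather
  than full posteriors; uncertainty in directions/concentrations is not
  propagated (complexity selection leans on the weight posterior and the
  restart ladder instead).
* VBWMM fits only positive concentrations (clusters around axes), by
  design; girdle-shaped components ($\kappa<0$) remain available in the
  density/sampler layer.
* The BG-NMF ELBO surrogate is a bound-of-bound; its absolute value is
  not comparable across different inner dimensions $K$, so $K$ is chosen
  by RMT (or by the user), not by ELBO comparison.
* Real-cohort performance depends on preprocessing choices (probe
  filtering, normalization) that are out of scope here.
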