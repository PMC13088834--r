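---
title: "Methods: ensemble distance-based association testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble distance-based association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emanova)
```

## The testing problem

Microbiome profiling yields, for each of $n$ samples, relative abundances of
$K$ taxa (OTUs), usually with $K > n$, extreme sparsity, and a compositional
constraint. The scientific question is whether community composition is
associated with covariates of interest $X_1$ (a phenotype, an exposure)
after adjusting for confounders $X_2$ (age, sex, ...). Distance-based
multivariate regression handles this by reducing the $K$-dimensional
profiles to an $n \times n$ dissimilarity matrix $D$ and asking whether the
dissimilarity structure aligns with $X_1$.

The classic pseudo-F statistic converts $D$ to similarities
$s_{ij} = -d_{ij}^2/2$, double-centers them ($K = HSH$ with
$H = I - n^{-1}\mathbf{1}\mathbf{1}^\top$), and contrasts the projection
onto the full design against the projection onto the confounders alone.
Its null distribution behaves like a weighted sum of chi-square variables,
with weights given by the eigenvalues of $K$. Two practical weaknesses
follow: significance is usually obtained by permutation (slow, and floored
at $1/B$), and power depends strongly on how the association signal lines
up with the kernel's eigenstructure and on the distance chosen.

## The ensemble statistic

This package addresses both weaknesses with an ensemble of *base tests*.
For each distance $d$ and each exponent $r > 0$:

1. $S = -D^2/2$, $K = HSH$.
2. PSD repair: $K = U\Lambda U^\top$, $K^* = U|\Lambda|U^\top$. Microbiome
   distances (UniFrac, Bray-Curtis) are not Euclidean-embeddable and
   genuinely produce negative eigenvalues (there is a regression test
   documenting this), so the repair is not optional.
3. Spectral reweighting: $(K^*)^r = U|\Lambda|^r U^\top$. Small $r$
   flattens the spectrum, spreading weight over minor axes of variation;
   large $r$ concentrates on the dominant axes. Different signals are
   detectable at different spectral scales.
4. Base statistic $T_{d,r} = \mathrm{tr}\{(H_X - H_{X_2})(K^*)^r\}$, where
   $H_X$ and $H_{X_2}$ are hat matrices of the centered designs
   $(X_1, X_2)$ and $X_2$. The denominator of the classic pseudo-F is
   omitted: it converges to a constant and does not affect p-values.

The base p-values over the grid $d \in D$, $r \in R$ are combined with the
Cauchy combination
$T = \frac{1}{|D||R|}\sum_{d,r} \tan\{(0.5 - p_{d,r})\pi\}$,
$P = 0.5 - \arctan(T)/\pi$, which is a valid (tail-calibrated) combination
under arbitrary dependence among the base tests.

## Distances

Three metrics are built in, all bounded in $[0,1]$:

* **Weighted UniFrac** (`wuf`): branch-length-weighted comparison of
  per-branch descendant abundances $p_{il}$, with abundance exponent
  $\alpha$ applied to $(p_{il}+p_{jl})$ in both numerator and denominator.
  Default $\alpha = 0.5$, the robust intermediate between pure abundance
  weighting and pure presence weighting. Branches with
  $p_{il}+p_{jl}=0$ are dropped from both sums (the formula's limit), which
  at $\alpha = 0$ makes the denominator the length of branches present in
  either sample.
* **Unweighted UniFrac** (`uuf`): presence/absence mismatch weighted by
  branch length, divided by the *total* tree length. Presence is strict
  positivity; no pseudo-counts.
* **Bray-Curtis** (`bc`): $\sum_k |p_{ik}-p_{jk}| / \sum_k (p_{ik}+p_{jk})$,
  computed through `vegan::vegdist`; on compositions this is half the L1
  distance.

Trees are used exactly as stored: the basal node acts as the root, and a
basal multifurcation (the storage form of an unrooted Newick string) is
accepted as-is, since the computation only needs branch directions.
Relocating the root changes descendant sets and therefore UniFrac values;
re-rooting is deliberately left to the user rather than silently applied.

## Analytic permutation p-values

The permutation null of a base test is the distribution of
$T(\pi) = \mathrm{tr}(G\,\Pi K_r \Pi^\top)$ over all $n!$ simultaneous
row/column permutations of the kernel with the design contrast
$G = H_X - H_{X_2}$ held fixed (equivalently: permuting sample labels of
the microbiome block while keeping the design). The package computes the
first three moments of this distribution *exactly*, in closed form, with
no sampling.

The derivation used here decomposes $E[T^m]$ over the partition lattice of
the $2m$ index slots: each pattern of index coincidences contributes a
product of matrix contraction sums, recovered from unconstrained
contractions by Moebius inversion, divided by a falling factorial of $n$.
Because both $G$ and $K_r$ are double-centered, every contraction in which
some index appears exactly once vanishes, leaving a small dictionary of
cheap invariants (traces, diagonal sums, entrywise power sums,
$\mathrm{tr}(X^3)$, ...). The implementation is validated against
exhaustive enumeration over all $n!$ permutations at $n \le 7$ (relative
error is at floating-point level, around $10^{-15}$) and against
100,000-sample Monte Carlo moments at $n = 100$. The enumeration oracle —
not any particular printed formula — is treated as the normative
definition.

Given mean, variance, and skewness $\gamma$, the standardized statistic is
referred to a Pearson type III distribution (a shifted gamma) with matching
first three moments: for $\gamma > 0$, shape $\hat b = 4/\gamma^2$, scale
$1/\sqrt{\hat b}$, location $-\sqrt{\hat b}$; for $\gamma < 0$ the mirror
image. The Pearson type III family is preferred over a plain gamma because
negative skewness occurs routinely for $r < 0.5$. At $|\gamma| < 10^{-8}$
the standard normal limit is used. P-values are clipped to
$[10^{-15}, 1-10^{-15}]$ so the Cauchy transform never receives 0 or 1;
the analytic path can therefore report arbitrarily small p-values, which a
permutation procedure cannot.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `distances` | `wuf, uuf, bc` | metrics entering the ensemble (unitless distances in $[0,1]$) |
| `r` | `0.125, 0.25, 0.5, 1, 2` | kernel exponents; geometric grid including $r=1$ (the classic statistic). Values outside $[0.125, 2]$ warn: they add little power and strain the three-moment approximation |
| `alpha_unifrac` | `0.5` | abundance weighting of weighted UniFrac, in $[0,1]$ |

Equal Cauchy weights over all $(d, r)$ pairs are used; a degenerate base
test (numerically zero permutation variance, e.g. a permutation-invariant
kernel) is dropped from the combination with a warning and the weights
renormalize over the remainder.

## The synthetic-data generator

`simulate_table()` emulates the statistical shape of a real 16S dataset:
$n = 100$ samples by $K = 330$ OTUs by default, a random coalescent
phylogeny, a strongly skewed log-normal rank-abundance profile
(`base_sdlog = 1.25`), Dirichlet overdispersion of per-sample compositions
(total concentration `theta = 50`), log-normal library sizes (median 5000
reads), and entry-level dropout calibrated analytically so the expected
zero fraction is `zero_target = 0.7` (each sample's dominant entry is
protected, so rows remain valid compositions). These values were chosen
once as realistic for a sparse stool/throat-style 16S table: about 63% of
entries are zero before dropout, 70% after, matching the "more than
half zeros" character of real tables.

Outcomes follow
$y_i = 0.5X_{1i} + 0.5X_{2i} + \beta f(\mathrm{scale}(\sum_{k\in A} Z_{ik}))
+ \epsilon_i$ with standard normal $\epsilon_i$, Bernoulli(0.5) $X_1$, and
$X_2$ either independent standard normal or correlated with the aggregate
signal ($\rho = 0.5$; the correlation strength is this package's choice —
only the existence of a correlated mode is prescribed by the scenario
design). A logistic analogue generates binary outcomes. The link $f$ is
fixed by scenario: identity (S1, S2), real signed cube root (S3), sine
(S4). The associated set $A$ is either a union of phylogenetic clusters
(S1/S3: average-linkage clustering of the cophenetic distance into 20
groups, clusters accumulated until $|A| \ge 10\%$ of $K$) or the top 10%
of OTUs by mean relative abundance (S2/S4). The 10% target is a design
choice; the benchmark literature leaves the set size open.

What the generator does *not* emulate: fitting to a specific empirical
template dataset (e.g. via an empirical-quantile simulator), phylogenetic
signal in the abundances themselves (abundances are exchangeable across
the tree given the rank-abundance profile), taxon-taxon correlation beyond
the compositional constraint, and batch or sequencing-run structure.
Consequently, passing the calibration and power checks here demonstrates
the statistical validity and responsiveness of the test under controlled
conditions, not its power on any particular real cohort; power values tied
to an empirical template are expected to differ.

## Numerical choices

* Eigenvalues below $10^{-12}\max|\lambda|$ are zeroed before powering
  ($r < 1$ would amplify numerical noise).
* Eigenvector sign/order indeterminacy is harmless — only
  $U f(\Lambda) U^\top$ is consumed; a test asserts invariance under
  re-decomposition.
* One eigendecomposition per distance is reused across all exponents.
* Hat matrices use a rank-revealing SVD with tolerance
  $10^{-8}\sigma_{\max}$, so collinear design columns are handled.
* Centering of moment inputs is a checked precondition (row-sum tolerance
  $10^{-6}$ relative), not silently re-applied.
* Stable tangent evaluation: $\tan\{(0.5-p)\pi\} = 1/\tan(p\pi)$ for small
  $p$ and $-1/\tan((1-p)\pi)$ near 1; the ensemble p-value folds the
  arctangent symmetrically so tiny p-values keep full relative precision
  (an all-equal input reproduces the common p-value exactly).
* Pairs with no shared nonzero branches get weighted-UniFrac distance 0
  with a warning; an all-zero sample is an input error.

## Problem sizes used by the test-suite

The statistical checks run at the generator's study conditions where the
claim depends on them (type I error: 1000 replicates at $n=100$, $K=330$;
analytic-vs-Monte-Carlo agreement: 20 datasets at $n=50$ with $B=20000$;
moment exactness: enumeration at $n \le 7$), and at reduced sizes
($n \approx 30{-}80$, $K \approx 40{-}150$) for structural and directional
properties, keeping the default suite in the minutes range.

## Known limitations

* **Mid-range accuracy of the three-moment approximation.** The Pearson
  type III fit matches three moments only. When a powered kernel is nearly
  rank-one (weighted UniFrac at $r \ge 1$ often concentrates over 90% of
  its spectrum on one eigenvalue), the permutation null is strongly skewed
  ($\gamma \approx 2.5$) and close to discrete; the analytic p-value then
  deviates from the true permutation p-value by up to a few hundredths in
  the *upper* range ($p \gtrsim 0.4$), while remaining accurate in the
  testing-relevant tail. Decisions at conventional significance levels are
  unaffected; exact mid-range p-values are not a design goal.
* **Mid-range behavior of the Cauchy combination.** Under dependence the
  combined p-value is calibrated in the tails, not uniform across its whole
  range; a slight liberal drift at $\alpha = 0.05$ is known and tolerated.
* The moment machinery covers the first three moments; no fourth-moment or
  saddlepoint refinement is attempted.
* Permutation is plain (kernel rows/columns against a fixed design
  contrast). Residualization-based schemes for confounders are out of
  scope; confounders are handled through the projection contrast.
* The number of design columns must stay below $n$; high-dimensional
  designs are out of scope.

## A worked call

```{r example}
sim <- simulate_dataset(sim_config(n = 40, K = 60, scenario = "S1",
                                   beta = 1, seed = 7))
fit <- emanova(sim$table, x1 = sim$y, x2 = cbind(X1 = sim$x1, X2 = sim$x2),
               tree = sim$tree)
summary(fit)
```
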