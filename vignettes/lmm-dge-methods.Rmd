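---
title: "Mixed-model differential expression for quantitative traits: models, choices, and caveats"
author: "lmmdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model differential expression for quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk RNA-seq cohorts now reach hundreds of samples, and the phenotypes of
interest — rates of cognitive decline, neuropathology burdens, physiological
measurements — are continuous. Testing each gene's expression against such a
quantitative trait with ordinary per-gene regressions looks innocuous but is
not: expression data carry pervasive shared structure (batch, cell-type
composition, ancestry, technical factors), and whenever a latent factor
influences both many genes and the trait, every one of those genes becomes
spuriously associated with the trait. The result is genome-wide inflation of
test statistics that multiple-testing correction cannot repair, because the
null distribution itself is wrong.

`lmmdge` implements a linear-mixed-model (LMM) association test that absorbs
this shared structure through a sample-by-sample relatedness matrix built
from the expression data themselves, alongside three widely used comparison
engines (ordinary least squares, Huber robust regression, and a
voom/moderated-*t* two-group analysis of the median-dichotomized trait), a
genomic-control diagnostic layer, and a count simulator whose latent
confounder makes the calibration contrast reproducible without access to any
restricted cohort data.

# Normalization

Raw counts $K_{ij}$ (gene $j$, sample $i$) are modeled as negative binomial
with mean $\mu_{ij} = s_i x_{ij}$; the per-sample size factor $s_i$ is the
median-of-ratios estimate

$$ s_i = \mathrm{median}_{j:\,K^R_j \neq 0} \; \frac{K_{ij}}{K^R_j}, \qquad
   K^R_j = \Big(\prod_{i=1}^{n} K_{ij}\Big)^{1/n}, $$

where genes containing any zero count have geometric mean zero and are
excluded from the reference set. The median is taken on the log-ratio scale
(for an even number of reference genes the two central ratios are averaged
geometrically), which makes the estimate agree bit-for-bit with the standard
median-of-ratios normalizer; the test suite asserts that agreement.
Normalized expression is $x_{ij} = \log_2(K_{ij}/s_i + 1)$.

Data preparation follows the conventional bulk RNA-seq filters, applied in
this order: samples with fewer than ten million total mapped reads are
removed (strictly below; equality is retained), then genes expressed below
0.1 TPM in strictly more than 20% of the retained samples are removed. The
TPM filter needs gene lengths; when they are absent the pipeline skips the
filter and says so rather than silently substituting a counts-per-million
rule, because a silent substitution would change the retained gene set.

One point the literature leaves open is whether such filters should be
applied before or after merging discovery and validation sets; `lmmdge`
applies them per dataset, which is the only option when datasets arrive
separately.

A caveat worth knowing: because the geometric-mean reference is itself
recomputed from the data, multiplying one sample's counts by $c$ scales that
sample's size factor *relative to the others* by exactly $c$, but also shifts
every size factor by a common $c^{1/n}$. Only ratios of size factors are
identified; all downstream tests are invariant to that common factor.

# The mixed-model test

For each gene $j$ the model is

$$ Y = W\alpha + X_j \beta_j + u + \varepsilon, \qquad
   u \sim N(0, \gamma \tau^{-1} M), \quad
   \varepsilon \sim N(0, \tau^{-1} I_n), $$

with $W$ the $n \times c$ covariate matrix (intercept first), $X_j$ the
gene's log2-normalized expression, $M$ the expression-derived relatedness
matrix, $\gamma$ the ratio of the random-effect variance to the error
variance, and $\tau$ the error precision. The null hypothesis
$H_0: \beta_j = 0$ is assessed by a Wald test.

## Relatedness matrix

$M$ summarizes sample-sample similarity across all genes; a latent factor
that loads on many genes surfaces as a leading eigenvector of $M$, and the
random effect then soaks up precisely the trait variance aligned with that
structure. Two constructions are available:

* **centered** (default): genes are centered and $M = X_c^\top X_c / p$,
  rescaled to unit average diagonal. Genes that (co)vary strongly — exactly
  the carriers of a shared factor — contribute proportionally more, which
  concentrates the confounder in the top eigenvalue. This is the default
  kinship convention of the genetic association tools this test mirrors.
* **standardized**: genes are standardized first and $M$ is the
  sample-sample Pearson correlation of the standardized matrix (unit
  diagonal by construction). Every gene contributes equally.

The distinction matters more than it looks. A single variance ratio
$\gamma$ scales *all* of $M$'s eigenvalues at once, so the model can only
down-weight a confounded direction relative to the bulk by the ratio of the
corresponding eigenvalues. Standardizing every gene to equal weight dilutes
strongly loaded genes and caps that ratio; on the package's own confounded
scenario the standardized construction cannot push the genomic-control
factor below about 1.3 no matter how large $\gamma$ gets, while the centered
construction calibrates to $\lambda \approx 1$. The centered form is
therefore the default; the standardized form is kept because it is the
natural reading of "sample-sample correlation" and is the construction the
correlation-oracle tests pin down.

$M$ is rescaled to unit average diagonal only for interpretability; any
constant rescaling of $M$ is absorbed exactly by $\gamma$.

## REML through one eigendecomposition

$M = U\,\mathrm{diag}(d)\,U^\top$ is decomposed once per dataset; rotating
$y$, $W$ and every gene by $U^\top$ makes the marginal covariance diagonal,
$\mathrm{diag}(\gamma d_i + 1)/\tau$, so each restricted-likelihood
evaluation costs $O(nq^2)$ rather than $O(n^3)$. $\tau$ is profiled out
analytically; $\gamma$ is estimated per gene — the tested gene sits in the
fixed effects, so the REML optimum is gene-specific — by a 50-point log10
grid on $[10^{-5}, 10^5]$ followed by bounded scalar refinement of the best
bracket. If the refinement ever returns a value below the grid maximum the
best grid point is used and the gene is flagged. The test suite holds the
rotated path to within $10^{-8}$ of a dense oracle that forms
$\Sigma = \gamma M + I$ explicitly.

Numerical guards: eigenvalues in $[-10^{-8}, 0)$ are clamped to zero
(round-off on a PSD matrix); genes collinear with the covariates or constant
across samples are reported with $p = 1$ and an explicit flag rather than
dropped; p-values are floored at the smallest positive double.

## Reference distribution

The Wald statistic $\hat\beta_j / \mathrm{se}(\hat\beta_j)$ is referred to a
*t* distribution on $n - c - 1$ degrees of freedom, the convention of the
mixed-model association tools this engine mirrors. The OLS engine instead
uses the standard normal by default — that is the classical large-sample
presentation of the same test — with a `reference = "t"` switch. At the
sample sizes this package targets (hundreds), the two references are
numerically indistinguishable.

# Comparison engines

**Ordinary least squares** fits $Y = W\alpha + X_j\beta_j + \varepsilon$ by
least squares, vectorized across genes through the Frisch–Waugh–Lovell
projection; results equal the per-gene normal-equation solution to
$10^{-10}$.

**Huber robust regression** minimizes $\sum_i \rho(e_i)$ with the Huber
loss, by iteratively reweighted least squares with weights $w(e) = 1$ for
$|e| \le k$ and $k/|e|$ beyond. The tuning constant is $k = 1.345\,
\hat\sigma$ with $\hat\sigma$ the median absolute residual divided by
0.6745, re-estimated every iteration — the standard, reproducible choice.
Iterations stop when the largest coefficient change drops below $10^{-8}$
(default cap 50 iterations; non-convergence is flagged, never hidden). At
convergence the coefficients satisfy the score equations of the convex
fixed-$k$ objective, and the suite checks the objective value against a
generic numerical minimizer. The Wald test uses an M-estimation sandwich
covariance $A^{-1} B A^{-1}$ with $A = X^\top \mathrm{diag}(\psi'(e)) X$ and
$B = \tfrac{n}{n-q} X^\top \mathrm{diag}(\psi(e)^2) X$, referred to a *t* on
$n - c - 1$ df. This reproduces the behavior of the usual robust-F
approaches without binding to any package's internals; it is an asymptotic
approximation, and its finite-sample calibration is tested empirically
(Kolmogorov–Smirnov on null simulations).

**voom + moderated t** is the two-group route: the trait is dichotomized at
its median (strictly greater than the median maps to 1 — the printed rule,
so ties at the median go to 0), counts become $\log_2$ counts-per-million
with a 0.5 offset over library sizes plus 1, a lowess curve (span 0.5) of
square-root residual standard deviations on average log2 count supplies a
per-observation precision weight $w = \widehat{\mathrm{sd}}^{-4}$, and
per-gene weighted regressions of expression on covariates plus the group
indicator are shrunk with an empirical-Bayes variance prior whose scale and
degrees of freedom are estimated by matching the mean and variance of the
log residual variances (a trigamma inversion). Note the reversed regression
direction — expression on trait — recorded in the `model` column of every
result table. The implementation is cross-checked against the reference
voom/eBayes pipeline to $10^{-6}$ and exposes the shrinkage parameters, so
the no-shrinkage ($d_0 = 0$) and complete-shrinkage ($d_0 = \infty$) limits
are directly testable. Which covariates enter the two-group design is not
settled usage; `lmmdge` includes the same $W$ as the other engines.

# Calibration diagnostics

The genomic-control factor is
$\lambda = \mathrm{median}_j\, \chi^2_1(1 - p_j) \,/\, 0.4549$, the
median-based variant (the regression variant is not implemented; the
median form is the common convention and is insensitive to the signal
tail). $\lambda \approx 1$ indicates calibrated nulls. QQ tables use the
median-unbiased plotting positions $(i - 0.5)/m$. Bonferroni thresholds are
$\alpha/m$; with $\alpha = 0.05$ and $m = 37$ this is the familiar
replication threshold $0.00135$. Volcano tables apply the conventional
$|\beta| > 0.05$, $p < 0.05$ coloring with top-5 labels per direction;
Manhattan tables lay genes out in contiguous per-chromosome blocks (the
package has gene order, not base-pair positions) and echo the requested
threshold lines.

# The simulator and what it does (not) show

`simulateDGE()` generates: latent $u_i \sim N(0,1)$; loadings
$l_j \sim N(0, \sigma_l^2)$; log2 signal $z_{ij} = b_j + l_j u_i + e_{ij}$
with unit idiosyncratic noise; counts
$K_{ij} \sim \mathrm{NB}(\mu = s_i 2^{z_{ij}}, \alpha)$ in the
mean–dispersion parameterization $\mathrm{var} = \mu + \alpha\mu^2$ (stated
explicitly because "dispersion" is overloaded); log-normal library-size
factors; and a trait built on the log2-scale signal,
$y = W\eta + \sqrt{\mathrm{share}}\,u + \beta\sum_{j \in C} z_{ij} +
\sqrt{1-\mathrm{share}}\,\epsilon$, so that with no causal genes the
confounder contributes exactly the stated share of trait variance. One
master seed expands into named substreams (library sizes, baselines,
confounder, counts, covariates, trait) so switching a component on never
perturbs the draws of the others — spiking causal genes leaves the count
matrix bit-identical.

The canonical **confounded null scenario** fixes $n = 300$, $p = 2000$,
loading variance 0.6, trait share 0.4, dispersion 0.1, library-size log-sd
0.3, no causal genes, intercept-only covariates. Baseline log2 means are
uniform on $[3, 8]$ (mean counts roughly 8–256), a realistic mid-abundance
band for filtered bulk data; the value is a package choice, fixed once. On
this scenario the LMM's genomic control sits at $\lambda \approx 1$ while
OLS and the robust engine exceed 40 and the dichotomized voom engine
exceeds 30 — the calibration contrast, at simulation scale, that motivates
the mixed model. The acceptance script reproduces these numbers as medians
over five seeds.

What the simulator does **not** emulate: real marginal count distributions,
gene-length effects, correlated gene modules beyond a single factor,
outlying samples, or isoform structure. Passing the calibration contrast
here shows the engines behave as designed under a pervasive single-factor
confounder; it does not certify calibration on any particular real cohort,
where confounding can be multi-factorial and partially observed.

Problem sizes used by the test suite and acceptance script (chosen as
representative desk-scale analyses): the five-seed calibration contrast at
$n = 300$, $p = 2000$; oracle equivalences at $n \le 50$; null-uniformity
checks at $n = 150$, $p = 2000$; variance-ratio recovery over 50 replicates
at $n = 200$.

# Known limitations

* The LMM assumes normal errors on the log2 scale; heavy-tailed expression
  can bias effect estimates (a Poisson mixed model or quantile-regression
  extension would address counts and heterogeneous effects, and is out of
  scope here).
* A single random effect with one kernel cannot remove confounding whose
  eigen-structure the kernel does not separate from the bulk (see the
  centered-vs-standardized discussion above); $\lambda$ should always be
  inspected.
* The robust engine's sandwich variance is asymptotic; at very small $n$ it
  runs slightly anticonservative.
* Median dichotomization discards information by construction; the voom
  engine is included as a comparator, not a recommendation, for
  quantitative traits.

# A minimal session

```{r example, eval = FALSE}
library(lmmdge)

dds <- scenarioNullConfounded(seed = 1)
dds <- estimateSizeFactors(dds)
dds <- normalizeLog2(dds)

resLMM <- runLMM(dds, trait = "trait")
resOLS <- runOLS(dds, trait = "trait")

genomicControlLambda(resLMM$pvalue)   # ~ 1.02
genomicControlLambda(resOLS$pvalue)   # ~ 65
```
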