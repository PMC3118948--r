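---
title: "Association models, category distinguishability, and Monte-Carlo power for ordinal agreement studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association models, category distinguishability, and Monte-Carlo power for ordinal agreement studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuapower)
```

## The model

Classifications of $N$ objects by two raters on an ordinal scale with $I$
categories give counts $n_{ij}$ with a full multinomial distribution over
the $I^2$ cells, expected means $m_{ij} = N\pi_{ij}$. The package fits the
log-linear family

$$\log m_{ij} \;=\; \mu + \lambda^A_i + \lambda^B_j \;-\; \sum_g \beta_g\, x_g(i,j),$$

where the association covariates are indexed by equality classes $g$ of
adjacent category pairs $k \in \{1,\dots,I-1\}$ (pair $k$ = categories
$k, k+1$):

$$x_g(i,j) \;=\; \frac{|i-j|}{2}\;\#\{k \in g:\ \min(i,j) \le k \le \max(i,j)-1\}.$$

With no class this is the independence model; with a single class holding
all $I-1$ pairs it is the uniform association (UA) model; with singleton
classes the full non-uniform association (NUA) model; intermediate
groupings express "close" or "symmetric" distinguishability patterns.

The coding is pinned by four consequences that any parameterisation of
this family must satisfy, and that the test suite asserts:

1. the UA model is the NUA special case with all $\beta_{k,k+1}$ equal
   (merging all classes reproduces the UA fit bitwise);
2. the adjacent-pair odds ratio is
   $\tau_{k,k+1} = m_{kk}m_{k+1,k+1}/(m_{k,k+1}m_{k+1,k}) = e^{\beta_{k,k+1}}$;
3. under UA, $\tau_{ij} = e^{\beta (i-j)^2}$;
4. in general $\log \tau_{ij} = |i-j| \sum_{k=\min}^{\max-1} \beta_k$, so
   distinguishability varies with inter-category distance even between
   adjacent pairs.

The Darroch–McCloud degree of distinguishability is $\delta_{ij} = 1 -
1/\tau_{ij}$; it is reported from the fitted $\beta$ (model-based) rather
than from raw counts, because observed tables routinely contain zero cells
that make the empirical odds ratio undefined. The raw-count version
(`empirical_tau()`) is exposed for diagnostics and errors out loudly on a
zero cell — no continuity correction is applied by default.

Row and column main effects are always free: the fit does **not** impose
marginal homogeneity between raters, which is standard agreement-modelling
practice and leaves the likelihood-ratio degrees of freedom a function of
the association grouping alone. Marginal homogeneity enters only the
simulator (below), where it is a property of the data-generating truth.
Identifiability uses a corner constraint internally
($\lambda^A_1 = \lambda^B_1 = 0$); reported effects are re-centred to sum
to zero.

## Estimation and testing

The multinomial likelihood with fixed total is maximised through the
equivalent Poisson log-linear likelihood (the intercept absorbs $N$).
The solver is Newton–Raphson with step-halving on likelihood decrease,
convergence declared when the largest score component (observed minus
fitted sufficient statistics) falls below $10^{-10}$ relative to the table
total, and a 100-iteration cap. Failure modes are reported, not raised: an
empty observed row or column makes a main effect diverge, so such fits
return `converged = FALSE` with a diagnostic, a policy the power engine
consumes. The residual degrees of freedom are
$I^2 - (2I - 1) - (\text{number of classes})$.

Nested models are compared with the deviance difference
$\Delta G^2 = G^2_{\text{null}} - G^2_{\text{alt}}$, chi-squared with
$\Delta df$ = difference in class counts. For a 5-category scale the three
canonical alternatives — pair (1,2) free; pairs (1,2),(2,3) vs
(3,4),(4,5); extremes (1,2),(4,5) vs middle — all have $\Delta df = 1$;
the all-free alternative has $\Delta df = 3$.

## The simulator

To generate tables under a prescribed distinguishability pattern with
controlled margins, the cell probabilities are taken as
$\pi_{ij} = \exp(\mu + \lambda_i + \lambda_j - c(i,j))/N$ with
$c(i,j) = \frac{|i-j|}{2}\sum_{k=\min}^{\max-1}\beta_{k,k+1}$: a shared
$\lambda$ for both raters (marginal homogeneity between raters) plus the
symmetric association kernel. Given $\beta$ and target margins $\pi^S$,
the $I+1$ unknowns $(\mu, \lambda_1,\dots,\lambda_I)$ solve the nonlinear
system of $I$ margin equations $\sum_j \pi_{ij} = \pi^S_i$ plus the
normalisation $\sum_i \lambda_i = 0$, which keeps $\mu$ the overall
effect. Because the margin equations sum to one, the solved surface is
automatically a symmetric probability distribution with equal row and
column margins.

Numerical choices:

* Newton iteration with the analytic Jacobian, damped by residual-norm
  step-halving; residual tolerance $10^{-12}$ (contract: $\le 10^{-10}$).
* Cold start $\lambda = 0$, $\mu = \log N + 2\,\overline{\log \pi^S}$;
  along a grid of tested odds ratios each solve is warm-started from the
  previous solution (`warm_start_path()`), since the system is sensitive
  to starting values.
* If Newton fails, a symmetric iterative-proportional-fitting (Sinkhorn)
  pass on the kernel $e^{-c(i,j)}$ is used instead — valid because kernel
  and margins are symmetric, and equivalent at the fixed point.
* Margins below $10^{-3}$ are allowed with a warning: they drive
  $\lambda_i \to -\infty$ and slow convergence.
* The surface $\pi$ depends only on $\beta$ and the margins; $\mu$ absorbs
  $N$, so a solved design is re-targeted to a new sample size without
  re-solving (`design_with_n()`).

Tables are then drawn from the full multinomial
$\mathcal{M}(\pi, N)$; row and column totals are random, only $N$ is
fixed.

## Power estimation

`nua_power()` repeats draw–fit–test: one multinomial table, UA and NUA
fits, the $\Delta G^2$ test at level $\alpha$. The estimate is the
proportion of significant tests among converged replicates. Replicates
where either fit fails (in practice: an empty observed row/column at small
$N$ or sparse margins) are excluded from the denominator and reported —
assigning them to either outcome would bias the estimate by an arbitrary
convention, and the failure count keeps any such exclusion visible. A
warning fires when failures exceed 1% of replicates.

The significance level defaults to $\alpha = 0.05$; the simulated null
rejection rates (about .05–.06 at $N = 250$) confirm the calibration.
Reproducibility is by a master seed from which per-replicate seeds are
drawn up front, making results independent of evaluation order; identical
seeds give identical estimates.

`nua_power_grid()` arranges scenarios the way the tabulated grids are
laid out: the varying pairs get $\beta = \log K$ for each tested odds
ratio $K$ (default grid $1,\dots,10,12,14,16$), the fixed pairs sit at
$\log(\text{null OR})$ (3 by default, with 2 and 4 as variants), so the
$K = \text{null OR}$ row estimates the type-I error. Designs are solved
along the $K$ grid with warm starts.

### Study conditions and what the defaults emulate

The generator's defaults are the study conditions of the power tables the
package reproduces: a 5-category scale, homogeneous margins $(.2)^5$,
sample sizes $50$–$250$, null odds ratio 3, $\alpha = .05$. The simulated
tables are "ideal" agreement data: multinomial sampling, marginal
homogeneity between raters, and an association surface exactly of the
model's form. Real agreement tables can violate each of these — rater
drift (marginal heterogeneity *between* raters), clustering of objects,
association structure outside the NUA family — so passing power
reproduction here demonstrates correctness of the machinery under the
stated conditions, not that the tabulated power applies to an arbitrary
real study. The effect of marginal heterogeneity *within* raters is
covered: skewed target margins (e.g. $(.05,.15,.40,.30,.10)$) demonstrably
lower power at fixed $N$.

Monte-Carlo sizes: the tabulated grids use 10000 replicates per cell
(binomial standard error $\le .005$); the routine default is 2000
(standard error $\le .011$), which the test suite uses to keep runs to a
few seconds, and the acceptance script uses 10000.

## Interpolation and required sample size

Tabulated power grids are piecewise-linear in both directions. For an
intermediate association parameter $\beta$, power is interpolated between
the two bracketing $\beta$ rows per $N$ column; the required $N$ for a
target power then comes from inverse linear interpolation between the two
bracketing $N$ columns. All arithmetic uses full-precision stored values —
2-decimal rounding is presentation-only (`round_display()`, half away from
zero). This ordering matters: interpolating the shipped panel at
$\beta = 2.25$ gives $.725$ at $N = 150$ and $.840$ at $N = 200$
unrounded, hence a required $N$ of $182.61 \to 183$ for 80% power; using
the rounded $.73$ would give $181.82$. No extrapolation is performed
beyond either grid.

```{r worked-example}
pt <- read_power_table(system.file("extdata", "table3_panel_b.csv",
                                   package = "nuapower"))
interp_power_at_beta(pt, 2.25)
required_n(pt, beta = 2.25, target = 0.80)
```

## Design decisions that were genuinely open

* **Failure policy in power loops.** Unconverged replicates are excluded
  from the denominator rather than counted as non-significant; failure
  counts are part of the output. The alternative (counting them as
  non-rejections) deflates power at small $N$ by a convention rather than
  by evidence.
* **Free main effects in the fitted models.** Imposing marginal
  homogeneity in the *fit* would change the reference distribution of the
  tests; keeping the effects free matches agreement-modelling practice
  and the type-I calibration validates it.
* **Model-based DDs.** Reported distinguishabilities come from fitted
  $\beta$; the empirical odds ratio is a diagnostic only.
* **Newton over derivative-free root-finding** for the margin system: the
  Jacobian is analytic and cheap at these dimensions; warm starts handle
  the initial-value sensitivity; IPF is the fallback.
* **Seeding.** One master seed, per-replicate (and per-grid-cell)
  sub-seeds drawn up front: reproducible, order-independent, no external
  RNG-stream dependency.

## Limitations

* Rectangular tables, structural zeros, kappa-type summary statistics, and
  Bayesian estimation are out of scope.
* The simulator enforces marginal homogeneity between raters; differing
  row and column targets are not supported.
* DD confidence intervals are not provided.
* Problem sizes: the test suite runs grids at hundreds of replicates and
  the acceptance checks at 2000; the shipped fixture tables were tabulated
  at 10000. All are configurable through `nsim`.
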