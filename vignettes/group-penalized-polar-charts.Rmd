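---
title: "Group-penalized regression and multi-level polar coefficient charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-penalized regression and multi-level polar coefficient charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarlasso)
```

## The models

High-dimensional genomic predictors often come with a natural group
structure: SNPs fall into genetic regions, genes into pathways, probes into
genes. `polarlasso` fits the three standard sparse estimators for this
setting. For a response $y$ ($n$ samples), design $X$ ($n \times p$), and a
partition of the $p$ predictors into groups $g = 1,\dots,G$ with blocks
$\beta_g$, the fitted objectives are

* **lasso**: $\frac{1}{2n}\lVert y - X\beta\rVert_2^2 +
  \lambda\lVert\beta\rVert_1$,
* **group lasso**: $\frac{1}{2n}\lVert y - X\beta\rVert_2^2 +
  \lambda\sum_g p_g\lVert\beta_g\rVert_2$,
* **sparse group lasso**: $\frac{1}{2n}\lVert y - X\beta\rVert_2^2 +
  \alpha\lambda\lVert\beta\rVert_1 +
  (1-\alpha)\lambda\sum_g p_g\lVert\beta_g\rVert_2$,

with the squared-error term replaced by the mean logistic negative
log-likelihood for a binomial response. The lasso zeroes individual
coefficients; the group lasso zeroes whole blocks, discarding irrelevant
groups; the sparse group penalty is the convex combination of the two and is
sparse at both levels. At $\alpha = 1$ the mixed penalty **is** the lasso
penalty and at $\alpha = 0$ the group-lasso penalty, so the package routes
those settings through the identical code paths; at $\lambda = 0$ all three
objectives reduce to the unpenalized loss.

Two conventions deserve note because they move $\lambda$ by a constant
factor relative to objectives written without them:

* the smooth loss carries a $1/(2n)$ (gaussian) or $1/n$ (binomial) factor,
  which keeps $\lambda$ grids comparable across sample sizes;
* the group weights default to $p_g = \sqrt{\text{size}_g}$, the standard
  choice that stops a large group from being selected merely for its size.
  There is no canonical formula for "a weight considering group size"; the
  square root is an assumption, and `group_weights` overrides it per group.

## The solver

The objectives are convex but nonsmooth, so the package uses deterministic
cyclic block proximal descent. One sweep visits each group (each coordinate
for pure-$\ell_1$ fits) in first-appearance order and applies a gradient
step on the smooth loss at the exact block Lipschitz step size
$1/L_g$, $L_g = \lambda_{\max}(X_g^\top X_g)/n$ (times $1/4$ for the
logistic loss, whose curvature never exceeds that bound), followed by the
two-stage proximal map: elementwise soft-thresholding at
$\alpha\lambda/L_g$, then block soft-thresholding at
$(1-\alpha)\lambda p_g/L_g$. Because the steps majorize the loss no line
search is needed, every sweep decreases the objective, and the whole
procedure is reproducible to the last bit. The binomial intercept takes an
unpenalized gradient step at the same $1/4$-curvature bound.

Paths are computed on a decreasing log-spaced $\lambda$ grid (default 100
values) starting at `lambda_max()` — the smallest $\lambda$ whose
stationarity conditions admit the all-zero solution, computed in closed
form for the pure penalties and by bisection for the mixed one, with a
$10^{-10}$ relative safety margin so floating-point ties cannot leak the
argmax group into the "zero" fit. The grid floor is `1e-4` of the top for
gaussian fits with $p \le n$, and `1e-2` otherwise and for binomial fits,
where the tail of the path approaches a (near-separable) unpenalized
logistic fit that is expensive and statistically uninteresting. Warm starts
carry each solution to the next $\lambda$. Convergence is declared when the
largest coefficient change in a sweep, relative to $\max(1, \max_j|\beta_j|)$,
drops below `tol` (default $10^{-7}$); a sweep cap (default $10^5$) turns
non-convergence into a warning plus a `converged = FALSE` flag, never a
silent wrong answer. Columns are centered and scaled to unit variance by
default and coefficients mapped back to the original scale; constant
columns get coefficient 0 with a warning.

Solutions can be certified after the fact: `check_optimality()` evaluates
the subgradient stationarity conditions and returns the largest violation
(zero groups must satisfy
$\lVert S(\nabla_g, \alpha\lambda)\rVert_2 \le (1-\alpha)\lambda p_g$;
active coordinates must satisfy exact stationarity). The test suite also
re-solves each instance with an independent full-vector accelerated
proximal-gradient (FISTA) implementation and, for the lasso, with glmnet,
and compares objective values; agreement is at machine precision on the
instances tested.

## Cross-validation

`cv_pl_fit()` fixes the $\lambda$ grid on the full data, refits on each of
$k$ fold complements (default $k = 10$), and evaluates the held-out squared
error (gaussian) or binomial deviance at every $\lambda$. `cvm` is the mean
of the per-fold mean losses and `cvsd` their standard deviation over folds
divided by $\sqrt{k}$ — a fold-level standard error, the convention of the
established path-fitting packages; sample-level alternatives exist but are
not offered. Folds are balanced to within one sample, stratified by class
for binomial responses, and a deterministic function of `(n, k, seed)`.
`select_lambda()` implements the two standard rules: `"min"` takes the
$\lambda$ minimizing `cvm` (ties resolved toward the larger, sparser
$\lambda$), `"1se"` the largest $\lambda$ with `cvm` within one standard
error of that minimum. The 1se rule therefore always returns a $\lambda$ at
least as large as the min rule and, in the package's reference simulations,
keeps at most as many variables in essentially all replicates.

## The chart

A fitted coefficient vector with hundreds of groups is hard to read from a
table. The multi-level polar chart summarizes it in one figure:

* **outer level** — one sector per selected group (a group survives if any
  member coefficient is nonzero). The circle is split into equal angles,
  counterclockwise, the rank-1 group starting at 0°. Ranking uses the
  group's feature: the maximum (`sort_type = "max"`, default) or mean
  (`"mean"`) of the absolute member coefficients. Sector radius is the
  feature divided by the largest feature, so the top group has radius 1.
  Sector color encodes the number of displayed variables in the group —
  brighter means smaller, darker larger — normalized over the displayed
  groups only, so the spectrum readjusts after `max_shown` truncation.
* **inner level** — one point per selected variable, at relative radius
  $|\beta_j| / \max_{j' \in g}|\beta_{j'}|$, always against the group's own
  maximum even under `sort_type = "mean"` (otherwise points could overshoot
  their sector radius; the sector radius itself still uses the chosen
  feature). Symbols encode the sign (circle positive, square negative);
  each point is jittered angularly — uniform within the central 80% of the
  sector, seeded, never radially, since the radius carries meaning — and
  carries a "group / variable / coefficient" tooltip with the coefficient
  printed to 4 decimals.

For a plain lasso fit there are no groups: every selected variable becomes
its own size-1 sector containing one point at radius 1, and in the
interactive rendering the whole sector is a hover target.

The geometry is computed by `summarize_groups()` →
`apply_max_shown()` → `compute_layout()` → `assign_styles()` (or the
one-call `chart_layout()`), entirely independent of any drawing backend,
and serializes to a documented JSON schema. `render_static()` writes
byte-deterministic SVG (or PNG); `render_interactive()` writes a single
self-contained HTML file whose tooltips are native SVG `<title>` elements,
so no JavaScript dependency is bundled. Groups whose coefficients are all
zero are omitted rather than drawn as zero-radius sectors — a chart of
selected groups, not of the full dictionary.

```{r, eval = FALSE}
sim <- generate_dataset(sim_config(seed = 1))
cv <- cv_pl_fit(sim$data, group = sim$groups, method = "grouplasso",
                k = 10, seed = 1)
lay <- chart_layout(cv, lambda_type = "min", sort_type = "max")
render_interactive(lay, "chart.html")
```

## The synthetic-data generator

`generate_dataset()` draws block designs with exchangeable within-group
correlation $\rho$ (each column is $\sqrt{\rho}\,z_g + \sqrt{1-\rho}\,e_j$
with a shared group factor), independent across groups — a one-parameter
structure that is easy to verify empirically, chosen over AR(1) for that
reason. Truth is group-sparse: `n_active` groups drawn at random, a
`within_frac` fraction of members active inside them, magnitudes uniform on
`effect_range` with random signs. Gaussian noise is set from a target
signal-to-noise ratio $\mathrm{SNR} = \mathrm{var}(X\beta)/\sigma^2$
(default 5) unless $\sigma$ is given; binomial responses are
Bernoulli-logistic. The default configuration — $n = 200$, $G = 10$ groups
of 5, 3 active groups, $\rho = 0.3$, SNR 5 — is the package's reference
scenario for its selection-behavior and support-recovery tests; $\rho=0.3$
is a moderate within-region dependence typical of grouped genomic
predictors.

What the generator does **not** emulate: linkage-disequilibrium decay,
allele-frequency spectra, discrete genotype coding, heavy-tailed expression
noise, or batch structure. Tests passing on these simulations certify the
optimization, selection, and geometry machinery — not that any particular
real dataset will be recovered equally well.

## Numerical choices and edge cases

* Prox thresholds compare $\lVert v\rVert_2 \le t$ inclusively, so a block
  exactly at the boundary collapses to zero (and `lambda_max` carries the
  safety margin described above).
* Ranking ties are broken lexicographically by group label; CV ties toward
  the larger $\lambda$.
* Binomial deviances clamp probabilities to $[10^{-10}, 1-10^{-10}]$.
* An all-zero coefficient vector is an error at charting time (with a hint
  to lower $\lambda$), not an empty plot.
* A single selected variable yields one 360° sector of radius 1.
* Problem sizes in the shipped tests (instances of $n = 50$, $p = 20$,
  $G = 5$ for oracle certification; 50 replicates of the $n = 200$
  reference scenario for selection rates) were chosen as the smallest sizes
  at which the tested properties are stable, so the whole suite runs in
  well under a minute of compute.

## Limitations

Overlapping groups, Cox and multinomial families, adaptive per-feature
penalties, and screening rules (strong rules, SAFE) are out of scope; the
solver favors correctness and determinism over raw speed and is intended
for desk-scale problems (thousands of predictors, not millions). Numeric
agreement with other implementations' default grids is not promised — only
agreement with the minimizers of the objectives above, which the KKT and
oracle checks certify.
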