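---
title: "Methods: geodetector screening, maximum-entropy modelling and range forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geodetector screening, maximum-entropy modelling and range forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangecast)
```

`rangecast` implements a complete workflow for forecasting where a
species can live under current and shifted climates: screen candidate
environmental variables by their spatially stratified association with
occurrences (the geodetector q-statistic), fit a presence/background
maximum-entropy distribution model on the retained variables, project
suitability onto current and perturbed climate stacks, and summarise the
outcome as class areas, range gains and losses, centroid displacement
and extrapolation (MESS) diagnostics. This vignette documents the models,
the numerical choices, and what the synthetic test bed does and does not
establish.

## The geodetector factor detector

Spatial stratified heterogeneity asks how much of a response's variance
disappears when the study area is partitioned by the classes of an
explanatory variable. For a response $y$ over $N$ sample units
partitioned into $L$ strata with sizes $N_h$ and population variances
$\sigma_h^2$,

$$q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N\sigma^2}
    = 1 - \frac{SSW}{SST},$$

so $q \in [0,1]$, with $q = 1$ exactly when every stratum is internally
constant. We use divisor-$N$ (population) variances so the $q = 1$
boundary is attained exactly on pure strata. `factor_q()` exposes the
full decomposition ($SSW$, $SST$, per-stratum pieces), and the suite
checks it against a brute-force grouped-variance oracle on a thousand
random instances.

The screening pipeline (`screen_variables()`) follows the workflow this
statistic is used for in invasion-risk mapping:

1. a **fishnet** lattice of sampling points is laid over the valid cells
   at 10 km spacing (`build_fishnet()`); kilometres are converted to
   degrees with 111.32 km/degree and the cosine of the grid's mean
   latitude for longitude;
2. the response is **binary presence** per fishnet cell: 1 when at least
   one occurrence falls in the square of side equal to the spacing
   centred on the point (a count response is available via
   `presence_response(response = "count")`);
3. each variable is discretised into $L = 5$ classes by **Fisher–Jenks
   natural breaks** (`jenks_breaks()`), the exact dynamic program run on
   the unique values with multiplicities — for one-dimensional
   contiguous least-squares partitions an optimum never needs to split
   tied values, so equal values always receive equal strata;
4. variables with $q$ **strictly greater than 0.1** are retained.

Classes are lower-closed: a value equal to a break belongs to the upper
class, and breaks are reported as the minimum of each upper class so
stratification reproduces the optimal partition exactly.

Significance is assessed by a permutation test:
$p = (1 + \#\{q_{\text{perm}} \ge q_{\text{obs}}\})/(B + 1)$ with $y$
permuted against the stratum labels. The original geodetector software
uses a noncentral-F approximation instead; we prefer the permutation
construction because it is assumption-free and exact under the null,
and the two rank variables identically. Permutations default to 199 in
the pipeline (a floor of 99 is enforced; below that the p-value is not
computed).

## The maximum-entropy model

Given presence samples and a background sample of the landscape, the
model is the Gibbs distribution over background cells

$$p_\lambda(x) \propto \exp\!\big(\textstyle\sum_j \lambda_j f_j(x)\big),$$

with features $f_j$ built from the raw variables in five classes —
linear, quadratic, pairwise products, hinge (forward and reverse, 50
knots per variable per direction at equispaced quantiles of the training
values) and threshold step indicators at the same knots. Features are
min–max normalised to $[0,1]$ on the training data; hinge and threshold
features are in $[0,1]$ by construction. The fit maximises the penalised
presence log-likelihood

$$\ell(\lambda) = \frac1m \sum_{i} \lambda^\top f(x_i) - \log Z_\lambda
  - \sum_j \beta_j \, RM \, |\lambda_j|,$$

where $\beta_j$ follows the published per-class default schedules
(linear/quadratic/product interpolate $(10,30,100) \to (1.0,0.2,0.05)$
in the presence count, hinge is $0.5$, threshold interpolates
$(10,100)\to(2.0,1.0)$), scaled by the feature's presence-sample
standard deviation over $\sqrt m$. The presence sd is floored at
$10^{-3}$ as a numerical guard for features constant on presences. The
regularization multiplier `rm` scales all penalties at once and is the
user-facing overfitting dial.

**Optimizer.** Cyclic coordinate descent with exact soft-threshold
updates on a quadratic model of each coordinate, objective-guarded step
halving, and an active set consisting of nonzero coordinates plus
KKT-violating ones. The fit is declared converged when every feature
satisfies the stationarity condition

$$\big|\bar f_j^{\text{presence}} - E_{p_\lambda}[f_j]\big| \le \beta_j RM + \varepsilon,$$

with $\varepsilon$ = `kkt_tol` = $5\times10^{-5}$ by default. This
condition is the central correctness oracle of the test suite: it is
checkable independently of the optimisation path. An iteration cap of
500 sweeps mirrors the conventional default. With a single binary
feature and no penalty the optimum has the closed form
$\lambda = \log\frac{\bar p (1-\bar b)}{(1-\bar p)\bar b}$, which the
suite verifies to $10^{-6}$.

**Outputs.** Raw output normalises to 1 over the training background.
With $H$ the entropy of the fitted background distribution, the
logistic output is $r e^H/(1 + r e^H)$ and the default cloglog output
$1 - \exp(-r e^H)$, matching the convention of recent maximum-entropy
SDM software; the all-zero model therefore scores $1 - e^{-1} \approx
0.632$ everywhere. Projection clamps each variable to its training range
by default so feature extrapolation is frozen at the range edge.
Duplicate presences within one grid cell are collapsed to a single
record before training.

`tune_maxent()` sweeps `rm` over 0.5–4 by 0.5 against the six feature
combinations L, LQ, H, LQH, LQHP and LQHPT on a fixed seeded 75/25
presence split and reports AUC and gain for all 48 fits without
selecting one — parameter choice is left to the analyst.

## Evaluation

ROC AUC is computed by ranks as the Mann–Whitney probability that a
presence outscores a background point (ties count half). The headline
evaluation mode is a single seeded 75/25 split, with the held-out count
taken as `round(0.25 n)` (round half up); 10-fold cross-validation is
available via `cross_validate()`. Variable influence is reported three
ways, mirroring conventional SDM reports:

- **percent contribution** — positive per-update training-gain
  increments accumulated onto each updated feature's source variables
  (product features split equally), normalised to 100;
- **permutation importance** — the training-AUC drop when one
  variable's column is permuted jointly across presence and background
  rows, negative drops floored at zero, normalised to 100;
- **jackknife gains** — the regularized training gain of each
  with-only-this-variable and without-this-variable refit next to the
  full-model gain.

Response curves are marginal: one variable sweeps its training range
while all others sit at their background means. `optimal_range()`
extracts the maximal intervals where the predicted suitability meets a
threshold (0.6 by default, the highly-suitable cut) plus the argmax.

## Spatial reporting

Suitability is classified with lower-closed bins at 0.1/0.3/0.6 into
unsuitable, poorly, moderately and highly suitable. Areas are spherical:
a cell in rows spanning latitudes $[\varphi_b, \varphi_t]$ contributes
$R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)$ with $R$ = 6371 km;
against an ellipsoid the error is far below the two-decimal rounding of
the reported $10^4$ km² tables, and a global grid tiles $4\pi R^2$ to
within 0.01%. Range change compares binary maps (default cut: any
suitable class, configurable via `min_class` — the reclassification cut
is exposed rather than fixed because published stable+loss totals do
not always equal the current suitable total). Centroids are
spherical-area-weighted means of suitable cell centres, uniform over
the binary mask; displacement uses the haversine on the same sphere.

MESS uses the standard percentile construction: with $f$ the percent of
reference values strictly below the cell value, similarity is $2f$ for
$f \le 50$, $2(100-f)$ for $f < 100$, and scales linearly into negative
values beyond the reference minimum or maximum; a cell's $S$ is the
minimum over variables and the minimising variable is recorded. Strict
"less than" resolves ties toward the smaller percentile. $S = 100$ is
attained only at the multivariate reference median and $S < 0$ exactly
flags extrapolation.

## The synthetic test bed

Because real occurrence records and climate rasters cannot ship with
the package, every downstream stage is exercised on a virtual species
whose truth is known (`synthetic_scenario()`):

- **Fields.** Seven layers on a 60 × 80 grid of 0.05° cells (a 3° × 4°
  window): temperature-like fields are a latitudinal gradient plus
  kernel-smoothed Gaussian noise, precipitation-like and noise fields
  are pure smoothed noise; all are standardised. The smoothing radius
  is 1 cell (≈ 5 km), enough for clear positive Moran's I while leaving
  many effectively independent patches in the window — important
  because the geodetector's null distribution widens as spatial
  autocorrelation eats degrees of freedom.
- **Truth.** $\text{suitability} = \text{logit}^{-1}(\beta_0 + \sum
  \beta_i x_i + \sum \gamma_i x_i^2)$ with defaults $\beta =
  (3, 2.5, 3, -3)$ on two temperature and two precipitation variables,
  one negative quadratic ($\gamma_{temp1} = -1.5$, interior optimum at
  $x^\* = 1$), and $\beta_0 = -8$. The strong per-SD effects describe a
  climate-specialist; the low intercept keeps mean suitability near
  6–7% of the landscape, comparable to a restricted invasive. These
  values were fixed once as the package's study conditions.
- **Occurrences.** 200 distinct cells drawn without replacement with
  probability proportional to suitability, matching the
  one-record-per-cell deduplication used in training.
- **Futures.** Additive warming (+2 standardised degrees by default) on
  temperature-tagged layers and a ×1.15 factor on precipitation-tagged
  layers.

What passing tests show: the q-statistic and the fitted model rank the
truly informative variables above pure-noise fields, held-out AUC
typically lands near 0.93, and the response-curve optimum recovers the
generating quadratic's optimum to a few percent of the variable's
range. What they do not show: behaviour under strong inter-variable
correlation (real bioclim variables are heavily collinear; the
synthetic fields are independent by design), sampling bias in
occurrences, or coastline-shaped nodata masks. AUC values on real
presence-only data also depend on prevalence and extent and are not
comparable to the synthetic numbers.

## Numerical choices and edge cases

- `factor_q()` raises an explicit error when the response is constant
  ($SST = 0$) rather than returning NaN.
- `jenks_breaks()` requires at least $L$ distinct finite values; the
  screening wrapper lowers $L$ per variable when necessary.
- Background sampling caps the request at the number of jointly valid
  cells, with a message.
- Nodata propagates: a sample or projection cell is invalid if any
  layer is nodata there.
- Point-in-cell assignment uses half-open cells with boundary points
  going to the east/south neighbour, except on the extent edge where
  they are pulled inside; an exactly-reproducible rule matters because
  occurrence cells and fishnet cells feed deterministic counts.
- Coordinate-descent steps are capped at ±10 per update with objective
  step-halving, and the background weight vector is rescaled before it
  can overflow.
- All randomness (fields, occurrence draws, splits, background,
  permutations) flows through explicit integer seeds; a pipeline run is
  bit-reproducible given its config and seed.

Test problem sizes (a 30 × 40 grid for unit fixtures, the 60 × 80
default scenario for recovery checks, 30–50 seed replicates, reduced
hinge-knot counts for models refit many times) were chosen to keep the
default suite in the low minutes while leaving every statistical
assertion comfortably powered.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  scenario = synthetic_scenario(seed = 1),
  geodetector = list(n_permutations = 199, q_threshold = 0.02),
  model = list(fc = "LQH", n_knots = 10, background_n = 4800),
  seed = 1
)
run <- run_pipeline(cfg, "my_run")
make_report("my_run")
```

The run directory holds every artifact as plain text (`.asc` rasters,
CSV tables, a human-diffable model lambdas file and a timing log), and
`make_report()` rebuilds the summary tables from those artifacts alone,
recomputing percent changes from the persisted areas so every derived
number remains auditable.
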