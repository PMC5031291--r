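---
title: "Calibrating cell population growth models with cellpopfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating cell population growth models with cellpopfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpopfit)
```

## The problem

Cell-count time series — live, dead, or total cells per well, measured a
handful of times over a few days — are among the most common outputs of
cell biology and high-content screening (HCS) experiments. Turning them
into biologically meaningful numbers (a growth rate with an honest error
bar, a carrying capacity, separate birth and death rates) usually means
ad hoc spreadsheet regressions that silently differ between labs.
`cellpopfit` makes that analysis systematic: one spreadsheet in, a
ranked set of calibrated dynamical models out, with uncertainty
estimates and reproducible reports.

## Models

Six canonical models are registered (`model_registry()`), all in hours
and 1/h:

* **live**, **total** — net exponential growth, $dN/dt = r\,N$. $r$ is a
  *net* rate (birth minus death) and may be negative for a shrinking
  culture.
* **live_logistic**, **total_logistic** — logistic growth,
  $dN/dt = r\,(1 - N/K)\,N$, capturing confluence or substrate
  depletion through a carrying capacity $K$.
* **live_dead** — a two-compartment birth–death–clearance model:
  $d[\mathrm{Live}]/dt = (b - d)[\mathrm{Live}]$,
  $d[\mathrm{Dead}]/dt = d\,[\mathrm{Live}] - c\,[\mathrm{Dead}]$.
  The clearance rate $c$ is the rate at which dead cells degrade or stop
  being recognised by cell-detection software.
* **live_dead_logistic** — the same with logistic suppression of birth.

All but the last have closed-form solutions, which the package uses for
exactness and speed inside the optimisation loop. The linear dead-cell
equation has the resonant case $b - d + c = 0$; it is handled by the
analytic limit $(D_0 + d L_0 t)e^{-ct}$, triggered when
$|b - d + c| < 10^{-12}$/h. `live_dead_logistic` is integrated with an
adaptive-step solver (lsoda) at relative tolerance $10^{-8}$ and
absolute tolerance $10^{-6}$ cells — two orders tighter than anything
the tests assert about trajectories.

Initial conditions are *fitted* parameters, started at the first
observation, so measurement noise at $t_0$ does not anchor the fit.
Mechanistic rates ($b$, $d$, $c$) are constrained nonnegative; net rates
may be negative. One numerical caveat: the logistic equation with a
negative rate and a starting population *above* capacity diverges in
finite time — this is a property of the equation, not of the code, and
such parameter combinations are not admissible cultures.

## Calibration

Replicates are aggregated per time point into a mean and a sample
standard deviation $\sigma_i$ (replicates must share one time grid to
within $10^{-6}$ h; the package never interpolates and never smooths).
Calibration minimises the weighted sum of squared errors

$$\mathrm{WSSE} = \sum_i \frac{1}{\sigma_i}
  \frac{(\mathrm{Data}_i - \mathrm{Sim}_i)^2}{\mathrm{Data}_i}$$

with the Levenberg–Marquardt algorithm. Two conventions in this
objective deserve comment, because they are deliberate: the weight uses
$1/\sigma_i$ (not the conventional $1/\sigma_i^2$) and additionally
divides by $\mathrm{Data}_i$. This is the exact historical form of the
metric this package reproduces, and it is implemented verbatim rather
than normalised to a textbook chi-squared — the two agree about which
fit is perfect, but differ in relative weighting. Consequences: points
with $\sigma_i = 0$ (identical replicates) or a single replicate get
unit weight with a logged warning, and points with
$\mathrm{Data}_i = 0$ are excluded from WSSE and MAPE with a warning,
since both formulas are undefined there.

Fit quality is summarised by

$$\mathrm{MAPE} = \frac{1}{N}\sum_i 100\,
  \frac{|\mathrm{Data}_i - \mathrm{Sim}_i|}{\mathrm{Data}_i},
  \qquad
  \chi^2_\nu = \frac{\mathrm{WSSE}}{N_\mathrm{data} - N_\mathrm{params}},$$

and per-parameter uncertainty by
$\mathrm{SEM}_i = \sqrt{\chi^2_\nu\,\mathrm{Cov}(i,i)}$, where Cov is
the unscaled inverse of $J^\top J$ for the weighted-residual Jacobian
$J$, computed by central finite differences at the optimum (with an SVD
pseudo-inverse fallback if $J^\top J$ is singular). A model with $n$
parameters requires at least $n$ data points to fit and $n + 1$ to
report $\chi^2_\nu$ and SEMs; below $n$ points the fit refuses with a
typed error.

Starting values are deterministic and scale-aware — the net rate from a
log-linear regression on the positive means, capacities at twice the
maximum observed count, death at 10 % of the net-rate guess, clearance
at 0.01/h, initial populations at the first observations — and there is
no random multistart, so a fit is bit-reproducible given identical
input. Bounds are generous but finite (rates in [0, 10]/h, net rates in
[−10, 10]/h, capacities up to $10^6\times$ the largest observation).

Confidence intervals are symmetric, $\hat\theta \pm z\,\mathrm{SEM}$
with the normal quantile (1.96 at 95 %) by default; a Student-t
multiplier with $N_\mathrm{data} - N_\mathrm{params}$ degrees of
freedom is available. The normal default was chosen because neither
convention is decisively better at the handful of points typical here,
and z is the more common reporting convention for this metric family.

Model *selection* is automatic from the data shape: live counts alone
admit the exponential and (with ≥ 3 points) logistic live models;
live + dead counts additionally admit the birth–death–clearance pair
and the total-count models (the total series is derived replicate-wise
as live + dead). Each candidate must have at least as many data points
as parameters. Fitted models are *ranked* ascending by reduced
chi-squared and by MAPE (both orderings are always reported); ties break
towards fewer parameters, then model name.

## The synthetic screen generator

`generate_screen()` produces a drug screen with known ground truth for
validating the cytostatic/cytotoxic decomposition: two drugs × 5 doses
× 5 biological replicates of live and dead counts. The defaults emulate
an adherent cancer line in an HCS platform:

* baseline birth 0.04/h and death 0.005/h (net 0.035/h, a ~20 h
  doubling time), clearance 0.005/h, wells seeded at 1000 live cells
  with a 10-cell dead/debris baseline;
* a half-log dose ladder 0.1–10 with EC50 = 1 and Hill slope 1 — the
  minimal standard monotone dose–response;
* the **cytostatic** archetype multiplies the birth rate by
  $1 - e_{\max}\mathrm{Hill}(\mathrm{dose})$ with $e_{\max} = 1$, so the
  net rate dips slightly negative at top dose; the **cytotoxic**
  archetype multiplies the death rate by
  $1 + 5\,\mathrm{Hill}(\mathrm{dose})$, producing a deliberately
  shallow net-rate response. Together they reproduce the classic trap:
  the drug whose *net* rate collapses is the one that merely stops
  division, and only the birth/death decomposition says so.
* multiplicative Gaussian noise, mean 1 and CV 0.10 per well and time
  point (clipped at zero), approximating combined instrument and
  biological variability;
* measurements every 12 h over 72 h. The sampling density is a design
  choice worth explaining: HCS platforms image wells repeatedly over a
  run, and the five-parameter birth–death–clearance model *needs* that
  density. With only three time points the model has one residual
  degree of freedom and an almost flat ridge in the (death, clearance)
  plane — the live series constrains only $b - d$, and for large $c$
  the dead series approximates $d\,L_0 e^{(b-d)t}/(b-d+c)$, so noise can
  push the decomposition arbitrarily far along the ridge while
  *improving* the objective. Seven time points pin the transient and
  make the decomposition stable (mean recovery errors of ~5 % per rate
  class at 10 % noise).

The generator is fully seeded (the seed is mandatory): a fixed seed
reproduces byte-identical datasets. The ground truth is written next to
the dataset so recovery is auditable, and the generated bundle is a
first-class input to the fitting pipeline.

What the generator does *not* emulate: systematic (non-Gaussian,
correlated) segmentation errors, edge effects across a plate,
pharmacokinetics or time-varying dosing, and resistance dynamics. A
passing recovery test therefore demonstrates statistical identifiability
under well-behaved noise, not robustness to every failure mode of real
imaging pipelines.

## Input format

The single input is a spreadsheet workbook (XLSX/XLS) or an equivalent
CSV bundle, hand-editable in any office suite. Each observable gets a
`Data_<Observable>` sheet (`data_<observable>.csv`) with columns
`condition`, `time`, `rep_1`, `rep_2`, …; a `Conditions` sheet maps
conditions to environment variables (drug, dose); `Metadata` and `User`
are key–value sheets. An explicit condition column (rather than a
column-group map) keeps the layout self-describing and losslessly
round-trippable. Times may be in hours, minutes or days
(`time_unit` key) and are converted to hours on load. Parsing is
strict: no silent numeric coercion, every bad cell reported with sheet,
row and column, and no partial datasets. Optical-density series are
accepted as proportional counts.

`subsample_series()` supports sampling-sparsity experiments: it keeps
the native points nearest to $t_0 + k\Delta$ and is deterministic,
idempotent and monotone (a coarser interval never yields more points).
Where a historical sample-count table implies a different truncation
convention at the series end, ours — anchor at the first point,
truncate at the last native time — is the declared one.

## Reports

`render_report()` writes a self-contained local HTML directory: an
index ranking every fitted model per condition by both metrics, a page
per model with a layperson description, LaTeX equations, parameter
table (SEM and CI) and metrics, growth-curve figures (linear and log
scale; colour and black-and-white variants using marker shape and line
style), tables in CSV and TSV, and a minimal hierarchical phenotype XML
record (cell line identity, model, parameters with units and SEM,
metrics, provenance) that round-trips bit-exactly. The XML schema is a
deliberately minimal stand-in for a full community phenotype standard,
with the extension point left explicit. Report content is a pure
function of the fits — the single timestamp lives in one provenance
field and is injectable, so rendering is byte-reproducible.
Dose–response panels (`plot_dose_response()`) plot net, birth and death
rates against dose with SEM bars, reading every number from the fit
results rather than recomputing anything. Spreadsheet-format tables are
emitted as CSV and TSV.

## Problem sizes used in the tests

The shipped tests run the whole pipeline at desk scale: trajectory
oracles on 100 randomised parameter sets over 0–100 h; noiseless
recovery for all six models on 7-point grids; the recovery study on 20
seeded screens (2 drugs × 5 doses × 5 replicates × 7 time points each);
and sparsity fits from 95 points down to 2. These sizes were chosen so
the full suite exercises every code path in well under a minute while
keeping the statistical claims meaningful.

## Known limitations

* The WSSE convention is reproduced verbatim (see above); comparisons
  with tools using $1/\sigma^2$ weighting will differ in borderline
  rankings.
* The birth–death decomposition needs dead-cell counts with enough time
  points; with three or fewer the clearance rate is effectively
  unidentifiable and only the net rate should be trusted.
* Gompertz growth, cell-cycle compartments, pharmacodynamics models,
  bootstrap/cross-validation uncertainty, and user-defined models are
  out of scope.
* No data smoothing is ever applied — by design, which is also why the
  fits keep working at very low sample counts where smoothing-based
  estimators break down.

## A worked example

```{r example, eval = FALSE}
gen <- run_generate(output_dir = "screen_data", seed = 42)
res <- run_fit("screen_data", "screen_report", models = "live_dead")
rec <- recovery_report(read_truth_table(gen$truth_path),
                       lapply(res$fits, `[[`, "live_dead"))
rec[c("birth", "death", "net")]
```
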