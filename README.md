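# cellpopfit

Calibration of canonical cell population dynamics models to time-series
cell counts — a "phenotype digitizer" for growth experiments.

Biologists routinely measure live/dead/total cell counts over time (plate
readers, high-content screening, manual counts) and need biologically
meaningful parameters out of them: a net growth rate with an honest error
bar, a doubling time, a carrying capacity, or separate birth and death
rates that distinguish a *cytostatic* drug (stops division) from a
*cytotoxic* one (kills cells). `cellpopfit` does this systematically from
a single spreadsheet, for users who would otherwise hand-roll regressions
in a spreadsheet.

## What it computes

Six registered models (time in hours, rates in 1/h):

| model | dynamics | parameters |
|---|---|---|
| `live`, `total` | dN/dt = r·N | r, N₀ |
| `live_logistic`, `total_logistic` | dN/dt = r·(1 − N/K)·N | r, K, N₀ |
| `live_dead` | dL/dt = (b − d)·L; dD/dt = d·L − c·D | b, d, c, L₀, D₀ |
| `live_dead_logistic` | dL/dt = b·(1 − L/K)·L − d·L; dD/dt = d·L − c·D | b, d, c, K, L₀, D₀ |

Closed forms are used wherever they exist; only `live_dead_logistic` is
integrated numerically. Each applicable model (chosen automatically from
the observables and point counts) is calibrated by Levenberg–Marquardt
minimisation of the weighted sum of squared errors

    WSSE = Σᵢ (1/σᵢ) · (Dataᵢ − Simᵢ)² / Dataᵢ

where σᵢ is the replicate standard deviation of point i. Fit quality is
reported as MAPE and reduced chi-squared χ²ν = WSSE/(N_data − N_params);
parameter uncertainty as SEMᵢ = sqrt(χ²ν · Cov(i,i)). Models are ranked
by both metrics. A seeded synthetic high-content-screen generator with
known ground truth (cytostatic and cytotoxic drug archetypes on a Hill
dose–response) validates recovery of the birth/death decomposition.

## Worked example

Fit the bundled template workbook (one untreated culture, live counts at
0/24/48 h, three replicates) and inspect the best-ranked model:

```r
library(cellpopfit)
tmpl <- system.file("extdata", "template_live", package = "cellpopfit")
res <- run_fit(tmpl, "report_dir", formats = "png")
best <- rank_models(res$fits$control)[[1]]
best
#> <fit_result 'live': n_data=3, WSSE=3.312e-05, MAPE=0.0584%, chi2_nu=3.312e-05>
#>                  estimate          sem  unit
#> growth_rate     0.0294072 3.194137e-05   1/h
#> initial_live 1010.4586853 9.979034e-01 cells
doubling_time(best$estimates[["growth_rate"]])
#> [1] 23.57066
```

The culture grows at 0.0294/h — a doubling every 23.6 h — starting from
about 1010 cells; the tiny MAPE says the exponential model explains the
counts to a twentieth of a percent. `report_dir/index.html` ranks all
fitted models with figures, parameter tables (CSV/TSV) and a phenotype
XML record.

Synthetic drug screen, end to end:

```r
gen <- run_generate("screen_data", seed = 42)       # 2 drugs x 5 doses x 5 reps
res <- run_fit("screen_data", "screen_report", models = "live_dead")
rec <- recovery_report(read_truth_table(gen$truth_path),
                       lapply(res$fits, `[[`, "live_dead"))
unlist(rec[c("birth", "death", "net")])   # mean |%| error per rate class
```

The same two subcommands are exposed as a shell tool:

```sh
Rscript inst/scripts/cellpopfit.R generate --outdir screen_data --seed 42
Rscript inst/scripts/cellpopfit.R fit --input screen_data --outdir screen_report
```

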