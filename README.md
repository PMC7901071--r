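# soarhmm

Unsupervised behavioral-state classification for seabird biologging data.
`soarhmm` takes raw tri-axial accelerometer (g) and magnetometer (µT)
streams from back-mounted tags, and decodes each 30-s window of a
deployment into one of three major movement modes — **flapping flight**,
**soaring flight**, or **on-water** — producing behavioral time series,
classification-accuracy tables, bout structures, and time-activity
budgets. It is written for movement ecologists working with
albatross-like IMU deployments, but every stage is generic: any regularly
sampled tri-axial record with kinematically distinct modes fits the same
pipeline.

The package covers the full chain:

* **Preprocessing** — decimation to 25 Hz, tag roll-offset estimation
  from resting-on-water data, magnetometer trimming/median filtering,
  data-driven hard/soft-iron ellipsoid calibration, and tilt-compensated
  heading.
* **Features** — fixed 30-s windows summarized into dominant heave
  frequencies (`df`, `hf`), static-heave statistics (`ms`, `ss`, `p5`),
  dynamic-heave spread (`iqr`), mean ODBA (`mo`), and the circular SD of
  heading (`sh`), plus a correlation screen for selecting a minimally
  correlated working set.
* **Model** — an N-state hidden Markov model with per-feature Weibull
  state distributions and multinomial-logit transition probabilities,
  optionally modulated by a species covariate. Writing `f_i(x_t)` for the
  product of Weibull densities of window `t`'s features under state `i`,
  the likelihood per individual is the forward product
  `δᵀ diag(f(x₁)) Γ(c) diag(f(x₂)) … Γ(c) diag(f(x_T)) 1`, where
  `Γ(c)` is the row-stochastic transition matrix of covariate level `c`
  with `γ_ij = exp(η_ij)/Σ_j exp(η_ij)`, `η_ii = 0`. Fitting uses 25
  random restarts of Baum–Welch EM with a quasi-Newton polish; decoding
  uses the Viterbi algorithm; diagnostics use forecast pseudo-residuals
  and AIC.
* **Evaluation** — seeded validation-window sampling, confusion matrices
  with exact Clopper–Pearson intervals, per-group (species) accuracy,
  bout extraction, and activity budgets.
* **Synthetic truth** — a seeded generator that renders raw 25 Hz
  deployments (flapping oscillations, dynamic-soaring heading arcs with
  banked turns, on-water swell, magnetometer iron distortion, tag-mount
  roll offsets) from a window-scale Markov chain with known states, so
  the whole pipeline is testable without field data.

## Worked example

Simulate a four-bird deployment, run the full pipeline (preprocess →
features → HMM fit → label → decode → evaluate), and inspect the results:

```r
library(soarhmm)

cfg <- generator_config(n_individuals = 4, windows_per_individual = 150,
                        seed = 11)
dep <- simulate_deployment(cfg)
run <- run_pipeline(dep, utils::modifyList(default_run_config(),
                                           list(trim_start_s = 0,
                                                n_restarts = 8)))
run
#> <soarhmm pipeline run>
#>   600 windows, 4 individuals
#>   loglik 3490.6, AIC -6917.3, 1/8 restarts at the optimum
#>   decoded-vs-truth accuracy: 100.0%

tidy(run$fit)
#> # A tibble: 9 × 5
#>   state feature  shape  scale   mean
#>   <chr> <chr>    <dbl>  <dbl>  <dbl>
#> 1 soar  hf        8.33 0.211  0.200
#> 2 soar  p5       19.2  1.10   1.07
#> 3 soar  sh       23.3  1.09   1.06
#> 4 water hf        5.40 0.108  0.0994
#> 5 water p5      126.   1.05   1.05
#> 6 water sh        2.94 0.0258 0.0230
#> 7 flap  hf       30.9  2.64   2.60
#> 8 flap  p5       82.5  1.05   1.04
#> 9 flap  sh        2.73 0.0674 0.0600

run$confusion
#> <confusion matrix: rows = assigned, cols = true; column %>
#>         true
#> assigned flap soar water
#>    flap   100    0     0
#>    soar     0  100     0
#>    water    0    0   100
#> Overall accuracy: 100.0% (99.4, 100.0), n = 600
```

The `tidy()` table is the fitted model in behavioral terms: the flapping
state owns the wingbeat band (mean `hf` ≈ 2.6 Hz), the soaring state owns
heading dispersion (mean `sh` ≈ 1.06 rad, the signature of ~80° soaring
arcs), and the on-water state sits at low frequency and near-zero heading
spread. The confusion matrix compares the Viterbi decoding against the
generator's hidden truth. Budgets and bouts come from the same run:

```r
dplyr::filter(run$budgets, individual_id == "bird01")
#> # A tibble: 3 × 4
#>   individual_id state n_windows   pct
#> 1 bird01        flap         36    24
#> 2 bird01        soar         99    66
#> 3 bird01        water        15    10

head(extract_bouts(run$states), 3)
#> # A tibble: 3 × 6
#>   individual_id state start_window end_window n_windows duration_min
#> 1 bird01        soar             1          1         1          0.5
#> 2 bird01        flap             2          5         4          2
#> 3 bird01        soar             6         24        19          9.5
```

`autoplot(run$fit, run$features)` draws the state-dependent Weibull
densities over the feature histograms, and
`autoplot(run$confusion)` / `plot_budgets(run$budgets)` plot the
evaluation products. For real files, `read_sensor_csv()` ingests the
documented delimited schema and `preprocess_individual()` +
`window_features()` + `fit_hmm()` compose the same chain.

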