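# tidysmt

Single-molecule tracking (SMT) analysis of nuclear protein dynamics, in
tidyverse style: tibbles in, tibbles out, broom-compatible models,
ggplot2 `autoplot()` everywhere.

Live-cell SMT of transcription factors (e.g. HaloTag-labeled
glucocorticoid receptor imaged by HILO microscopy) produces thousands of
short 2D trajectories. Two questions dominate their analysis: **how is
the population split among chromatin-bound, confined and freely
diffusing molecules**, and **how long do bound molecules stay on
chromatin** once photobleaching is corrected for. tidysmt implements the
full chain for both, plus a synthetic-data generator that makes every
stage verifiable without a microscope:

* **Simulation** — multi-state Brownian trajectories with confinement
  (reflecting disk of radius L), exponential state switching, motion
  blur (sub-step position averaging over the exposure), localization
  noise, and photobleaching; ground-truth labels included; optional
  rendering to Poisson-noise image stacks.
* **Detection & linking** — matched-filter spot detection with
  sub-pixel Gaussian refinement; optimal bipartite frame-to-frame
  linking gated at 4 px (5 Hz) or 6 px (83 Hz), minimum track length 2,
  no gap closing.
* **Diffusive states** — perturbation expectation-maximization (pEM)
  over whole trajectories with the blurred-SPT covariance model: per
  state k, displacement variance `2*D_k*dt + 2*eps_k^2` and adjacent-lag
  covariance `-eps_k^2`, with effective noise `eps_k^2 = sigma^2 -
  D_k*t_E/3` derived from one shared static localization variance
  `sigma^2`. BIC (`-2 lnL + 2K ln n_disp`) selects the number of states;
  states with < 5% of tracks at posterior > 0.6 are discarded;
  posterior-weighted MSD curves and bound/confined/free fractions are
  reported.
* **Residence times** — dwell extraction from slow (200 ms time-lapse)
  tracks, cell-weighted ensemble pooling, triple-exponential
  photobleaching fit on a stable H2B-like control, survival correction
  `S_corr = S_obs / S_bleach`, continuous tail MLE for the power-law
  exponent `alpha = 1 + n / sum(log(t_i/t_min))`, and two-sample KS
  comparison between conditions.

## Worked example

Simulate a fast-acquisition experiment with a bound (35%, D = 0.005
µm²/s) and a free (65%, D = 0.5 µm²/s) population, pick the number of
diffusive states by BIC, and summarize the fractions:

```r
library(tidysmt)

model <- simulation_model(
  list(motion_state("bound", 0.005), motion_state("free", 0.5)),
  initial_weights = c(0.35, 0.65), localization_sigma_um = 0.03,
  seed = 42)
sim <- simulate_tracks(model, protocol_fast(n_frames = 21), 1000)

sel <- select_model(sim$tracks, K_range = 1:3, seed = 1,
                    n_restarts = 1, n_perturbations = 2)
sel
#> <pem_selection> BIC over candidate state counts
#>  K   loglik       bic converged error
#>  1 41241.52 -82463.22      TRUE  <NA>
#>  2 48274.84 -96510.07      TRUE  <NA>
#>  3 48241.75 -96424.08      TRUE  <NA>
#> selected K = 2

fit <- filter_states(sel$best)       # 5% / 0.6 population rule
tidy(fit)
#> # A tibble: 2 × 6
#>   state diffusivity_um2_s weight population  eps2_um2 sigma2_um2
#>   <int>             <dbl>  <dbl>      <dbl>     <dbl>      <dbl>
#> 1     1           0.00354  0.351      0.349  0.000900   0.000912
#> 2     2           0.498    0.649      0.651 -0.000748   0.000912

summarize_fractions(fit)[, 1:3]
#> # A tibble: 1 × 3
#>   fraction_bound fraction_confined fraction_free
#>            <dbl>             <dbl>         <dbl>
#> 1          0.351                 0         0.649
```

The fit recovers both diffusivities (0.0035 vs. the apparent bound
mobility, 0.498 vs. 0.5 µm²/s), the mixture weights (0.351/0.649 vs.
0.35/0.65), and the static localization variance (0.000912 vs. the
simulated 0.03² = 0.0009 µm²). `autoplot()` methods exist for track
sets, state models, BIC tables, MSD curves, dwell survivals and fraction
summaries; `state_msd(fit)` returns the posterior-weighted MSD curves as
a tibble.

For residence analysis, see `simulate_residence_tracks()`,
`extract_dwell_times()`, `pool_weighted()`, `fit_triple_exponential()`,
`correct_photobleach()`, `fit_power_law()` and `compare_dwell()`; the
whole chain (and the state analysis above) can also be driven from one
YAML file with `run_pipeline(read_run_config(...))` — a demonstration
configuration ships in `inst/extdata/demo_config.yaml`.

The methods vignette (`vignettes/tidysmt-methods.Rmd`) documents the
generative model, the pEM covariance parametrization, every default and
its rationale, and the package's known limitations.

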