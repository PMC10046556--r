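# thetanet

Theta-band EEG functional network analysis of mental workload and skill
acquisition.

`thetanet` is for researchers who study how training and task difficulty
reshape large-scale brain coordination with scalp EEG. It implements, as a
tested R pipeline, the analysis chain used in longitudinal sensorimotor
training studies (e.g. simulated drone piloting under graded wind
disturbance): individualized theta-band phase-synchronization networks,
graph-theoretic efficiency and small-worldness, and the within-subject
statistical layer that compares them across sessions and difficulty
levels. Because such EEG cohorts are rarely public, the package ships a
synthetic-data generator with known phase-coupling ground truth, so every
stage is verifiable by recovery.

## The method in brief

1. **Preprocessing** — zero-phase 0.5–48 Hz bandpass, decimation to
   250 Hz, event segmentation, removal of segments shorter than 30 s.
2. **Individual alpha peak frequency (iAPF)** — spectral center of gravity
   of eyes-closed rest over 7.5–12.5 Hz, averaged over pre- and
   post-session rests; the subject's theta band is (4, 0.8 × iAPF) Hz.
3. **Connectivity** — weighted Phase Lag Index per channel pair from
   analytic signals in the theta band,

   $$\mathrm{wPLI} = \left|\frac{\sum_t |\mathrm{Im}\,S_{xy,t}|\,
   \mathrm{sgn}(\mathrm{Im}\,S_{xy,t})}{\sum_t |\mathrm{Im}\,S_{xy,t}|}\right|,
   \qquad S_{xy,t} = z_{x,t}\overline{z_{y,t}},$$

   which discounts zero-lag (volume-conducted) coupling by construction.
4. **Graphs** — binarization at the pooled median of each subject's test
   session; characteristic path length $L$, global efficiency
   $E_{global}$, per-node local efficiency $E_{local}$, clustering $C$,
   and small-worldness $\sigma = \gamma/\lambda$ with
   $\gamma = C/C_{random}$, $\lambda = L/L_{random}$ normalized by 100
   degree-preserving surrogate networks ($\sigma > 1$ = small-world).
5. **Statistics** — 4 (test) × 3 (scenario) fully within-subject ANOVA
   with unconditional Greenhouse–Geisser correction and generalized eta
   squared, Bonferroni paired post hocs, and mass-univariate variants over
   channel pairs (divisor 276) or channels (divisor 24).

See `vignettes/theta-network-workload.Rmd` for the models, defaults and
numerical conventions.

## Worked example

```r
library(thetanet)

# a canonical small-world graph at the study's network size
g   <- sample_ws_graph(n = 24, k = 4, p = 0.1, seed = 1)
graph_metrics(g, n_surrogates = 100, seed = 2)
#> <graph_metrics> L=2.670 E_global=0.470 E_local=0.542 C=0.404
#>                 gamma=3.874 lambda=1.155 sigma=3.353

# ground-truth coupling is recovered by the wPLI estimator
sp <- oscillator_spec(n_channels = 2, sample_rate = 250, duration = 12,
                      coupling   = matrix(c(0, 1, 1, 0), 2),
                      phase_lags = matrix(c(0, pi/2, -pi/2, 0), 2),
                      noise_sd = 0, phase_noise_sd = 0,
                      coupling_gain = 25, seed = 3)
z <- analytic_signals(generate_task_epoch(sp), band = c(4, 8))
wpli(z[1, ], z[2, ])
#> [1] 1

# iAPF by center of gravity, and the individualized theta band
rest <- generate_rest(oscillator_spec(n_channels = 4, sample_rate = 250,
                                      duration = 40, alpha_peak = 10.3,
                                      seed = 4))
estimate_iapf_cog(rest)
#> <spectral_profile> iAPF = 10.17 Hz (window 7.5-12.5 Hz),
#>                    theta band 4.00-8.14 Hz
```

The Watts–Strogatz graph is strongly small-world ($\sigma = 3.35 > 1$); a
fully coupled oscillator pair with a quarter-cycle lag and no noise gives a
wPLI of exactly 1; and the center-of-gravity estimator recovers a 10.3 Hz
alpha peak to 0.13 Hz from 40 s of rest.

## The analysis workflow

The `analysis/` directory is a numbered end-to-end study on synthetic
data; each script prints what it found and writes tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | 6-subject, 4 test × 4 scenario × 2 trial study with declining post-schema coupling density |
| `02_preprocess.R` | iAPF recovery per session; individualized theta bands |
| `03_networks.R` | full pipeline: wPLI, median-threshold graphs, metrics |
| `04_stats.R` | RM-ANOVA (L3 excluded) + paired post hocs per metric |
| `05_report.R` | condition-mean tables and local-efficiency scalp maps |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

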