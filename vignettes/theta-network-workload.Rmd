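---
title: "Theta-band functional networks under mental workload: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-band functional networks under mental workload: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetanet)
```

## The scientific problem

When people acquire a demanding sensorimotor skill — here, piloting a
simulated quadrotor drone through waypoints under increasing wind
disturbance — the way their brain coordinates activity across regions
reorganizes. `thetanet` implements the full analysis chain used to study
this reorganization with scalp EEG: phase-synchronization networks in a
subject-specific theta band, binarized into graphs whose efficiency and
small-world structure are compared across training sessions and task
difficulty levels with repeated-measures statistics.

Because EEG cohorts of this kind are rarely public, the package is built
around a synthetic-data generator with a *known* ground truth. Every stage
of the pipeline — spectral estimation, connectivity, graph construction,
statistics — can therefore be validated by recovering what was put in.

## The generator: coupled phase oscillators

Task epochs are produced by a stochastic Kuramoto-style phase model. Channel
$i$ carries a phase $\theta_i(t)$ advancing at a carrier frequency drawn
from the theta range (4–8 Hz), updated with Euler steps at the sampling
rate:

$$\dot\theta_i = \omega_i + g \sum_j C_{ij}\,
  \sin(\theta_j + \Delta_{ij} - \theta_i) + \xi_i(t),$$

where $C$ is a symmetric coupling matrix in $[0,1]$, $\Delta$ an
antisymmetric matrix of target phase lags, $g$ the coupling gain, and
$\xi_i$ white phase noise. The observed signal is
$x = M\cos(\theta) + \varepsilon$, with $M$ an instantaneous mixing matrix
emulating volume conduction and $\varepsilon$ white measurement noise. The
ground truth the pipeline must recover is the support and strength of $C$;
the lags $\Delta$ are drawn away from $0$ and $\pi$ so that genuinely
coupled pairs carry imaginary cross-spectral mass.

Two defaults deserve comment:

* **Coupling gain** (`coupling_gain = 4` s⁻¹) places the network in the
  *partial-synchronization* regime. With a much larger gain, any connected
  coupling graph collapses into one globally synchronized cluster in which
  indirectly connected channel pairs hold phase relations just as stable as
  directly coupled ones — the structural density of $C$ then leaves no
  imprint on the connectivity matrix and nothing is recoverable. The
  partial regime, where directly coupled pairs synchronize strongly and
  synchronization decays with graph distance, is both the recoverable and
  the physiologically intended setting.
* **Phase noise** (`phase_noise_sd = 2.5` rad/√s) sets how fast uncoupled
  channels decorrelate. Together with the 4 Hz bandwidth of the theta band
  it fixes the chance level of the connectivity estimator (below).

Rest recordings use a different mechanism: inverse-FFT synthesis from a
target spectrum $P(f) = f^{-\gamma} + h\,e^{-(f-f_\alpha)^2/2w^2}$ — a $1/f$
background (slope $\gamma = 1$) plus a Gaussian alpha bump of height
$h = 2$ and width $w = 1.5$ Hz at the subject's alpha peak $f_\alpha$.
Subjects draw $f_\alpha \sim \mathcal N(10, 0.8^2)$ Hz, clipped to 8–12 Hz.

A study is a fully crossed within-subject design: 4 test sessions (T1–T4)
× 4 difficulty scenarios (L0–L3) × 4 trials, i.e. 16 task trials per
session, plus eyes-closed rest before and after each session. An *effect
map* assigns each (test, scenario) cell a coupling density and strength.
The default map encodes the qualitative pattern of interest: early sessions
have a flat density of 0.35 (networks still reorganizing while the task
schema forms), while post-schema sessions (T3, T4) have density falling
with difficulty, 0.5 / 0.3 / 0.2 / 0.15 for L0–L3. Coupling strength is
0.8 throughout. Every recording derives its own RNG seed from the top-level
seed and its (subject, test, scenario, trial) indices, so any single trial
is regenerable in isolation and whole runs are bit-reproducible.

What the generator does *not* emulate: realistic head-volume geometry,
ocular/muscle artifacts, non-stationary amplitude dynamics, and
between-channel spectral differences. Passing recovery tests on this
generator therefore demonstrates the correctness and calibration of the
*estimators*, not robustness to real-world artifact structure.

## Preprocessing and the individualized theta band

Recordings are band-limited to 0.5–48 Hz and decimated to 250 Hz. The
filter realization is a zero-phase (forward–backward) 4th-order Butterworth
chain: an anti-alias low-pass at the native rate, integer decimation, then
the bandpass at the target rate. Applying the highpass edge at the target
rate avoids the numerical fragility of an IIR bandpass with a normalized
edge of 0.001 at 1 kHz; zero-phase application matters because all
downstream measures are phase-based. Event-marked segments shorter than
30 s (aborted trials) are discarded, with counts logged.

The individual alpha peak frequency (iAPF) is estimated from eyes-closed
rest by the spectral center of gravity: Welch PSD (2 s Hann windows, 50 %
overlap, i.e. 0.5 Hz resolution), averaged over all channels, then
$\mathrm{iAPF} = \sum_f P(f) f / \sum_f P(f)$ over a 7.5–12.5 Hz search
window. The pre- and post-session estimates are averaged into a session
iAPF. The COG estimator is deliberate: it is defined for flat or split
alpha peaks where an argmax is unstable, and it is exactly invariant to
global power rescaling. Two biases are worth knowing: the $1/f$ background
pulls the centroid slightly toward the window center, and a peak near the
window edge is truncated asymmetrically; both are well inside ±0.5 Hz for
peaks in the 9–11 Hz range. Channel selection (all channels vs a posterior
subset) is configurable; all-channel averaging is the default since no
electrode subset is canonical here.

The session's connectivity band is the individualized theta band
$(4, 0.8 \times \mathrm{iAPF})$ Hz, degenerate (an error) if
$\mathrm{iAPF} \le 5$ Hz.

## Weighted Phase Lag Index

For analytic signals $z_x, z_y$ (zero-phase Butterworth bandpass to the
theta band, FFT Hilbert transform, 1 s trimmed per edge against filter and
Hilbert transients), the per-sample cross-spectrum is
$S_{xy,t} = z_{x,t} \overline{z_{y,t}}$ and

$$\mathrm{wPLI} = \left|
  \frac{\sum_t |\mathrm{Im}\,S_{xy,t}|\,\mathrm{sgn}(\mathrm{Im}\,S_{xy,t})}
       {\sum_t |\mathrm{Im}\,S_{xy,t}|}\right| .$$

Weighting lead/lag consistency by the imaginary cross-spectral magnitude
makes the index blind to zero-lag interactions — exactly the signature of
volume conduction, which the generator's mixing matrix reproduces as a
negative control. When $\sum_t |\mathrm{Im}\,S_{xy,t}| = 0$ (a purely
zero-lag relation) the index is defined as 0, consistent with that design
intent. The index is exactly invariant to per-channel amplitude scaling
and sign flips.

Within a condition (subject × test × scenario), the numerator and
denominator sums are pooled across all trial segments before the ratio is
taken — equivalent to concatenation, and length-weighted when segments are
unequal. Averaging per-segment wPLI values is available as a config option
(`method = "average"`).

**Chance level.** The wPLI estimator has a positive small-sample bias of
order $(T \cdot B)^{-1/2}$ for data length $T$ and bandwidth $B$, because
the imaginary cross-spectrum decorrelates no faster than the band allows.
With the 4 Hz theta band, a single 60 s epoch sits near 0.06 under true
independence and pooling the trials of a condition pushes it toward 0.03.
The null and leakage-rejection contracts are asymptotic statements, so the
shipped Monte-Carlo controls pool several minutes of data per estimate,
where the bias floor is well separated from the 0.05 bound.

## Graphs and their metrics

Connectivity matrices are binarized at the **median of all scenario data
within each (subject, test) group** — pooled upper-triangle values across
that session's scenarios. A common per-session threshold keeps the *total*
edge mass comparable while letting density differences between scenarios
express themselves; that is precisely what makes a density effect across
scenarios recoverable. Entries strictly greater than the threshold become
edges, so an all-ties matrix yields an empty graph. Group-level pooling
across subjects would also be defensible; per-subject-per-test is the
default because the within-session scenario contrast is the comparison of
interest.

On the resulting undirected graphs ($N$ nodes, BFS hop distances
$d_{ij}$):

* characteristic path length
  $L = \frac{1}{N(N-1)}\sum_{i\ne j} d_{ij}$, computed over *finite* pairs
  only, with the number of unreachable ordered pairs reported — at ~50 %
  density on 24 nodes disconnection is rare, and excluding rather than
  propagating $\infty$ keeps the surrogate normalization finite;
* global efficiency
  $E_{global} = \frac{1}{N(N-1)}\sum_{i\ne j} d_{ij}^{-1}$ (unreachable
  pairs contribute 0, no convention needed);
* local efficiency $E_{local} = \frac{1}{N}\sum_i E_{global}(G_i)$, where
  $G_i$ is the subgraph induced by the neighbours of $i$ (node $i$
  excluded); nodes of degree < 2 score 0;
* clustering coefficient $C = \frac{1}{N}\sum_i 2E_i/k_i(k_i-1)$, with
  $E_i$ the edge count among the neighbours of $i$; degree < 2 scores 0.

Small-worldness normalizes against an ensemble of 100 surrogate random
networks obtained by degree-preserving edge swaps (10 × |edges| attempted
swaps each): $\gamma = C/C_{random}$, $\lambda = L/L_{random}$,
$\sigma = \gamma/\lambda$, with $\sigma > 1$ read as small-world
organization. Degree-preserving rewiring is the field default for these
normalizers; for degree sequences that admit no swap at all (a star), the
ensemble falls back to density-matched Erdős–Rényi graphs with a warning.
If an ensemble has no triangles at all ($C_{random} = 0$, possible for very
sparse graphs), $\gamma$, $\lambda$, $\sigma$ are reported as `NA` rather
than poisoning downstream tables.

## The statistical layer

Network metrics (and, in a real study, behavioral scores) enter a
4 (test) × 3 (scenario) fully within-subject ANOVA; the hardest scenario
(L3) is excluded by configuration, mirroring the exclusion of a condition
whose perceived difficulty was inconsistent across raters. Sums of squares
are partitioned into A, B, A×B with error strata A×S, B×S, A×B×S.

The Greenhouse–Geisser $\varepsilon$ of each effect comes from the
covariance of orthonormalized contrast scores,
$\varepsilon = \mathrm{tr}(\Sigma)^2 / (d\,\mathrm{tr}(\Sigma^2))$, bounded
to $[1/d, 1]$, and is applied **unconditionally**: conditioning the
correction on a Mauchly pretest adds an unreported analyst degree of
freedom, and the correction is exact ($\varepsilon = 1$) for two-level
factors and conservative otherwise. Effect sizes are generalized eta
squared with the full fully-within denominator,
$\eta_g^2 = SS_{effect}/(SS_{effect} + SS_{subjects} + \sum SS_{error})$.

Post hoc paired $t$-tests are Bonferroni-corrected by the comparison family
size. Mass-univariate variants run the same ANOVA per channel pair
(Bonferroni divisor $\binom{24}{2} = 276$) or per channel (divisor 24);
units with zero-variance error strata are skipped with a logged reason, and
a comparison with zero difference variance but non-zero mean is flagged
degenerate instead of reporting an infinite $t$.

Under a null simulation (i.i.d. normal responses, 3 × 4 design, 20
subjects), the G-G-corrected per-effect type-I error at $\alpha = 0.05$
stays within [0.03, 0.07] — verified by a 1000-replication test in the
suite.

## Numerical and design choices at a glance

* One observation per cell is enforced; trial-level tables are collapsed
  with `condition_average()` first.
* Ties at the binarization threshold are non-edges (strict inequality).
* All randomness flows from one seed through multiplicative-hash derived
  per-recording seeds (kept below $2^{31}$), and generator calls restore
  the caller's RNG state.
* Welch windows are 2 s Hann at 50 % overlap; changing the window length
  trades iAPF grid resolution against variance.
* Edge trimming after the Hilbert transform is 1 s per side; segments must
  retain ≥ 2 s.

## Problem sizes used in the shipped checks

The test suite and analysis scripts run the pipeline at reduced but
faithful scale, chosen so each check exercises the same estimator regime as
a full study: condition-level wPLI uses 2–4 pooled trials of 30–32 s at
250 Hz; the end-to-end recovery study uses 10 subjects × 2 post-schema
sessions × 3 scenarios × 2 trials of 32 s on the 24-channel montage with
the 0.5/0.3/0.2 density map; surrogate ensembles use the full 100 networks
wherever $\sigma$ is asserted; ANOVA calibration uses 1000 null
replications. The analysis scripts under `analysis/` run a 6-subject,
full 4 × 4 design end to end.

## Known limitations

* The generator's coupling topology is an Erdős–Rényi graph at the
  configured density; real functional networks are spatially structured.
  Topology is a per-call argument, so structured maps can be supplied.
* ICA-based artifact removal is inherently manual and is not reimplemented;
  the pipeline accepts pre-cleaned input instead.
* Only the theta band is analyzed; the band machinery is general but other
  bands' conventions (e.g. alpha asymmetry windows) are not built in.
* $\gamma$, $\lambda$, $\sigma$ inherit the finite-pair path-length
  convention; for graphs far sparser than 50 % density the `NA` guard and
  the fallback ensemble become relevant and results should be read with
  the logged warnings in hand.
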