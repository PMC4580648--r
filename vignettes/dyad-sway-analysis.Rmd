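---
title: "Quantifying synchronization and directed influence in dyadic postural sway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synchronization and directed influence in dyadic postural sway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

When two people stand face to face, their continuous small postural
adjustments (sway) can become coordinated. Two questions follow. First,
*is* the sway synchronized, and with what time offset — do the two move
together (lag-0 synchronization), or does one lead? Second, *who is
influencing whom*, and by how much? `dyadsync` implements a complete
pipeline for both questions on paired 1-D head-position series (mm),
recorded at 200 Hz for 60-s trials under a factorial design: interpersonal
DISTANCE (Near/Far) crossed with VISUAL INTERACTION — each participant
either sighted (O) or blindfolded (B), giving conditions OO, BO, OB, BB.
Throughout the package, the first letter of a condition code is participant
x's state: in "BO", x is blindfolded and y sighted.

## Synchronization: normalized cross-correlation

For one trial with series $x(t)$, $y(t)$ ($t = 1..N_t$), the lag-resolved
correlation is

$$R_{xy}(\tau) = \frac{1}{N_t - 1}\sum_{t=1}^{N_t - |\tau|}
\frac{(x(t+\tau)-\bar x)(y(t)-\bar y)}{\sigma_x \sigma_y},$$

computed over the overlapping range only (no zero padding), with means and
SDs taken once on the full series using the $N_t-1$ denominator
(`cross_correlation()`). Before correlation each channel is linearly
detrended and tapered with a full-length Hanning window
(`preprocess_xcorr()`); the taper is applied *before* the means and SDs
are computed, so the statistic is a self-consistent correlation of exactly
the signals entering the sum. Curves are averaged across trials
(`average_curves()`) and the synchronization lag is the location of the
maximum *positive* correlation within ±1 s (`detect_peak_lag()`); ties
break toward the smallest |lag|, then toward the more negative internal
lag, so detection is deterministic.

**Sign conventions.** In the raw grid a peak at positive $\tau$ means y's
fluctuations precede x's (since $x(t+\tau)$ is paired with $y(t)$). Because
a fixed orientation must be chosen for reporting, all user-facing tables
use the opposite, **x-leads-positive** orientation (a positive lag means
participant x precedes); `convention = "y_leads"` exposes the raw
orientation, in which a blindfolded, hence driving, participant x yields
*negative* lags. Both are available because the two orientations are each
natural in different summaries and mixing them silently is the main
practical hazard of lag analyses.

## Directed influence: the noise contribution ratio

Influence is quantified from a bivariate autoregression fit to each trial
after decimation to 5 Hz:

$$x(t) = \sum_{i=1}^{N} a_i\,x(t-i) + b_i\,y(t-i) + u_x(t), \qquad
  y(t) = \sum_{i=1}^{N} c_i\,x(t-i) + d_i\,y(t-i) + u_y(t),$$

with independent white driving noises $u_x, u_y$ (`fit_var()`, ordinary
least squares per equation, no intercept since inputs are detrended; noise
variances use the $n_\mathrm{eff} - 2N$ denominator). The transfer matrix

$$H(f) = \Big(I - \sum_i A_i e^{-j 2\pi f i \Delta t}\Big)^{-1}
       = \begin{pmatrix} \alpha(f) & \beta(f)\\ \gamma(f) & \delta(f) \end{pmatrix}$$

decomposes each channel's spectrum into own-noise and partner-noise parts,
and the **noise contribution ratio**

$$\mathrm{NCR}_{y\to x}(f) =
\frac{|\beta(f)|^2\sigma_{uy}^2}{|\alpha(f)|^2\sigma_{ux}^2 + |\beta(f)|^2\sigma_{uy}^2}$$

is the fraction of x's power at $f$ attributable to y's driving noise
(`ncr_spectrum()`); the Akaike-style causality measure. Integrating
trapezoidally over $[0, f_s/2]$, normalizing by the Nyquist bandwidth and
scaling by 100 gives one $\Sigma\mathrm{NCR}$ percentage per direction
(`integrate_ncr()`); the normalization is chosen so a frequency-constant
ratio $c$ maps to $100c$ and values are comparable across sampling rates.
`frequency_response()` also offers a truncated impulse-response route that
must agree with the direct inversion to $10^{-8}$ — a standing numerical
cross-check.

The decomposition assumes white, mutually independent driving noises;
`check_residual_whiteness()` (Ljung–Box per channel plus the lag-0
residual correlation) gates that assumption per fit.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| Decimation | 200 Hz → 5 Hz, factor 40 | AR modeling needs time steps on the scale of visuo-postural feedback; 5 Hz keeps 300 samples per trial. |
| Anti-alias FIR order | 30 | The classical FIR decimator; note below on its transition band. |
| AR order | 3 (fixed) | Chosen once from AIC behavior and held fixed across all fits so order selection cannot differ between conditions; `select_order_aic()` (range 1–20, common effective sample, penalty $2\cdot4p$) remains available as a diagnostic. |
| Peak window | ±1 s | Synchronization peaks concentrate near lag 0; a bounded window keeps the estimator away from spurious edge maxima. |
| NCR grid | 512 points on $[0, f_s/2]$ | At AR(3) smoothness the trapezoid's grid error is far below 0.1 percentage points (verified against a 4096-point grid). |
| Simulation | 40 reps × 300 samples at 5 Hz | Matches one decimated trial; per-pair means refine the 200-ms native lag resolution below one sample. |

**A note on the decimator.** A 30th-order FIR with cutoff at 1/40 of
Nyquist necessarily has a transition band much wider than its cutoff:
applied forward-backward it is ~−2 dB just above the new Nyquist (2.5 Hz)
and reaches "deep-stopband" attenuation (>40 dB) only above roughly 12 Hz.
Postural sway concentrates its power well below 2 Hz, so the residual
aliasing is immaterial here, but the filter is not a brick wall and the
tests check attenuation in the deep stopband, not at the band edge. The
filter kernel is normalized to unit DC gain and applied zero-phase (one
pass of the forward-backward kernel with odd-reflection edge padding), so
constants pass exactly and no group delay biases subsequent lag estimates.

## In-silico replication

`simulate_from_model()` drives a fitted model with fresh standard-normal
noise (the empirical residuals are replaced by unit-variance white noise),
zero initial state, 500-sample burn-in. `run_simulation_study()` repeats
this per pair × condition (40 reps by default, cycling over the per-trial
models when several are supplied), reruns the identical lag analysis on
each simulated dyad, and `compare_sim_behavioral()` regresses behavioral
on simulated per-pair lags with Bonferroni correction across the three
simulated conditions (OO, BO, OB; BB is excluded — an uncoupled pair has
no synchronization to replicate).

## Linking influence to lag

The package's central diagnostic regression (`single_regression()`)
relates each pair's influence asymmetry to its synchronization lag. The
two variables must be co-oriented: with x-leads-positive lags the
predictor is $X = \Sigma\mathrm{NCR}_{x\to y} - \Sigma\mathrm{NCR}_{y\to x}$
— influence *exerted* minus *received* by x — because the partner who
drives both precedes and exerts the larger influence. Under this
orientation, graded-asymmetry synthetic studies produce a positive slope
essentially always (20/20 replicate studies in the acceptance run). The
opposite pairing (received-minus-exerted) would flip the slope's sign;
only the orientation, not the inference, changes.

Group-level inference mirrors the factorial design: per-axis lag t-tests
(OO against 0 ms, uncorrected; BO and OB against OO, paired, Bonferroni
×2), and a three-way repeated-measures ANOVA on participant-level
$\Sigma\mathrm{NCR}$ with factors SENDER, RECEIVER and DISTANCE
(`rm_anova_ncr()`). A participant's value in a cell is the
partner-to-self integrated NCR; SENDER is the partner's visual state and
RECEIVER the participant's own, so each of the $2\times$pairs participants
fills the full 2×2×2 within design. With two-level factors every effect
is a per-participant contrast, so F is the squared one-sample t of that
contrast with $(1, n-1)$ df, $\eta_p^2 = F/(F + n - 1)$, and no sphericity
question arises; this exact partitioning is also what the type-I
calibration checks (all seven effects hold 5% within [3%, 7%] over 1000
null tables). `variance_summary()` reports detrended signal variance
stratified by axis, distance, and both partners' visual states.

## The synthetic-data generator

`synth_spec()` + `generate_dataset()` produce full factorial studies with
known ground truth, used by every downstream test. The generative model
is the same family the pipeline estimates: a stable bivariate AR(3) at
5 Hz whose cross-coupling encodes visibility — a participant's equation
receives partner history only if that participant is sighted. Defaults,
chosen once as the study conditions: self coefficient 0.5 and coupling
0.3 at lag 1, both decaying with the alternating profile $(-0.5)^{i-1}$
over 3 lags (a genuine AR(3): the lag-3 terms are large enough that AIC
recovers order 3 in ~85–90% of 5000-sample fits); innovation SD 1 mm,
scaled ×1.3 for a blindfolded participant (sway grows without vision);
coupling ×0.4 at Far distance (weaker influence at larger separation,
encoded multiplicatively since no separate mechanism is modeled); trend
slopes uniform on ±0.02 mm/s; measurement noise 0.05 mm; 22 pairs × 2
distances × 4 conditions × 4 trials of 60 s. Trials are simulated at the
model rate with a 500-sample burn-in, upsampled ×40 by band-limited FIR
interpolation (`signal::interp`) — not sample-and-hold — so the 200 Hz
series is smooth and the pipeline's decimation approximately inverts the
upsampling. Per-trial seeds derive deterministically from the spec seed;
identical specs regenerate bit-identical datasets.

What the generator does *not* emulate: the 1/f-like low-frequency
structure, intermittency and nonstationarity of real sway, biomechanics,
or any nonlinearity in visual coupling. Passing tests therefore establish
that the estimators recover *linear-AR* ground truth at realistic sizes
and noise levels — not that real sway satisfies the linear model; on real
data the residual-whiteness diagnostics are the guard.

## Numerical and design choices

- Cross-correlation uses the direct overlapping-range sum, not FFT
  convolution, so the printed normalization is honored exactly.
- OLS fits go through QR; rank deficiency (e.g. `x == y`) is an error,
  not a silent pseudo-inverse.
- Degenerate inputs fail loudly: zero-variance series, unstable
  coefficient sets (reported with their companion spectral radius),
  singular transfer matrices (reported with the frequency), incomplete
  ANOVA cells, constant regressors.
- In an all-equal ANOVA cell (zero contrast variance) F is defined as 0
  with p = 1; a nonzero mean contrast with zero variance gives F = Inf,
  $\eta_p^2 = 1$.
- Recorded datasets are ingested from a documented CSV-per-pair layout
  with a JSON manifest (`read_sway_dataset()`); MATLAB containers must be
  converted first, which makes the variable-to-pair/axis/condition
  mapping explicit instead of guessed.
- Problem sizes used by the shipped verification runs: null calibration
  on 200 white dyads of 300 samples; direction recovery on 100
  unidirectional dyads; coefficient recovery on 20 × 10⁴-sample and order
  recovery on 50 × 5000-sample simulations; 20 replicate 22-dyad
  graded-asymmetry studies; 1000 null simulations per inferential test.

## A worked example

```{r example, eval = FALSE}
spec <- synth_spec(n_pairs = 22, seed = 1)
cfg <- study_config(spec = spec, axes = "AP", seed = 1)
res <- run_pipeline(cfg)

res$lag_tests[["AP.Near"]]     # OO near 0; BO positive, OB negative (x leads)
res$anova$AP                    # RECEIVER and RECEIVER:DISTANCE dominate
res$ncr_lag_regression$AP       # positive influence-asymmetry/lag slope
res$simulation$summary          # white-noise-driven replication of the lags
```

## Known limitations

- Bivariate only: no conditional (multi-node) causality, partial directed
  coherence or directed transfer function.
- Linear, time-invariant AR: slow drifts are removed by detrending, but
  genuine nonstationarity within a trial violates the model.
- The absolute scale of $\Sigma\mathrm{NCR}$ depends on the bandwidth
  normalization; comparisons should stay within one pipeline
  configuration.
- Lags from 5 Hz simulations have 200 ms native resolution; sub-sample
  precision exists only in across-trial means.
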