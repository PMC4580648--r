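# dyadsync

Synchronization and directed influence in dyadic postural sway.

When two people stand face to face, their postural sway — the continuous
small motion of the head while standing — can synchronize. `dyadsync` is
for researchers in movement science, social neuroscience and
biostatistics who record paired physiological time series (here: head
position in mm along the anterior-posterior or left-right axis, 200 Hz,
60-s trials) under a factorial design of interpersonal DISTANCE
(Near/Far) and VISUAL INTERACTION (each partner sighted, **O**, or
blindfolded, **B**: conditions OO, BO, OB, BB) and want to answer two
questions per dyad:

1. **Are they synchronized, and who leads?** The normalized
   cross-correlation
   $R_{xy}(\tau) = \frac{1}{N_t-1}\sum_t
   \frac{(x(t+\tau)-\bar x)(y(t)-\bar y)}{\sigma_x\sigma_y}$
   is computed over the overlapping range on detrended, Hanning-tapered
   signals; the peak within ±1 s is the synchronization lag (reported
   x-leads-positive).
2. **Who influences whom, and how much?** A bivariate autoregression
   $x(t)=\sum_i a_i x(t-i)+b_i y(t-i)+u_x(t)$ (and symmetrically for y)
   is fit to 5 Hz-decimated data; the transfer matrix
   $H(f) = (I-\sum_i A_i e^{-j2\pi f i\Delta t})^{-1}$ splits each
   channel's power into own-noise and partner-noise parts, and the noise
   contribution ratio
   $\mathrm{NCR}_{y\to x}(f)=\frac{|\beta|^2\sigma_{uy}^2}
   {|\alpha|^2\sigma_{ux}^2+|\beta|^2\sigma_{uy}^2}$, integrated over
   $[0, f_s/2]$, yields one directed influence percentage
   $\Sigma\mathrm{NCR}$ per direction (Akaike-style causality).

Around this core the package provides: a synthetic dyad generator with
known ground-truth coupling (`synth_spec()`, `generate_dataset()`), the
signal conditioning chain (`detrend_linear()`, `apply_hanning()`,
`decimate_fir()`), AIC order selection and residual-whiteness
diagnostics (`select_order_aic()`, `check_residual_whiteness()`),
white-noise-driven replication of the lag structure from fitted models
(`simulate_from_model()`, `run_simulation_study()`), and the inferential
layer (lag t-tests, repeated-measures ANOVA on $\Sigma\mathrm{NCR}$ with
SENDER/RECEIVER/DISTANCE factors, influence-asymmetry-vs-lag
regression). `run_pipeline()` chains everything with full provenance and
seed-deterministic outputs.

## A worked example

```r
library(dyadsync)
spec <- synth_spec(n_pairs = 8, n_trials_per_condition = 2, seed = 1)
cfg  <- study_config(spec = spec, axes = "AP", sim_reps = 10, seed = 1)
res  <- run_pipeline(cfg)

res$lag_tests[["AP.Near"]]
#>   condition     comparison n mean_lag_ms sd_lag_ms     t df  p_raw p_corrected
#> 1        OO           vs 0 8       -40.9      83.7 -1.38  7 0.2093      0.2093
#> 2        BO vs OO (paired) 8       165.0     127.3  4.27  7 0.0037      0.0074
#> 3        OB vs OO (paired) 8      -278.4     205.3 -3.37  7 0.0119      0.0239
```

Mutually sighted pairs (OO) synchronize with no significant lag; when one
partner is blindfolded the blindfolded partner leads — x-leads-positive,
so BO (x blindfolded) lags are positive and OB negative — and both differ
from OO after Bonferroni correction.

```r
res$anova$AP
#>                     effect df1 df2    F        p eta_p_sq
#> 1                   SENDER   1  15 11.8 3.71e-03    0.440
#> 2                 RECEIVER   1  15 98.8 5.42e-08    0.868
#> 3                 DISTANCE   1  15 99.3 5.23e-08    0.869
#> ...
```

Influence received ($\Sigma\mathrm{NCR}$) is governed mainly by whether
the receiver can see (RECEIVER) and by distance, as the generator's
ground truth dictates.

```r
res$ncr_lag_regression$AP
#> <regression_result> n = 8 | B1 = 31.56 (t = 2.577, p = 0.04197) | ...
```

Pairs with larger influence asymmetry show proportionally larger
synchronization lags: the pair-level regression of peak lag on
$\Sigma\mathrm{NCR}_{x\to y}-\Sigma\mathrm{NCR}_{y\to x}$ has a positive
slope (ms per percentage point).

```r
aggregate(mean_lag_ms ~ condition, res$simulation$summary, mean)
#>   condition mean_lag_ms
#> 1        BO         310
#> 2        OB        -362
#> 3        OO         -25
```

Driving the fitted models with fresh white noise reproduces the
behavioral lag ordering — the linear feedback system alone accounts for
the lag structure.

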