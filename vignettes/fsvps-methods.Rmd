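---
title: "T2*-based neurofeedback from unsuppressed-water spectroscopy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{T2*-based neurofeedback from unsuppressed-water spectroscopy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsvps)
library(dplyr)
```

## The measurement problem

Functional single-voxel proton spectroscopy (fSVPS) repeatedly acquires the
free-induction decay (FID) of the unsuppressed water signal from one cubic
voxel — here emulating a 7 T spin-echo protocol with TR = 1 s, TE = 20 ms,
1 kHz bandwidth and 512 complex points per readout. The BOLD effect
modulates the apparent transverse relaxation time T2\* of the water line by
a few percent between rest and activation, so a per-repetition T2\*
estimate is a direct, low-latency functional signal: one number per second,
no image reconstruction, no volume processing.

`fsvps` implements the full chain from raw complex FID frames to a
displayable neurofeedback value, plus a synthetic session generator with
ground truth so that every stage is testable without scanner data.

## Signal model and T2\* estimation

A raw FID is modelled as a sum of decaying complex oscillators

$$s(t) = \sum_j A_j\, e^{i 2\pi f_j t}\, e^{i\phi_j}\, e^{-t/T^*_{2,j}},$$

water dominating by an order of magnitude over residual lipid/metabolite
lines. Per frame the package:

1. locates the water peak in the magnitude spectrum (maximum bin plus
   three-point parabolic interpolation on the log-magnitude),
2. multiplies the time signal by $e^{-i 2\pi \hat f t}$ so the water line
   sits at 0 Hz,
3. applies a Gaussian window $e^{-f^2/(2\sigma^2)}$ in the frequency
   domain, suppressing off-resonance contamination, and
4. fits the logarithm of the remaining (ideally single-component) decay,
   $\ln s(t) = -t/T_2^* + \ln A + i\phi$, a complex straight line, as two
   real ordinary least-squares fits: log-magnitude for the decay rate and
   amplitude, unwrapped phase for $\phi$ and any residual frequency.

### Window width and the fit-start offset

The window width `gaussian_sigma` (default 20 Hz) is not a published
constant; it must pass the few-Hz-wide water line after shimming while
suppressing lines ≥ ~100 Hz off-water at 7 T, and it is exposed in
`svps_filter()`.

Windowing in the frequency domain convolves the time signal with a kernel
of width $1/(2\pi\sigma)$ (~8 ms at 20 Hz). Away from the acquisition edges
this convolution maps an exponential onto an exact multiple of itself, so
the decay rate is untouched; at the edge ($t \approx 0$) the transient
biases the fitted T2\* by several percent. The regression window therefore
starts three kernel widths in (`fit_start`, default $3/(2\pi\sigma)$ = 24 ms
at the default width), which removes the edge bias to ~10⁻⁶ relative while
keeping the fit inside the high-SNR early decay. With the window disabled
(`gaussian_sigma = Inf`) the offset is 0 and a noiseless single-component
frame is recovered exactly (relative error below 10⁻⁸ for every window of
at least three samples — one of the package's acceptance checks).

### Regression length and its optimisation

The fit uses only the first `regression_length` seconds of the conditioned
decay (default 0.2 s). Too short a window wastes SNR; too long a window
drags in the poorly-shimmed, contaminated tail. Because the useful length
is voxel- and shim-specific, `optimize_regression_length()` scans a grid of
candidate lengths on a labelled (non-feedback) session, computes the full
T2\* series for each, scores it with the block-design GLM t-value, and
returns the argmax (ties towards the shorter length, which favours fast
acquisition). Frame conditioning does not depend on the length, so it is
done once and each candidate refits only the log-line; the result is
verified in the test suite against an independent brute-force loop over
candidates.

Failed per-frame fits (a non-negative log-magnitude slope, i.e. an
undefined decay) carry the previous valid estimate forward with a warning —
a streaming-safe convention, since a real-time chain cannot look ahead.

## The real-time conditioning chain

Each retained repetition's raw T2\* sample passes through three stages in a
fixed order (the test suite confirms the order matters on drifting input):

**1. EMA detrend.** The exponential moving average
$\bar y_t = \alpha \bar y_{t-1} + (1-\alpha)y_t$ with $\alpha = 0.98$
tracks slow drift; its residual $y_t - \bar y_t$ is the detrended signal.
At TR = 1 s the implied time constant is $\alpha/(1-\alpha) = 49$ samples
and the −3 dB high-pass cutoff $1/(2\pi\tau)$ rounds to 0.003 Hz, below the
0.01–0.12 Hz band in which block-design BOLD power lives. The closed-form
residual gain $|1 - H(e^{i\omega})|$ is exported as `ema_residual_gain()`
and verified against simulation to 2%.

**2. Spike-gated scalar Kalman filter.** A random-walk Kalman filter
(H = 1) acts as an adaptive low-pass: predict $x^-_t = x_{t-1}$,
$p^- = p + q$, gain $K = p^-/(p^- + r)$. The update ratio $\lambda = 4$
keeps the effective cutoff near $1/(\pi\lambda)$ of the sampling rate
(~0.08 Hz at TR = 1 s); the package realises this by tracking the
observation noise $r$ from the running variance of the filter's input and
setting $q = r/\lambda^2$. Two details of that tracker are deliberate:
it ingests only *accepted* samples, and never the current one — otherwise a
large outlier inflates $r$, deflates $K$, and masks itself at exactly the
step where it must be caught.

The spike gate vetoes the measurement update when the update term exceeds a
threshold, $|K(y_t - x^-_t)| > \mathrm{Th}_{sp}$ with
$\mathrm{Th}_{sp} = 0.9\,\mathrm{std}(y_0 \ldots y_t)$, the incrementally
computed (Welford) standard deviation of the raw input series up to and
including the current sample. On a veto the filter coasts on its
prediction, so the displayed signal never contains the outlier. Two
conventions are configurable because the source of that SD is ambiguous in
practice: `spike_source = "raw"` (default — the raw T2\* series, whose SD
is signal-dominated and therefore a stable yardstick) or `"detrended"`
(the Kalman input itself, which tracks the noise floor but false-triggers
on ordinary noise extremes). The gate arms only once the SD tracker holds
`spike_warmup = 20` samples: an SD estimated from fewer samples has ~16%+
relative error, too unstable to set a rejection threshold.

**3. Range normalisation.** The filtered value is mapped to a display
fraction via the incrementally updated session minimum and maximum, with
the effective range floored at 1% of the first valid baseline T2\* (the
expected magnitude of a BOLD effect) and never allowed to shrink within a
session — a subject who has reached a level can hold it or do better. The
first sample maps to 0 by convention.

## Quality metrics

Scored on the retained repetitions of a processed session
(`session_metrics()`):

- **CNR** $= (\overline{y}_{cond} - \overline{y}_{bas}) /
  \sqrt{s^2_{cond} + s^2_{bas}}$ and the **block-design GLM t-value**
  (OLS on intercept + boxcar, $n-2$ dof, no motion regressors) are computed
  on the conditioned series — detrended and Kalman-filtered, i.e.
  everything except normalisation. An optional canonical-HRF convolution of
  the boxcar exists but is off by default; with 30 s blocks the difference
  is minor. Sample variances use the $n-1$ convention throughout.
- **Percent signal change** $= (\overline{y}_{cond} - \overline{y}_{bas}) /
  \overline{y}_{bas}$ is computed on the *raw* T2\* series with
  gate-flagged repetitions excluded: the detrended series is zero-mean by
  construction, so a percent baseline only exists before drift removal.
- **Event-related average**: the retained series is cut into complete
  baseline+activation cycles aligned to the design's block boundaries
  (cycles touching discarded repetitions and partial trailing cycles are
  dropped), giving a position-wise mean and SD. The **event-related SNR**,
  peak-to-peak amplitude of the cycle mean over the mean position-wise SD,
  is an explicit package convention — the quantity is often reported
  without a definition, so ours is stated and tested rather than assumed
  comparable to any published number.

## The synthetic session generator

`simulate_session()` emulates the study conditions end to end: 300
repetitions at TR = 1 s (the first 10 discarded against T1 saturation),
five 30 s baseline blocks alternating with five 30 s activation blocks, a
water line at amplitude 1 with baseline T2\* = 84.2 ms, and a 5% T2\*
increase during activation. Block transitions are first-order with
`transition_tau = 3` s — a deliberately simple stand-in for haemodynamic
rise and fall (no published haemodynamic model applies directly to this
protocol); a boxcar is recovered with `transition_tau = 0`. Nuisance terms
mirror what the conditioning chain exists to remove:

- additive complex Gaussian noise per sample (default SD 0.008, calibrated
  once so a default session yields a raw-series CNR near 3 and t-values in
  the low twenties — the quality regime such sessions typically reach);
- a slow sinusoidal T2\* drift (amplitude 2 ms, period 240 s) with uniform
  random phase per session, since scanner drift has arbitrary phase
  relative to the paradigm;
- sporadic repetition-level T2\* spikes (probability 0.02). A spike adds
  `spike_scale` × SD of the clean T2\* series to that repetition's T2\*.
  An amplitude-only corruption of the frame would leave the log-slope, and
  hence the derived T2\* sample, untouched — so the outlier is injected
  where the despiker actually sees it. The default magnitude is 8 SD (a
  clear artifact); gate stress tests inject 100 SD;
- a random walk of the water centre frequency (0.2 Hz/step), exercising
  the per-frame peak tracking.

Ground truth records the BOLD-driven T2\* separately from the realised
(drift + spike) series, the spike positions, the centre-frequency track and
the labels, so recovery can be scored against the component of interest.

What the generator does *not* emulate — and hence what passing tests cannot
show — includes subject motion, multi-compartment water (CSF/vascular
partial volume, which in vivo inflates apparent T2\* and would need a
multicomponent decay model), shim-dependent non-Lorentzian lineshapes
beyond a single contaminant line, and any physiological noise structure
(cardiac/respiratory aliasing). Conclusions about those require real data.

## Numerical and design choices

- **Abstract repetition counts.** Session length is 300 repetitions with 10
  discarded (so 290 analysed); where a total of 310 is quoted elsewhere it
  is treated as 300 retained + 10 discarded, and the package keeps
  `n_reps = 300`, `n_discard = 10`.
- **Complex regression as two real fits.** The complex log-line is fitted
  as log-magnitude and unwrapped-phase OLS; this sidesteps the branch
  ambiguity of the complex logarithm while the real part still carries
  T2\*. Phase is unwrapped by cumulative 2π-jump correction along time.
- **Recovery is judged against the truth series, not the nominal plateau.**
  With first-order transitions, block-mean percent change of the *true*
  T2\* series is ~4.0% for a 5% plateau contrast (the transitions dilute
  both block means deterministically). The estimator is therefore tested
  for agreement with the truth series' own block percent change across 200
  simulated sessions (Monte-Carlo CI of the difference), which is the
  property an unbiased estimator can and should satisfy under these
  conditions.
- **Problem sizes.** The test suite and acceptance script use 200 sessions
  of 300 × 512-point frames for recovery, 2000 null simulations for the
  type-I check, 10⁴-sample runs for filter spectra, and 10–12 session pairs
  for the spike gate — sizes chosen so the whole suite completes in a few
  minutes on one core while leaving Monte-Carlo error well below the
  effects under test.
- **Degenerate inputs.** All-zero spectra, zero magnitudes inside a fit
  window, series without both conditions, zero residual variance in the GLM
  (infinite-t flag), and fewer than two complete cycles in the event
  average are all detected and reported as typed errors (or NA fields where
  a downstream report can tolerate them) rather than silently propagated.

## Limitations

The estimator assumes the windowed, shifted FID is single-component; real
voxels are not, and the absolute T2\* should be read as an *apparent* joint
relaxation time. The spike gate's threshold inherits the usual weakness of
SD-based gates: a burst of several spikes inflates the tracked SD and can
mask later, smaller spikes within the same session. The normalisation range
is monotone by design, so a session whose dynamic range collapses mid-run
will compress the displayed signal rather than re-scale. None of these
affect the relative, within-session feedback signal the method is built to
deliver, but they matter for quantitative cross-session comparisons.
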