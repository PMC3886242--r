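# fsvps

Signal processing for **functional single-voxel proton spectroscopy
(fSVPS) neurofeedback**: estimating BOLD-driven T2\* changes from
unsuppressed-water free-induction decays (FIDs) and conditioning them into
a real-time feedback signal.

In an fSVPS experiment a 7 T scanner repeatedly acquires the water FID of
one cubic voxel (TR = 1 s, TE = 20 ms, 1 kHz bandwidth, 512 complex
points). Neural activation changes the apparent transverse relaxation time
T2\* of the water line by a few percent, so a per-second T2\* estimate is a
direct functional signal with minimal processing latency — no image
reconstruction, no volume registration. `fsvps` is aimed at researchers
prototyping or validating such real-time spectroscopy pipelines.

## What it computes

Each FID frame is modelled as a sum of decaying complex oscillators,
`s(t) = Σⱼ Aⱼ exp(i2πfⱼt) exp(iφⱼ) exp(−t/T2*ⱼ)`. After shifting the water
peak to 0 Hz and applying a Gaussian spectral window, the surviving single
component obeys

```
ln s(t) = −t/T2* + ln A + i φ
```

— a complex straight line whose real slope gives T2\* by ordinary least
squares over an optimisable early segment `l` of the decay
(`optimize_regression_length()` picks `l` by maximising the session's
block-design t-value). The per-repetition T2\* series then passes through
the real-time chain: EMA detrending (α = 0.98, cutoff ≈ 0.003 Hz), a
spike-gated scalar Kalman filter (update ratio λ = 4, threshold
0.9 × running SD), and monotone range normalisation into [0, 1]. Sessions
are scored with CNR, percent signal change, block-design GLM t-values, and
event-related averages. A synthetic session generator with ground truth
(drift, spikes, B0 wander, first-order BOLD transitions) makes the whole
chain testable.

## Worked example

```r
library(fsvps)

ses <- simulate_session(seed = 42)   # default 7 T block-design session
ses
#> <svps_session> 300 repetitions (10 discarded), 512 points/FID, TR 1 s
#>   spikes: 9, baseline T2* 0.0842 s, activation delta +5%

lc <- optimize_regression_length(ses,
        candidate_lengths = seq(0.02, 0.45, by = 0.01))
lc
#> <svps_lcurve> 44 candidates; l_optim = 0.21 s (t = 9.885)

fb <- process_session(ses, svps_filter(regression_length = lc$l_optim))
session_metrics(fb, ses$design)
#>     cnr percent t_value dof event_snr n_cycles n_spikes
#> 1 1.042    0.05  12.538 288     2.679        4        2
```

Reading the output: the regression-length scan found its optimum at
0.21 s of FID; the conditioned series separates activation from baseline
with CNR ≈ 1.0 and a block-GLM t ≈ 12.5 on 288 degrees of freedom; the raw
(despiked) T2\* series shows a 5.0 % signal change, matching the injected
5 % BOLD contrast; two of the session's spikes landed in the analysed,
gate-armed region and were flagged. `autoplot(fb)` shows the four
conditioning stages; `autoplot(lc)` the t-value-versus-length curve;
`tidy()`/`glance()` methods return the underlying tables.

A command-line wrapper covers the same flow on stored sessions:

```sh
Rscript inst/cli/svps.R simulate --config run.yaml
Rscript inst/cli/svps.R optimize --config run.yaml --session runs/demo
Rscript inst/cli/svps.R process  --config run.yaml --session runs/demo
```

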