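---
title: "From raw two-channel photometry to group-averaged PSTHs: the methods behind photometr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw two-channel photometry to group-averaged PSTHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photometr)
```

## The problem and the signal model

Fiber photometry records bulk fluorescence from a genetically encoded
indicator (GCaMP, dLight, ...) through a single implanted fiber. The raw
signal channel mixes four components: slow photobleaching, movement
artifacts, sensor-dependent neural activity, and photon/electronics
noise. A second excitation wavelength at the indicator's isosbestic point
produces a control channel that carries the bleaching and movement
components but *not* the activity. The pipeline's core assumption is that
artifacts appear in both channels in proportion to each channel's overall
brightness, so that an affine map of the control onto the signal cancels
them.

The chain implemented here is:

1. **Denoise** both channels with a zero-phase moving-average filter.
2. **Trim** a fixed interval from the recording start (light-on artifact).
3. **Excise** user-selected artifact segments, keeping a list of chunks
   and realigning behavioral timestamps.
4. Per chunk, **fit** the control to the signal by least squares
   (degree 1) and form `dFF = (signal - fitted_control) / fitted_control`.
5. **Standardize** the concatenated trace to z units (three conventions).
6. Count **transients** with a two-stage median/MAD threshold.
7. Build event-aligned **PSTHs**, optionally baseline-corrected per
   trial, with AUC/peak measures in up to five windows.
8. **Average across sessions** with equal weights.

## Filtering

The moving-average FIR kernel of `filter_window` samples is applied
forwards and then backwards (`moving_average_zero_phase()`). The
double pass squares the magnitude response and cancels the phase, so
transient peaks are not shifted in time — a property the PSTH latencies
depend on, and one the test suite checks by brute-force
cross-correlation. Each pass reflect-pads the trace by one window length
and crops afterwards; reflection avoids the startup ramp a zero-padded
filter would smear into the light-on region. `filter_window` is *per
pass* and defaults to 100 samples, appropriate for kHz-rate acquisition;
at camera-style rates it should be scaled down to keep the smoothing
span around 0.1–0.5 s (the examples here use 10 samples at 20 Hz).

## Channel alignment and chunked fitting

Interleaved (multiplexed LED) acquisitions give each channel its own
frame times. `harmonize()` restricts both channels to their overlapping
time range and linearly interpolates the control onto the signal's grid;
signal samples are never altered. Linear interpolation is this package's
choice for the alignment; its error is second order in the frame period
and is tested against an analytic bound.

Artifact excision (`apply_chunks()`) keeps half-open `[start, end)`
intervals snapped to sample times, so both channels cut at identical
indices. Each kept chunk is fitted and normalized *separately* — a large
artifact in one segment then cannot corrupt the control fit of another —
and the chunks are concatenated before z-scoring. Retained event
timestamps are remapped with
`t' = concatenated_chunk_start + (t - chunk_first_sample_time)`, which
preserves every event's sample offsets exactly; the suite asserts that
trial extraction from a cut-and-reassembled trace is identical to
extraction from the uncut trace. Note that the per-chunk fits themselves
necessarily differ from the whole-trace fit (each chunk's least squares
sees different data), so continuity at the joins is checked statistically
(no step larger than five times the local noise) rather than exactly.

## Normalization conventions

* The degree-1 fit minimizes `sum((signal - (a*control + b))^2)`; a
  constant control is rejected as degenerate with a pointer to the
  pseudo-control path.
* `dFF` uses an epsilon guard (`1e-9` a.u.) on the denominator so a
  pathological fitted control produces a diagnosable error rather than
  silent `Inf`.
* **standard z**: mean and standard deviation over the whole trace. The
  *population* convention (denominator `n`) is used and locked by a
  scalar-loop test; for the trace lengths involved the difference from
  `n - 1` is negligible, but fixing it makes outputs bit-reproducible.
* **baseline z**: mean and deviation from a designated window, given in
  absolute session seconds (half-open). The per-trial, event-relative
  variant lives in the PSTH layer instead.
* **modified z**: `0.6745 * (x - median) / MAD`, with the *raw* MAD
  (no 1.4826 consistency factor — the 0.6745 multiplier plays that role:
  it is the third quartile of the standard normal, making the statistic
  agree in scale with the standard z for Gaussian data, which the suite
  verifies on 1e5 draws).

When no isosbestic channel exists, `fit_exponential_control()` smooths
the signal and fits `a * exp(-t / tau) + c` (tau > 0) by
Levenberg–Marquardt. A single exponential with offset was chosen as the
simplest bleaching model with a non-zero asymptote; initialization is
`a = first - last`, `c = last`, `tau = duration / 3`, and a
non-converging fit falls back to a linear trend with a warning. This
path corrects bleaching only — fast movement artifacts remain, which is
inherent to single-channel recordings.

## Transient detection

`detect_transients()` works on the z trace in two stages. Stage 1
partitions the trace into consecutive, non-overlapping windows of
`window_s` (default 15 s; the final partial window is processed as-is)
and removes, per window, samples above `median + 2 * MAD` — the
transients themselves — leaving a "resultant" noise-floor trace. Stage 2
takes `m = median(resultant)` and `d = MAD(resultant)` and counts strict
local maxima of the **full** trace exceeding `m + 3 d`. Candidates are
taken from the full trace because removing supra-threshold samples from
it would delete the very peaks being counted; only the statistic pool is
filtered. A local maximum is strictly greater than both neighbors;
plateaus contribute their first sample. Reported amplitude is the z
value at the peak, with no baseline subtraction.

Three consequences worth knowing:

* The procedure is invariant to adding a constant and to rescaling, so
  its operating point depends only on the trace's *shape*. On raw
  (unfiltered) white noise it will flag noise maxima at a stable,
  simulation-bounded rate; after the pipeline's low-pass filtering the
  candidate density drops sharply. The suite bounds the null behavior by
  simulating matched noise-only traces.
* Raising the stage-2 multiplier can only shrink the detection set
  (tested as a monotonicity property).
* The window must be long relative to one transient so each window's
  median tracks the noise floor; 15 s comfortably holds for ~1 s decay
  kernels.

## PSTHs and window measures

Trials are extracted on a uniform relative grid `[A, B)` with step
`1/rate` by **nearest-sample lookup** at `event + t` — events need not
coincide with sample times, and interpolation would smear the very
latencies being measured. Events whose window leaves the recording are
dropped and counted (`n_dropped`), never padded. With a baseline window
`[a, b)`, each trial's baseline mean is subtracted from that trial
before averaging, so corrected trials average exactly zero over the
baseline (tested to 1e-10). The mean PSTH carries the standard error
(`sd / sqrt(n)`, denominator `n - 1`).

AUC uses the trapezoidal rule on the mean PSTH (and, per trial, on each
row; by linearity the trial-mean of AUCs equals the AUC of the mean, an
identity the suite checks — no such identity holds for peaks, so both
per-trial and mean-PSTH peaks are reported). One deliberate exception to
the package's half-open interval convention: AUC/peak measurement
windows include both endpoints, so a constant trace `v` over a width-`w`
window integrates to exactly `v * w`.

Group averages stack one mean trace per session — equal weighting, so an
animal with many trials cannot dominate — and fail loudly on grid or
event-name mismatches rather than resampling.

## The synthetic generator

`generate_session()` builds `control = bleach_c(t) + artifact(t) + noise`
and `signal = bleach_s(t) + gain * artifact(t) + activity(t) + noise`,
with independent bleach parameters per channel (so the control-to-signal
fit is exercised nontrivially), Gaussian artifact bumps shared by both
channels, and difference-of-exponentials transients
(`exp(-t/decay) - exp(-t/rise)`, unit-normalized; rise 0.1 s, decay 1 s)
only in the signal. Defaults emulate a 30 min, 20 Hz striatal GCaMP
recording: bleach amplitudes of a few hundred a.u. over ~15–20 min time
constants, transients peaking near 5% dFF, and per-sample noise at 0.5%
of the bleach amplitude. The artifact gain defaults to the default
channels' brightness ratio (~1.6), reflecting that movement artifacts
scale with each channel's throughput — precisely the proportionality
assumption that lets isosbestic correction work. Generation is
bit-reproducible under a fixed seed, and the seed does not perturb the
caller's RNG stream.

What the generator does **not** emulate: hemodynamic contamination,
nonstationary noise, sensor kinetics beyond the fixed kernel, slow drift
that is not exponential, or correlated (pink) noise. Passing tests on
synthetic sessions therefore demonstrate correctness of the *pipeline
arithmetic and its contracts*, not robustness to every failure mode of
real recordings.

A known quantitative limitation, visible in the generator studies: the
fitted control multiplies control-channel noise by the fit slope, so
when the signal channel is much brighter than the control (slope ~2),
per-sample noise at 2% of the bleach amplitude drives the
dFF-to-true-activity correlation down to ~0.86; at the default 0.5%
noise it is ~0.94. Heavier smoothing does not recover this, because it
starts attenuating the ~1 s transients themselves.

## Problem sizes and determinism

The test suite and the acceptance script use 10–30 min sessions at
10–20 Hz (12,000–36,000 samples), 20–120 events per session, 1e4–1e5
draws for the statistical oracles, and 3-session groups with 40
repetitions for the averaging study — sizes at which every stochastic
check is stable across seeds while the whole suite runs in seconds. All
randomness flows through explicit seeds; repeated runs of the same
folder are asserted bit-identical.

## A worked example

```{r, eval = FALSE}
dir <- tempfile("demo")
write_demo_session(dir, seed = 1)            # 120 s synthetic session
params <- analysis_parameters(filter_window = 10,
                              psth_window = c(-2, 4),
                              psth_baseline_window = c(-2, 0),
                              measure_windows = list(c(0, 2)))
man <- run_analyze(params, dir, out_dir = file.path(dir, "out"))
summary(man$analyses[[1]])
plot(man$analyses[[1]]$psth$reward)
```
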