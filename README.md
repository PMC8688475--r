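# photometr

A headless, scriptable analysis pipeline for fiber photometry — bulk
fluorescence recordings of genetically encoded indicators (GCaMP,
dLight, ...) taken through an implanted optic fiber while an animal
behaves. It is aimed at labs that want the standard two-channel analysis
chain as plain R functions and a CLI, with every stage testable against
synthetic ground truth instead of screenshots.

## What it computes

Given a signal channel `S(t)` and an isosbestic control channel `C(t)`
(which carries bleaching and movement artifacts but no activity), the
pipeline:

1. applies a zero-phase moving-average filter (forwards + backwards) to
   both channels;
2. trims the light-on artifact and excises user-selected artifact
   segments, realigning behavioral timestamps exactly;
3. fits the control to the signal per kept chunk by least squares,
   `F(t) = a C(t) + b`, and forms

   ```
   dF/F = (S - F) / F
   ```

4. standardizes the concatenated trace: standard z
   `(x - mean)/sd`, baseline z (mean/sd from a designated window), or
   modified z `0.6745 (x - median) / MAD`;
5. counts whole-session transients with a two-stage MAD threshold
   (per-window removal of samples above `median + 2 MAD`, then strict
   local maxima above `median + 3 MAD` of the cleaned trace), reporting
   mean amplitude and frequency;
6. builds peri-event time histograms on a window `[A, B]` around each
   event, optionally subtracting each trial's baseline-window mean
   (`PSTH(i) = z(i) - mean(baseline of z(i))`), with trapezoidal AUC and
   peak in up to five measurement windows;
7. averages PSTHs across sessions with equal weight per session.

Recordings without an isosbestic channel are handled by fitting
`a exp(-t/tau) + c` to the smoothed signal as a bleaching pseudo-control.

Inputs are plain CSV (one `timestamps,data` file per channel, or a
single camera-style interleaved file with a `LedState` column; event
times as single-column CSVs). Outputs are full-precision CSV arrays plus
a JSON attribute sidecar. A synthetic-session generator
(`synth_params()` / `generate_session()`) produces ground-truth
recordings — bleaching, shared artifacts, signal-only transients, event
streams — in both input formats.

## Worked example

```r
library(photometr)
dir <- "demo"
write_demo_session(dir, seed = 1)   # 120 s synthetic session, 20 Hz
params <- analysis_parameters(filter_window = 10, psth_window = c(-2, 4),
                              psth_baseline_window = c(-2, 0),
                              measure_windows = list(c(0, 2)))
man <- run_analyze(params, dir, out_dir = file.path(dir, "out"))
summary(man$analyses[[1]])
```

```
<fp_analysis> 'demo'
  dF/F      : 2400 samples @ 20 Hz
  z-score   : method 'standard'
  transients: 14 (7 /min, mean amplitude 2.64 z)
  PSTH 'reward' : 11 trials (0 dropped)
<fp_measures> 'reward'
  [0, 2] s: AUC 4.211 z.s, peak 3.689 z
```

The demo session injects a calcium transient 0.5 s after each of 11
rewards plus spontaneous noise, so the analysis finds ~7 transients/min
and a reward PSTH peaking near +3.7 z shortly after the event; the AUC
is the area of that mean response over the first two seconds.
`plot(man$analyses[[1]]$psth$reward)` draws the mean ± SEM trace.

The same run from a shell:

```sh
Rscript inst/cli/photometry.R fixtures --out demo --seed 1
Rscript inst/cli/photometry.R analyze --config params.json --out results demo
Rscript inst/cli/photometry.R group   --config params.json --out results demoA demoB
```

## Layout

- `R/` — io (CSV readers, harmonization, results writer), preprocessing
  (filter, trim, chunking, exponential pseudo-control), normalization
  (fit, dF/F, z-scores), transients, PSTH, group averaging, synthetic
  generator, pipeline drivers
- `inst/cli/photometry.R` — `analyze` / `group` / `fixtures` / `plot`
  subcommands
- `vignettes/photometry-pipeline.Rmd` — the methods and their
  assumptions, parameter guidance, numerical conventions, limitations
- `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code)
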