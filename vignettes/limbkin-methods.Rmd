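---
title: "Measuring ballistic limb movements: the limbkin data model, protocol engine and kinematic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ballistic limb movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbkin)
```

## The measurement problem

In studies of use-dependent motor plasticity, a subject wearing a
glove-mounted three-axis MEMS accelerometer performs a ballistic movement
(typically a thumb flick) each time an acoustic cue sounds. Cues are
delivered at a fixed rate for the duration of a *block*; blocks are
repeated with rest breaks in between. The behavioural readout is the peak
acceleration of each cued movement and how its per-block mean changes over
the session. `limbkin` implements this measurement stack headlessly: the
recording data model and text format, the stimulation scheduler, signal
conditioning, the kinematic summaries, and a synthetic sensor that makes
the whole pipeline testable without hardware.

## Data model and on-disk format

A **sample** is one time point: time `t` on the continuous sample clock
plus acceleration `ax, ay, az` in m/s² (optionally raw sensor counts and
temperature). An **event** is the fixed window of `event_samples` samples
recorded after one trigger (1 s in the reference protocol). A **block**
collects the consecutive events of one stimulation period. In memory a
recording is a single sample table keyed by `sample_id` (global, 0-based,
contiguous), `block_id` (0-based contiguous) and `event_id` (0-based
contiguous *within* its block) — a deliberately flat representation that
any table tool can process; `get_event()`/`get_block()` slice it.

On disk a recording is three tab-separated/flat text files
(`.data.tsv`, `.time.tsv`, `.meta.txt`) with `#` comment lines and a
one-line header. The original acquisition software's file syntax is not
published; this dialect is a re-design chosen to be greppable, diffable
and loadable by any table reader, not a reverse-engineered match. Floats
are written with 17 significant digits, which makes the write→read round
trip bit-exact for doubles (verified over randomized recordings). The
second file carries ISO-8601 wall-clock stamps per sample with a marker
column, so breaks and delays remain visible although `t` is continuous.
`validate_recording()` collects every invariant violation (ID
monotonicity/contiguity, per-event sample counts against the governing
protocol, timestamp/metadata consistency) without raising, and the
reader rejects exactly what the validator flags.

## Protocol engine

`protocol_config()` captures the acquisition settings: stimulation rate
in **mHz** (the field's convention for slow cue rates; 500 mHz = one cue
per 2 s), block duration and pause in seconds, repetitions, event length
in samples, and the sampling rate (4 Hz–4 kHz, full scale ±2/4/8 g).
Two conventions are underdetermined by the acquisition-software
description and fixed here explicitly: events per block is
`floor(block_duration_s × stim_rate_mHz / 1000)` and the first cue of
each block fires at the block start — `floor` plus start-anchoring
guarantees all events fit inside their block. The schedule places block
*b* at `b × (block_duration_s + pause_s)`. The reference protocol
(6 × 30 events of 1000 samples at 1 kHz, 60 s breaks) does not uniquely
determine the cue rate; `reference_protocol()` uses 500 mHz with 60 s
blocks, the simplest configuration consistent with 30 one-second events
per block. Trigger edge and beep are kept as schedule metadata — timing,
not electrical levels or audio, is what matters downstream.

`run_protocol()`/`external_trigger_run()` execute a schedule against a
movement *source* — any function mapping times to an n×3 acceleration
matrix. Schedules are seed-invariant; only source noise consumes random
numbers, so one integer seed reproduces a recording exactly.

## Signal conditioning

MEMS accelerometers carry constant per-axis bias, and the sensor at rest
additionally reads the gravity projection. `estimate_offset()` implements
automatic offset calibration on a static window (at least 0.5 s): the
offset is the per-axis mean, minus 9.81 m/s² on an explicitly named
gravity axis if the 1 g reading should be preserved. Gravity handling is
an explicit parameter rather than a heuristic because removing gravity
silently would corrupt orientation experiments, while keeping it would
corrupt peak detection. `calibrate_recording()` applies this to a whole
recording, pooling the pre-movement window (default first 0.1 s, inside
the ~150 ms human reaction time to the cue) of every event; its default
`gravity_axis = "none"` drives all axes to zero mean, removing bias *and*
gravity — the preparation peak analysis needs. Peak extraction refuses
uncalibrated recordings unless forced, since `max |a|` of an uncalibrated
signal measures orientation (≈9.81 m/s²), not movement.

The optional high-pass stage is a first-order Butterworth filter
(`signal::butter`), default cutoff 0.1 Hz: first order matches the
single-pole DC-drift removal typical of MEMS front ends and is the
simplest defensible choice, since neither order nor cutoff is dictated by
the hardware description. Range clipping saturates at ±range·9.81 m/s²
and flags affected samples instead of dropping them. The gravity constant
is fixed at 9.81 m/s² throughout (rather than 9.80665) to match the
conventional 1 g ↔ 9.81 conversion used in this field's reports.

## Kinematics and statistics

`analyze_segment()` evaluates a user-chosen sub-window of one event
(half-open, 0-based `[start, end)` indices). Velocity and displacement
are cumulative trapezoidal integrals (`pracma::cumtrapz`) with
`v(0) = s(0) = 0`: the segment is assumed to start at rest, which is what
makes the user's habit of placing the start marker just before movement
onset meaningful. No detrending or drift correction is applied inside a
segment — over the ≤1 s windows involved, residual bias after calibration
integrates to negligible drift, and silent detrending would make the
displacement estimate untraceable. Trapezoid integration is exact for
(piecewise-)linear acceleration and has O(dt²) error for smooth signals;
the tests pin this against closed forms and an independent 10×-refined
oracle. Summaries report min/max/mean for all twelve
quantity × component combinations (a, v, s × x, y, z, abs).

Peak acceleration is `max |a|` over the event: the absolute-value channel
is the default component because it is the only rotation-invariant
choice (axis-specific peaks remain available). `block_stats()` reports
the per-block mean and sample SD (n−1 — the standard error-bar convention
over repeated trials; flagged `NA` for single-event blocks), and
`percent_change()` compares first and last block as
`(m_last − m_first)/m_first × 100`, which is invariant under common
rescaling of all accelerations. No significance testing is provided: the
intended use is descriptive block summaries and export
(`export_stats()`) for whatever inferential analysis a study prescribes.

## Synthetic sensor

Three generators emulate the validation experiments a physical setup
would undergo:

* `static_signal()` projects gravity onto the sensor axes under a
  sequence of single-plane tilts (axis vertical, 45°, …). Single-plane
  tilts cover every placement used in rotation validation with far less
  surface than full quaternion orientation. The noiseless magnitude is
  exactly 1 g at every sample; a vertical axis reads 9.81 m/s², a 45°
  tilt puts 9.81/√2 ≈ 6.94 m/s² on each of the two involved axes.
* `flick_signal()` models the cued ballistic movement as silence during
  the reaction time followed by a biphasic accelerate-then-brake pulse —
  the derivative of a Gaussian, truncated at ±3σ (duration = 6σ) and
  scaled so the programmed peak is the exact continuous-time maximum of
  |a|. The symmetric truncation returns the velocity integral exactly to
  zero at the pulse end while displacement stays positive: the limb
  stops in a new position. The real movement's profile is known only
  qualitatively, so this shape is an explicit modelling choice: smooth,
  biphasic, and with the correct integral behaviour.
* `learning_experiment()` assembles a full protocol recording: event
  *j* of block *b* gets true peak
  `base_peak × block_trend[b] × (1 + e)`, `e ~ N(0, event_cv)`, plus the
  gravity projection, constant bias and white sensor noise
  (default SD 0.02 m/s² per axis at 1 kHz — a low-noise MEMS figure,
  kept configurable since the exact noise density is sensor-datasheet
  territory). The programmed per-event peaks are attached as ground
  truth.

Default study conditions mirror the reference experiment: 6 blocks × 30
events × 1000 samples at 1 kHz with 60 s breaks, baseline peak 2 m/s²,
a linear trend to 1.525× (a +52.5 % last-vs-first change, the magnitude
reported for motivated subjects in this paradigm), and 5 % event-level
coefficient of variation — a realistic trial-to-trial variability for
ballistic movements. With 30 events per block the standard error of a
block mean is `0.05/√30 ≈ 0.9 %` of its mean, so the recovered percent
change scatters around the programmed value with an SD of roughly 2
percentage points; the end-to-end test uses a ±3.9-point band at a fixed
seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: reaction-time variability and anticipatory
movements, multi-axis movement curvature, sensor-axis misalignment and
cross-axis gain, temperature drift, quantization, and transport timing
jitter. Parameter recovery here demonstrates that the *pipeline* is
faithful, not that any behavioural effect exists.

## Numerical and degenerate-case choices

* Exact text round trip via 17-significant-digit floats; integer ID and
  raw-count columns stay integer.
* Empty recordings (0 blocks) are valid and write header-only files;
  empty trigger lists yield empty recordings; empty segments and empty
  events are errors, not silent zeros.
* SD of a single-event block is `NA`, never 0; percent change requires a
  positive baseline and ≥2 blocks (`NA` reported otherwise by the
  analysis command).
* Range clipping saturates and flags rather than drops, mirroring the
  physical sensor rail.
* Problem sizes in the test suite are chosen so the whole suite runs in
  well under a minute: the full 180 000-sample reference experiment is
  exercised once end-to-end, all other properties use scaled-down
  protocols (a few blocks of a few short events), which exercise the
  identical code paths.

## Limitations

The format dialect is package-defined, not compatible with the original
acquisition software's files. Calibration assumes the pre-cue window is
truly static; subjects who anticipate the cue violate this and bias the
offset. Integration is segment-local with no drift correction, so
displacement over windows much longer than a movement accumulates O(t²)
error from any residual bias. The protocol engine models timing ideally —
no jitter, latency or dropped samples.
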