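# limbkin

Headless analysis of wearable three-axis accelerometer recordings of cued
ballistic limb movements — the kind of data produced by a glove-mounted
MEMS sensor in motor-practice and plasticity studies, where a subject
flicks the thumb on an acoustic cue and the change of peak acceleration
across trial blocks is the behavioural readout.

The package implements the whole measurement stack in software:

* **Data model & format** — a recording is an ordered table of *samples*
  (one time point of x/y/z acceleration), grouped into *events* (the
  fixed-length window after one trigger) and *blocks* (a session of
  events separated by breaks). On disk a recording is three plain-text
  files: `<base>.data.tsv` (samples), `<base>.time.tsv` (wall-clock
  timestamps with break/delay markers) and `<base>.meta.txt` (key=value
  metadata). The write→read round trip is exact.
* **Protocol engine** — acoustic-stimulation scheduling (stimulation rate
  in mHz, block duration, pause, repetitions), free-running and
  external-trigger acquisition, executed against simulated movement
  sources.
* **Signal conditioning** — automatic offset calibration with explicit
  gravity handling, first-order high-pass filtering, magnitude
  computation, range clipping.
* **Kinematics & statistics** — segment-wise trapezoidal integration of
  acceleration a(t) to velocity v(t) = ∫a dt and displacement
  s(t) = ∫v dt (from rest at the segment start), per-event peak
  acceleration `max |a|`, per-block mean ± SD of peaks, and the percent
  change of the mean peak between first and last block,
  Δ% = (m_last − m_first)/m_first × 100.
* **Synthetic sensor** — static gravity projections under sensor rotation
  (a vertical axis reads 1 g = 9.81 m/s²; at 45° two axes read
  6.94 m/s²), biphasic ballistic movement pulses with a programmed peak,
  and complete multi-block experiments with a programmed learning trend —
  so every stage is testable without hardware.

## Worked example

Simulate the reference protocol — 6 blocks × 30 cued events of 1000
samples at 1 kHz, 60 s breaks — with a +52.5 % programmed last-vs-first
block trend in true peak acceleration, and analyse it:

```r
library(limbkin)

rec <- learning_experiment(reference_protocol(), base_peak = 2,
                           block_trend = seq(1, 1.525, length.out = 6),
                           event_cv = 0.05, seed = 7, gravity_axis = "z")
base <- tempfile()
write_recording(rec, base)              # three text files

rec <- calibrate_recording(read_recording(base))  # remove bias + gravity
stats <- block_stats(rec)               # per-block mean +/- SD of peaks
stats
#> Peak acceleration by block [m/s²]:
#>  block_id n_events mean_peak sd_peak
#>         0       30     2.065 0.11397
#>         1       30     2.238 0.08834
#>         2       30     2.446 0.11367
#>         3       30     2.678 0.11488
#>         4       30     2.883 0.11893
#>         5       30     3.085 0.14364
#> last vs first block: +49.4%
```

Each row is one block: the mean and standard deviation (n−1) over the 30
per-event peak accelerations. The recovered change (+49.4 %) estimates
the programmed +52.5 % within the sampling error of 30 events/block at
5 % event-to-event variability. Kinematics of a single event:

```r
ev <- get_event(rec, block_id = 5, event_id = 0)
sa <- analyze_segment(ev, dt = 1e-3)    # velocity + displacement series
sa$summary                               # min/max/mean for a, v, s (x,y,z,abs)
```

A thin command-line wrapper is installed at `inst/exec/limbkin`
(`limbkin simulate|analyze|validate`), driven by YAML scenario configs.

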