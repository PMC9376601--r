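# tremorsense

Quantifies postural tremor from six-channel inertial recordings — 3-axis
linear acceleration plus 3-axis angular velocity, as produced by a
smartphone strapped to the hand or a finger-mounted IMU — and turns a 1-min
recording into a single, gain-invariant tremor score suitable for tracking
essential tremor (ET) and Parkinson's disease (PD) tremor over time, e.g.
as the sensing side of on-demand deep-brain-stimulation adjustment.

It is written for researchers and engineers in movement-disorder digital
biomarkers who need a scoring pipeline that is deterministic, testable
without patient data, and identical across heterogeneous sensors.

## The metric

Tremor is rhythmic; everything else the sensor sees (sway, voluntary
corrections, noise) has a scale-free 1/f^β spectrum. Per 50%-overlapping
8-s window and channel, the pipeline separates the two with IRASA
(irregular-resampling auto-spectral analysis): the window's ordinary
("mixed") PSD is divided by a fractal PSD obtained by resampling the signal
by factors h and 1/h (h = 1.10, 1.15, …, 1.90), geometric-averaging each
pair of periodograms and taking the bin-wise median across factors —
rhythmic peaks shift under resampling and drop out of the median, the
power-law background does not. The resulting oscillatory **ratio spectrum**
is ≈1 in background and ≫1 at a tremor peak, and is exactly invariant to
sensor gain.

Each window's **tremor index** is the maximum of the Gaussian-smoothed
(σ = 1 Hz) ratio spectrum over 3.5–10 Hz. The recording's score *I* is the
median of the top third of all (window × channel) indices, and is reported
in decibels relative to a control cohort:

    I_dB = 10 · log10( I / ⟨I_CTRL⟩ )

so 0 dB means "at the control-population average".

Because no raw patient recordings are available, the package ships a
simulator (`simulate_recording()`, `simulate_cohort()`) that generates
recordings with the statistical structure the pipeline assumes — fractal
background, amplitude-modulated frequency-jittered tremor projected onto
six channels, paired finger/phone sensors, ET/PD/control cohorts with a
severity surrogate — plus cohort evaluation tools (`roc_auc()`,
`correlate_severity()`, `peak_over_background()`, `cohort_report()`).

## Worked example

```r
library(tremorsense)

# a simulated ET subject: 6 Hz tremor at 3x the background RMS,
# recorded by the phone sensor (60 s at 100 Hz)
p   <- subject_params("ET", seed = 41, tremor_rel_amp = 3, tremor_freq = 6)
rec <- simulate_recording(p, sensor_model("phone"))
rec
#> <tremor_recording> phone sensor, position P1, subject 'sim000041'
#>   6 channels x 6000 samples at 100 Hz (60.0 s)

# calibrate a control reference from 7 simulated control subjects
ctrl <- sapply(1:7, function(i) {
  cp <- subject_params("CTRL", seed = 2000 + i)
  score_recording(simulate_recording(cp, sensor_model("phone")))$index
})
ref <- write_control_reference(ctrl)

score_recording(rec, control = ref)
#> <tremor_score> index 28.91 (10.48 dB vs control mean 2.587)
#>   dominant frequency 6.06 Hz; 28 of 84 windows used
```

Reading the output: the smoothed oscillatory ratio peaks at 28.9 — the
rhythmic component stands ~29× above the fractal background — at a
dominant frequency of 6.06 Hz (the simulated 6 Hz tremor, recovered to
within one 0.125-Hz frequency bin). The score is +10.5 dB above the
control-population mean; simulated controls themselves score within about
±1 dB of 0.

The same pipeline is scriptable from a shell via the installed CLI
(`system.file("cli/tremorsense", package = "tremorsense")`) with the
subcommands `score`, `simulate`, `calibrate` and `report`; a control
reference is bound to a hash of the pipeline configuration and `score`
refuses a reference produced under different settings.

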