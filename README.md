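# fmgposture

Real-time classification of upper-extremity postures from forearm
**force myography** (FMG): an eight-channel strap of force-sensing
resistors (FSRs) reads the surface pressure pattern of the forearm
muscles, and an **extreme learning machine** (ELM) maps each processed
sample to one of the six postures of the *drinking task* used in
constraint-induced movement therapy — relax, 90° elbow flexion, fingers
extension, soft grasp, 120° elbow flexion, wrist pronation. The intended
users are rehabilitation-engineering researchers who want a tested,
fully reproducible software pipeline for FMG posture recognition,
complete with a physically motivated synthetic strap so that every stage
runs without hardware.

## What is inside

**Sensing model.** Each channel is a voltage divider
`V = Vcc·R_base/(R_base + R_fsr(p))` (5 V, 22 kΩ) where the FSR falls
from >10 MΩ at rest as `R_fsr(p) = min(R_rest, k/p)`. The simulator adds
the human and sensor effects that make real sessions hard: 0.5–1.5 s
response delays after each command, 0.5 s linear transitions between
postures, per-repetition template jitter, Gaussian noise and slow drift.

**Processing chain** (causal, streaming): 1 kHz sampling → 2nd-order
Butterworth low-pass at 4 Hz → moving-average decimation (window 200,
step 100 → 10 Hz features; 5 s ⇒ exactly 50 samples) → per-channel
min–max normalization fitted on the training buffer only.

**Classifier.** Non-kernel sigmoid ELM: hidden weights `(a_i, b_i)` are
random and fixed (uniform on [−1, 1], `L = 200` nodes); only the output
weights are trained, in closed form, as the ridge solution

    β = Hᵀ(I/C + HHᵀ)⁻¹T        (N ≤ L)
    β = (I/C + HᵀH)⁻¹HᵀT        (N > L, algebraically identical)

with `C = 2⁷` and `T` the 1-of-K target matrix. Training the default
900 × 8 buffer is a single 200 × 200 solve — milliseconds — so the
classifier is retrained every time the strap is put on.

**Protocol and evaluation.** Training: 6 postures × 3 repetitions, 5 s
recorded per hold (900 features). Testing: the instruction sequence
1-2-3-4-5-6-5-4-3-1, three repetitions, classified in streaming order.
Evaluation estimates the wearer's response delay at the relax→flexion
transitions, shifts predictions forward by the mean delay, and reports
overall/per-class accuracy, the most-misclassified class, and the
stability of the result under re-training with fresh random bases.

## Worked example

```r
library(fmgposture)

cfg <- run_config(seeds = list(simulation = 7, templates = 7, basis = 7))
res <- run_study(cfg)          # simulate, train, stream-classify, evaluate

res$delay
#> <delay_estimate> sections: 1.5, 1.5, 1.2 s; mean 1.40 s, SD 0.17 s
res$report
#> <eval_report> overall accuracy 94.83% over 1006 samples
#>   per-class %:  1= 97.9  2= 87.8  3= 95.0  4= 91.7  5= 95.6  6= 96.7
#>   most misclassified: class 2 (87.8%)
res$stability
#> <stability_report> accuracies: 94.8, 94.8, 94.7, 94.8, 94.9, 94.8 %
#>   mean 94.8%, SD 0.1%
```

Reading the output: the simulated wearer took ~1.4 s to react to each
instruction (this includes the pipeline's own ~0.1–0.2 s group delay);
after compensating that shift, 94.8 % of the 10 Hz grid points are
classified correctly. Class 2 (90° elbow flexion) is the weakest class,
and the remaining errors sit almost entirely within ±0.5 s of command
changes — transitional samples the classifier never sees in training.
Re-training with five fresh random hidden bases moves the accuracy by
only ±0.1 points: the random basis is not a sensitive ingredient. The
same conventions reproduce the published six-volunteer aggregates
exactly, e.g.

```r
aggregate_stats(reference_results()$realtime$accuracy)
#> $mean
#> [1] 92.33
#> $sd
#> [1] 3.19
```

A command-line driver wraps the same pipeline
(`system.file("cli", "fmg.R", package = "fmgposture")`) with
`simulate` / `train` / `evaluate` / `study` subcommands operating on CSV
session files and a YAML configuration.

## Further reading

See the methods vignette (`vignettes/fmgposture-methods.Rmd`) for the
sensor model, the design decisions behind the filter/decimator/
normalization choices, what the synthetic data does and does not
emulate, and known limitations.
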