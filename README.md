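# renyieeg

Wavelet Rényi entropy analysis of resting-state prefrontal EEG for
tracking mental fatigue across repeated assessments.

## The problem

Prolonged cognitive load under stress — long shifts, multi-day
competitions, sleep deprivation — degrades alertness in ways that
self-report scales capture only coarsely and short cognitive tasks often
miss. A spectral signature of this state is visible in eyes-closed
resting EEG over the prefrontal cortex: the alpha-dominant band profile
of the alert brain *flattens*, spreading power more evenly across the
delta, theta, alpha and beta rhythms. `renyieeg` turns that flattening
into a single per-session marker and provides the full analysis chain
around it, for researchers who want to apply or stress-test the marker
without access to the original recordings.

## The marker

Each preprocessed channel is cut into 8-s windows (50% overlap). A
4-level discrete wavelet transform (Daubechies-4, periodized) at the
62.5 Hz effective rate assigns detail levels 1–4 to the β, α, θ and δ
bands. After an in-band threshold denoising step (coefficients with
|w| > mean(|w|) + 2·sd(|w|) are halved), band energies and relative
energies are

    E_j = Σ_k w_j(k)² ,   p_j = E_j / Σ_j E_j ,

and the per-window marker is the normalized order-2 Rényi entropy

    RE = −log(Σ_j p_j²) / log 4  ∈ [0, 1] ,

averaged over windows to one session value. RE = 1 for a flat profile,
0 for a one-band profile; rising RE across sessions indicates
accumulating fatigue. Inference across sessions uses within-subject
ANOVA with unconditional Greenhouse–Geisser correction, Mauchly
sphericity diagnostics, LSD post-hoc contrasts and pooled Pearson
correlations with sleep duration.

Because no public dataset accompanies the design this package targets,
a seeded synthetic cohort generator (band-limited filtered-noise
oscillations on 1/f background, programmed entropy trajectories, SSS /
oddball reaction-time / sleep trends) is a first-class module; every
stage is validated closed-loop against programmed ground truth. See the
methods vignette (`vignettes/wavelet-renyi-fatigue.Rmd`) for the model,
parameter choices and limitations.

## Worked example

```r
library(renyieeg)

spec <- cohort_spec(n_subjects = 4, duration_s = 64, n_channels = 1, seed = 42)
rec  <- generate_eeg(spec, subject = 1, session = "Day1")
rec
#> <eeg_recording> 1 channels x 16000 samples @ 250 Hz (64.0 s)
#>   channels: AFp7
#>   subject: 1  session: Day1

epochs <- preprocess_channel(rec, channel = "AFp7")  # bandpass -> zscore -> decimate -> segment
epochs
#> <epoch_set> 15 epochs of 8 s (500 samples) @ 62.5 Hz, overlap 0.5, channel AFp7

session_entropy(epochs)
#> <entropy_result> 15 epochs, q = 2, normalized: session value 0.7615 (range 0.6681-0.8525)
```

The session value 0.76 sits where a Day-1 (rested) recording should:
well above the one-band floor of 0, below the flat-profile ceiling of 1.
Running the whole pipeline on a small simulated cohort:

```r
cfg <- pipeline_config(seed = 42,
                       cohort = list(n_subjects = 4, duration_s = 64,
                                     n_channels = 2))
res <- run_pipeline(cfg, output_dir = "out", quiet = TRUE)

res$anova$entropy_timepoint
#> <rmanova_result> condition: F(1.861, 5.583) = 10.850, p = 0.01247 (GG eps = 0.372; ...)

subset(res$summary, metric == "entropy")
#>   metric session      mean         sd
#>  entropy    Day1 0.8067497 0.04850973
#>  entropy    Day2 0.8236729 0.05425029
#>  entropy    Day3 0.8121582 0.05929304
#>  entropy   Day4A 0.8415529 0.02751227
#>  entropy   Day4B 0.8433667 0.04296758
#>  entropy    Day5 0.8833329 0.04601454
```

Session mean entropy rises across the six assessments (flat through the
rested phase, jumping in the sleep-deprivation phase), and the
GG-corrected timepoint effect is significant even for this 4-subject,
64-s-per-recording miniature. `res$correlations` additionally reports
the pooled entropy–sleep correlation (negative: less sleep, higher
entropy), and `out/` contains the per-epoch entropy table, assessments,
ANOVA, LSD and summary CSVs, each stamped with the config hash.

A command-line front end with `simulate` / `extract` / `behav` /
`stats` / `report` / `run` subcommands is installed at
`inst/cli/renyieeg-cli.R`:

```sh
Rscript inst/cli/renyieeg-cli.R run --seed 7 --out out/
```

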