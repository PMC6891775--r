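# rdfd: altitude-corrected driving fatigue estimation

`rdfd` estimates a driver's accumulating fatigue from physiological
recordings — beat-to-beat heart period (R-R intervals) and spontaneous
eye blinks — on mountain roads where rapid altitude change distorts
heart-rate-based measures.  It is aimed at researchers in driver-state
monitoring and transportation safety who work with heart-rate belts or
ECG plus eye-tracking data on high-altitude routes.

## The method

Within each aggregation window (default 2 min) the R-R intervals are
summarized by their mean M and sample standard deviation SDNN, giving
the variation coefficient

    RRVC = SDNN / M

The **driving fatigue degree** normalizes the rise of RRVC over the
drive by the fatigue the driver brings to the wheel:

    BDF   = RRVC_initial − RRVC_static        (pre-drive fatigue)
    FC_i  = RRVC_i − RRVC_static              (cumulative fatigue)
    DFC_i = RRVC_i − RRVC_initial             (cumulative driving fatigue)
    DFD_i = DFC_i / BDF

where `RRVC_static` comes from a seated-rest recording and
`RRVC_initial` from the first driving window after the 1000-s
excitement-period trim.  A blink-frequency analogue (blinks/min in the
same windows, same normalization) is insensitive to altitude and serves
as reference.  On segments with rapid altitude change the HRV-based
series is rescaled by an altitude-dependent cubic correction factor,
calibrated per slope direction (up/down) from the pointwise ratio of
the two series:

    rDFD_i = δ(h_i) · DFD_i,   δ(h) = c0 + c1·h + c2·h² + c3·h³

Cubic trends fitted to the fatigue series yield fatigue-state
breakpoints at their inflection points, t* = −b2/(3·b3).  The package
also ships the published calibration results for the 3540–4768 m study
range (`delta_reference()`, `rdfd_reference()`), a Pan-Tompkins-style
R-peak detector for raw ECG, and a synthetic-data generator that plants
known fatigue trajectories and correction factors for end-to-end
validation.

## Worked example

Generate a drive with a known planted correction factor and run the
full pipeline:

```r
library(rdfd)

cfg <- scenario_config()                      # 7000-s high-plateau drive
sc  <- gen_coupled_scenario(cfg, delta_reference("up"), seed = 3)

report <- run_pipeline(sc$rr, sc$blinks, sc$altitude,
                       rrvc_static = cfg$rrvc_static,
                       bf_static   = cfg$bf_static)
report
#> <rdfd_report>
#>   42 windows of 120 s, BDF 0.01921
#>   slope segments: up, down, up
#>   agreement with the blink reference:
#>     comparison        ss        F        sig_F        r2  n
#>   dfd_vs_blink 2345.0625 211.1944 1.495972e-17 0.8407608 42
#>  rdfd_vs_blink  132.3188 383.2993 4.235710e-22 0.9055042 42
#>   fatigue breakpoints: hrv 2996 s, blink 3442 s, revised 3376 s
```

Reading the output: the drive splits into up/down/up slope segments;
the uncorrected HRV fatigue series agrees with the blink reference at
R² 0.84, and after altitude correction the revised series reaches
R² 0.91 with a sum of squared differences an order of magnitude
smaller (2345 → 132) — the correction removes most of the
altitude-induced distortion.  The fitted cubic trends place the
fatigue-state breakpoint near 3000–3400 s into the drive.  The
published upslope correction factor evaluates as

```r
evaluate_delta(delta_reference("up"), c(3540, 4000, 4768),
               warn_extrapolation = FALSE)
#> [1] 1.532726 4.375000 2.482444
```

A thin command-line wrapper with `simulate`, `dfd`, `calibrate`,
`revise` and `run` subcommands is installed at
`system.file("cli", "rdfd.R", package = "rdfd")`.

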