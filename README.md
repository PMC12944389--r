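# wovmd — surface-EMG denoising for high-duty-cycle tasks

`wovmd` denoises single-channel surface electromyography (sEMG) recorded
during rapid, repetitive tasks such as keystrokes. In that regime two
standard ingredients of decomposition-based denoising fail quietly: the
parameters of variational mode decomposition (VMD) are usually hand-tuned,
and the classical universal threshold estimates the noise level from the
whole record — which is inflated by sustained muscle activation, so the
threshold over-attenuates the activity it should preserve.

The package implements a pipeline that fixes both:

1. **Preprocessing** — zero-phase Butterworth band-pass (10–500 Hz) and a
   50 Hz notch.
2. **WO-VMD** — a walrus-optimizer search over the mode count
   *K* ∈ [2, 15] and bandwidth penalty *α* ∈ [500, 2000]; each candidate
   runs a full VMD (ADMM in the frequency domain, compiled inner loop) and
   is scored by the **minimum mode envelope entropy**: the smallest
   Shannon entropy of the time-normalized Hilbert envelopes across modes
   carrying ≥ 1 % of the energy. Burst-structured activity scores low;
   noise scores near the log₂ *N* maximum.
3. **Mode screening** — modes whose mean instantaneous frequency falls
   outside the physiological band (10–500 Hz) are discarded.
4. **Interval thresholding** — each retained mode is tiled at its zero
   crossings and thresholded per interval from the interval's single
   extremum (hard: keep/kill; soft: additionally shrink by
   (|u(q)| − T)/|u(q)|). The threshold is the **rest-calibrated**

   &nbsp;&nbsp;&nbsp;&nbsp;*T = C σ √(2 ln N_rest)*,&nbsp;&nbsp;
   σ = median(|u_rest|)/0.6745,

   with σ estimated on a resting segment (a protocol rest prefix, or one
   found by sliding-window RMS) and *C* an operator-dependent calibration
   (0.3 soft, 0.7 hard). The classical universal threshold
   σ√(2 ln N) is included as the comparison baseline.
5. **Metrics** — SNR, RMSE, median frequency (Welch PSD) and their delta
   forms (ΔSNR, ΔRMSE%, ΔMDF%).

Because the underlying human recordings are not public, the package ships
a synthetic keystroke-sEMG generator (5 s rest + 20 keystrokes at 60 BPM,
1500 Hz, 20–450 Hz band-limited bursts, calibrated white-noise injection
at exact input SNRs) used by the tests and the benchmark harness.

## Worked example

```r
library(wovmd)

# simulate one keystroke trial and contaminate it at 10 dB input SNR
cfg <- synthetic_config(n_keystrokes = 8, seed = 51)
clean <- generate_keystroke_semg(cfg)
noisy <- add_wgn(clean, input_snr_db = 10, seed = 151)

# denoise with the proposed configuration (T4, soft, C = 0.3)
res <- denoise_pipeline(noisy, wo = wo_config(pop_size = 10, max_iter = 10,
                                              seed = 51))
res
#> <denoise_result> scheme T4 (soft, C = 0.3), K = 15, alpha = 885
#>   kept 15/15 modes; thresholds: 0.0185, 0.0166, 0.0152, 0.0159, 0.0158,
#>   0.0149, 0.0149, 0.0141, 0.0151, 0.0149, 0.0142, 0.014, 0.014, 0.0156,
#>   0.0186

evaluate_denoising(clean, noisy, res$denoised)
#> <metrics_report>
#>   SNR: 10.00 -> 15.03 dB (delta 5.03 dB)
#>   RMSE: 0.07496 -> 0.04199 (44.0% removed)
#>   MDF: 222.4 -> 219.3 Hz (-1.40% shift)
```

The search selected 15 modes with α = 885; all mean instantaneous
frequencies fell inside 10–500 Hz, so every mode was kept, thresholded
with its own rest-calibrated threshold and summed. Denoising gained
5.0 dB of SNR, removed 44 % of the RMSE, and shifted the median frequency
by under 2 % — i.e. noise was removed without distorting the spectral
content that downstream sEMG analyses (fatigue, force estimation) rely
on.

A command-line front end with `simulate`, `denoise`, `evaluate` and
`benchmark` subcommands is installed at `inst/cli/wovmd.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/wovmd.R", package="wovmd"))')" \
    simulate --snr 10 --out clean.csv --out-noisy noisy.csv
```

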