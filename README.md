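# biostress

Detecting transient emotional stressors from multimodal wearable
biosignals.

When a person rides or drives a vehicle, sudden stressors — a narrow
corridor, an unexpected obstacle — leave a coordinated trace across their
physiology: skin conductance rises within a couple of seconds, heart rate
follows about 6.5 s later, blinking intensifies about 4.65 s behind the
self-report, and frontal EEG alpha power becomes asymmetric between the
hemispheres. `biostress` implements a complete analysis pipeline for
recovering those moments from raw sensor streams, together with a
deterministic synthetic-cohort simulator that provides ground truth for
every stage. It is aimed at researchers in affective computing and
psychophysiology who need a tested, reproducible reference implementation
of this class of multi-sensor analysis.

The pipeline has four analysis stages on top of the simulator:

1. **Characterizations, organized by time scale.**
   Long-term: blink counts in 2 s bins, the tonic skin conductance level
   (SCL, 30 s running median), the heart-rate-variability ratio
   LF/HF = ∫₀.₀₄⁰·¹⁵ S(f) df / ∫₀.₁₅⁰·⁴ S(f) df computed per 20 s window by
   Welch's method (Hamming-tapered overlapping segments on the 4 Hz
   resampled inter-beat series), and the Mindwave meditation score.
   Short-term: square-wave encodings of significant slope increases in
   smoothed GSR and blink rate (slope > k·1.4826·MAD of the derivative,
   k = 3; each run becomes a rectangle of width = run duration and
   height = peak amplitude), the median RRI (reciprocal of the 5 s
   windowed median RR interval), and frontal alpha asymmetry
   (right-minus-left 8–13 Hz band power over F3/FC3/C3 vs F4/FC4/C4).
2. **Correlation mapping.** Kolmogorov–Smirnov normality screening,
   one-parameter Box–Cox transformation (yₜ = (yˡ − 1)/λ, log for λ = 0),
   pairwise Spearman ρ with the significance rule p < 0.001 and |ρ| > 0.5,
   primary/secondary tiers relative to the evaluation lever, and lag
   estimation by rank cross-correlation.
3. **EEG time–frequency analysis.** Zero-phase 8–25 Hz band-pass,
   spectrograms at 0.1 Hz frequency resolution, condensation into α₁
   (8–12 Hz), α₂ (13–15 Hz) and β (16–20 Hz) bands, per-band slope and
   variance, and z-score counting of significantly activated channels.
4. **Stressor-presence classification.** Stressor-interval labels (2/4/5 s
   interval means against per-source cutoffs; 1 = presence, 2 = absence),
   3–50 Hz preprocessing, alpha-ratio features (8–13 Hz power over
   4–30 Hz, per channel or left-minus-right), and stratified ten-fold
   cross-validation with LDA, linear SVM, or logistic regression.

## A worked example

Simulate one five-minute autonomous-riding session with six stressor
events, characterize it, and map the correlations:

```r
library(biostress)

sched <- make_schedule(duration = 300, n_events = 6, min_gap = 10, seed = 42)
cfg   <- sim_config(n_participants = 1, trials = 1, seed = 42, duration = 300,
                    channels = c("gsr", "ibi", "lever", "meditation", "blink"))
s  <- simulate_session(session_meta("P01", "autonomous", "wide"),
                       sched, participant_profile(), cfg, seed = 42)
ch <- characterize_session(s)

gsr_siginc(s$streams$gsr)
#> <squarewave_series 'GSRsiginc'> 6 event(s)
#      onset width height
#   1  36.7   5.5   6.49
#   2  90.9   6.4   6.71
#   3 144.1   6.7   6.80

estimate_delay(ch$Lever, ch$GSRsiginc, max_lag_s = 12)$lag_s   # 1.9
estimate_delay(ch$Lever, ch$medianRRI, max_lag_s = 12)$lag_s   # 9.4

spearman_map(ch[c("GSRsiginc", "medianRRI", "Lever")], reference = "Lever",
             lags = c("Lever|GSRsiginc" = 1.9, "Lever|medianRRI" = 9.4,
                      "GSRsiginc|medianRRI" = 7.5))
#> <correlation_map> 3 nodes, 3 significant of 3 edges (ref Lever)
#           a         b   rho         p      tier
#   GSRsiginc medianRRI 0.552 6.46e-233 secondary
#   GSRsiginc     Lever 0.892  0.00e+00   primary
#   medianRRI     Lever 0.625 2.48e-314   primary
```

The detector recovers all six scheduled events; the square-wave onsets
trail the schedule by the simulated 2 s electrodermal lag, and the
estimated lever-to-GSR delay (1.9 s) matches it. The GSRsiginc–lever edge
is a strong primary correlation, and GSRsiginc–medianRRI is a significant
secondary edge (ρ ≈ 0.55) — the structure this analysis is designed to
surface. The lever-to-heart raw cross-correlation lag (9.4 s) overshoots
the simulated 6.5 s cardiac delay because the cardiac response outlasts
the stimulus; see the methods vignette for why, and for how injected-lag
recovery is validated instead.

`run_pipeline()` drives the whole chain (simulate → characterize →
correlate → timefreq → classify) from a single YAML/list config with stage
caching and a checksummed run report.

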