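---
title: "Neuroforecasting audience outcomes from EEG: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuroforecasting audience outcomes from EEG: models, estimators, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroforecast)
```

## The problem

A small "neural focus group" (a few dozen viewers wearing EEG caps) watches
a set of video stimuli — here, entrepreneurial pitch videos — and we ask
whether moment-to-moment features of their brain activity forecast outcomes
measured far outside the lab: the stated interest of a much larger
population of raters, whether a pitch secured funding, and how much money
it raised. Two neural statistics carry the analysis:

* **Frontal alpha asymmetry (FAA).** Alpha-band (8–13 Hz) power is
  inversely related to cortical activity, and relatively greater
  left-frontal activity indexes approach motivation. FAA is defined as

  $$\mathrm{FAA} = \ln P_{F4} - \ln P_{F3},$$

  the log alpha power at the right-frontal electrode minus that at the
  homologous left-frontal electrode; positive values mean greater
  left-hemisphere engagement.

* **Inter-subject correlation (ISC).** For each video, every pair of
  subjects contributes the Pearson correlation of their alpha-power
  envelopes on mid-central channels (Cz, C3, C4); the mean over all
  $n(n-1)/2$ pairs (378 pairs at $n = 28$) indexes how strongly the
  stimulus locks viewers' brains into a shared trajectory — a marker of
  communication effectiveness.

Both statistics are evaluated on a rolling-window grid — 5-s windows
stepped by 1 s, $[0,5), [1,6), \dots, [58,63)$, truncated at the shortest
video (63 s) — so that each window yields one across-video correlation
with an outcome ("moment-to-moment forecasting").

## Pipeline and estimators

The stage order is fixed: band-pass filter → epoch → bad-channel handling
→ ocular cleanup → baseline correction → spectral estimation → metrics →
forecasting → regression models.

**Filtering.** Zero-phase FIR band-pass, 0.3–50 Hz, Hamming design. The
kernel is convolved with its own reverse so the effective response is
$|H(f)|^2$ with no group delay; this keeps window timestamps aligned to
video onsets, which matters because the claims are about *when* prediction
peaks. Filter length targets a transition width of about the lower edge
and is capped at a quarter of the signal; the per-channel mean is removed
first. The family and order are our choice — they are not derivable from
the upstream description.

**Epoching.** Half-open sample ranges, 0-based onsets; the epoch spans
$[-0.2\,\mathrm{s}, d)$ and the onset sample belongs to the epoch, not to
the baseline. Baseline correction subtracts the per-channel mean of
$[-0.2, 0)$.

**Bad channels.** A deliberately simple, fully specified detector replaces
consensus-based tooling: a channel is bad when its log-variance z-score
across channels exceeds 4, or when its best absolute correlation with any
other EEG channel falls below 0.4. Bad channels are replaced by the
unweighted mean of their good montage neighbors, using a fixed adjacency
table for the 19-channel 10–20 layout shipped in
`extdata/montage_adjacency_1020.csv`. The detector's correlation criterion
encodes a physical fact — volume conduction makes neighboring channels
correlate — and the synthetic generator therefore includes a shared
broadband background (see below).

**Ocular cleanup.** Direct EOG regression replaces ICA: for each EEG
channel, the Fisher-z correlation score against the EOG channel
($z = \operatorname{atanh}(r)\sqrt{n-3}$) is compared to 1.96, and only
above-threshold channels have their least-squares EOG projection
subtracted. The 1.96 gate is retained from the reference pipeline; the
z-score form makes the gate a 5% test under independence, so clean
channels are left untouched.

**Spectral estimation.** Whole-video alpha power uses Welch's method:
2-s Hamming segments, 50% overlap, one-sided density scaling, band bins
inclusive at both edges. The 2-s segment gives 0.5-Hz resolution across
the alpha band; the method's parameters are otherwise unstated upstream
and chosen here once. Time-resolved power uses complex Morlet wavelets on
a 1-Hz grid (8–13 Hz), fixed $n_{\text{cycles}} = 7$, squared magnitudes
averaged across frequencies. Samples within half a wavelet of an epoch
edge are flagged and excluded from window averages. Envelopes above
250 Hz are linearly resampled to 250 Hz before windowing and ISC, which
standardizes sampling; on smooth envelopes this moves window means by
well under 1% (tested).

**Metrics.** Whole-video FAA uses Welch powers; windowed FAA applies the
log-ratio to window-averaged Morlet envelopes, then averages across
subjects ("group FAA"). ISC correlates channel-averaged (Cz/C3/C4)
envelopes per pair within each window; a config switch computes
per-channel-then-average as a sensitivity variant. Powers are floored at
$10^{-12}$ before logs so silent synthetic channels cannot produce
$-\infty$; a value whose both inputs sat at the floor is flagged
unreliable rather than dropped.

**Forecasting.** One correlation per window across videos. Binary
outcomes use the point-biserial correlation, which is exactly Pearson on
0/1 coding (tested to machine tolerance); `rank_order = TRUE` switches to
Spearman. Confidence intervals come from a percentile bootstrap that
resamples *videos* — the forecasting unit ($n = 14$ in the emulated
design) — with 5,000 iterations by default; degenerate resamples are
redrawn and counted. Subject-level resampling was considered and rejected
as the default because the across-video correlation is a video-level
statistic; the unit is configurable. Per-window p-values are reported
unadjusted, matching per-window reporting conventions; an FDR-adjusted
mask is available and off by default. With 59 windows and no correction,
the family-wise any-window false-positive rate under the full null is
far above 5% — the per-window calibration (about 5% of windows
significant under the null, verified over 200 simulated null studies) is
the honest guarantee, not family-wise control.

**Models.** Individual interest is modeled with crossed random
intercepts, `interest ~ predictors + (1|subject) + (1|video)`, fitted by
ML (so likelihood-ratio tests between nested fixed-effect sets are
valid), with continuous predictors z-scored within the estimation sample
and binary predictors left 0/1 — coefficients are standardized.
Optimization is delegated to `lme4`/`lmerTest` (Satterthwaite p-values);
this stage's contract is the model specification, standardization, and
comparison logic. Funding amounts are modeled by video-level OLS
(amount on mean FAA, stated predictions, sentiment covariates), reporting
standardized coefficients, AIC, and adjusted $R^2$. Whether unfunded
(amount 0) videos enter is configurable; the default keeps them, since
dropping them conditions on the outcome.

**Power analysis.** `simulate_power()` draws bivariate-normal pairs at
the video level and applies the exact two-sided t-test of zero Pearson
correlation; power is the rejection fraction with a Wilson 95% interval.
With 14 videos this yields roughly 6% power for $\rho = 0.10$ and 17–18%
for $\rho = 0.30$ — video-level correlational designs of this size are
exploratory. At $\rho = 0.50$ the simple design gives ~47%, noticeably
above some published figures near 38%; mechanisms with additional
pair-level noise would lower it, and we document rather than guess that
mechanism. The Fisher-z closed form (`fisher_z_power()`) agrees with the
simulation within two points for $|\rho| \le 0.3$ (tested).

## What the synthetic generator emulates

`generate_study()` produces the whole study from one seed. Per video $v$,
a latent standardized interest $I_v \sim N(0,1)$ drives everything:

* **Asymmetry.** F3/F4 alpha amplitudes are scaled by $(1 \mp A_v(t)/2)$
  with $A_v(t) = a_1 I_v\,(b\ \text{if } t < 10\,\mathrm{s}\ \text{else } 1)$,
  clamped to $[-1.6, 1.6]$. Positive interest lowers left alpha, raising
  FAA, with the coupling boosted in the first 10 s (the "thin-slice"
  structure). Defaults: $a_1 = 0.4$, early boost 2.5.
* **Shared envelope.** A smoothed positive (< 0.7 Hz) process common to
  all subjects for a given video modulates Cz/C3/C4 alpha with coupling
  $\kappa_v(t) = \kappa_0 + \kappa_1 D_v\, t/d_v$ (defaults 0.15, 0.9):
  funded videos' coupling ramps up over the pitch, reproducing by
  construction the funded/unfunded ISC divergence in the later portion of
  the video.
* **Outcomes.** $D_v \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(0.3 + I_v))$;
  funded amounts are lognormal,
  $312{,}000 \cdot \exp(0.5 I_v + \varepsilon)$ USD, giving a right-skewed
  distribution with mean near \$364k.
* **Behavior.** Five 7-point interest items around
  $\mu + b I_v + u_s + \varepsilon$ with item noise calibrated to
  Cronbach's $\alpha \approx 0.90$; fourteen DC items around a subject
  trait ($\alpha \approx 0.88$); a binary deal prediction; population
  interest as the mean of 497 simulated raters per video.
* **Signal floor.** Every channel carries $1/f$ pink noise (10 µV) under
  a 10 µV alpha carrier — band SNR around 5. A fraction (0.7) of the
  broadband background variance is shared across a subject's EEG channels
  and the alpha rhythm is one coherent per-subject oscillation seen with
  small per-channel phase lags: without this volume-conduction structure,
  real-EEG assumptions built into the bad-channel detector (neighbors
  correlate) would be violated by construction. Blinks are Poisson events
  on EOG/Fp1/Fp2. Videos play in randomized order per subject, and one
  subject can be truncated to 10 videos to mirror a missing-data path.

**What it does not emulate.** Real EEG has non-Gaussian artifacts
(movement, electrode pops), spatially structured source geometry, 1/f
slopes that vary by state, non-stationary alpha peaks, and genuinely
shared *stimulus content* rather than an injected common envelope.
Passing recovery tests therefore shows the *estimators and inference
machinery* are correct and calibrated — not that real pitches produce
these effect sizes.

## Validation design and problem sizes

Every stage is tested against independent oracles: FFT periodograms for
Welch, amplitude-step fixtures for the Morlet envelope, brute-force pair
loops for ISC, closed forms for FAA and the point-biserial equivalence,
OLS reduction and simulation calibration for the mixed models, and the
Fisher-z closed form for power. Recovery tests run the full pipeline on
scaled-down studies — 8 subjects × 8 videos × 63 s at 128 Hz with a
reduced montage for multi-seed runs (50 seeds for FAA sign recovery and
null calibration, 20 for ISC trajectories), and 3–4 subjects × 5–6 videos
for single-seed structural tests. These sizes are our choice of a
simulation budget that keeps the whole suite comfortably reproducible on
one CPU; the generator's *defaults* remain the full design (28 × 14,
256 Hz, 20 channels + EOG).

Numerical conventions worth stating once: sample indexing is 0-based in
events and half-open in windows; all times are seconds from video onset;
window means exclude wavelet edge samples; power floors guard logs;
degenerate bootstrap resamples are redrawn; windows whose metric or
outcome is constant across videos are flagged undefined rather than
given a correlation.

## Known limitations

* The EOG cleanup removes only what correlates linearly with the EOG
  channel; real ocular artifacts have nonlinear propagation.
* Neighbor-mean interpolation is cruder than spherical-spline methods;
  with many simultaneous bad channels it shrinks topographies.
* ISC is computed on channel-averaged envelopes; source-space or
  component-based ISC would be less sensitive to montage choices.
* The amount regression treats amounts as Gaussian after standardization;
  with 14 videos any distributional refinement overfits.
* EDF support covers the standard 16-bit format with one sampling rate
  across EEG signals and basic EDF+ annotations.
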