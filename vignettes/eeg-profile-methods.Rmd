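---
title: "EEG band-power profiles for ambulatory equine recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG band-power profiles for ambulatory equine recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoofbeat)
```

## The statistic

Awake equine EEG recorded from forehead electrodes is dominated by three
frequency bands: alpha (8–12 Hz, prominent in relaxed states), beta
(12–30 Hz) and gamma (>30 Hz, associated with heightened awareness); the
slow-sleep bands delta and theta are present at low amplitude. The **EEG
profile** condenses a session into the proportions

$$ p_b \;=\; \frac{P_b}{P_\alpha + P_\beta + P_\gamma}, \qquad
   b \in \{\alpha, \beta, \gamma\}, $$

where $P_b$ is the mean spectral power of band $b$ across all artifact-free
500 ms epochs and all channels. Being a ratio, the profile cancels
electrode-impedance and amplifier-gain differences, which is what makes it
usable across head-mounted telemetric set-ups and repeated electrode
placements. Stability is summarised with coefficients of variation
($\mathrm{Cv} = \mathrm{SD}/\mathrm{mean}$, reported in percent):

* **inter-individual Cv** — across horses within a session, averaged over
  sessions (`stability_report()$inter_cv`);
* **intra-individual Cv** — across sessions within a horse, averaged over
  horses (`$intra_cv`).

The per-day-then-average convention is adopted because it is the convention
under which the published inter-individual CVs of the reference equine
study are exactly recomputable from that study's printed day-wise group
summaries (shipped as `reference_profiles()`); the `summary_inter_cv()`
helper performs that arithmetic. Sample SDs use the $n-1$ denominator
throughout; with five horses this is the natural small-sample default, and
the reference-value checks use printed SDs and are insensitive to the
choice.

## Pipeline stages and their parameters

`run_pipeline()` chains the stages below; every parameter is exposed in
`pipeline_config()` and the defaults mirror the acquisition this package
models: 1 kHz sampling, four channels RO/RF/LO/LF, 500 ms epochs, ±3 SD
outlier screening.

### Artifact masking (`detect_artifacts()`)

Movement artifacts (body, head, ears) are transients one to two orders of
magnitude above the EEG background. Visual screening is replaced by a
reproducible surrogate: any sample with $|x| >$ `amp_thresh` (default
100 µV) or a one-sample step $> $ `grad_thresh` (default 50 µV/sample) on
any channel is flagged; flagged runs are padded by `pad` (default 0.25 s)
on both sides and merged. With an EEG background of ~20–25 µV RMS and
artifacts of hundreds of µV the amplitude criterion separates the two
populations cleanly; the padding absorbs artifact tails below threshold.
Ground-truth annotations (e.g. from the simulator or manual EDF+ markings)
can be used instead via `mask_from_annotations()`.

### Epoching (`segment_epochs()`)

Consecutive, non-overlapping 500 ms epochs are tiled over every unmasked
run; partial tails are discarded, so the count is
$\sum_\text{runs} \lfloor \text{run}/0.5\,\mathrm{s} \rfloor$.
Non-overlapping epochs keep the epoch count arithmetic of independent
analysis units. Each epoch is demeaned per channel: the DC offset is
electrode polarisation, not brain signal, and the DC bin is excluded from
every band in any case.

### Spectra (`epoch_spectra()`)

Each epoch and channel receives a plain FFT (rectangular window by
default). One-sided bin powers are scaled so that they sum exactly to the
mean square of the (windowed, demeaned) epoch — Parseval's identity holds
bin-exactly, which the test suite asserts at $10^{-6}$ relative tolerance.
At 500 ms the grid spacing is 2 Hz; an on-bin sinusoid of amplitude $A$
lands $A^2/2$ in its bin. A Hann taper is available (`window = "hann"`),
with the caveat that its 4-bin main lobe is wider than the whole alpha band
at this resolution; the rectangular default is also the closest
operationalisation of a bare FFT on short epochs.

### Band powers (`band_power()`)

Bands are half-open, $[f_{lo}, f_{hi})$, so alpha/beta and beta/gamma share
no bin (the 12 Hz bin belongs to beta, the 30 Hz bin to gamma). Gamma is
nominally open-ended; its default ceiling `gamma_hi = 45` Hz keeps the band
clear of 50 Hz mains while retaining eight 2 Hz bins. Delta (0.5–4 Hz) and
theta (4–8 Hz) — ranges the field's clinical convention, as the profile
definition leaves them unspecified — are reported alongside but never enter
the profile denominator.

### Outlier-epoch screening (`reject_outlier_epochs()`)

For each frequency bin in the scan range, the mean and sample SD of a
per-epoch statistic are computed across epochs in a single pass, and an
epoch is discarded if it falls outside mean ± `k`·SD (default `k = 3`) at
any scanned bin. Three numerical choices need justification:

1. **The statistic is log₁₀ of the channel-averaged bin power.** For a
   stationary Gaussian-like signal, a single epoch's bin power is
   approximately $\chi^2_2$-distributed (SD ≈ mean), so a mean ± 3 SD rule
   on *raw per-channel* power flags $e^{-4} \approx 1.8\%$ of values per
   (channel, bin). Multiplied over 22 scanned bins × 4 channels, the
   expected survival of a perfectly clean epoch is
   $\exp(-88 \times 0.018) \approx 20\%$ — the rule would discard most of
   the data it is meant to protect. Averaging the four channels
   ($\chi^2_8$-like, milder tail) and taking logs (symmetrising the
   distribution) brings the per-epoch false-alarm rate to roughly 10–13%
   while leaving genuine broadband transients — which are large on *all*
   channels simultaneously — glaring. Both choices can be disabled
   (`pool_channels = FALSE`, `log_power = FALSE`) to screen raw
   per-channel power.
2. **The scan range defaults to [2, 45) Hz**, the analysis range: scanning
   all 250 bins up to Nyquist multiplies the number of tests ~10-fold and
   rejects the majority of clean epochs by sheer multiplicity.
3. **Degenerate bins reject nothing**: if the SD at a bin is zero
   (spectrally identical epochs) the bin is skipped, and a run in which
   every epoch is flagged raises an error rather than returning an empty
   set. Screening is single-pass — statistics come from the full input
   set, not recomputed after each removal — and therefore permutation
   invariant in the epoch order.

### Hemisphere comparison and pooling

Per-recording, left (LO, LF) and right (RO, RF) profiles are compared; if
all per-band differences are within `hemisphere_tol` (default 5 percentage
points) the hemispheres are considered equivalent and the final profile
pools all four channels by averaging band power before normalising. The
5 pp tolerance is a pragmatic pooling criterion, not a hypothesis test;
the reference study likewise pooled hemispheres after observing no
difference.

## The simulator

### What it emulates

`synthesize_recording()` builds each channel as a sum of independent
band-limited Gaussian noise components — delta 4, theta 5, alpha 14, beta
13, gamma 12 µV RMS by default, i.e. low-amplitude (<10 µV) slow bands
under dominant fast bands, matching amplitude ranges reported for relaxed
standing horses — plus optional 50 Hz mains and transient movement
artifacts (`inject_artifacts()`: Poisson arrivals, default 5/min, raised
cosine bursts of 0.2–0.8 s and 200–500 µV on all channels, each annotated).
Band noise is white noise brick-wall filtered in the frequency domain
(zero-phase) and rescaled to its target RMS *after* filtering, so the RMS
is exact. The default 50 s session is sized so that, after artifact
masking, a session yields on the order of 86 usable epochs, the epoch count
scale of the reference study. One master seed drives everything through a
documented counter scheme (`derive_seed()`), so any channel/band/recording
sub-stream is bit-reproducible on its own.

### Bin-aligned band synthesis

By default the pass-band of each component is not the flat interval
$[f_{lo}, f_{hi})$ but the union of 1 Hz-wide lines centred on the 2 Hz
analysis grid points inside the band (clipped at the band edges;
`grid_df = NULL` restores the flat band). The reason is a resolution
limit, not an aesthetic: a 500 ms rectangular epoch convolves the true
spectrum with a Fejér kernel whose mass extends well beyond ±2 Hz, so for
a *flat* 4 Hz-wide alpha band only roughly 60–75% of the band's power is
recovered in the band's own two bins — power generated near 11–12 Hz lands
mostly in the 12 Hz bin, which belongs to beta. A flat-spectrum generator
therefore cannot serve as an unbiased recovery target at this epoch
length: the measured profile of a flat-band signal understates narrow
bands by up to ~10 percentage points by construction. With bin-aligned
synthesis the generated power sits where the epoch analysis can attribute
it, recovery is unbiased to ~1 pp, and recovery tests check the pipeline
rather than the Fejér kernel. The trade-off is a comb-like in-band
spectrum and epoch-to-epoch correlation on the ~1 s scale of the line
bandwidth; both are acceptable in a validation generator and are
documented limitations for realism (see below).

### Cohort dispersion calibration

`simulate_cohort()` draws, for horse $i$ and session $j$, a true profile
$p + \delta_i + \varepsilon_{ij}$ around the population mean profile $p$
(default 0.3763/0.3438/0.2799, the day-1 group means of the reference
study). Because proportions sum to one, the deviations live on the
zero-sum plane, and per-band dispersion targets cannot be chosen freely:
three zero-sum deviations with SDs $(s_1, s_2, s_3)$ exist iff the SDs
satisfy the triangle inequality (three plane vectors of those lengths
closing a triangle). The generator therefore draws from degenerate
Gaussian covariances built by that *triangle construction*:

* $\Sigma_\varepsilon$ from the within-individual targets (default
  6/5/9%), so intra-individual CVs are matched exactly;
* the individual-level covariance as
  $\Sigma_\delta = \mathrm{PSD}\!\left[\Sigma_{tot} - \Sigma_\varepsilon\right]$,
  where $\Sigma_{tot}$ comes from the between-individual targets (default
  12/6/12%, the inter-individual CVs of the reference study) and PSD
  clipping zeroes negative eigenvalues.

The clipping is needed because an exact decomposition does not always
exist (for beta the between/within gap 6% vs 5% implies an individual-level
variance too small to be compatible with the alpha/gamma covariances); it
slightly inflates the realized inter CVs of the affected bands.
`cohort_design()` reports the analytic realized CVs — at the defaults
roughly 12.0/6.7/12.4% inter against exactly 6/5/9% intra — so the
discrepancy is visible, and the calibration tests compare Monte-Carlo
sample CVs against these realized values corrected by the small-sample SD
bias factor $c_4(n)$ ($c_4(5)=0.940$, $c_4(2)=0.798$). Because profiles
sum to one *exactly* (the all-ones direction is exactly degenerate), no
renormalisation step distorts the calibration.

Each recording then realizes its true profile through band amplitudes:
band power proportional to the target proportion with the total
alpha+beta+gamma power held fixed across recordings (at
$14^2+13^2+12^2 = 509$ µV², the default relaxed-state budget), i.e.
$\mathrm{RMS}_b = \sqrt{p_b \cdot 509}$ µV — the proportions are the only
quantity that varies across the cohort.

### What the simulator does not emulate

Channels are simulated independently: real hemispheric signals share
sources and volume conduction, so real left/right profiles are *more*
similar than simulated ones — the hemisphere-pooling test is conservative
in that respect. The comb spectrum, Gaussian amplitude statistics and
stationarity within a session are idealisations; real EEG has 1/f
background, nonstationary state changes, and muscle/ocular contamination
below the amplitude threshold. The RF telemetry chain (chopping, FM and
envelope demodulation) is not modelled beyond an optional additive 50 Hz
term. Passing recovery tests on this generator therefore demonstrates
correctness of the computation, not robustness to every physiological
artifact class.

## Validation problem sizes

The test suite and the acceptance script use, as the package's standard
validation sizes: 45–60 s single sessions (90–120 epochs) for recovery and
false-rejection checks; 20 replicate cohorts for truth-level calibration;
24 replicate 5×2 cohorts, full pipeline, for the inter/intra ordering
study; 20 seeded runs of the 100-clean + 5-contaminated screening
scenario. At these sizes the whole suite runs in about a minute on one
CPU.

## Known limitations

* The published intra-individual CVs of the reference study cannot be
  recomputed from printed summaries (they require per-horse session
  values), so only the inter-individual CVs serve as exact reference
  checks.
* At 2 Hz resolution the alpha band spans two bins; profiles from very few
  epochs are accordingly noisy, and the ±3 SD screening removes ~10% of
  genuinely clean epochs (the multiplicity floor discussed above).
* EDF output quantises to 16 bits over a symmetric physical range chosen
  from the data; amplitudes beyond the declared range raise an error
  rather than clip.
* `stability_report()` on a 2-individual × 2-session table frequently
  yields near-identical inter and intra CVs — a combinatorial property of
  absolute differences of four numbers, not an implementation artefact;
  five individuals and two sessions (the default design) do not suffer
  from it.
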