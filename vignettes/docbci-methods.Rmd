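---
title: "Spectral EEG and closed-loop MI-BCI analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral EEG and closed-loop MI-BCI analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docbci)
```

## The scientific setting

Patients with prolonged disorders of consciousness (pDoC) are stratified
behaviourally into unresponsive wakefulness syndrome (UWS) and the
minimally conscious state (MCS) using the Coma Recovery Scale-Revised
(CRS-R, total score 0-23). Resting EEG in this population is
slow-wave-dominant, more so in UWS; during motor-imagery (MI) training with
a closed-loop brain-computer interface (BCI), MCS patients typically show
multiband modulation (delta/theta enhancement with alpha/beta suppression
over frontal-parietal cortex) while UWS patients show at most localized
gamma changes. The BCI monitors a beta/alpha "attention index" at the
prefrontal electrode Fp1 and triggers a rehabilitation glove when the
index's moving average crosses a fixed threshold; the fraction of trials
with a trigger is the session's classification accuracy.

`docbci` implements this entire analysis — preprocessing, Welch relative
band power by cortical region, the closed-loop attention-index engine, and
the nonparametric statistical battery — together with a synthetic-EEG
cohort generator, so that every stage can be verified quantitatively
without clinical recordings (none are publicly deposited for this
paradigm).

## Data model

A recording is a 30-channel scalp montage (10-10 positions; the classic
`T3/T4/T5/T6` temporal labels) plus one EOG channel, sampled at 500 Hz at
rest and 250 Hz during the task session. Channels are grouped into four
regions — frontal (12 channels), parietal/central (9), temporal (6),
occipital (3) — and spectra into five bands tiling 1-45 Hz: delta (1-4),
theta (4-8), alpha (8-15), beta (15-30), gamma (30-45 Hz). The alpha/beta
boundary is reported inconsistently in this literature (13 vs 15 Hz); the
band edges are a constructor argument (`analysis_bands()`), defaulting to
the 8-15/15-30 convention.

## The synthetic cohort generator

`make_cohort()` draws per-subject profiles around group-level templates
(`default_effect_config()`):

* **Resting composition.** Region-by-band relative-power weights; the UWS
  template is delta-dominant (frontal delta ~0.45) while MCS carries less
  delta and more beta, consistent with the reported group medians.
  Between-subject variability is log-normal jitter (SD 0.15) followed by
  renormalization.
* **Task modulation.** Multiplicative factors applied to the weights
  during cue windows, then renormalized. MCS: frontal/parietal delta and
  theta factors above 1, alpha/beta well below 1, parietal gamma 0.5; UWS:
  parietal gamma 3.0 and everything else exactly 1. Subject jitter scales
  each factor's log magnitude (SD 0.25) so an effect's *direction* is
  never flipped — this is what makes paired within-group contrasts behave
  like consistent physiological modulation rather than random noise.
* **CRS-R linkage.** CRS-R totals are uniform on 4-9 (UWS) and 10-20
  (MCS). The attention gain is a logistic map of CRS-R,
  `plogis(-3.2 + 0.2 * crs + e)` with `e ~ N(0, 1.55)`. The noise SD was
  calibrated once, against the latent chain only, so that the *recoverable*
  rank correlation between session attention indices and CRS-R is near the
  configured target of 0.43 (a moderate correlation requires a deliberately
  noisy linkage); it was then frozen.
* **Amplitude.** Background RMS is 15 uV per channel, placing ordinary
  activity at 5 sigma from the 75 uV artifact screen.

Signals are sums of five band-limited noise components: white Gaussian
noise (a seeded, platform-stable generator in compiled code) shaped by the
same order-6 Butterworth second-order sections used by the preprocessing
stage, with a 3 s synthesis margin trimmed so no filter edge transients
reach the delivered data. Component variances are not set naively to the
target weights: the measured band fraction of a filtered component is
biased by filter roll-off and by the 500 ms Hamming window's spectral
leakage (dominant for the 3 Hz-wide delta band). The generator therefore
calibrates, once per sampling rate and deterministically, a cross-talk
matrix by pushing unit-variance components through the package's own
filter + Welch chain, and solves a small linear system so the *measured*
region band fractions converge to the profile weights (verified to within
0.02 by simulation).

During cue windows the component amplitudes switch to the modulated
weights. The Fp1 channel is excluded from regional modulation and instead
driven by the latent attention trace `a(t)` (per-trial Gaussian bumps
peaking 4 s after cue onset — delayed responses are characteristic of this
population — with smoothed noise, clipped to [0, 1]): its beta component is
scaled by `sqrt(1 + 1.2 a(t))` and alpha by the inverse, shifting the
beta/alpha power ratio upward in proportion to the gain. Artifacts are
frontal-dominant ~0.35 s blink waves (mirrored, amplified, on EOG) and
~40 ms single-channel spikes of 120-180 uV; during sessions they are
placed outside cue windows, emulating blink suppression during engaged
imagery.

What the generator does *not* emulate: volume conduction and realistic
source mixing, non-Gaussian background rhythms (spindles, mu bursts),
nonstationary drift, and any direct physiological coupling between CRS-R
and spectra beyond the configured templates. Passing tests therefore
demonstrate that the *pipeline* recovers what the generator encodes — not
that the clinical effect sizes themselves are reproduced.

## Preprocessing

Fixed stage order (`preprocess_recording()`): broadband filter, bad-channel
interpolation, ICA artifact attenuation, common average reference (CAR),
5 s epoching with the amplitude screen.

* **Filtering.** 1-45 Hz Butterworth band-pass of design order 6 and a
  50 Hz biquad notch (2 Hz bandwidth), applied forward-backward so event
  latencies are preserved. The 12-pole band-pass is numerically unstable
  in transfer-function form for the narrow delta band at 500 Hz (pole
  modulus > 1 after polynomial expansion), so all filters are designed and
  run as second-order sections.
* **Bad channels.** "Visual inspection" is replaced by a stated automated
  rule: a channel whose log RMS deviates from the montage median by more
  than 4 robust SDs is flagged and rebuilt by inverse-squared-distance
  interpolation over good channels. The MAD is floored at 0.1 log units so
  a homogeneous montage does not flag ordinary variation; more than 30%
  bad channels is a subject-level failure.
* **ICA.** Symmetric FastICA (tanh contrast, seeded initialization) on the
  30 scalp channels; components whose absolute correlation with the EOG
  reference exceeds 0.7 are zeroed before back-projection. Channel count
  and rank are preserved, and untouched components back-project exactly,
  so lack of global rotation convergence (expected when background sources
  are near-Gaussian) is harmless; channel-wise EOG regression is the
  fallback for numerical failure only.
* **CAR and epoching.** The 30-channel instantaneous mean is subtracted
  (EOG excluded); non-overlapping 5 s epochs are rejected iff any scalp
  sample exceeds 75 uV in magnitude — the only sample-level exclusion.
  Epochs are non-overlapping so that downstream nonparametric tests see
  approximately independent units.
* **SNR gauge.** 10 log10 of mean 8-30 Hz Welch power in cue windows over
  pre-cue baseline windows, averaged over scalp channels. The raw value is
  computed right after filtering; the post-cleaning value after ICA *and*
  after excluding windows failing the 75 uV screen, matching the
  convention that the "cleaned" figure follows bad-segment rejection. Only
  the improvement direction is a testable property; the values themselves
  are data-dependent.

## Spectral estimation

`welch_psd()` averages modified periodograms of 500 ms Hamming windows
with 250 ms overlap, within and then across kept epochs (equal epoch
weights), with one-sided density scaling (integrating the PSD recovers the
variance; verified by a Parseval check and an independent brute-force
oracle to 1e-9).

Two numerical choices deserve emphasis:

* **Frequency grid.** Segments are zero-padded eight-fold (0.25 Hz grid).
  With the native 2 Hz grid of a 500 ms window, half-open band-bin
  assignment `[f1, f2)` cannot reproduce the analytic bandwidth fractions
  (delta holds a single bin); on the fine grid the flat-spectrum fractions
  3/44, 4/44, 7/44, 15/44, 15/44 are recovered within 0.005.
* **Detrending.** Per-segment mean removal is *off* by default. A 500 ms
  segment is shorter than one period of 1-2 Hz activity, so removing its
  mean deletes genuine delta power (about 15% of the delta fraction on
  flat input). The broadband 1 Hz high-pass already enforces zero mean;
  `detrend = "constant"` remains available.

Band power sums PSD bins with `f1 <= f < f2` (top band closed at 45 Hz);
relative power divides by the 1-45 Hz total, so the five values sum to 1
exactly; regions average their channels with equal weights (the montage
assigns no obvious weighting and the choice is exposed). Channel-resolved
relative power with montage coordinates is exported for topographic
mapping; no figure rendering is done in-package.

Note one consequence of epoching the whole session: task-condition epochs
include calibration, pre-cue and inter-trial periods, so measured task
modulation is diluted by the cue duty cycle. The paired within-group tests
remain well-powered because the dilution is common to all subjects.

## The closed-loop engine

`attention_index()` reconstructs the online control signal offline, with
the same Welch machinery as the spectral module: per 1 s sliding window
(0.5 s hop) at Fp1, `R = Ebeta/Ealpha`; windows with zero alpha energy are
marked invalid. The 0-100 normalization is fitted per subject on the
session's calibration baseline: log R's robust range (2.5th-97.5th
percentiles) is mapped linearly onto 0-62.5, i.e. the fixed threshold of
50 sits at the upper edge of resting variability. A symmetric map of the
calibration range onto the full scale would put the resting *median* at
50, and a threshold at the median of baseline noise triggers on almost
every trial regardless of attention — destroying the discriminative
purpose of the accuracy metric; anchoring the threshold above the resting
range restores a meaningful operating point. A trailing moving average
(3 windows, about 2 s) smooths the index; a trial succeeds iff the moving
average exceeds 50 anywhere in its cue window (one glove actuation per
trial; re-crossings ignored), and accuracy is the percentage of successful
trials. Practice trials are not modelled: the session plan contains scored
trials only.

The index is scale-invariant (a ratio of band powers), monotone in the
underlying ratio wherever unclipped, and the engine's success probability
is non-decreasing in the attention gain — all property-tested. With the
default generator the simulated group accuracies come out near 70% (MCS)
vs 47% (UWS); the clinical values (55% vs 38%) are lower, which is
expected since real patients carry sources of failure the generator does
not model. Only the direction and ordering are treated as testable.

## Statistics

The battery mirrors the study design: Wilcoxon rank-sum between groups,
Wilcoxon signed-rank within group (rest vs task), Welch's unequal-variance
t for the demographic and accuracy summaries (the pooled Student form is
available behind a flag), uncorrected Pearson chi-square for the 2x2 sex
table (Fisher's exact p reported alongside), and Spearman's rank
correlation with a seeded 2000-resample percentile bootstrap interval.

Conventions, stated once and used everywhere: midranks for ties; zero
differences dropped before signed-ranking (the classical procedure — the
effective n is reported); exact small-sample p values (rank-sum for
combined n <= 10, signed-rank for n <= 15 non-zero pairs, Spearman
permutation for n <= 9) via the classical distributions when tie-free and
full enumeration under ties, normal approximation with continuity and tie
correction beyond; two-sided throughout; quartiles are type-7 linear
interpolation. Every exact path is tested against independent
full-enumeration oracles.

`build_contrast_tables()` assembles the tables in the shape the field
reports them: for each of frontal/parietal x five bands, per-group
median (Q1, Q3) at rest and task, the signed-rank W and standardized Z
with p, the per-subject delta summarized as median (Q1, Q3), and
between-group rank-sum tests at rest, at task and on the delta. Both W and
Z are always emitted because reporting conventions for the within-group
statistic vary. No multiplicity correction is applied — matching how such
tables are reported — and the total number of contrasts is attached so a
reader can judge the burden.

## Reproducibility machinery

Every random stage derives its own stream from the master seed via a
stable label hash (`derive_seed(seed, subject, stage)`), so per-subject
results do not depend on cohort order. `run_pipeline()` executes
generation, preprocessing with QC, spectra, sessions and statistics from a
single serializable configuration, writes all tables as CSV stamped with
the configuration hash, plus a JSON manifest; identical configurations
give byte-identical CSVs. `validate_run()` re-reads a run directory and
asserts the invariant suite (tables present, band sums equal to 1 within
1e-6, relative powers and accuracies within bounds, p values in (0, 1],
row counts matching the manifest). Recordings can be exchanged as EDF
(16-bit, one-second records) with events in a CSV sidecar.

## Simulation scales used by the test suite

The study conditions are the generator defaults (12 + 19 subjects, 5 min
rest at 500 Hz, 15-trial sessions at 250 Hz, 5 s imagery windows with 4 s
pre-cue baselines and 3 s inter-trial intervals — trial timing is not
specified by the protocol and these are explicit, configurable choices).
Monte-Carlo verification runs instead use reduced problem sizes chosen to
keep each property estimable: type-I calibration on 200 null cohorts of
6 + 6 subjects with 10 s recordings at 125 Hz; effect-direction recovery
on 50 cohorts of 12 + 19 with 10 s rest and 15 s single-trial task
segments; correlation recovery on 100 cohorts of 12 + 19 with 3-trial
sessions at 100 Hz. Reducing duration raises only estimation variance —
never the direction of an injected effect — so these scales trade
statistical sharpness, not validity. The convergence test (region
fractions approaching the profile weights as 15 s to 240 s) documents that
the residual bias of the calibrated generator sits near 0.001-0.005,
well inside the 0.02 acceptance band.

## Known limitations

* Gaussian band noise cannot probe ICA's behaviour on realistic
  non-Gaussian rhythms; the ICA test isolates exactly the blink component
  because it is the only strongly non-Gaussian source.
* The online device's internal filtering and normalization are unknown;
  the offline engine is a reconstruction, calibrated so its behavioural
  summaries are ordered like the reported ones, not a bit-exact emulator.
* Relative power depends mildly on the Welch window choice near band
  edges; all defaults are recorded in the `psd_result` metadata, and
  conclusions should quote them.
* The statistics assume one value per subject per cell; repeated CRS-R
  assessments are reduced to the highest total upstream, as is standard.
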