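---
title: "Harmonicity, roving oddballs and mismatch responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonicity, roving oddballs and mismatch responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rovingmmn)
```

# The scientific problem

A harmonic complex tone has partials at exact integer multiples of a
fundamental frequency (F0); jittering those partials makes the tone
inharmonic. In predictive-processing accounts of audition, the brain's
mismatch responses — the mismatch negativity (MMN, a frontocentral
negativity roughly 100–250 ms after a deviant sound) and the P3a (a
subsequent frontocentral positivity) — index prediction errors weighted by
the precision of sensory evidence. `rovingmmn` implements the full
computational chain needed to study how harmonicity modulates these
responses in a passive roving-oddball design:

1. synthesis of harmonic and frequency-jittered complex tones;
2. roving-oddball event sequences with deviant-order and F0-shift labels;
3. approximate-entropy quantification of stimulus regularity;
4. a synthetic multi-participant EEG generator carrying the assumed effect
   structure;
5. an ERP pipeline (filtering, baseline, averaging, difference waves,
   peak measures);
6. from-scratch spatio-temporal cluster-based permutation tests;
7. balanced repeated-measures ANOVA, Tukey HSD contrasts and an a-priori
   power simulation.

The three experimental conditions are *harmonic* (plain harmonic
complexes), *inharmonic* (one jitter pattern shared by every tone in a
block, so the spectrum is strange but stable) and *changing* (a fresh
jitter pattern for every sound, so the spectrum changes unpredictably from
tone to tone).

# Stimulus synthesis

Tones are 70-ms complexes built by summing equal-amplitude zero-phase
sines at every partial below the Nyquist limit (24 kHz at the 48-kHz
sampling rate), with 5-ms on/off ramps. "Up to the Nyquist limit" is read
as *strictly below*: a sine-phase component at exactly Nyquist is
unrepresentable, and the strict bound is alias-safe. Jitter pattern entry
`u[n] ~ U(-0.5, 0.5)` multiplies harmonic `n` as `f_n = n F0 (1 + u_n)`;
the F0 itself is never jittered, which preserves a fundamental pitch
anchor across conditions. Jittered partials pushed to or past Nyquist are
dropped rather than clipped to keep the jitter distribution intact.

Because beats between close partials are audible artifacts, patterns are
rejection-sampled until all surviving partials are at least 30 Hz apart —
at *every* F0 on the 500–800 Hz grid, since one pattern must serve a whole
block as the F0 roves. Rejection resamples the entire pattern; a cap
(default 10,000 draws) guards against degenerate configurations.

The ramp shape is not a constrained quantity; linear ramps are the
default, with a raised-cosine option (`ramp_shape = "cosine"`).

Loudness normalization follows ITU-R BS.1770 K-weighting (the published
48-kHz biquad cascade) with an *ungated* mean square: the standard's
400-ms gating block is longer than the whole 70-ms clip, so gated loudness
is undefined and the ungated energy is the only consistent choice. The
gain landing a clip on the −12 LUFS target can push the impulsive,
high-crest-factor harmonic complexes past full scale; samples are then
clipped to ±1 (flagged via `attr(, "clipped")`). A consequence worth
knowing: equal loudness does not mean equal RMS. Across a pool the
inharmonic tones' RMS agree to ~0.5%, while the harmonic tones deviate by
a few percent because of the headroom clamp.

# Roving paradigm

Blocks are 600 tones at a 600-ms onset-to-onset interval (6 min per
block), which is the only reading of the stimulation interval consistent
with both printed constants. Train lengths are drawn from 3–11 with
lengths 3–7 four times as likely as 8–11 (`E[L] = 5.75`, so a block holds
about 104 trains); the final train is truncated so the block length is
exact. At each train change the F0 moves to a uniformly chosen *different*
grid value, giving signed shifts of 50–300 Hz. The first three tones of
every train after the first are labeled deviants of order 1–3; tones at
position ≥ 4 are standards; the first five tones of a block are excluded.
The block-initial train cannot contain a deviant (nothing precedes it).

Under these rules the expected number of first-order deviants per block is
about 103 (104.3 trains minus the block-initial one); the package does not
force any other figure.

The changing condition draws a fresh pattern *per sound* by default; a
per-train variant is available (`changing_per_train = TRUE`) because
descriptions of the design differ on this point and both are defensible.

# Approximate entropy

`approximate_entropy()` is the classic regularity statistic
`ApEn = Phi_m(r) − Phi_{m+1}(r)` with embedding dimension `m = 2`,
tolerance `r = 0.2 × SD` (population SD) and Chebyshev distance,
self-matches included. The C++ kernel is checked against a brute-force
double-loop oracle to 1e-10.

What to feed it is a genuine modeling choice, and an instructive one.
Applied to the raw 48-kHz waveform (`on = "waveform"`, the default for
`pool_entropy_summary()`), ApEn separates the conditions by an order of
magnitude (harmonic ≈ 0.08, inharmonic ≈ 1.97 on a 100-pattern-per-F0
pool): a broadband waveform sampled at 48 kHz is sample-to-sample almost
unpredictable once jittered. Applied instead to the tone's *spectral
recipe* — the sorted list of surviving partial frequencies
(`on = "partials"`) — the harmonic series is an exact arithmetic ramp with
ApEn ≈ −0.03 (slightly negative: for a perfect ramp the template-match
counts are identical at both embedding dimensions and only the
denominator edge effects remain), while jittered recipes land at ≈ 0.18
(SD across F0 ≈ 0.01). The partial-series reading is the one that matches
the scale on which pool summaries of this stimulus class are usually
reported (a few hundredths for harmonic, ≈ 0.2 for inharmonic); both
readings agree on the ordering, harmonic < inharmonic at every F0, which
is the scientifically load-bearing fact. Whether entropy is computed
before or after loudness normalization is immaterial because `r` is
SD-relative.

# The synthetic EEG generator

The generator stands in for a real 30-channel recording and carries
exactly the effect structure the analysis chain is supposed to detect.

**Components.** Five canonical components with Gaussian time courses and
a shared frontocentral Gaussian topography (unit peak between Fz and FCz,
spatial SD 0.45 on the unit disc): N1 (−2 µV, 100 ms, SD 25 ms), P2
(+2 µV, 141 ms, SD 40 ms) on every tone; MMN (150 ms, SD 25 ms) and P3a
(250 ms, SD 40 ms) on first-order deviants only; an ORN-like negativity
(141 ms, SD 25 ms) on every inharmonic and changing tone. Default
deviant amplitudes: MMN −1.0 / −0.7 / 0 µV and P3a +0.8 / +2.0 / 0 µV for
harmonic / inharmonic / changing; ORN −1.0 µV on inharmonic and changing
tones of either role. The changing condition carries *no* deviance
response at all: that is the substantive finding the generator emulates
(per-sound spectral change makes F0 deviants undetectable), and it is
also the only self-consistent choice — a deviant-only changing-condition
effect of a few tenths of a microvolt would be exactly as detectable as
the inharmonic MMN, so one cannot simultaneously ask the cluster test to
find the latter and miss the former.

**Variability.** Each subject draws one amplitude offset per component
(`subject_sd`, default 0.25 µV, shared across conditions) and one per
component × condition (`subject_cond_sd`, default 0.8 µV). Offsets attach
only to components actually present in a condition: an absent response is
absent, not randomly present with mean zero. (The alternative — giving
the changing condition a random-sign "MMN" of a few µV — injects
between-subject variance into a null condition and, through the
peak-picking step below, biases its measured amplitude far from zero.)

**Noise.** Per channel and trial, 1/f ("pink", FFT-synthesized) plus
white noise, 3 µV each by default. Epochs span −100 to 450 ms at 1000 Hz
(551 samples); component tails at the baseline are below a few nV·10³
(the Gaussians are effectively causal).

**Calibration, and what passing tests mean.** Single-trial noise levels
and per-subject amplitude spreads are not quantities with a published
ground truth; they were calibrated, once, so that the analysis-stage
outputs land where the emulated study reports them: subject-level Tukey
contrasts of MMN mean amplitude near −0.9 / −0.7 / −0.2 µV
(harmonic−changing / inharmonic−changing / harmonic−inharmonic) with the
first two significant and the third not, cluster tests detecting MMN- and
P3a-range clusters for harmonic and inharmonic but nothing for changing,
and contrast SEs of roughly 0.1–0.3 µV. Even at the calibrated optimum the
harmonic−inharmonic contrast sits near the Tukey critical value by
construction (true gap 0.3 µV), so across random seeds the full
qualitative pattern reproduces in roughly two-thirds to three-quarters of
simulated studies — about the fragility one should expect of the
underlying three-way pattern at N = 35. Passing tests on this generator
demonstrate that the pipeline recovers a known effect structure from
realistic noise; they say nothing about artifact rejection, volume
conduction, or any property of real EEG the generator does not model
(no ocular/cardiac artifacts, no channel covariance beyond the shared
topography, no latency jitter across trials or subjects).

**Two generation paths.** `simulate_study()` defaults to drawing each
subject × condition × role *average* directly: the signal part is the
exact trial mean implied by the event tables and the noise part is one
1/f-plus-white field at `SD/sqrt(n_trials)` — precisely the distribution
of the mean of that many independent noise epochs, at a fraction of the
cost. `method = "epochs"` builds every single trial (and
`simulate_subject()` returns full epoch sets); a test verifies the two
paths coincide in the noise-free limit.

# ERP pipeline

Epoched data are zero-phase low-pass filtered at 30 Hz (4th-order
Butterworth, forward–backward), baseline-corrected over −100–0 ms,
averaged into standard and first-order-deviant ERPs per condition, and
subtracted into mismatch difference waves. All of these stages are linear,
so filtering subject averages equals filtering every trial; the study
driver exploits this. The high-pass that a real recording would receive
before epoching is deliberately absent from the synthetic path (the
generator produces epoched, drift-free data); a real-data adapter should
high-pass the continuous recording first.

Peak measures follow the component-window convention: MMN latency is the
most negative sample of the frontocentral ROI (F3, Fz, F4, FC1, FC2)
difference trace between 70 and 250 ms, P3a the most positive between 150
and 400 ms; amplitudes are means over the 50-ms window centered on the
peak, clipped at epoch edges and flagged when clipping occurs; ties break
to the earliest sample for determinism. P2 amplitude (for the ORN
analysis) is the mean over a fixed 141 ± 25 ms window of the standard or
deviant trace itself, not of a difference wave; the 50-ms width mirrors
the MMN/P3a convention since no separate width is prescribed.

One methodological caveat the package makes visible: picking an extremum
in a window biases the measured amplitude away from zero under noise, so
a condition with no true response (changing) still shows a negative
"MMN mean amplitude" of a few tenths of a µV. Condition *contrasts*
partially cancel this bias; fixed-window means (as in the sign-recovery
test) avoid it entirely.

# Cluster-based permutation tests

The mass-univariate engine is written from scratch. Per (channel, time)
cell: a one-sample t on within-subject differences (paired contrast) or a
one-way repeated-measures F across the three conditions
(`MS_cond / MS_cond×subject`). Cluster-forming thresholds are the
parametric quantiles at α = 0.05 implied by the design's degrees of
freedom (t(34) ≈ 2.032, F(2, 68) at n = 35) — the standard "automatic"
threshold rule. Supra-threshold cells are grouped by connectivity =
temporal adjacency within a channel OR spatial adjacency (2-D distance
below a radius giving median degree ≈ 5) at the same time point; positive
and negative t exceedances cluster separately; the cluster statistic is
the mass (sum of member statistics). The null is the per-permutation
maximum |mass| across the whole map — both tails for t, so the two-sided
family-wise rate is controlled jointly — with per-subject sign flips (t)
or within-subject condition-label permutations (F), 1024 permutations by
default, and `p = (1 + #{null ≥ observed}) / (1 + n_perm)`, flooring p at
1/1025. Zero-variance cells get statistic 0: a cell with no variability
cannot carry evidence and must not seed clusters. Post-hoc pairwise
cluster tests after the omnibus F are judged against a Bonferroni α of
0.05/3 ≈ 0.0167.

On null data at reduced scale (20 subjects, 6 channels, 200 permutations,
500 Monte-Carlo repetitions) the family-wise false-positive rate lands
near the nominal 0.05 (about ±0.02 across seeds, consistent with the
Monte-Carlo standard error of 0.01). Cluster formation is verified cell-for-cell
against a brute-force flood-fill oracle on hundreds of random maps.

# Repeated-measures inference

For the balanced designs this study uses, the condition test of a
random-intercept linear mixed model is *exactly* the classical
within-subject ANOVA, so `rm_anova_oneway()` computes
`F = MS_cond / MS_cond×subj` in closed form (and refuses unbalanced
tables rather than pretending to be a general mixed-model fitter). The
3 × 2 model for P2/ORN pools the three within-subject error strata into
one term with `(n·k·m − 1) − (n−1) − 5` degrees of freedom — 170 at
n = 35, matching the `F(2, 170)` reporting shape. Tukey HSD contrasts use
the ANOVA error term and the studentized-range distribution; a test
cross-checks estimates, SEs and adjusted p-values against
`lme4` + `emmeans` on balanced tables. Model comparison reports
`df_err · log(RSS_null / RSS_full)`, a degrees-of-freedom–corrected log
RSS ratio: the naive `N·log` version inflates by `N/df_err` in these
designs, whereas the corrected statistic is ~χ²(k−1) under the null
(verified by simulation against a KS test).

# Power simulation

The a-priori power analysis asks how many participants are needed to
detect a 1-µV harmonic–inharmonic difference, under the working
assumption that changing does not differ from inharmonic (condition means
0/1/1 µV). Each simulated dataset draws subject intercepts
(SD 1.5 µV) and per-cell residuals, and tests the condition effect with
the one-way RM-ANOVA at α = 0.05. The residual SD default of 1.5 µV is a
calibration choice with a closed-form rationale: the noncentrality is
`λ = N·(2/3)/σ²`, and σ = 1.5 puts power at N = 33 near 0.80 (λ ≈ 9.8
against F(2, 64)); smaller residual SDs (e.g. 1.0 µV) would push power at
N = 33 above 0.99 and make the whole exercise vacuous. Power is ≈ α at
zero effect and non-decreasing in N within Monte-Carlo error.

# Numerical and design notes

- Problem sizes in the test-suite: entropy pools use 100 inharmonic
  patterns per F0; permutation calibration uses 500 Monte-Carlo nulls at
  200 permutations; power curves use 2,000 simulations per N; the effect
  recovery study uses the full 35 subjects with 1024 permutations.
- All randomness flows through R's RNG; every generator takes a seed and
  restores the caller's RNG state, and the C++ permutation loops draw
  from R's stream so `set.seed()` governs everything.
- WAV I/O is a minimal canonical-format 16-bit PCM reader/writer —
  deliberately small, since the package only ever writes mono 48-kHz
  files it later reads back.
- The pattern-id hash is a cheap rolling polynomial over the jitter
  bytes; it exists for manifests and joins, not cryptography.
- Epoch containers serialize as raw little-endian float64 plus a JSON
  sidecar; round-tripping is tested.

# Known limitations

- The generator's topography is a single isotropic frontocentral bump;
  component-specific topographies and realistic volume conduction are out
  of scope, so sensor-level cluster *extents* should not be compared
  quantitatively with real recordings.
- No artifact model (blinks, cardiac, movement) and no trial-level
  latency jitter.
- The mixed-model machinery intentionally covers balanced designs only;
  trial-level models with frequency-shift regressors are not fitted
  (shift labels are exported for external tools).
- The behavioral experiment's ordinal modeling is out of scope; only the
  deviant-count error metric is provided.
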