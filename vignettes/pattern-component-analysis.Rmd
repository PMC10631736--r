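---
title: "Classifying motion integration: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying motion integration: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the estimators, the tunable parameters that matter, and the
places where the design was genuinely open and a choice had to be made.

## The question and the analysis chain

Direction-tuned visual neurons can signal the motion of a whole pattern or
of its oriented components. Probed with drifting gratings and 120°
cross-angle plaids at 12 directions, a unit's observed plaid curve is
compared (by partial correlation) against an ideal *pattern* prediction
(its own grating curve) and an ideal *component* prediction (the sum of
the grating curve shifted by ±60°). The Fisher-transformed partial
correlations `Zp` and `Zc` (with `sqrt(n − 3) = 3` for 12 directions) and
the one-sided 90% criterion (1.28) yield the three-way label
pattern / component / unclassified; `PI = Zp − Zc` is the scalar summary.
The direction-selectivity flag (`DSI > 0.33`) is reported separately so
analyses can condition on it or not.

A linear unit with a compact ("blobby") receptive field can *look* like a
pattern cell: its broad tuning merges the two plaid peaks. The package's
central test resolves this: estimate the unit's linear filter from its
responses to correlated noise (STA), use the estimate as the front end of
an LN model, predict the grating/plaid battery, and reclassify. A unit
whose selectivity truly is linear keeps its label under this loop; a unit
built on nonlinear pooling loses it.

## Stimuli

All stimuli live on a reduced pixel grid (default 64 × 48 over
120° × 90°, i.e. 1.875°/pixel). With protocol spatial frequencies of 0.02
and 0.04 cycles/degree this oversamples the finest carrier more than
six-fold; a guard refuses any grating sampled at fewer than 4 pixels per
cycle. Luminance is `0.5 + 0.5·contrast·cos(2π(sf·u − tf·t) + φ0)` with
`u` the coordinate along the drift direction; 0° drifts rightward and
angles grow counter-clockwise. The spatial phase `φ0` is 0 for all
parametric stimuli — it is irrelevant after trial averaging and fixing it
makes runs reproducible. Plaids are additive in contrast around mid-gray,
two half-contrast components at ±60°, clipped (with a warning) only if a
caller requests component contrasts that leave the displayable range.
Frame counts are `round(duration · frame_rate)`.

Noise movies are Gaussian white noise given an exponential temporal
autocorrelation (AR(1), time constant `temporal_corr`, default 50 ms), a
Gaussian spatial autocorrelation (half-width at half maximum
`spatial_corr`, default 6°), a sinusoidal contrast envelope (period 10 s,
depth 0.8), 3σ clipping and an affine map into [0, 1]. The construction of
such movies is conventional rather than prescribed, so every scale is an
exposed parameter with these defaults; the tests verify the delivered
correlation scales empirically. A movie is a pure function of its seed, so
sessions store seeds, never frames.

## Synthetic units

Four mechanisms, each with a ground-truth label for recovery testing:

* **`ln_component`** — one space-time drifting Gabor filter (carrier phase
  advances across 10 lags of 33.3 ms at the unit's temporal frequency,
  raised-cosine lag envelope peaking at 100 ms) followed by a rectifying
  power-law nonlinearity. Default aspect ratio 3 (envelope sigma along the
  edge three times the 8° sigma across it).
* **`ln_blobby`** — the same cascade with aspect ratio 0.5 and an envelope
  that scales with the carrier wavelength (`0.2/sf`, 10° at 0.02 cpd): a
  compact subfield, broadly tuned in both orientation and spatial
  frequency. Because blobbiness is only meaningful relative to the
  wavelength, these units are modelled as low-SF-preferring.
* **`energy_complex`** — sum of squared outputs of a quadrature filter
  pair: phase-invariant, weakly modulated responses.
* **`pooled_pattern`** — a genuine nonlinear integrator: two
  quadrature-energy channels tuned to the two plaid component directions,
  combined as the geometric mean of their envelopes (a coincidence
  detector that fires when *both* components are present), plus a direct
  channel at the preferred direction whose contrast threshold (40% of its
  peak full-contrast-grating drive) keeps half-contrast plaid components
  from driving it. The direct channel carries the grating tuning, the
  coincidence channel the plaid tuning; both peak at the preferred
  direction. The coincidence weight is calibrated per unit so the
  preferred plaid evokes 80% of the preferred-grating response, giving the
  mild cross-orientation suppression seen in real populations.

Two design points deserve emphasis because simpler alternatives fail in
instructive ways. First, the output nonlinearity defaults to half-
*squaring* (exponent 2, the standard spike-threshold expansion), not plain
rectification: with exponent 1 and a centred even-symmetric filter the
trial-averaged plaid response of any linear unit is exactly proportional
to the component prediction (the two component drives share one temporal
frequency and add coherently), so blobby units could never express the
pattern mimicry they are meant to exhibit. Second, the pattern unit's
coincidence channels must be phase-invariant: multiplying two
phase-sensitive (simple-cell-like) channels makes the product vanish for
roughly antiphase subunit phases, flipping the unit's observed class for a
large fraction of random draws. Energy subunits remove that fragility
(24/24 random constructions classify as pattern, noiselessly, across
preferred directions and both SF/TF combinations). A rectify-then-sum fan
of component afferents — the textbook-sounding construction — is
mathematically component-classified under this battery (its trial-averaged
plaid curve *is* the shifted sum of its pooled grating curve) and is
therefore not used.

Rates are `baseline + gain · drive`, with the gain calibrated so the
preferred full-contrast grating evokes 30 spikes/s over a 2 spikes/s
baseline. Because the drive fluctuations produced by the noise movies are
more than an order of magnitude weaker than a matched grating's, each unit
also carries a noise-adapted operating point (threshold at 0.5 SD of the
noise drive; gain recalibrated to a 10 spikes/s mean evoked rate on a
reference movie) — the contrast gain control of real neurons, without
which reverse correlation would see only baseline spiking. Spiking is
inhomogeneous Poisson, piecewise constant over frames; interstimulus
intervals (1 s) carry baseline Poisson spiking and provide the reference
distribution for z-scoring.

## Metrics

Responses are trial-averaged rates over the full 1.5-s window, z-scored
against the pooled ISI firing-rate distribution (SD floored at
0.1 spikes/s), negatives clipped to zero. A unit is responsive when its
best condition exceeds both 2 spikes/s (baseline-subtracted) and 6
z-points. `DSI = (Rpref − Ropp)/(Rpref + Ropp)` with exact-bin opposite
lookup. The modulation index is the standardised power of the 10-ms PSTH
at the stimulus temporal frequency, `|PS(f1) − ⟨PS⟩| / sd(PS)` over non-DC
frequencies up to Nyquist with `f1` mapped to the nearest grid bin; values
above 3 mark simple-like modulation. `CSI = (Rg − Rp)/(Rg + Rp)` on peak
raw rates. Best SF/TF maximises the peak grating response, ties breaking
toward the lowest SF then TF.

## STA, significance and RF structure

The STA at lag k averages the contrast frame shown k noise frames before
each spike, pooled over the 20 noise movies. Decorrelation divides the
frame's spatial spectrum by the stimulus power spectrum regularised by a
ridge (10% of peak power), with the whitening filter normalised to unit
mean so white stimuli pass unchanged. Significance comes from a
permutation test: the unit's spike count is redistributed uniformly over
the noise epochs (200 draws by default, 100 in the reduced test
configurations), each null STA receives the same decorrelation, and every
pixel is z-scored against its null mean and SD. Because uniformly
distributed spike times remain uniform under any lag shift, one null
ensemble serves all 10 lags, which cuts the cost tenfold without changing
the null. A practical note on decorrelation: at realistic recording
lengths the whitened STA is *farther* (in correlation) from the true
filter than the raw STA, because whitening amplifies residual estimation
noise faster than it removes smoothing bias; its benefit is asymptotic.
Parameter-recovery checks therefore score the raw STA, while the z-scored
frames — whose pixelwise calibration is what the downstream stages need —
drive the LN predictions and RF-structure metrics.

RF structure is summarised by the contrast index (mean of the top 1% of
|z| in a frame; homogeneous of degree one and monotone in SNR), a 2-D
Gabor fit (Levenberg–Marquardt, 8 orientation-seeded starts, `R²` as
explained variance), a lobe count (binarise at 3.5 z — or at half the peak
|z| for very high-SNR frames, so the count reflects dominant subfields
rather than recording depth — then count 8-connected components of each
sign with at least 4 pixels), and the dominant spatial frequency (radial
peak of the zero-padded amplitude spectrum, DC excluded).

## LN prediction and reclassification

The z-scored STA sequence, bilinearly upsampled ×2, becomes the filter of
an LN model probed with the 12-grating/12-plaid battery at 0.02 cpd (the
spatial scale STA estimates resolve best) and the unit's best TF. The
prediction nonlinearity mirrors the generator family: half-squaring with a
threshold at 30% of the peak grating drive. That fraction was calibrated
on noiseless ground-truth filters — over thresholds between 10% and 30%
both filter types reproduce their own observed classification, with the
blobby pattern margin growing toward the upper end, so the upper end is
the default; at 40% even component filters start failing. Units whose
best-frame contrast index falls below the 95th percentile of their own
permutation-null CI are excluded (flagged, not dropped silently).
Predicted curves are classified with the identical Zp/Zc machinery, and
transitions are tabulated per observed class (to-same / to-opposite /
to-unclassified) for units consistently classified at both SFs (the strict
set). Under this loop component units retain their label essentially
always, and pooled-pattern units essentially never (their predicted Zp
collapses toward zero). Blobby linear units sit closer to the decision
boundary: the LN prediction reliably preserves their patternness direction
(Zp' above Zc'), but whether the margin clears the 1.28 significance
criterion fluctuates with Poisson noise at 20 trials, and because their
blobbiness is wavelength-relative they are often labelled differently at
the two SFs and so drop out of the strict set.

## Regressor-bank tuning models

Each unit's concatenated grating+plaid profile (24 bins, peak-normalised)
is modelled as a ridge-regularised linear combination of bank member
curves. Banks are synthetic pools of von Mises-shaped reference tuning
curves — component members (plaid peaks at ±60°), pattern members
(congruent curves) and heterogeneous members constructed to fail both
criteria — standing in for the unit pools of a pretrained motion network;
the interface accepts any member-by-24 matrix, so externally supplied
activations plug in unchanged. Cross-validation holds out 3 of the 24
bins per fold (8 folds, each mixing grating and plaid bins); the ridge
penalty is chosen from 7 log-spaced values by the same CV, and the
reported RMSE is the CV error at the chosen penalty (a single-level
scheme: slightly optimistic in absolute terms, but common to every bank
and therefore neutral for model comparison, which is all it is used for).
Confidence of the winning bank is its relative RMSE advantage over the
runner-up, `(second − best)/second`, with 0.3 the conventional
high-confidence mark; exact ties give confidence 0 and resolve by bank
order.

## Problem sizes and determinism

The headline analyses (classification recovery, LN retention, RF
structure) run on sessions of 5 units per mechanism class, the full
20-trial battery and the full 20 × 60-s noise set, on the default 64 × 48
grid — the scale at which STA filter correlations reach ≈ 0.85–0.95 and
the LN margins are stable. Unit tests use a 32 × 24 grid, fewer trials
and shorter noise. Every random quantity (session, movie, permutation,
fold assignment) is a deterministic function of an explicit seed, and
seeded generators save and restore the caller's RNG state.

## What the synthetic data do and do not show

The generator reproduces the stimulus protocol, Poisson variability,
baseline activity, the linear/nonlinear mechanism distinction and the
contrast-adaptation gap between parametric and noise stimulation. It does
not model eye movements, adaptation within a session, correlated
variability across units, spike-sorting artefacts, laminar or areal
differences, or the diversity of real receptive-field shapes (positions
are centred; phases, SF and TF are drawn from the protocol grid). Passing
tests therefore certify the *analysis chain* — that the estimators and the
classification logic recover known mechanisms under realistic noise — not
any claim about biological populations. Two known cosmetic gaps: pattern
units here keep strongly modulated (simple-like) grating responses because
their direct channel is phase-sensitive, whereas real pattern cells lean
complex-like; and observed CSI values are mildly positive by construction
for pattern units (0.8 plaid/grating ratio) but larger for sharply tuned
linear units, whose preferred plaid is genuinely a weaker stimulus.
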