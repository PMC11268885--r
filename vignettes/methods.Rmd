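---
title: "ringmem: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringmem: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The task and its feature geometry

Each trial presents three items; every item has a screen location and a color,
both drawn from nine values evenly spaced on their respective rings (0°–320°
in 40° steps, with a small ±1°–3° jitter added after all constraints are
checked on the nominal grid). Within a trial, locations are pairwise distinct
(hence ≥ 40° apart at the grid), colors are pairwise distinct, and color ≠
location at each serial position. In the aligned-trajectory condition (AT)
the color triple is the location triple rotated by a random nonzero grid
angle, so the signed inter-item distances d(1→2) and d(2→3) match across
domains; misaligned (MAT) trials are resampled until the full-trajectory
match fails, a single matching leg being permitted. The full design is 648
trials per participant with AT and MAT randomly interleaved.

One clause of the original design description ("each value occurred 36
times") cannot be reconciled with 648 trials × 3 serial positions (uniform
balance would give 72 per position); the generator samples values uniformly
per position rather than guessing the intended constraint, and
`validate_design()` checks everything that is well defined.

## Behavioral model

Reported values are the presented values plus von Mises noise — the standard
circular analogue of Gaussian noise — with concentration κ. Location memory
is more precise than color memory in this task, so the defaults are
asymmetric: κ_location = 12 (circular SD ≈ 17°) and κ_color = 6 (≈ 24°),
magnitudes typical of delayed-estimation working-memory reports. Precision is
1/σ with σ = √(−2 ln R) in radians (R the mean resultant length); degrees are
accepted at the API boundary and converted. The closed form
σ(κ) = √(−2 ln(I₁(κ)/I₀(κ))) is used as the calibration oracle in the tests.

The shared-structure effect is modeled by `coupling_sd` (default 8°): on AT
trials only, one normal draw per leg is added to the second item's error (leg
1–2) and to the third item's error (legs 1–2 plus 2–3) in *both* domains.
Trajectory errors (wrapped later-minus-earlier item errors) then co-vary
across domains on AT trials while per-item noise stays independent, and MAT
trials never receive coupling. At these defaults the trial-level AT
trajectory-error correlation is ≈ 0.1 and the group binned correlation
(below) is positive with wide cohort-to-cohort spread — a deliberately
weak-signal regime, since the group procedure exists precisely to aggregate
weak trial-level coupling.

Wrapping convention: all signed circular quantities live in (−180°, 180°],
with exactly ±180° mapping to +180 by convention (tested). The circular
correlation is the Fisher–Lee pairwise-sine estimator, chosen because the
original analysis does not name its estimator; it is rotation-invariant and
hits ±1 on perfectly (anti-)aligned inputs. The group-level binned
correlation sorts each subject's trials by location trajectory error into 4
equal-count bins (remainder trials are assigned to the leading bins — the
remainder rule is unspecified in the source analysis and documented here),
takes per-bin means of both domains' errors, pools subjects × bins points,
and reports a *linear* Pearson correlation, matching the
scatter-plus-linear-fit presentation of such group analyses; per-subject
statistics use the circular coefficient.

## Forward model and synthetic epochs

Sensor data are generated under the same linear encoding assumption the
decoder inverts: each sensor reads a weighted sum of nine feature-tuned
channels per domain, `B = W_loc C_loc(t) + W_col C_col(t) + ε`. Channel
responses are the idealized tuning curves evaluated at the trial's item
values, gated by item-locked raised-cosine envelopes (the true evoked
envelope shape is unknown; a raised cosine is a simulation choice, not a
claim). Weights are iid Gaussian (full column rank almost surely); noise is
iid Gaussian scaled to a target signal-to-noise variance ratio, with
`snr = Inf` producing data exactly in the column space of the true weights
(tested). Encoding epochs default to items at 0, 1.5 and 3.0 s (mirroring 1 s
presentations with 0.5 s gaps) with 0.8 s envelopes; recall epochs plant a
forward replay of one domain's three items at onsets t₀, t₀+Δt, t₀+2Δt with a
configurable lag Δt and short (0.12 s) envelopes, emulating temporally
compressed reactivation.

What the generator does *not* emulate: volume conduction from a head model,
1/f background spectra, eye movements or muscle artifacts, ICA residues,
trial-to-trial latency jitter, or representational drift. Passing tests
therefore validate the *algorithms* (recovery, calibration, invariances) —
they do not certify performance on real recordings.

## Inverted encoding model

The basis is nine half-wave rectified sinusoids raised to the eighth power,
`f_k(θ) = max(0, cos(θ − φ_k))^8`, centers at the 9-point grid. The original
description says "sinusoids" without phase; cosine-of-the-angular-difference
is the standard idealized-tuning reading and makes `f_k(φ_k) = 1` a testable
landmark. Training solves `Ŵ = B₁C₁ᵀ(C₁C₁ᵀ)⁻¹` per time sample; inversion
applies `Ĉ₂ = (ŴᵀŴ)⁻¹ŴᵀB₂`. Training labels are the *nominal* grid centers —
jitter (±1–3°) is sub-grid and ignored for channel alignment, so recentering
is an exact whole-channel rotation (features further than 5° from the grid
are rejected).

The slope score folds the recentered curve about 0° (averaging the ±d
offsets, d ∈ {40°, 80°, 120°, 160°}, keeping the center point by default — the
original is silent on whether the center entered the regression; both are
supported via `include_center`) and regresses the folded response on the
proximity axis (180 − d)/180, oriented so that better decoding gives a
*positive* slope. Cross-validation is leave-one-block-out over the recording
block ids carried in the `EpochSet` (synthetic designs assign equal-size
contiguous blocks); every trial is decoded exactly once, recentered responses
are averaged over all trials, and the slope time course is smoothed with a
40 ms-SD Gaussian kernel *after* fold aggregation (the ordering is
unspecified in the source; this default is logged here). The kernel is
renormalized over its valid support at the epoch edges, so constant signals
are preserved exactly and no padding assumption is made.

Numerical degeneracies are handled explicitly: a training fold whose labels
miss a grid value leaves that channel unconstrained (singular C₁C₁ᵀ), and the
decoder falls back to the minimum-norm pseudoinverse with a warning — at the
desk-scale trial counts used in the examples this occurs occasionally and is
benign; `train_weights()` itself rejects singular designs with a rank
diagnostic, and a time sample with zero signal (possible only in noiseless
simulations) contributes a flat zero response rather than an error.

## Replay detection

For three decoded item time courses, the lagged correlation at lag L ≥ 0 is
the Pearson correlation of x(t) with y(t+L) over the overlapping window
(variable-length overlap; zero-variance overlaps yield flagged NAs). The
directional measure subtracts the reverse direction from the forward
direction per lag for pairs 1→2 and 2→3 and averages the two profiles; the
peak of the mean profile estimates the inter-item lag, with ties broken to
the smallest lag. Negative lags are represented by the reverse profile rather
than a two-sided axis. The theoretical transition pattern of a clean forward
replay is the superdiagonal 0/1 matrix; the empirical matrix collects all
nine ordered-pair lagged correlations (diagonal included by default, with an
off-diagonal-only flag) at the consensus lag, and similarity is the Pearson
correlation over cells.

The permutation null shuffles the item-identity assignment of the decoded
time courses independently within each subject, then recomputes the group
statistic on the grand average; this preserves each subject's autocorrelation
while destroying consistent ordering. The group statistic operates on
grand-averaged time courses (aggregation before cross-correlation); whether
the original analysis aggregated before or after is unknown, so per-subject
profiles are also accessible. The threshold is the 95th percentile of 1000
permutations, p-values use the (b+1)/(n_perm+1) convention.

Two resolution choices matter for lag estimation. First, the replay module
consumes the *unsmoothed* slope time courses: the 40 ms-SD display kernel is
four sampling steps wide, and pre-smoothing flattens the asymmetry profile
around its peak until sample-level localization becomes unreliable; the
smoothed curves are kept for plotting and cluster statistics. Second,
recall-epoch reactivation envelopes default to 70 ms — the width of the
recall-period decodable windows observed in this paradigm (~60–70 ms per
item) — so that reactivations remain temporally separate even at the shortest
lag studied (80 ms).

Analysis-window choice: recall epochs are 1.0 s at 100 Hz; the default
maximum lag is 0.5 s, but the cohort-level recovery analyses in the tests use
0.3 s, comfortably above the largest planted lag (0.20 s) while keeping at
least 70 overlap samples per correlation. Cohort sizes in the recovery tests
(6 subjects × 72 recall trials, 16 sensors, 4 blocks, 100 cohorts cycling
over lags 0.08/0.13/0.20 s) are the package's desk-scale study conditions.

## Cluster-based permutation inference

Pointwise one-sample t-tests against the null value (0 for slopes, 0.125 for
8-way classifier accuracy) define suprathreshold samples at the
cluster-defining alpha (0.05 default; 0.001 is first-class for strong
encoding-period effects); contiguous same-sign runs form clusters scored by
their *size* in samples (cluster mass is available behind a flag). The
Monte Carlo null exchanges each subject's observed values with the null
constant — algebraically a per-subject sign-flip of deviations — and records
the maximal cluster size per permutation; corrected p = (b+1)/(n_perm+1).
Zero-variance samples yield infinite t and count as suprathreshold.

A property worth knowing: on temporally *white* null data the size statistic
is extremely conservative (null clusters are 1–2 samples wide, so the
discrete max-size distribution barely admits rejections). The test's actual
inputs in this pipeline are time courses smoothed with the 40 ms kernel, so
the package's calibration analyses draw null subjects as 40 ms-smoothed
Gaussian noise at 100 Hz — the data class the test consumes — where the
family-wise error sits near the nominal 5%.

The bootstrap group-difference test resamples each group with replacement and
reports the two-sided zero-crossing proportion with the (b+1)/(n+1)
convention; like most bootstrap mean tests it is mildly liberal for very
small groups, so its calibration check uses 20 subjects per group.

## Trajectory classification

The eight signed trajectory distances (±40°…±160°; exactly eight exist on the
9-point ring, enumerated exhaustively in the tests) are decoded with a linear
maximum-margin one-vs-rest classifier (e1071 SVM, cost 1 — the original gives
no regularization constant, so contracts are written against chance and
separability rather than a specific margin). Folds are stratified (the
original says only "fivefold"; stratification prevents empty-class folds at
desk scale), with 50 fresh random partitions averaged. Features are
standardized inside the SVM, making accuracy invariant to global rescaling.
Alpha-band power uses complex Morlet wavelets, 7 cycles, 8–12 Hz in 1 Hz
steps, averaged over frequencies; power features are log-transformed before
classification (a documented choice; the original is silent).

## Preprocessing

Zero-phase Butterworth band-pass 2–50 Hz (order 6, chosen to keep a > 20 dB
stopband just past the upper edge while remaining stable under
forward-backward filtering), decimation to 100 Hz, per-trial per-sensor
baseline subtraction over −300…−100 ms, and rejection of trials whose total
variance exceeds the median × 5. A sensor-subset argument supports restricting
decoding to a named posterior set; the default is all sensors.

## Problem sizes and determinism

All simulation stages take explicit integer seeds and are byte-reproducible;
results files embed the configuration hash and seed. The bundled analyses use
desk-scale sizes (8–12 subjects, 72–648 trials, 16 sensors) chosen so each
stage completes in seconds to a few minutes while leaving the recovery
margins wide; the statistical procedures themselves are size-agnostic.

## Known limitations

* The forward simulation is deliberately minimal (see above); absolute effect
  sizes on synthetic data do not transfer to real EEG.
* The cluster test corrects over time only; sensor-adjacency clustering and
  TFCE are out of scope.
* The replay module implements lagged-correlation asymmetry, not
  TDLM-style sequenceness or hidden-Markov decoders.
* Inferential omnibus tables (repeated-measures ANOVA, GLMMs) are left to
  standard routines; the package exposes tidy summaries to feed them.
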