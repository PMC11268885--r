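# ringmem

Decoding and replay analysis of multi-sequence working memory on ring-valued
features, in R.

## The problem

In multi-sequence working-memory experiments, participants memorize a short
sequence of items (here: three colored disks) whose two features — screen
location and color — each live on a circular feature space, sampled from nine
values (0°–320° in 40° steps). The key manipulation is whether the two
sequences share a *trajectory*: in the aligned condition (AT) the signed
inter-item distances d(1→2) and d(2→3) are identical for the location and
color rings (one ring is a rotation of the other), while in the misaligned
condition (MAT) the full trajectories differ. Shared structure is expected to
(a) improve memory precision, (b) couple the reported location and color
trajectories, and (c) show up neurally as reactivation of the common
trajectory and fast sequential replay of the stored sequence.

`ringmem` implements the complete analysis chain for such experiments, plus a
ground-truth synthetic-data generator so that every stage is testable without
any recordings:

* **Synthetic data** — `generate_design()` (constraint-checked ring designs,
  648 trials by default, AT/MAT interleaved, ±1–3° jitter),
  `simulate_behavior()` (von Mises report noise with an optional AT-only
  shared trajectory perturbation), `simulate_eeg()` (forward-model sensor
  epochs `B = W · C(t) + noise`, with optional planted sequential replay at a
  known inter-item lag).
* **Behavior** — `response_errors()`, `circular_sd()` (σ = √(−2 ln R)),
  `memory_precision()` (1/σ), `trajectory_error()`, the Fisher–Lee circular
  correlation `circ_cor()`, and the group `group_binned_correlation()`
  (per-subject quartile binning by location trajectory error, pooled across
  subjects).
* **IEM decoding** — `make_basis()` (nine half-wave-rectified sinusoids raised
  to the 8th power), least-squares training `Ŵ = B₁C₁ᵀ(C₁C₁ᵀ)⁻¹`, inversion
  `Ĉ₂ = (ŴᵀŴ)⁻¹ŴᵀB₂`, recentering to 0°, the slope score of the folded tuning
  curve, leave-one-block-out `decode_timecourse()` with 40 ms Gaussian
  smoothing.
* **Replay** — `lagged_correlation()`, forward-minus-reverse
  `direction_asymmetry()`, `find_peak_lag()`, theoretical vs. empirical
  `TransitionMatrix` similarity, and the across-subject label-shuffle
  `replay_permutation_null()`.
* **Inference** — `cluster_permutation()` (cluster-size statistic,
  sign-flip Monte Carlo null, corrected p = (b+1)/(n_perm+1)) and
  `bootstrap_group_diff()`.
* **Trajectory classification** — `trajectory_labels()` (8 signed classes
  ±40°…±160°, chance 1/8), `morlet_alpha_power()` (7-cycle Morlet, 8–12 Hz),
  and `decode_trajectory()` (one-vs-rest linear SVM, stratified 5-fold CV ×
  50 repeats).
* **Pipeline** — `preprocess()` (2–50 Hz band-pass, downsample to 100 Hz,
  −300…−100 ms baseline, variance-based trial rejection) and
  `run_pipeline()`, the end-to-end driver used by the numbered scripts under
  `analysis/`.

## Worked example

Plant a forward replay of the color sequence at a 130 ms inter-item lag,
decode it back, and test it against the label-shuffle null:

```r
library(ringmem)
res <- run_pipeline(pipeline_config(seed = 4000, n_subjects = 8,
                                    n_trials = 96, replay_lag = 0.13))
res$replay$peak_lag                  # 0.13
res$replay$similarity                # 0.973
res$replay$permutation$observed     # 0.851
res$replay$permutation$threshold    # 0.361
res$replay$permutation$p            # 0.000999
round(res$replay$empirical_matrix, 3)
#        [,1]   [,2]  [,3]
# [1,]  0.065  0.878 0.142
# [2,]  0.120  0.177 0.898
# [3,] -0.090 -0.046 0.014
```

The recovered peak lag equals the planted 130 ms; the empirical 3×3
transition matrix concentrates its mass in the (1,2) and (2,3) cells — the
forward superdiagonal pattern — and correlates at r = 0.973 with the
theoretical pattern, far above the 95th percentile of the permutation null.
The numbers above are what `analysis/04_replay.R` prints.

The full synthetic study is organized as numbered drivers:

```sh
Rscript analysis/01_simulate.R            # designs + behavioral reports
Rscript analysis/02_behavior.R            # precision, trajectory correlations
Rscript analysis/03_iem_decoding.R        # encoding-period IEM + cluster stats
Rscript analysis/04_replay.R              # recall-period replay detection
Rscript analysis/05_trajectory_decoding.R # 8-way trajectory classifier
Rscript analysis/06_cluster_stats.R       # inference calibration
```

Each writes its tables under `results/` and prints a short narrative of what
it found.

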