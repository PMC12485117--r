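# olfactr

Analysis of simultaneously recorded neuronal (calcium) and neurochemical
(acetylcholine / serotonin) volumetric fluorescence imaging during repeated
odor presentations in the fly brain.

Modern dual-color volumetric imaging records a calcium indicator and a
genetically encoded neurotransmitter sensor (GRAB-type ACh or 5-HT
indicators) at the same time, across dozens of brain regions, over hours of
repeated odor trials. `olfactr` implements the analysis chain such
experiments need, end to end, for users who have denoised, motion-corrected,
atlas-aligned volumes plus a trial table:

- **ΔF/F extraction** with a sliding baseline: per frame,
  `F0` is the mean of the lowest 30% intensities among the previous 200
  frames and `ΔF/F = (F − F0)/F0` (compiled, exact to a sort-based oracle).
- **Response metrics** per voxel and region: significance-gated Pearson
  responsiveness to the binary stimulus sequence, response intensity (sd or
  AUC of ΔF/F in the response window), phase delay (onset-to-peak time) and
  pulse width (FWHM with sub-frame interpolation), and odor tuning (AUC
  difference versus the other odors pooled, Mann–Whitney + BH gated).
- **Functional connectivity** at region level (full weighted Pearson
  networks) and voxel level (top-30% correlation edges): Louvain/greedy
  communities, community ratio of the olfactory community, weighted degrees,
  clustering coefficients, Wasserstein/energy distances between
  degree-centrality distributions, and the dual-channel *deflation-ratio*
  statistics: for correlation matrices `M` the deflation ratio is
  `(M − M̄)/M̄`, the difference matrix is
  `Δ = (M_N − M̄_N)/M̄_N − (M_C − M̄_C)/M̄_C`
  (neurochemical minus calcium), and `Δ_w⁺ − Δ_b⁺` — the mean positive `Δ`
  within calcium-defined clusters minus between them — quantifies
  cross-cluster connectivity *complementation* by the neurochemical channel.
- **Odor-identity decoding** at four tiers: 4×4×2-voxel block accuracy maps
  (PCA→SVM), per-region classification (PCA at 80% variance → LDA at the
  third post-onset frame → linear SVM on trial trajectories), voxel-level
  multi-region decoding (block-wise PCA at 90% variance → global PCA to 25
  dimensions → LDA → SVM), and region-average decoding (PCA at 99.8%).
  Everything is fitted per cross-validation fold on training trials only;
  composed block-PCA × PCA × LDA maps give per-voxel identification-weight
  maps.
- **Manifold geometry**: the fitted transforms project full trial windows
  (−2 s to +33 s) into the discriminant space; folds are aligned by
  orthogonal Procrustes; distance-to-origin, inter-/intra-class distance,
  return-to-one-fifth and return-to-random times, and stage-wise (4 × 15
  sessions) temporal-stability summaries are computed on the combined
  manifold.
- **Motion controls**: motion energy from behavior video frame differences,
  behavioral PCs, SVM decoding of stimulus period and odor identity from
  behavior, ridge variance partitioning of neural PCs into behavior- and
  stimulus-explained parts, and ±1 s lagged cross-correlation profiles.
- **Statistics**: an exact Scheirer–Ray–Hare nonparametric two-way ANOVA on
  ranks (tie-corrected, chi-squared reference), Benjamini–Hochberg
  correction, and a uniform-record wrapper for the standard nonparametric
  battery with rank-biserial effect sizes.
- **Synthetic data generator**: plants odor-tuned voxel ensembles in atlas
  regions, channel-specific double-exponential kinetics, per-session
  amplitude drift schedules, motion coupling and noise — with full ground
  truth — so every stage of the pipeline can be validated against known
  answers.

## Worked example

Generate a desk-scale synthetic experiment (two channels, 20 sessions × 3
odors, 2.3 Hz), decode odor identity from the calcium channel, and inspect
the manifold and the region-level network:

```r
library(olfactr)

espec <- lapply(setNames(nm = c("calcium", "ach")), function(ch)
  lapply(setNames(nm = c("OCT", "MCH", "EA")), function(od)
    list(regions = 1:2, fraction = 0.1, amplitude = 0.6)))
cfg <- synth_config(grid_shape = c(12, 6, 4), n_regions = 4,
                    olfactory_regions = 1:2, n_sessions = 20,
                    rest_duration = 120, noise_sd = 0.05,
                    ensemble_spec = espec, seed = 2024)
ex <- generate_experiment(cfg)
ex
#> Synthetic odor-imaging experiment
#>   grid: 12 x 6 x 4 ( 288 voxels )
#>   channels: calcium, ach
#>   trials: 60 ( 20 sessions x 3 odors )
#>   frames: 5188 at 2.3 Hz

dff <- dff_tensor(ex, "calcium")
trials <- extract_trials(dff, ex$trials, pre_frames = 0, post_frames = 20)
res <- multiregion_classify(trials, ex$voxel_coords,
                            spec = decoder_spec(seed = 1))
res
#> Odor decoding (multiregion): accuracy 100.0% (100%, 100%, 100%, 100%, 100% per fold)

rate <- ex$frame_rate
full <- extract_trials(dff, ex$trials, ceiling(2 * rate), ceiling(33 * rate))
traces <- align_folds(project_manifold(res, full))
manifold_metrics(traces)
#> Manifold metrics: max dist-to-origin 9.905 at 0.87 s; t_fifth 3.36 s; t_random 6.87 s
#>   max inter-class 17.091 ; mean intra-class (0-12 s) 2.855

reg <- region_average(dff)
stim <- stimulus_vector(ex$trials, ex$n_frames, rate)
fc <- build_fc(reg[, stim == 1], edge_rule = "all")
comm <- detect_communities(fc, "louvain", seed = 1)
olf <- as.integer(rownames(reg)) %in% cfg$olfactory_regions
community_ratio(fc, comm$assignment, olf)
#> [1] 0.9608
```

Reading the numbers: with ensembles planted in the two olfactory regions at
12× the noise sd, the decoder separates the three odors perfectly; the
manifold expands to its maximum extent 0.87 s after odor onset, contracts to
one fifth of that extent after 3.4 s and reaches the pre-trial (random)
level by ~7 s; and 96% of the region-network's positive edge weight lies
inside the community containing the olfactory regions.

The planted ground truth (`ex$ground_truth`) records ensemble memberships,
kinetics, drift schedules and the motion trace, so recovery can be checked
quantitatively at every stage.

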