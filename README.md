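# eegsourcenet

Source-space EEG brain-network analysis in R: from multichannel resting-state
recordings to group-level network statistics, with a synthetic-cohort
generator whose spectral and phase-coupling structure is known in closed
form.

The package targets the kind of study where high-density EEG is recorded
from a patient group and matched controls (here: a Parkinson's-disease-like
group with a paired stimulation ON/OFF condition), cortical activity is
reconstructed on a 68-region atlas, and group differences are tested on
band power, graph-theoretic network topology, and edgewise connectivity.
Because such clinical recordings are rarely shareable, the package ships a
simulator that emulates the design with planted, analytically tractable
effects, so every stage of the pipeline can be validated against ground
truth.

## The pipeline

1. **Synthetic cohort** (`simulation_spec`, `simulate_coupled_sources`,
   `simulate_group_study`): each region carries band-limited oscillations in
   theta (4–8 Hz), alpha (8–13 Hz), beta1 (13–20 Hz) and beta2 (20–30 Hz)
   plus 1/f background noise. Coupled region pairs share a band phase; the
   non-reference member adds von Mises jitter with concentration κ, so the
   population phase-locking value is exactly

   PLV(κ) = I₁(κ) / I₀(κ)

   (ratio of modified Bessel functions). The patient-like group has elevated
   theta and reduced beta amplitudes and a planted beta2 subnetwork whose κ
   changes between the OFF and ON conditions.
2. **Preprocessing** (`bandpass_filter`, `epoch_recording`,
   `reject_artifact_epochs`, `interpolate_bad_channels`): zero-phase 1–30 Hz
   Butterworth filtering, non-overlapping 2-s epochs, peak-to-peak artifact
   rejection (default 150 µV), inverse-distance bad-channel interpolation.
3. **Inverse solution** (`compute_wmne_operator`, `apply_inverse`,
   `parcellate`): weighted minimum-norm estimation
   K = W Gᵀ (G W Gᵀ + λ² C)⁻¹ with depth weights wⱼ = ‖gⱼ‖^(−2γ)
   (defaults λ² = 1/9, γ = 0.8), then sign-aligned averaging of vertex time
   series into the 68 Desikan–Killiany regions.
4. **Spectra** (`welch_psd`, `band_power`, `band_snr`): Welch/Hanning PSD
   (4-s windows, 50% overlap), band powers and within/without band SNR.
5. **Connectivity** (`instantaneous_phase`, `plv`, `pli`,
   `connectivity_matrix`): band-pass + Hilbert phases, phase-locking value
   PLV = |⟨e^{i(φx−φy)}⟩| (phase lag index as comparator), all 2,278 region
   pairs per band.
6. **Graph metrics** (`proportional_threshold`, `characteristic_path_length`,
   `global_efficiency`, `clustering_coefficient`, `local_efficiency`,
   `normalize_vs_random`): weighted graphs thresholded to the top 5–50% of
   edges, distances d = 1/w, Onnela clustering, Maslov–Sneppen null models.
7. **Group statistics** (`permutation_test`, `t_statistic`, `fdr_bh`, `nbs`,
   `edge_count_summary`): label-shuffling/sign-flip permutation tests,
   Benjamini–Hochberg FDR, and the network-based statistic (edge p = 0.05,
   component p = 0.01, 5,000 permutations by default).

`run_pipeline()` chains all stages from a single config (R list or YAML) and
writes TSV/JSON outputs plus a reproducibility manifest.

## Worked example

```r
library(eegsourcenet)

## a coupled pair with kappa = 2 against independent background regions
cp  <- data.frame(i = 1, j = 2, band = "beta2", kappa = 2)
sim <- simulate_coupled_sources(
  simulation_spec(n_regions = 6, fs = 1000, duration = 60,
                  coupling = cp, seed = 21))
cm  <- connectivity_matrix(sim$sources, "beta2", epoch_scheme = "whole")

expected_plv(2)          # 0.6977747  (I1(2)/I0(2))
cm$values[1, 2]          # 0.7046  measured PLV of the planted pair
median(cm$values[upper.tri(cm$values)][-1])   # 0.0239  background pairs

## the published per-band significant-edge counts, summarized
counts <- data.frame(
  band      = rep(c("theta", "alpha", "beta1", "beta2"), 2),
  direction = rep(c("decrease", "increase"), each = 4),
  edges     = c(85, 88, 112, 84, 207, 91, 156, 168))
edge_count_summary(counts)$by_direction
#>   direction   mean       sd n_bands
#> 1  decrease  92.25 13.27592       4
#> 2  increase 155.50 48.19751       4

updrs_improvement(46.5, 17.1)   # 0.6322581 -> 0.63 improvement rate
```

The planted pair's measured PLV (0.70) sits near its closed-form expectation
0.698 while uncoupled pairs stay below 0.1; the edge-count summary
reproduces the study-style means ± SDs (92.25 ± 13.28 decreased vs
155.50 ± 48.20 increased edges across bands).

## Vignette

`vignettes/methods.Rmd` documents the generative model and its closed forms,
the numerical choices in every stage, and the known limitations of the
synthetic validation.
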