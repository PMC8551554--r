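---
title: "Models and methods behind eegsourcenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eegsourcenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsourcenet)
```

`eegsourcenet` implements a complete source-space EEG network analysis —
weighted minimum-norm source reconstruction, band power spectra,
phase-locking connectivity over a 68-region cortical atlas, weighted graph
metrics across proportional sparsity thresholds, and permutation-based group
statistics including the network-based statistic (NBS) — together with a
synthetic cohort generator that emulates a patient/control study with a
paired stimulation ON/OFF condition. This vignette documents the generative
model and its closed forms, the tunable parameters and their defaults, the
numerical choices in every stage, and what the synthetic validation does and
does not establish about real data.

## The generative model

Each subject's source activity is a regions × samples matrix. Region $r$
carries, for each canonical band $b \in \{\theta, \alpha, \beta_1,
\beta_2\}$,

$$x_r(t) \;=\; \sum_b A_b \cos\!\big(\psi_{b,r}(t)\big) \; + \; \eta_r(t),$$

where $A_b$ is the band amplitude (unitless; controls group power effects)
and $\eta_r$ is 1/f background noise (FFT-shaped white noise with power
$\propto 1/f$, truncated below 1 Hz, total standard deviation `noise_sd`,
default 0.25).

**Band oscillator.** The phase $\psi$ is a bounded frequency-modulated
process: the instantaneous frequency wanders over the central 80% of the
band as $f(t) = f_{mid} + 0.8\,(BW/2)\tanh(1.5\,u(t))$ with $u$ a
unit-variance AR(1) process of correlation time 0.4 s, plus a small Brownian
phase roughness (4 rad²/s). Two design constraints drove this choice and
both are properties the package's own tests enforce:

* *Band confinement.* Band-power contrasts planted via $A_b$ must land in
  their own band. The bounded-FM spectrum keeps roughly 80–90% of each
  oscillator's power inside its band, so a planted 1.5× theta amplitude
  realizes a group power ratio close to $1.5^2 = 2.25$ (measured ≈ 2.1 at
  $n = 20$; the shortfall is cross-band leakage and background noise).
* *Null decorrelation.* Two independent oscillators must lose phase
  alignment quickly, otherwise the 60-s phase-locking value of *uncoupled*
  pairs does not approach 0. Pure "carrier ± small drift" models fail this
  badly (null PLV 0.08–0.13 at 60 s); the band-filling frequency wander
  plus roughness brings the null down to ≈ 0.03–0.05, the time–bandwidth
  limit of a 10-Hz-wide band observed for 60 s.

A narrower, more tonal oscillator would look more like textbook alpha but
cannot satisfy both constraints at once; the chosen constants are a
calibration of the generator to its own documented contract, not to any
test outcome.

**Phase coupling.** Coupling is specified per region pair and band as a von
Mises concentration $\kappa \ge 0$. Within a band, coupled pairs must form
star-shaped groups: the group's reference region (lowest index) carries the
shared phase $\psi$, and every other member adds jitter
$\theta_r(t) \sim \mathrm{vM}(0, \kappa_r)$. Because
$E[e^{i\theta}] = I_1(\kappa)/I_0(\kappa)$, the population PLV between the
reference and a member is exactly the Bessel ratio (`expected_plv()`), and
between two members the product of their ratios; both are recorded in the
returned ground truth. Arbitrary coupling graphs have no such closed form
under this construction, which is why non-star groups are rejected at
validation.

The jitter series must be *smooth* (white jitter would be destroyed by the
band-pass filter that precedes phase extraction) yet have an *exact* von
Mises marginal. Both are obtained with a Gaussian copula: an AR(1) process
(correlation time 0.5 s) is mapped through its normal CDF and the von Mises
quantile function (numerically inverted CDF on a 4,096-point grid; a
wrapped-normal limit $\theta = z/\sqrt{\kappa}$ is used for
$\kappa > 50$, where `besselI` overflows and the closed form switches to
the asymptotic $1 - 1/(2\kappa) - 1/(8\kappa^2)$).

**Paired design.** Every random stream is keyed by the subject seed, the
band, and the region (or coupling-group reference). The stimulation-OFF and
ON specs share the master seed, so a patient's background noise, band
phases, and jitter *draws* are identical across conditions; only the planted
coupling change (default: a 10-edge beta2 star with $\kappa = 5$ OFF and
$\kappa = 0$ ON) alters the series. Regions untouched by the planted
subnetwork are bit-identical between conditions.

**Group defaults.** The control-like group has unit amplitudes in all
bands; the patient-like group has theta × 1.5 and beta1/beta2 × 0.7,
emulating the slowed background activity characteristic of parkinsonian
EEG. The default group sizes follow the emulated study (21 controls, 20
patients); demonstration configs use smaller cohorts.

## Forward model and inverse solution

`make_toy_lead_field()` builds a spherical toy geometry: sensors on a unit
sphere (Fibonacci lattice with small seeded jitter), one source dipole per
region on a concentric sphere of radius 0.8, gain decaying as inverse
squared distance, globally scaled so the mean gain-column norm is 1. It is
a stand-in for a boundary-element forward model: adequate for validating
the linear-algebraic pipeline, with no claim to anatomical realism.

The inverse operator is weighted minimum-norm estimation,
$K = W G^{\top} (G W G^{\top} + \lambda^2 s C)^{-1}$, with diagonal depth
weights $w_j = \lVert g_j \rVert^{-2\gamma}$, noise covariance $C$
(identity by default), and $s$ the mean diagonal of $GWG^{\top}$ so that
$\lambda^2$ lives on the conventional dimensionless SNR scale
($\lambda^2 = 1/\mathrm{SNR}^2$; default $1/9$). The depth exponent
defaults to $\gamma = 0.8$: on the toy geometry $\gamma = 0.5$ localizes
noiseless single sources in only ~93% of placements whereas $\gamma = 0.8$
is essentially exact, and 0.8 matches common minimum-norm practice.
Orientations are fixed (one scalar per source); free orientations are out
of scope.

`parcellate()` averages member vertices per region after flipping each
vertex to agree with the region's first principal direction (first left
singular vector). The singular vector's global sign is arbitrary, so it is
anchored to preserve the polarity of the majority of vertices. With one
vertex per region (the toy geometry) parcellation reduces to reordering.

## Preprocessing

The band-pass is a 4th-order Butterworth applied forward–backward
(zero-phase, 8th-order magnitude). At 1–30 Hz and fs = 1000 this attenuates
a 60-Hz tone (one octave above the edge) by more than 40 dB; the exact
response at any frequency is checked in the tests against the filter's own
transfer function. Epochs are non-overlapping 2-s slices (trailing
remainder discarded). The artifact criterion — drop an epoch if any
channel's peak-to-peak amplitude exceeds 150 µV — is a deliberate, simple
stand-in for the unstated manual criteria of real studies; it is
configurable and sufficient for synthetic data, where artifacts exist only
if planted. Independent component analysis is intentionally absent: the
generator plants no biological artifacts, and real data are expected
pre-cleaned. Bad channels are replaced by the inverse-distance-weighted
mean of the k = 4 nearest good channels; *detecting* bad channels is left
to the caller.

## Spectral analysis

`welch_psd()` averages Hanning-tapered, 50%-overlapping 4-s segment
periodograms into a one-sided density (power per Hz), so the integrated
PSD matches the series variance (Parseval; verified to 5% against white
noise). Because a 4-s window cannot fit a 2-s epoch, surviving epochs are
re-concatenated (`epochs_to_recording()`) before PSD estimation. Band power
is the trapezoidal integral over the band; a shared band edge contributes
half-weight to each neighbour, so band powers are exactly additive over a
partition and no mass is double counted. Band SNR is within-band power over
out-of-band power inside 1–30 Hz. Group tests use absolute power by
default; relative power is a trivial post-hoc division.

## Connectivity

Phases come from zero-phase band-pass plus the FFT-constructed analytic
signal, with one second trimmed per side against filter and Hilbert edge
effects. PLV is the modulus of the time-averaged unit phasor of the phase
difference; PLI, the comparator, is the modulus of the mean sign of the
phase-difference sine (blind to zero-lag coupling, by construction). Two
epoch schemes exist: per-2-s-epoch PLV averaged across epochs (default,
mirroring the preprocessing epoch structure) and whole-recording (the
scheme under which the simulator's closed form applies — slowly varying
jitter looks locked within any single 2-s epoch, so the per-epoch estimate
is upward-biased by design and validation uses the whole-recording path).
The matrix is symmetric with unit diagonal (PLV), which is excluded from
all downstream statistics.

## Graph metrics

Proportional thresholding keeps the top $k = \mathrm{round}(s \cdot
n(n-1)/2)$ weighted edges, ties broken in stable (row, column) order;
weights are retained, not binarized. Shortest paths use distances
$d = 1/w$. Global efficiency is the Latora–Marchiori mean of inverse
distances (the literal reciprocal of the characteristic path length is
available behind a flag); clustering is Onnela's weighted form with weights
normalized by the graph maximum; local efficiency is the global efficiency
of each node's neighbour-induced subgraph. All four reduce to textbook
binary values on unit-weight graphs and are tested edge-for-edge against
exhaustive Floyd–Warshall and triple-enumeration oracles on ≤ 6-node
graphs. Normalization against randomness divides L and C by their means
over 20 Maslov–Sneppen degree-preserving rewired surrogates with the
original weights shuffled onto the rewired topology; disconnected
surrogates are re-drawn with a retry budget. Note that a 68-node graph at
sparsity 0.05 retains 114 edges, which spans all nodes only when the weight
structure is favourable — `minimum_connected_sparsity()` reports the first
grid point at which the thresholded graph is connected, and the
characteristic path length refuses disconnected graphs rather than
silently dropping pairs.

## Group statistics

Permutation tests use difference of group means (independent;
label-shuffling null) or mean of paired differences (sign-flip null), with
$p = (1 + \#\{|T^*| \ge |T|\})/(1 + n_{perm})$ — never zero, floor
$1/(n_{perm}+1)$. With $n$ pairs there are only $2^n$ distinct sign
patterns, so at small $n$ the identity pattern recurs among the draws and
the attainable floor rises accordingly. Edgewise and metric-wise t
statistics are the pooled two-sample and one-sample-on-differences forms
(vectorized across all 2,278 edges × permutations for NBS; cross-checked
against `stats::t.test`). Multiple comparisons over the sparsity-grid ×
metric family use Benjamini–Hochberg FDR via `stats::p.adjust`.

**NBS.** Edgewise t statistics are thresholded one-sided at edge-level
p = 0.05 (Student quantile at the design's degrees of freedom), separately
for the increase and decrease contrasts; connected components of the
supra-threshold graph are scored and compared against the permutation null
of the maximal component score. The component statistic defaults to
**intensity** (summed supra-threshold t) rather than extent (edge count).
The reason is structural: at an edge threshold of p = 0.05, about 5% of
the 2,278 edges cross by chance alone (~114 edges on 68 nodes, mean degree
≈ 3.3), so the null supra-threshold graph *percolates* into a giant
component of 80–100 edges. Max-extent nulls are then dominated by
percolation geometry and a compact 10-edge effect can never reach
p < 0.01, no matter how strong (we measured perfect recall with p-values
scattered up to 0.98). Intensity separates cleanly because noise edges
contribute t ≈ 2 each while genuine edges contribute their full, much
larger t. Extent remains available (`component_stat = "extent"`) for
stricter primary thresholds, where the supra-threshold graph is
subcritical and extent behaves classically. Weak familywise error control
holds for either statistic and is verified by Monte Carlo (null rate at
component α = 0.01 measured ≈ 0.02 over 200 null datasets, two one-sided
contrasts combined).

## Problem sizes used in validation

The validation battery balances fidelity against runtime and states its
sizes explicitly as package choices: closed-form PLV recovery uses 60-s
recordings at the generator's native 1,000 Hz with seven coupled pairs per
κ and the beta2 rhythm isolated (with all four rhythms active, the beta1
oscillator sits inside the beta2 filter's transition band and acts as
phase noise — a property of band-adjacent rhythms, not of the coupling
model under test); the end-to-end planted-subnetwork runs use 10 patient
pairs, 30-s recordings at 128 Hz, 64 sensors, and 1,000 NBS permutations;
calibration uses 1,000 null repetitions (permutation test) and 200 null
datasets (NBS). The pipeline demo config defaults to 12 + 12 subjects at
60 s and 250 Hz.

## Known limitations

* The toy spherical forward model has no anatomy, no realistic
  conductivities, and one dipole per region; localization results on it do
  not transfer quantitatively to head models (the inverse and parcellation
  APIs accept many-vertex geometries, but fixtures stay small).
* Source leakage is not corrected (no orthogonalization), matching common
  PLV practice; planted effects are recovered *despite* leakage in the
  paired design, which cancels shared background exactly — real
  between-session data will not cancel so cleanly.
* The oscillator model trades spectral realism for analytic tractability:
  its linewidth is broader than typical resting alpha so that uncoupled
  pairs decorrelate within a 60-s recording. Passing the closed-form
  checks validates the estimator chain, not the realism of any particular
  rhythm.
* No artifact waveforms are modelled (in particular no high-frequency
  stimulation artifact: the 1–30 Hz band-pass would remove a 130-Hz
  artifact in any case, and whether subharmonics would contaminate the
  band is untested).
* Amplitude–amplitude coupling, cross-frequency coupling, and directed
  measures are out of scope.
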