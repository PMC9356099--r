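---
title: "Methods: kinematics, laterality and dynamics of tail wagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, laterality and dynamics of tail wagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wagdyn` analyses dog tail-wagging behaviour from 3D keypoint
trajectories of the withers, back, croup and tail tip, sampled at high
frame rate (150 Hz by default). This vignette explains the models and
procedures behind each stage, the parameters that matter, the numerical
choices the implementation makes, and what the synthetic-data tests do
and do not demonstrate.

## Preprocessing

Raw pose-estimation output carries per-landmark confidence; frames where
any landmark's likelihood falls below 0.9 are masked (masked, never
deleted — every stage preserves frame count and timestamps, and masking
only clears a validity flag). Coordinates are smoothed with a normalized
Gaussian kernel, default sigma 2 frames (about 13 ms at 150 Hz): enough
to suppress sub-millimetre tracking jitter without attenuating wagging at
up to ~6 Hz. Masked frames are excluded from the kernel support and the
kernel renormalized over what remains, so smoothing never bleeds
information across validity gaps and leaves constant trajectories
unchanged.

Alignment places the croup at the origin and rotates about the vertical
axis so the ground-plane projection of the croup-to-back direction points
along +y. Only yaw is corrected: the wagging angle is defined in the
ground plane, so spine pitch and roll are deliberately left alone.
Frames whose back and croup coincide in the ground plane (heading
undefined) are masked with a warning.

Still intervals are removed with a sliding 50-frame window (stride 1): a
window's spread is the square root of the summed per-axis sample
variances of the 3D tail-tip position — a single scalar in cm comparable
to the 1.2 cm threshold — and every frame covered by any sub-threshold
window is masked. Computing the spread per window over raw coordinates
keeps the rule monotone (more masking can only remove frames) and
deterministic. The window is specified in frames rather than seconds;
50 frames is the default even though 0.3 s at 150 Hz would be 45, and
both window and threshold are configurable.

## Kinematics and bouts

The signed wagging angle is `theta = atan2(x, -y)` in degrees of the
body-frame tail tip: 0 when the tail points straight back, negative to
the dog's left, positive to the right, in (−180°, 180°]. Angle extrema
are detected per contiguous valid run from sign changes of first
differences, with plateau ties resolved to the first plateau index (a
deterministic convention). Adjacent extremum pairs whose swing is below a
2° prominence floor are pruned, smallest swing first; without this,
noise-scale flutter near a turning point fragments bouts. Removing an
adjacent min/max pair always preserves alternation, so the pruned
sequence still alternates strictly.

A bout spans a minimum extremum, the following maximum, and the next
minimum (left → right → left); bouts tile each valid run with shared
endpoint minima, and leading maxima open no bout. A bout's side is the
sign of the mean angle over its frames: this agrees with the sign of
every extremum for one-sided bouts, and is robust for the rare bout that
straddles a side transition, where the mean of three extrema can be
swayed by one deep excursion. Amplitude is the absolute difference of
adjacent extremal angles (0–360°); bout velocity is the mean of
|Δtheta|/Δframes over adjacent extremum pairs, reported in degrees per
frame at the native frame rate (a helper converts to °/s).

The joint-distribution map used for figures accumulates one Gaussian
kernel per observation, `Z_i = S exp(-((X-a_i)^2 + (Y-b_i)^2)/sigma^2)`
with S = sigma = 0.5, into `H = 1 - prod_i(1 - Z_i)`: a saturating
"soft-OR" of kernels, so one isolated observation at a node peaks at 0.5,
two coincident ones at 0.75, and dense regions approach 1. The grid is
400×400 by default, spanning [−180°, 180°] on the angle axis and the data
range on the other; the published description of the grid constants is
internally inconsistent (a fixed 400-row matrix with unspecified offset),
so the grid is exposed as configuration rather than hard-coded.

## Laterality

Per kinematic bin (100 amplitude or velocity bins by default), the
asymmetric wagging index is `(X_r - X_l)/(X_l + X_r)`: −1 when every
counted extremum is left-sided, +1 when right-sided, undefined (NA, never
0) for empty bins. A `paper_literal` mode computes the alternative form
`(X_l - X_r)/max|X_l - X_r|`, which normalizes by the largest count
difference across bins; note its sign convention is inverted (+1 =
strongest left excess) and it is provided for comparison only — the
default mode is the one whose endpoints mean "complete left/right bias".

Each session is divided into 15 segments × 30 sub-segments (20 s and
0.67 s for a 5-min session at 150 Hz; trailing remainder frames are
dropped). Per sub-segment, valid frames with theta < 0 and theta > 0 are
counted (theta = 0 counts to neither side); per segment, the two
30-sample count vectors are compared with a two-tailed Welch t-test and
the segment labelled left/right by mean ordering when p < 0.05, else
none. Short sub-segments can produce constant counts, where the Welch
statistic is undefined: both groups zero-variance with equal means gives
p = 1, with unequal means p = 0 plus a degeneracy flag.

Day-level analysis pools segment labels per day, and compares every day
pair for every label with a Mann-Whitney test across animals (each
animal contributes its per-session label fraction; the normal
approximation is used since count ties are common). The whole family of
day-pair × label comparisons is Holm-Šídák adjusted at level 0.05; the
step-down Šídák form is implemented in-package since `stats::p.adjust`
offers Holm-Bonferroni but not Šídák. The test suite verifies the
procedure's realized type-I error under a null cohort (10 animals, three
identical days, 200 replicates) stays within 0.07, and that a planted
bias drift from 0.2 to 0.7 right-sided across three days is detected in
at least 18 of 20 replicates.

## Bout clustering and fingerprints

Dynamic time warping between bout traces accumulates squared point
distances over monotone alignment paths with unit steps (right, down,
diagonal), anchored at both endpoints; the reported distance is the
square root of the minimal accumulated cost, so distances scale linearly
with amplitude. The square root is monotone, so it never changes any
clustering decision. The default representation is the 1-D angle series
(a bout is defined by its angle trajectory); the ground-plane or 3D
tail-tip traces are available since spatial trajectories carry posture
information the angle discards. No Sakoe-Chiba band is applied: bouts are
short (tens of frames), so the full alignment polytope is affordable.
DTW is not a metric (no triangle inequality), which is why downstream
steps use exemplar-based clustering rather than geometric methods. The
compiled kernel is verified in the test suite against exhaustive
alignment-path enumeration on all pairs of sequences of length ≤ 5 over
a three-symbol alphabet.

Affinity propagation treats negated distances as similarities, with the
shared preference set to the median off-diagonal similarity (the common
default that yields a moderate cluster count), damping 0.9 and up to
1000 message-passing iterations; non-convergence is an error rather than
a silent partial result. The implementation is fully deterministic: a
tiny fixed tie-breaking offset replaces the random jitter usually used
against symmetric degeneracies, and an all-zero distance matrix is
short-circuited to a single cluster. Silhouette scores
`(b - a)/max(a, b)` validate partitions, with singleton clusters scored
0 and a single-cluster partition undefined.

A session's signature is its normalized cluster-ID frequency vector.
Cosine distances between signatures feed average-linkage hierarchical
clustering (exportable as Newick), and a Welch t-test compares
same-dog with different-dog session pairs. On synthetic cohorts where
each animal has its own motif bank, same-dog pairs come out
significantly closer — evidence the signature captures individuality
under the generator's assumptions, not proof it does so for real dogs.

The 2-D embedding of the bout distance matrix for figures is classical
metric multidimensional scaling (`stats::cmdscale`) on the precomputed
distances: deterministic, parameter-free, and sufficient for the
visual-separation role the embedding plays here.

## Stability analysis and modules

The largest Lyapunov exponent is estimated with Wolf's neighbor-tracking
algorithm on a delay embedding (m = 3, tau = 100 frames). A fiducial
point and its nearest neighbor evolve together until their separation
exceeds eps; the base-2 log of the divergence ratio is recorded, and a
replacement neighbor within eps is chosen minimizing the angle to the
evolved vector. The estimate is the mean recorded log-ratio over the M
replacement steps — bits per replacement step, not per unit time, which
follows the replacement-count normalization; a `per_iteration` mode
(replace after every sample step) gives bits per step, the convention
under which the fully chaotic logistic map `x <- 4x(1-x)` has exponent
exactly 1 bit. The test suite checks the estimator lands within 0.1 of
that value at n = 5000 and at or below 0.02 on a noise-free sinusoid.

Three numerical choices matter. First, eps = 0.16 is interpreted on the
per-window standardized series (unit variance): a fixed threshold in raw
cm would mean different things for a 5° and a 90° wag, and standardizing
makes the estimate invariant to affine rescaling; a raw-unit mode is
retained. Second, points closer than `eps/1000` to the fiducial are
excluded from neighbor choice: exactly periodic signals produce
float-level duplicate embedded points whose "divergence" is pure
round-off. Third, when no neighbor lies within eps, the nearest point is
used and the relaxation counted in a diagnostic attribute.

Profiles are computed per coordinate axis in 300-frame windows advanced
by 10 frames; windows touching masked frames are skipped. With m = 3 and
tau = 100, a 300-frame window yields only 100 embedded points — few, but
kept as the platform's configuration, with a warning when the count
drops below 50. The per-window sum of the three per-axis exponents is
the stability score; the session's 25th percentile of that score
(linear interpolation, R's type-7 quantile) is the stable/transient
threshold, with windows at or below it stable. Frames inherit the
majority class of covering windows (ties stable), and the percentile is
relative by construction: it always marks the chosen fraction of windows
stable regardless of absolute stability, which is why recovery fixtures
that are periodic by construction use a higher percentile (75) — under
the default 25 most genuinely stable wagging would be labelled
transient.

Bout runs are split spatially: consecutive bouts accumulate into a
segment while the body-frame tail position at the current bout's end
stays within 0.8 cm of the segment's start point; exceeding the gap, or
any temporal discontinuity between bouts, closes the segment. Stable
segments (majority stable frames) then pass a three-tier hierarchy:
DTW + affinity propagation over segment traces (micro-modules), the same
over micro-module exemplars (mini-modules), and k-means (50 restarts,
seeded) over PCA-reduced voxel occupancy histograms of the mini-module
exemplars, giving k stable modules (default k = 8) plus the pooled
transient module TM. Two design choices here are the package's own.
The voxel grid (default 100³, configurable; recovery tests use 20³) is
taken over a bounding box *shared* by all exemplars: per-segment
normalization would erase exactly the amplitude and position differences
that distinguish wagging styles. And the mini-module tier only runs when
there are at least 30 micro-modules: its purpose is scale reduction on
long recordings, and on small exemplar sets it merges aggressively
enough to starve the final k-means below k groups. Endpoint-anchored DTW
between multi-bout segments is dominated by bout-count differences
(aligning ten repetitions onto three costs several whole bouts
regardless of shape), so motif identity is best recovered when segments
hold comparable bout counts — the recovery fixture fixes run length at
four bouts for this reason, and real recordings with very uneven segment
durations should be interpreted with this confound in mind.

Transitions between consecutive segment labels give a first-order
transition graph (row-stochastic outgoing probabilities, occupancy = time
share), and the frame-level module track can be sliced into 30-s epochs
as an ethogram.

## The synthetic generator

`simulate_session()` emulates the structure of a recorded session: a
rigid 30 cm spine with slow heading change and positional drift, a tail
tip with 20 cm ground-plane reach swinging around a ±45° side centre,
bout waveforms drawn from a per-animal bank of motifs (1–3 harmonics of
a 2–6 Hz base frequency, amplitudes 12–24°, motif-specific vertical
oscillation), contiguous still blocks (~2 s each) with short cosine
tapers, and isotropic Gaussian tracking noise (0.2 cm default) plus
occasional sub-0.9 likelihood frames. Motifs occur in runs (geometric,
mean 8 bouts, or fixed length for recovery fixtures); each bout's side
is an independent Bernoulli draw with right probability `bias`, and a
right bout is the exact mirror image of the left bout of the same motif.
That mirror construction is deliberate: it makes the realized fraction
of right-sided extrema a binomial proportion converging to `bias`, and
makes left/right exactly exchangeable, which the mirror-symmetry tests
exploit. Cohorts split one master seed into per-animal and per-day
streams, so each animal keeps its motif bank (its fingerprint) across
days while days stay independent, and the lateral bias interpolates
linearly from the first to the last day.

The generator is a model of convenience, and passing tests on it shows
the *pipeline* recovers what the generator planted — not that real dogs
behave this way. Known departures from real data: wagging never crosses
the midline within a bout (real dogs' does); side centres and tail
geometry are fixed rather than postural; stillness is exactly zero
motion plus noise; there is no locomotion, no camera model, and no
correlated tracking error. Angle-level shortcuts
(`simulate_angle_session()`) are used for the large statistical
calibrations, where only the angle trace matters.

Problem sizes in the test suite are chosen to exercise each property at
desk scale: 10–180 s sessions, cohorts of 10 animals × 3 days at 60 s
for the bias-drift and null-calibration studies (200 null replicates, 20
drift replicates), a 90 s three-motif session for clustering recovery,
and 10-s sessions for the 30-session fingerprint fixture.

## Limitations

The package consumes already-reconstructed 3D trajectories; camera
calibration, triangulation and pose-estimation training are out of
scope, as is any claim about neural attractors behind the
stable/transient decomposition. Reported headline quantities from the
original recordings (bout counts, cluster counts, silhouette fractions,
absolute LLE thresholds) are data-dependent and not reproducible without
those recordings; the package reproduces the *procedures* and verifies
them on analytic cases and synthetic ground truth. HDF5 keypoint tables
are not read directly (no HDF5 binding among the package's
dependencies); the two CSV dialects cover the common export paths.
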