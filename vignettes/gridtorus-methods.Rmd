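---
title: "Methods: path integration, remapping, and toroidal population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path integration, remapping, and toroidal population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Grid cells of the medial entorhinal cortex fire on hexagonal spatial
lattices and are widely believed to support path integration — updating a
position estimate from self-motion alone. Hippocampal place cells encode
location and environment identity, and *globally remap* (redraw their
firing fields independently) between environments. `gridtorus` implements
a complete in-silico version of the experiment that links the two: a
recurrent network is trained to path integrate against place-cell targets
in several environments related by global remapping, and its learned units
are then characterised with the single-cell and population statistics used
in rodent electrophysiology — grid scores, spacing, phase and orientation
shifts, rotational-symmetry clustering, persistent homology of population
activity, and causal pruning.

A synthetic ideal-grid-cell generator provides analytic ground truth for
every estimator, so the entire analysis chain is testable without any
trained network.

# Components and their models

## Foraging trajectories

A random walker forages in a square box of side 2.2 (arbitrary box units)
centered at the origin. Speeds are Rayleigh with scale $b = 2\cdot0.13\pi$
per second, headings follow a Gaussian random walk with rotation-rate SD
$\sigma = 2\cdot5.76$ rad/s, and each step integrates velocity over
$\tau = 0.02$ s; trajectories are $T = 20$ steps. We treat $b$ and
$\sigma$ as per-second rates, so the per-step heading increment SD is
$\sigma\tau$ and the per-step displacement is $\tau \cdot \text{speed}$ —
the convention of the continuous-time model this walker emulates. The
radian (not degree) reading of $\sigma$ is adopted; it is configurable.

Walls are soft: within a 0.03 margin, an agent heading outward has the
outward velocity component reflected and its speed reduced by a factor of
0.25 (the reflect-and-slow rule is our concretisation of "soft
boundaries"; the hard containment clamp afterwards is what tests rely on).
The stored velocity is the effective, post-boundary-rule velocity, so
$x_t = x_{t-1} + \tau v_t$ holds exactly for every stored step, which
keeps the velocity the network sees consistent with the positions used to
build its targets.

## Place-cell code

Each place cell is a difference of two softmaxes over squared distances to
its center (widths $s_1 = 0.12$, $s_2 = 2s_1$), shifted and normalised per
location to be nonnegative and sum to one. The shift rule — add the
absolute value of the minimum entry, divide by the sum — is the only
location-wise rule satisfying both stated properties for a difference of
softmaxes, whose raw entries sum to zero. Decoding takes the unweighted
mean of the centers of the three most active cells, with rank-3 ties
broken toward the lowest cell index.

At full scale ($N_p = 512$) the code's intrinsic (baseline) decoding
error is about 0.04 box units. At desk scale we keep $N_p = 64$ but widen
tuning to $s_1 = 0.12\sqrt{512/N_p} \approx 0.34$: this preserves the
expected number of cells within a tuning radius, which is what makes the
top-3 decoder meaningful. With the full-scale width and only 64 cells the
second and third most active cells are essentially arbitrary and the
baseline error rises from ~0.14 to ~0.65, destroying the training signal.
This width scaling is a deliberate desk-scaling choice, made on geometric
grounds.

## The network

The model is bias-free throughout: $g_0 = W_e p_0$ (linear; no
rectification on the initial state), $g_t = \mathrm{ReLU}(W_g g_{t-1} +
W_v v_t)$, $\hat p_t = \mathrm{softmax}(W_d g_t)$, with Xavier-uniform
initialisation at unity gain. The loss is the time-averaged cross-entropy
between target and predicted place-cell activity **plus** $\lambda
\lVert W_g\rVert_F^2$ with $\lambda = 10^{-4}$: a subtracted penalty, as a
literal reading of the printed loss would have it, would *reward* large
recurrent weights and contradicts its own description as a penalty, so the
penalty is added. Training uses Adam (default moments, learning rate
$10^{-4}$) on minibatches of 200 trajectories; under the multi-environment
schedule every minibatch carries an equal share of each environment, under
the continual schedule environments are presented in blocks.
Backpropagation runs through all 20 steps (no truncation). The forward
pass and the backward/Adam step are implemented in RcppArmadillo; an R
reference recurrence and a central-difference check pin the gradient to
1e-10.

The KL divergence (whose optimum is zero regardless of label entropy) is
the convergence monitor; the package logs minibatch KL and, on fixed
held-out evaluation batches, per-environment KL and decoding error at the
final timestep. Desk-scale training (256 units, 64 place cells, 3
environments, 2000 minibatches, ~4 minutes on one CPU) reproduces the
qualitative training phenomenology: an initial drop and subsequent rise of
the recurrent L2 norm accompanying the KL decrease, familiar-environment
decoding error falling well below the untrained level, and a held-out
novel environment remaining at the untrained level.

## Synthetic grid modules

An ideal grid cell is the rectified sum of three plane waves with unit
wave vectors at 0°/60°/120° (rotated by the pattern orientation), spatial
frequency $f = 1/0.838$ by default, and a 2-D phase. The real-space peak
lattice of this construction has lattice constant $2/(\sqrt3 f)$ — note
this differs from the reciprocal wavelength $1/f$; both conventions appear
in the literature, and the package reports the lattice constant (what a
peak-distance estimator actually measures) while exposing $f$ itself.
Module phases are sampled uniformly over the fundamental parallelogram of
the lattice (an equal-area fundamental domain, equivalent to the
Wigner–Seitz hexagon for uniform sampling). Remapping scenarios: identity,
coherent phase shift (default $(-0.2,-0.2)$), coherent rotation (default
−5°), incoherent per-cell phase resampling, and incoherent per-cell
rotation.

## Spatial statistics

Ratemaps average unit activity per spatial bin (64×64 default; 32×32 for
clustering inputs, using only the final ten timesteps to avoid transient
initial states); unvisited bins are missing, never zero.
Autocorrelograms are masked Pearson correlations at every integer lag,
computed by FFT with per-lag overlap correction; lags with fewer than 20
overlapping bins are dropped. The grid score correlates an
annulus-masked autocorrelogram with its 30/60/90/120/150° rotations and
takes min(60°,120°) − max(30°,90°,150°), maximised over a sweep of
annulus radii (ideal grids score above 1, stripes below 0.3). Phase
shifts read the cross-correlogram's local peak nearest the center (3×3
local maxima after 1-bin Gaussian smoothing used for localisation only);
orientation shifts take the argmax over 1° rotations of the correlation
between autocorrelogram disks, with ties inside a 1e-4 correlation band —
the interpolation noise floor between hexagonally equivalent angles —
resolved toward the smallest rotation. Spacing sorts autocorrelogram peak
distances and takes the median of the isodistant set before the first
jump exceeding mean + 2 SD of the consecutive differences. Orientation
shifts wrap to $[-15, 15)$ via a 15°-shift, modulo-30, recentre rule.
Coherence of a shift distribution is quantified by circular variance
(orientation: period 30°; phase: per-axis on fractional lattice
coordinates), with coherent scenarios near 0 and incoherent ones near 1.

## Unit-type clustering

Each unit's rotational symmetry fingerprint is the vector of Pearson
correlations between the central disk of its ratemap's autocorrelogram
and rotated copies (360 angles). The correlogram — not the raw ratemap —
is rotated because the correlogram is phase-invariant and centered; on raw
ratemaps the rotation center is arbitrary relative to the pattern and the
symmetry signatures wash out (planted grid and band families become
inseparable). On fingerprints, hexagonal units peak at multiples of 60°,
band (stripe) units only at 180° (every correlogram is centrally
symmetric), and radially symmetric blobs correlate highly at all angles —
which is exactly the signature triple the clustering relies on.

Units with zero activity everywhere are excluded first; then units whose
mean rate exceeds the 99.75th percentile of the remaining population
(high-rate, weakly tuned units). Fingerprints are embedded into two
principal components and clustered with DBSCAN (min_samples = 30 at full
scale; the neighbourhood radius defaults to the 0.75 quantile of
min_samples-th-neighbour distances). No UMAP implementation exists in
this package's dependency set; since all quantitative claims are made on
the fingerprints, PCA coordinates and persistence diagrams — never on
embedding coordinates — a linear embedding serves the same purpose behind
the same interface, and `embed3d()` similarly provides a linear
3-D view for visual inspection only. Band-like clusters (the torus
ensemble candidates) are identified automatically as clusters whose mean
fingerprint has its only non-trivial peak at 180°, with a manual override;
K-means (k = 3) on the rows of the pairwise autocorrelogram-correlation
matrix then splits the ensemble into its three band orientations. The
k = 3 choice presumes three orientations roughly 60° apart; with a
different planted structure the split degrades visibly (silhouette drop),
which is documented behaviour, not a failure of the estimator.

## Population topology

Population activity over space — one point per spatial bin, one dimension
per unit — is projected onto six principal components. Fuzzy-neighbourhood
downsampling assigns memberships $a_{ij} = e^{-d_{ij}/\sigma_i}$ (cosine
distance, $\sigma_i$ bisected so that $\sum_j a_{ij} = \log_2 k$),
symmetrises $m_{ij} = a_{ij} + a_{ji} - a_{ij}a_{ji}$, and keeps the
points with the strongest mean membership, protecting the persistence
computation from outliers. On *noise-free* synthetic clouds this
protection is unnecessary and, at aggressive trimming fractions, harmful:
density ranking removes whole systematically-sparse regions of the ReLU
embedding and punctures the manifold (observably: a third long H1 bar
appears and H2 vanishes). Trims up to ~15% preserve the torus; the
package therefore trims ~5–10% for clean synthetic controls and reserves
the full-scale keep count (3000 of 4096) for noisy trained-network
clouds, where outliers are real.

Vietoris–Rips persistence in dimensions 0–2 over GF(47) is computed on
`n_landmarks` greedy-permutation landmarks (300 at desk scale, 500 at
full scale). The boundary-matrix reduction processes dimensions from the
top down with the twist (clearing) optimisation; simplices are enumerated
explicitly with neighbour bitsets. The filtration is cut at three times
the longest minimum-spanning-tree edge — a few multiples of the
connectivity scale — capped by the enclosing radius and by the distance
giving mean landmark degree 80 (a complexity bound); classes alive at the
cutoff are reported as essential and count as maximally persistent. The
reduction is validated end-to-end against an independent brute-force
full-matrix reduction on small random clouds.

A diagram is called a torus when its long-lived Betti numbers are
(1, 2, 1). Dimension 0 counts essential bars (components at the cutoff).
Dimensions 1–2 use a persistence-gap rule: bars below 10% of the cutoff
are noise; among the rest, the count is placed at the largest
multiplicative gap between consecutive sorted persistences, required to
exceed 1.8. The gap factor and floor were calibrated once on the canonical
controls — noisy circle (1,1,0), flat torus (1,2,1), Gaussian blob
(1,0,0), sphere (1,0,1), and the synthetic module cloud (1,2,1) — and
then frozen. The median-multiple rule one might first reach for fails on
real spectra: H1 noise is heavy-tailed, and greedy landmarks make *all*
H0 bars comparable multiples of the median.

Ideal-module controls behave as the geometry dictates: identity, coherent
phase, coherent rotation, and incoherent phase remapping all preserve the
population torus (phases live on the same lattice torus), whereas
incoherent per-cell *rotation* destroys the shared lattice and with it
the common toroidal structure — the detector correctly reports no torus
there, which is a property of the construction, not an estimator failure.

## Pruning

A unit is inactivated by zeroing its incoming recurrent and velocity
rows; with no bias terms its recurrent activity is identically zero from
the first step (the encoder still sets its initial state, which the
first recurrent update discards). Pruning curves draw increments of 10
units without replacement (cumulatively within a repeat) from a target
set — all units, the top cumulative-grid-score ensemble, or an
identified cluster ensemble — and evaluate the decoding error at timestep
20 on fresh 200-trajectory batches split equally across the familiar
environments, aggregated over repeats as median ± MAD. Time-course
variants fix 100 pruned units and sweep timesteps. Desk-scale comparisons
use 8–10 repeats (30 at full scale).

## Overlap statistic

The probability that the grid-score-ranked and torus ensembles (each 604
of 4096 units) share at most 56 members is computed as an exact Binomial
tail $P(X \le 56)$, $X \sim \mathrm{Bin}(604, 604/4096)$, by summation of
the mass function — about $10^{-4}$, i.e. the two ensembles overlap far
less than chance. The hypergeometric (without-replacement) tail is
reported alongside as a sensitivity check; the Binomial form is the
primary statistic by construction.

# Problem sizes

Desk-scale defaults — 256 recurrent units, 64 place cells (width-scaled),
2000 minibatches, 1000-trajectory ratemaps at 32×32, 300 landmarks,
repeats 8–10 — were chosen so that a full pipeline run and the entire
test suite complete on a single CPU in well under an hour while still
exhibiting every qualitative phenomenon the full-scale study reports.
Full-scale settings (4096 units, 512 place cells, $10^5$ minibatches per
environment, 64×64 ratemaps from 5000 trajectories, 500 landmarks,
30 repeats) are available via `experiment_config("paper")`.

# Known limitations

* At 2000 desk minibatches the network is early in training: spatial
  tuning is present but hexagonal patterning is weak (best grid scores
  ~0.9), so desk-scale cluster structure is coarser than the 18 unit
  types the full-scale regime develops.
* The walker's soft-boundary rule is one concretisation of wall
  avoidance; motion statistics within the margin differ from free space,
  and tests of the speed/heading laws exclude the wall band.
* The synthetic generator produces noise-free cells; it validates
  estimator correctness, not robustness to biological variability.
* Orientation estimates are identifiable only modulo the pattern's 60°
  symmetry; the smallest-rotation tie-break makes the conventional choice
  and the wrapped (mod-30) statistics are the robust summaries.
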