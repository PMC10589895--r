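# gridtorus

Simulation and analysis of grid-cell remapping and toroidal population
structure in recurrent networks trained to path integrate.

## The problem

Grid cells fire on hexagonal spatial lattices and are thought to support
path integration; place cells encode location and environment identity and
*globally remap* — redraw their firing fields independently — between
environments. Whether grid-cell remapping follows from place-cell
remapping, and which learned cell types actually carry path integration,
can be studied in silico: train a recurrent network to track its position
(in a place-cell basis) along simulated foraging trajectories in several
environments related by global remapping, then characterise its units
with the statistics used in rodent electrophysiology.

`gridtorus` implements that pipeline end to end, for computational
neuroscientists who want a tested, self-contained R implementation:

* **Trajectories** — 2D random walks in a 2.2×2.2 soft-walled box with
  Rayleigh speeds (scale b = 2·0.13π) and Gaussian heading increments
  (σ = 2·5.76 rad/s, τ = 0.02 s per step).
* **Place-cell code** — difference-of-softmax tuning curves
  (s₁ = 0.12, s₂ = 2s₁), shift-normalised to probability vectors;
  decoding by the unweighted mean of the top-3 cell centers; global
  remapping by uniform center resampling.
* **Network** — g₀ = Wₑp₀, gₜ = ReLU(W_g gₜ₋₁ + W_v vₜ),
  p̂ₜ = softmax(W_d gₜ), no biases, Xavier-uniform init; loss =
  time-averaged cross-entropy + λ‖W_g‖²_F (λ = 10⁻⁴); Adam, lr 10⁻⁴,
  minibatches of 200 trajectories; multi-environment or continual
  schedules (BPTT core in RcppArmadillo).
* **Synthetic grid modules** — ideal three-plane-wave cells
  (f = 1/0.838) with shared orientation and uniform phases, plus five
  remapping scenarios (coherent/incoherent phase and orientation shifts);
  analytic ground truth for every estimator.
* **Spatial statistics** — ratemaps, masked FFT autocorrelograms, grid
  score, grid spacing (isodistant-peak rule), phase shift (nearest
  cross-correlogram peak), orientation shift (1° rotation argmax, 30°
  wrapping), Gaussian-KDE shift densities, circular-variance coherence.
* **Ensembles & topology** — rotational symmetry fingerprints, DBSCAN
  clustering, band-cluster identification and K-means torus-ensemble
  refinement, PCA projection, fuzzy-membership downsampling, and
  Vietoris–Rips persistent homology (dims 0–2 over GF(47), authored in
  C++) with a Betti-signature torus detector: a 2-torus gives (1, 2, 1).
* **Pruning** — unit inactivation by zeroing incoming weights, grid-score
  and band-signature ensemble selection, pruning curves (median ± MAD)
  and time courses.
* **Statistics** — exact Binomial tail for ensemble overlaps, with the
  hypergeometric alternative as a sensitivity check.

## Worked example

Ideal grid-cell module, coherently reoriented by −5°, and the estimators
that recover it:

```r
library(gridtorus)

m   <- grid_module(5, seed = 1)          # 5 cells, f = 1/0.838, theta = 0
rm0 <- module_ratemaps(m, n_bins = 64)

m5  <- apply_remap_scenario(m, "coherent_rotation", angle = -5)
rm5 <- module_ratemaps(m5, n_bins = 64)

sapply(1:5, function(i) orientation_shift(rm0[,,i], rm5[,,i]))
#> [1] -5 -5 -5 -5 -5

grid_score(rm0[,,1])
#> [1] 1.773976            # hexagonal patterns score > 1
grid_spacing(rm0[,,1])
#> [1] 0.9551055           # analytic lattice constant 2/(sqrt(3) f) = 0.968

overlap_tail_probability(4096, 604, 604, 56)$p_binomial
#> [1] 3.910468e-05        # two 604-unit ensembles sharing <= 56 of 4096
```

The first number says every cell's orientation shift is recovered exactly
at 1° resolution; the grid score and spacing confirm the hexagonal
geometry (spacing within one 0.034-unit ratemap bin of the analytic
value); the last is the exact Binomial tail probability showing that a
56-unit overlap between two 604-unit ensembles is far below chance —
the grid-score-ranked and toroidal ensembles are largely distinct
populations.

Training and analysing a network end to end:

```r
res <- run_experiment(experiment_config("desk"), out_dir = "run1")
res$summary   # final KL, decoding errors, cluster count, torus verdict, ...
```

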