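---
title: "Methods: forward model, simulation, network and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward model, simulation, network and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the modeling choices behind `esicnn`: what is
computed, with which parameters and units, and where the implementation
deliberately simplifies. Code chunks are illustrative and not evaluated when
the vignette is built (several of them train a network).

## 1. The toy head model

EEG source imaging estimates a distributed current-dipole field from scalp
potentials. The package uses a deliberately small, fully analytic head model
so that every quantity can be verified against a closed form.

**Source space.** Each cortical hemisphere is modeled as a spherical cap
obtained by subdividing an icosahedron `n` times, giving `10 * 4^n + 2`
vertices per hemisphere (`5124` dipoles in total at level 4). The subdivided
sphere is mapped onto a half-sphere cap by halving each vertex's polar angle
about the `+x` axis (after a small fixed rotation that keeps no vertex at the
antipode), which is injective and keeps the triangulation intact; the two
caps are mirrored across the midline so hemispheres never overlap. Vertices
sit on a sphere of radius 79 mm; each carries one dipole oriented along the
outward surface normal, with moments in nanoampere-meters (nAm).

```{r}
library(esicnn)
space <- build_source_space(4)   # 5124 dipoles
montage <- build_montage("standard31")
```

**Electrodes.** 31 electrodes of the 10-20 system on a scalp sphere of radius
92 mm, rotated so `Cz` is exactly at the apex. Positions are shipped as a
plain-text `.sfp` file.

**Leadfield.** The gain of a unit dipole at `r_d` with orientation `n_d` at
electrode `r_e` is the infinite homogeneous-medium potential

```
phi = (1 / (4 pi sigma)) * n_d . (r_e - r_d) / |r_e - r_d|^3
```

with conductivity `sigma = 0.3` S/m. Columns are common-average referenced,
matching the referencing applied to data. This kernel ignores the skull's
insulating layers, so absolute amplitudes are not physiological; all
geometric structure that matters here (depth attenuation, spatial mixing,
reference coupling) is preserved, and the computation is exactly testable
against pointwise evaluation.

**Inverse-crime guard.** Evaluation data are never generated from the model
used for inversion. `perturb_to_agm()` derives an *alternative generative
model* (AGM) by jittering each electrode coordinate with independent Gaussian
noise (SD 2 mm), changing conductivity to 0.332 S/m, and moving the sources
to a one-level-finer mesh (level 4 vs level 3 by default). Ground truth
simulated on the AGM is transferred to the inversion space by an unweighted
5-nearest-neighbor average, rescaled so total dipole energy is conserved
(`map_sources()`, exact to better than 1e-9).

## 2. ERP simulation

`sample_source_config()` draws 1-5 dipole clusters (evaluation presets: 1, or
1-10). A cluster is grown by breadth-first search from a seed vertex to
neighborhood order `s` in 2-5 (all vertices within `s - 1` adjacency hops);
moments decay with Euclidean distance `d` from the seed as a Gaussian,
`exp(-d^2 / (2 sigma^2))` with `sigma` set to half the cluster radius; the
seed keeps the full drawn moment of 5-10 nAm. Overlapping clusters are
summed, keeping the forward map linear.

The source waveform is a 5 Hz half-sine (100 ms wide, 10 nonzero samples at
`fs` = 100 Hz) peaking at sample 50 of a 100-sample epoch, scaled to unit
maximum. Noise segments mix channel-independent `1/f`-shaped spectra through
a spatial Gaussian mixing kernel (scale 50 mm), then low-pass at 30 Hz;
each trial adds one segment scaled so the ratio of global field power (GFP;
the across-channel standard deviation) of signal to noise at the waveform
peak equals the target single-trial SNR of 1. Trials are baseline-corrected
over the first 100 ms and common-average referenced; 20 trials average into
one ERP, so the expected ERP SNR is `sqrt(20) ~ 4.5` (the Monte-Carlo
acceptance band is 3.5-5.5). Only the peak-latency scalp vector enters the
network.

The noise generator is a stand-in for real resting-state EEG: it reproduces
the `1/f` spectral envelope and distance-dependent channel correlation but
not alpha rhythms, artifacts, or non-stationarity. Results should be read as
a clean-world comparison of inversion methods, not as a performance claim
for recorded EEG.

**Eccentricity caveat.** Because all sources lie on a spherical shell of
fixed radius, the recorded eccentricity (distance from the head center to
the cluster seed) is degenerate — approximately 79 mm for every source. The
grouping by eccentricity kept in the evaluation reports is therefore
uninformative in this toy geometry and only becomes meaningful with a
volumetric or folded-cortex source space.

## 3. The network

The peak scalp vector is rendered as a 7 x 11 pixel image by azimuthal
equidistant projection about the vertex followed by Gaussian radial-basis
interpolation (plus a constant term, so constants are reproduced exactly);
the whole map is a fixed 77 x 31 linear operator, so the image adds no
information. Inputs are normalized by their maximum absolute value, making
predictions exactly scale-invariant.

Architecture (implemented from scratch in base R, see the design notes):

* conv layer: 8 filters, 3 x 3, same padding, batch norm, ReLU;
* flatten to `8 * 7 * 11 = 616`;
* fully connected 616 -> 512, batch norm, ReLU;
* fully connected 512 -> p, ReLU (nonnegative moment maps).

Batch normalization keeps running statistics (momentum 0.9) so single-sample
inference is well defined. Weights are He-initialized; optimization is ADAM
(learning rate 1e-3, beta 0.9/0.999) with bias correction.

**Loss.** Training minimizes a weighted Hausdorff distance between the
prediction `q` (normalized to unit maximum, with the normalizer treated as a
constant during backpropagation) and the set `Y` of active true vertices:

```
L = 0.5 * [ sum_x q_x d(x, Y) / (sum_x q_x + eps)
          + mean_y M_alpha_x( q_x d(x, y) + (1 - q_x) d_max ) ]
```

where `d(x, Y)` is the distance to the nearest target vertex, `M_alpha` is
the generalized mean with `alpha = -1` (a soft minimum), and `d_max` is a
fixed upper bound on mesh distances (twice the maximal distance from the
mesh centroid — a bound, not the exact diameter, which only shifts the
inactive-vertex constant). The first term pulls predicted mass onto the
target; the second term forces every target vertex to be covered by nearby
mass. The loss and its exact gradient are computed in C++ against a
precomputed mesh distance matrix; entries that are exactly zero contribute a
closed-form constant and receive no gradient, which is exact because zero
outputs come out of the final ReLU, whose backward pass masks those entries
anyway.

Since predictions are normalized, absolute amplitude is recovered afterwards
by a single scalar: `rescale_prediction()` minimizes the squared residual
between the forward-projected prediction and the observed scalp vector over
one scale factor using Brent's method. The closed form `<x_hat, x> /
||x_hat||^2` exists and the Brent solution agrees with it to numerical
precision; both are exposed, and their agreement is one of the acceptance
oracles.

```{r}
gm <- compute_leadfield(build_source_space(3), montage)
train <- generate_dataset(gm, 5000, "train", seed = 1)
net <- train_network(train, gm, train_config(epochs = 50, seed = 1))
```

## 4. Baselines

`minimum_norm()` implements the classical L2 estimate
`W = K' (K K' + lambda2 tr(K K')/q I)^-1`. `eloreta()` iterates the exact
low-resolution tomography weight fixed point `w_d <- sqrt(k_d' C^-1 k_d)`
until the relative weight change falls below 1e-6, then forms
`W^-1 K' C^-1`. The default `lambda2 = 1/9` corresponds to an assumed
amplitude SNR of 3 under the conventional reading of the regularization
fraction; eLORETA's zero-localization-error property on noiseless single
dipoles is insensitive to this choice and is asserted in the test suite.

## 5. Evaluation

All methods are scored on the same records:

* **AUC (two-sided).** ROC area for separating active from inactive
  vertices, computed twice: *close* negatives are subsampled from the 20% of
  inactive vertices nearest to any active vertex (sensitive to blur), *far*
  negatives from the farthest 50% (sensitive to spurious distant activity);
  each pool is subsampled to the number of positives, 10 draws are averaged,
  and the overall AUC is the mean of both sides.
* **Maxima and localization.** `find_maxima()` takes strict local maxima,
  discards candidates whose neighborhood mean is below 20% of the global
  maximum, and applies 30 mm non-maximum suppression. Estimated maxima
  within 30 mm of a true cluster center are *found*; farther estimated
  maxima are *ghosts*; unmatched true centers are *missed*. MLE is the mean
  distance from true centers to their nearest estimated maximum.
* **MSE / nMSE** on the full moment vectors, the latter after unit-maximum
  normalization of both.
* **Statistics.** Paired sign-flip permutation tests (two-sided, add-one
  p-value) and Cohen's d with pooled SD.

`run_benchmark()` wires everything together (GM + AGM, train/eval
simulation, training, all three inverters, per-set reports, markdown
summary) and asserts a fingerprint-based train/eval leakage check.

## 6. Desk-scale choices and numerical notes

* Problem sizes (level-3 GM with 1284 dipoles, 5000 training samples, 50
  epochs, 31 electrodes) are chosen so the full pipeline runs on one CPU
  core in minutes. They are roughly a factor 4 below the reference design in
  dipole count and a factor 20 in training-set size, which costs accuracy;
  the scaled-down acceptance threshold (overall single-source AUC >= 80%)
  accounts for this.
* The waveform, leadfield, cap mapping, and generalized-mean loss all have
  closed forms that the test suite compares against independent
  implementations (pointwise dipole potentials, exhaustive ROC pair
  counting, brute-force kNN, BFS region growth).
* Derived seeds: every stochastic stage receives its own seed through a
  fixed affine map of the run seed, so any stage can be reproduced in
  isolation and package functions never disturb the caller's RNG stream.
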