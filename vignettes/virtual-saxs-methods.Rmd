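---
title: "Virtual SAXS profiles and fast shape retrieval: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual SAXS profiles and fast shape retrieval: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsaxs)
```

## The problem

An X-ray free-electron laser delivers femtosecond pulses bright enough to
record a diffraction pattern from a single particle before it is destroyed.
Each recorded frame samples the particle's reciprocal-space intensity on one
Ewald-sphere cut at an unknown orientation. Full 3D merging requires
orientation recovery, which is slow; but if the orientations are uniformly
random, simply *summing* the azimuthally integrated 1D profiles of many
frames converges to the spherically averaged intensity — the same observable
a solution SAXS experiment measures. That "virtual SAXS profile" can then be
fed to fast SAXS model-retrieval machinery, giving near-real-time structural
feedback during a beam time.

`vsaxs` implements this pipeline end to end: a synthetic-data generator, beam
center refinement by Friedel symmetry, azimuthal integration and merging with
convergence monitoring, and a database search over size-rescalable shape
models ranked by a least-squares-scaled chi score.

## The synthetic-data generator

All development and testing runs on simulated data, so the generator is
first-class code, not a fixture. It emulates:

* **monodisperse particles** represented as bead models (identical spheres of
  radius $a$ on a cubic lattice filling the requested solid, weights
  optional);
* **uniform random orientations**, sampled as unit quaternions by the
  three-uniform-variate construction;
* **Ewald-sphere sampling**: pixel $(i, j)$ maps to
  $\mathbf{q} = k(\hat{s} - \hat{z})$ with $k = 2\pi/\lambda$, so
  $|q| = (4\pi/\lambda)\sin(\alpha/2)$ for full scattering angle $\alpha$;
* **coherent single-particle intensity**
  $I(\mathbf{q}) = F\,\Phi^2(qa)\,\bigl|\sum_j w_j e^{i\mathbf{q}\cdot R\mathbf{x}_j}\bigr|^2 / (\sum_j w_j)^2$,
  where $\Phi$ is the normalized uniform-sphere amplitude and $F$ the
  expected photon count at forward scattering (so the $q=0$ pixel counts $F$
  photons in expectation);
* **Poisson photon noise**, applied after masking;
* **beam-center jitter**, uniform within a per-axis half-width in pixels;
* **false positives**: with a set probability a frame is generated from a
  junk model instead of the sample. The default junk model is an irregular
  four-lobed aggregate at ten times the sample fluence — non-sample
  scatterers (droplets, aggregates) are larger and brighter than the
  particle, and their anisotropy makes each false-positive frame different,
  which is what shows up as fluctuations in the convergence trace. A smooth,
  equally bright decoy would be nearly invisible there.

It deliberately does **not** model jet/solvent background, detector panel
gaps, gain maps, polarization or solid-angle corrections, or shot-to-shot
fluence variation (the fluence is constant per run by default; the parameter
is per-shot if needed). Tests passing on this generator therefore demonstrate
the statistical logic of the pipeline, not robustness to instrument
systematics.

The direct bead-sum structure factor (no FFT) is exact on the Ewald sphere
and fast enough at the problem sizes used here (a few thousand beads times
a few thousand pixels, in compiled code).

## Beam-center refinement

For a real-valued scattering density, $I(\mathbf{q}) = I(-\mathbf{q})$
(Friedel symmetry). Near the reciprocal-space origin the Ewald sphere is
nearly flat, so the detector-plane reflection of a pixel through the beam
center is a good stand-in for $-\mathbf{q}$. The *flat region* is defined by
a fractional departure of the sphere from its tangent plane,
$1 - \cos\alpha \le 1\%$, equivalent to a half-angle cutoff
$\arccos(0.99)/2 = 0.0708$ rad.

The center is refined by an exhaustive grid search (default $\pm 5$ px in
1 px steps) minimizing the mean over flat-region Friedel pairs of
$(I_p - I_{p'})^2 / \max(I_p + I_{p'}, 1)$. The denominator is the Poisson
variance of the pair difference, so bright pixels do not dominate; the floor
of one count keeps empty pairs finite. The score consequently *scales*
linearly with a global intensity rescaling — what is invariant is the
location of its minimum, which is all the refinement uses. Partners falling
off-detector or on masked pixels are skipped; ties break toward the initial
center, then lexicographically. A second pass at a quarter step is available
but off by default: the noiseless recovery is already exact at integer
shifts, and sub-pixel refinement buys little against Poisson noise at these
count levels.

## Azimuthal integration and merging

Each centered frame is reduced to an "intensity profile" on linear, half-open
$q$ bins: the bin value is the **mean** of its pixel counts (the standard
estimator of the azimuthally averaged intensity, comparable across masks and
detector coverage), with $\sigma = \sqrt{\sum \text{counts}}/n_{\rm pix}$
from Poisson statistics. Summing bin totals times pixel counts reproduces the
frame's total counts exactly.

Merging *sums* per-bin intensities over frames (uncertainties in
quadrature), matching the physical picture of accumulating photons; no
per-shot normalization is applied. The merge is associative, so partial
merges can be combined freely. Empty bins stay empty and are excluded from
all fits and correlations.

**Convergence monitoring.** The Pearson correlation of the cumulative
profile with a reference (by default the full-set merge) is recorded as
frames accumulate. On linear intensities this correlation saturates
immediately — the forward-scattering peak spans orders of magnitude and any
single frame already gets it right — so the trace correlates
**log-intensities** by default, which weights the fringe structure where
orientational convergence actually happens. A split-half consistency check
(random equal partition, merge each half, correlate) is also provided.

## Model profiles: the Debye formula

Shape models are bead models; their spherically averaged intensity is
computed with the Debye formula
$$ I(q) = \Phi^2(qa) \sum_{i,j} w_i w_j \,\frac{\sin(q r_{ij})}{q r_{ij}}, $$
exact pair sums up to 2000 beads and a 1000-bin pair-distance histogram
above (agreeing to well under 1% away from the curve's zeros, at O(bins)
memory). The exact quantity is a spherical average of $|F|^2$ and hence
non-negative; the histogram approximation's tiny negative excursions near
deep minima are clipped at zero. An independent brute-force oracle — the
mean of the coherent intensity over Fibonacci-sphere directions — is used in
tests to cross-check the Debye route.

**Conventions for lattice models.** A lattice-discretized solid occupies
volume $n_{\rm beads}\,s^3$ for spacing $s$; its size is therefore measured
by the *volume-equivalent radius* $s\,(3n/4\pi)^{1/3}$, and analytic-limit
comparisons (solid-sphere curve, first minimum at $qR = 4.4934$, Guinier
$R_g = R\sqrt{3/5}$) are made at that radius. Relative-error comparisons
against reference curves are evaluated where the normalized curve is at
least $10^{-2}$ of its forward value: at the zeros of an oscillating
profile, relative error is ill-posed and any discretization produces large
excursions of no physical consequence.

**Guinier analysis** fits $\ln I$ against $q^2$ iteratively, restricting to
$qR_g \le 1.3$; when at least 8 points are available a $q^4$ term is included
and the slope read from the $q^2$ coefficient, which removes the percent-level
bias the pure Guinier form accumulates toward the end of its validity range.

## The shape database: size as a free parameter

Each model is recentered, scaled to unit *nominal radius* (the bounding
sphere about the centroid — the bead farthest from the centroid plus the
bead radius), and stored as a dimensionless profile $I_{\rm ref}(s)$ on a
shared grid of $s = qR$, normalized to $I_{\rm ref}(0) = 1$ (512 points,
$s_{\max} = 50$, comfortably past the fifth solid-sphere minimum). Because a
uniform rescaling of the model only rescales the argument,
$I(q; r) = I_{\rm ref}(qr)$: evaluating any database model at any trial
radius is a single interpolation, which is what makes the radius a cheap
extra search dimension. Interpolation is linear in $(s, \log I)$ to preserve
deep minima, falling back to linear intensity when a stored profile touches
zero. The bounding-sphere radius convention is a choice — other radius
conventions (volume-equivalent, $D_{\max}/2$, $R_g$-derived) differ by a few
percent for compact shapes, and users supplying a radius guess should know
which convention they are matching.

## Retrieval: chi score and golden-section radius search

Agreement between the experimental profile and a (rescaled) model profile is
the reduced chi score
$$ \chi = \Bigl[\tfrac{1}{N}\sum_i \bigl(\tfrac{I_e(q_i) - c\,I_m(q_i)}{\sigma_i}\bigr)^2\Bigr]^{1/2},
\qquad c = \frac{\sum I_e I_m/\sigma^2}{\sum I_m^2/\sigma^2}, $$
with the scale factor $c$ in closed form from least squares (clamped at
zero) — so stored-profile normalization never matters. Weighting uses the
experimental $\sigma$; where $\sigma$ is absent the residuals become
relative ($\sigma_i = I_e(q_i)$), and bins where both are non-positive are
excluded (an absolute fallback would break the scale invariance of the
ranking). Both weightings are exposed.

The radius is optimized by golden-section search over a default bracket
$[0.8\,r_0,\ 1.25\,r_0]$ around the user-supplied radius $r_0$ — symmetric
on the log scale ($1/1.25 = 0.8$), so over- and under-estimates of $r_0$ are
treated alike — to a tolerance of $0.01\,r_0$. The contraction arithmetic
gives exactly $\lceil \log(0.01/0.45)/\log 0.618 \rceil = 8$ iterations.
When $r_0$ is not supplied it is estimated from a Guinier fit as the
sphere-equivalent radius $R_g\sqrt{5/3}$ and reported.

Two search modes: **global** (default) minimizes
$J(r) = \min_{\rm models} \chi(r)$ and ranks every model at the common
optimum $r^*$ — all models scaled to the same radius; **per-model** runs an
independent golden section per model (pre-selecting the best 50 at $r_0$
when the database is larger) and ranks models at their own optimal radii.

The top ten models (configurable) are rasterized to voxel maps at their
fitted radii, clustered, and written as CCP4 maps.

## Clustering and model averaging

Maps are compared in a canonical frame: centroid at the origin, axes along
the eigenvectors of the occupancy-weighted second-moment tensor (eigenvalues
decreasing), each axis's sign fixed by requiring non-negative third central
moment along it (near-zero skewness leaves the eigenvector as returned;
determinant restored by flipping the least-skewed axis). Members are
resampled onto a shared symmetric grid by trilinear interpolation. Pairwise
similarity is the cosine overlap of the occupancy vectors; single-linkage
clustering at overlap $\ge 0.75$ groups the top models, classes numbered in
rank order of their best member. Class averages and the overall top-K
average are voxel-wise means in the canonical frame. Principal-axes
alignment cannot distinguish a shape from its mirror image, and for shapes
with degenerate moments the canonical frame is conventional rather than
unique — both are inherent limits of any alignment-based averaging.

## Problem sizes and numerical choices in the shipped tests

The test-suite and the acceptance script use desk-scale stand-ins chosen
once: a 64×64-pixel detector (λ = 2 nm, 500 mm, 1.5 mm pitch; 48×48 where
profile statistics, not resolution, are being exercised); 500 frames of a
135 × 68 nm prolate particle and 400 frames of a touching 91 nm-sphere
dumbbell for the end-to-end recoveries; 600 frames with 10% false positives
for convergence monitoring; 100 seeded trials for noisy center recovery; and
a 12-model demonstration database spanning five shape families
(`demo_shape_database()`). Orientation-average cross-checks use 2000
orientations: near a profile's first minimum the Monte-Carlo error of the
orientation mean decays slowly, and ~500 random orientations still carry
~3% error there, while 2000 bring the whole sub-minimum range inside 2%.

Recovered particle dimensions are read from the retrieved model at its
fitted radius: principal-axis extents for diameters, and the
volume-equivalent radius (per body) for sphere radii — the latter because
lattice models' bounding extents carry a surface-fattening bias of several
percent that volume measures do not.

## Known limitations

* A one-dimensional profile is a highly degenerate observable: distinct
  shapes can match it equally well. Retrieval reports ten models and their
  classes precisely because the single best chi can be structurally wrong.
* The pipeline assumes uniform orientation coverage; preferred orientations
  would require weighting schemes that are out of scope here.
* No outlier rejection is applied: the convergence trace and split-half
  check expose the information, and screening is left to the user.
* Bead models with a shared bead radius cannot represent smooth density
  variation; heterogeneity enters only through bead weights.
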