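---
title: "Quantitative microwave breast imaging with a quadratic-programming Born iteration and convolutional refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microwave breast imaging with a quadratic-programming Born iteration and convolutional refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bimqp)
```

## The imaging problem

A two-dimensional cross-section of the breast sits in a homogeneous
background medium (relative permittivity $\varepsilon_{rb}$, conductivity
$\sigma_b$) inside a square domain of interest $D$. A circular array of
line sources illuminates the domain one source at a time, and receivers on
the same circle sample the scattered electric field at several
frequencies. The goal is quantitative: recover the map of relative
permittivity $\varepsilon_r(\mathbf r)$ (and, through a tissue regression,
conductivity $\sigma(\mathbf r)$) inside $D$.

Two coupled integral equations describe the physics under the
$e^{j\omega t}$ convention. The *state equation* relates the total field
inside $D$ to the incident field and the field re-radiated by the induced
contrast currents $J = \chi E^t$; the *data equation* gives the scattered
field at the receivers as the radiation of those currents. The complex
contrast

$$
\chi(\mathbf r) \;=\; \frac{\varepsilon_r(\mathbf r) - \varepsilon_{rb}}
{\varepsilon_{rb}} \;-\; j\,\frac{\sigma(\mathbf r) - \sigma_b}
{\omega\,\varepsilon_b}
$$

vanishes identically outside the scatterer, which is what makes the
support of the problem compact. (Some treatments print the numerator as
$\varepsilon_r - 1$; with a non-unity background that would assign the
background itself a contrast of $0.9$ and break the compact-support
structure, so the package uses the background-referenced form above.)

Breast tissue at microwave frequencies is a *strong* scatterer
($\varepsilon_r$ from 2.5 up to 67 against a background of 10), so
single-scattering (Born) linearization is not valid globally — this is the
regime the iterative method and the learned refinement stage are designed
for.

## Discretization

`build_grid()` divides $D$ into $M \times M$ square pixels (row-major,
x fastest, origin at the domain center). Pulse-basis point matching with
the equal-area disc approximation turns the Green operators into matrices
with entries

$$
g_{mn} = -\tfrac{j}{2}\,\pi k_b a\, J_1(k_b a)\, H_0^{(2)}(k_b
|\mathbf r_m - \mathbf r_n|), \qquad
g_{nn} = -\tfrac{j}{2}\left[\pi k_b a\, H_1^{(2)}(k_b a) - 2j\right],
$$

where $a = \sqrt{\Delta x\,\Delta y/\pi}$ is the equivalent cell radius
and $k_b$ the background wavenumber. Both formulas follow from integrating
$k_b^2 \cdot (-\tfrac{j}{4}) H_0^{(2)}$ over the equal-area disc (Graf's
addition theorem); the unit tests verify them against direct 2D quadrature
of the continuous kernel. Because pixel centers sit on a regular lattice,
the package evaluates the radial kernel once per lattice displacement
($O(M^2)$ Bessel evaluations) and fills matrices by indexing.

The forward simulation (`simulate_dataset()`) renders the phantom on a
*fine* grid, solves the dense state equation restricted to the support of
the contrast (LU factorization per frequency, shared across sources), and
samples the data equation at the receivers. Inversion always runs on a
strictly coarser grid, so no inverse crime is committed; rendering is
4×4-supersampled per pixel so that sub-pixel structures (3 mm tumors at
5.6 mm pixels) contribute their partial volume instead of disappearing.

## The Born iteration as a quadratic program

Each outer iteration alternates:

1. a total-field solve $(I - G_D\,\mathrm{diag}\,\chi)E^t = E^i$ on the
   inversion grid with the current contrast, per frequency;
2. a contrast update posed as the quadratic program

$$
\min_{d,\chi}\ \sum_m |d_m|^2 + \lambda\,\|\nabla \chi\|^2
\quad \text{s.t.}\quad
d_m + \sum_n g_{mn}\chi_n E^t_n = \tilde E^s_m,
$$

with the rows stacked over all receivers, sources and frequencies, a
single contrast vector shared across all of them, and box bounds on
$\mathrm{Re}\,\chi$ and $\mathrm{Im}\,\chi$ derived from the physical
ranges $\varepsilon_r \in [2.5, 67]$ and $\sigma \in [0, 4]$ S/m. All
complex quantities are split into real and imaginary parts, so the
program contains only real variables; `qp_dense()` materializes exactly
this real form (with $2FLN_r$ equality rows and $2FLN_r + 2N$ unknowns)
for small systems and for the oracle tests.

Because the slack variables $d$ are eliminated exactly by the equality
rows, the solver works on the equivalent bound-constrained regularized
least-squares problem in $\chi$. Its complex normal matrix is assembled
frequency-blockwise as $A^\mathsf{H} A = \sum_f K_f \circ C_f$ with
$K_f = G_S^\mathsf{H} G_S$ (a geometry constant, memoized) and
$C_f = \bar E\,E^\mathsf{T}$ summed over sources, so assembly cost is
independent of the number of stacked rows. When no bound is active the
update is a single Hermitian solve; otherwise a projected-Newton
iteration (free-set Cholesky, exact quadratic line search truncated at
the first blocking bound, with a bulk-clipping fallback when the Newton
step would cross many bounds at once) refines the solution. Small systems
(N ≤ 256) iterate to projected-gradient stationarity below $10^{-8}$;
at production sizes the iteration budget is capped (12 cold / warm-started
across outer iterations), because the free-set Hessian of this inverse
problem is ill-conditioned enough that exact stationarity buys no visible
change in the reconstruction — the unit tests pin global optimality on
small instances where it is checkable.

### Choosing the regularization weight

$\lambda$ is nowhere given by the protocol this package follows, so it is
set by a scale-free default $\lambda = \mathrm{tr}(A^\mathsf{H}
A)/\mathrm{tr}(P)$, where $P = D^\mathsf{T} D$ is the first-difference
(replicate-boundary) roughness matrix. This equalizes the average
curvature of the data and penalty terms and is comparable across grids
and acquisition sizes. The multiplier was calibrated once by scanning
$\{10^{-2}, 10^{-1}, 1, 10\}$ and comparing the Frobenius reconstruction
error on both phantom families: small multipliers leave the update nearly
unregularized (the box constraints then do all the work, and the maps
oscillate at the pixel scale), while the unit multiplier reduced the
breast-class errors from 0.86–0.99 to 0.65–0.83 and kept the circular
model inside its expected band. It is overridable per run (`lambda` in
`bim_config()`).

### Initialization and stopping

Three initial guesses are implemented (`initial_guess()`): the
first-order Born inversion at the reference (mid-band) frequency
(`born_zero`), the same linearization stacked jointly over all sources
and frequencies (`multi_freq_source`), and the uniform map at the minimum
permittivity of the range (`constant_min`, used for the breast runs).
Stopping is a fixed iteration count — 10 for the circular validation, 5
for the breast sweep — matching the protocol the package reproduces; no
adaptive criterion is used. On all-zero data the regularized minimum is
the zero contrast, and the iteration keeps it exactly.

The multi-frequency contrast is modeled as frequency-independent; the
recovered imaginary part is converted to conductivity at the mid-band
reference frequency. This is exact for lossless phantoms and an
approximation for lossy ones; the frequency band of the breast sweep
(600 MHz–1 GHz) is chosen so that $|\mathrm{Im}\,\chi|$ stays of order
one. At the kilohertz end of the circular experiment's band the
conductive contrast of a lossy phantom would reach $10^3$ and the shared
model would break down — the circular phantom, however, is lossless
($\sigma = \sigma_b$), which is also why only its permittivity is
reconstructed.

## The synthetic phantoms

`circular_phantom()` builds the concentric validation target: an 8 cm
disc at $\varepsilon_r = 40$ containing a 6 cm disc at 4.5 and a 1 cm
"tumor" at 57, in a background of 10.

`synthetic_breast_phantom()` emulates 2D slices of an MRI-derived
numerical phantom repository without using its files: an outer skin ring
(radius 7.2 cm, thickness 4 mm, $\varepsilon_r = 38$) around a fatty
interior ($\varepsilon_r = 5$) textured with fibroglandular structures
($\varepsilon_r$ 38–52) drawn as a seeded sum of Gaussian blobs
thresholded at a class-calibrated quantile, so the fibroglandular area
fraction increases with density class (12%, 30%, 50%, 70% of the interior
for classes 1–4). The threshold is computed on a fixed internal reference
grid, which makes the rendered map a pure function of (class, tumor,
seed) and of the render resolution — the same phantom rendered at 150×150
and box-averaged to 64×64 agrees with a direct 64×64 rendering away from
region boundaries. A tumor disc at $\varepsilon_r = 60$ is implanted at
one of the nine sweep positions; conductivity is derived from the
permittivity map through the linear tissue regression
$\sigma = 0.019\,\varepsilon_r - 0.047$ (floored at zero, which only
matters below $\varepsilon_r \approx 2.47$).

What the generator does *not* emulate: real anatomical asymmetry and
ductal structure, tissue dispersion (no Debye model — properties are
frequency-independent), and 3D propagation. Passing tests on these
phantoms therefore demonstrate the correctness and calibration of the
reconstruction chain, not clinical performance on real breasts.

## The convolutional refiner

The refinement network is a small U-Net-style encoder–decoder
(`build_refiner()`): per contracting level two 3×3 convolutions, each
followed by batch normalization and ReLU, then 2×2 max-pooling with
channel doubling; per expanding level nearest-neighbor upsampling, a 2×2
convolution halving the channels, concatenation with the corresponding
contracting feature map, and two 3×3 convolutions with ReLU; a final 1×1
projection returns the single-channel map. It is implemented directly on
R arrays with im2col convolutions executed as BLAS products, and its
backward pass is verified against finite differences in the tests.

Inputs and targets are permittivity maps normalized to $[0,1]$ by the
physical range (2.5, 67); outputs are de-normalized and clipped back to
that range. Training minimizes pixel-wise squared error with Adam over
seeded mini-batches; everything (initialization, shuffling, splits) is
deterministic given the seeds. The 108-pair training set (4 classes × 3
tumor diameters × 9 positions, one anatomy per class) is split 90/10 by a
seeded shuffle (floor rule: 97 train / 11 validation).

The network regresses permittivity maps directly (not contrasts), and
conductivity is *not* refined by the network — it is regenerated from the
refined permittivity through the tissue regression, mirroring the
evaluation protocol.

## Problem sizes used by the shipped checks

The package's own acceptance checks (`scripts/acceptance.R`, mirrored in
`tests/testthat/test-acceptance.R`) use:

* circular model: simulation at 150×150, 18 sources, 30 receiver
  positions, 15 equispaced frequencies over 600 kHz–600 MHz, inversion at
  32×32 with 10 iterations;
* breast sweep: simulation at 40×40, inversion at 32×32, 4 frequencies
  over 600 MHz–1 GHz, 12 sources, 18 receivers, 5 iterations per phantom,
  108 phantoms; refiner with depth 3 and 8 base channels trained with
  Adam (batch 16) under the step-decay schedule of `refiner_schedule()`
  for 250 epochs on the 97/11 split, keeping the parameters of the best
  validation-loss epoch. A constant learning rate converges to maps that
  are several permittivity units too blurry for the per-map relative
  metric; the decayed phase recovers that sharpness.

These sizes are the package's scaled-down study conditions: large enough
that the circular model reproduces the expected error band and the
refined sweep exceeds 90% median accuracy, small enough that the whole
chain runs on one CPU in well under an hour. The inversion grid (32×32
rather than 64×64) halves the linear resolution of the published setup;
the relative-error metric is only mildly sensitive to this because it is
dominated by bulk tissue structure rather than pixel-scale detail.

## Numerical choices and degenerate inputs

* Hankel functions of the second kind throughout ($e^{j\omega t}$
  convention); `hankel2(x, nu) = J_nu(x) - j Y_nu(x)` on base R Bessel
  functions.
* Total-field solves are dense LU with an optional residual check
  (`check = FALSE` inside the Born loop, which monitors its own data
  residual); a singular system aborts with a conditioning diagnostic and
  the partial result.
* Ties in max-pooling route gradients to the first maximum; ReLU kinks
  make a handful of finite-difference gradient comparisons inexact, which
  the gradient test accounts for by bounding the median and the maximum
  deviation separately.
* Degenerate QP inputs: all-zero data returns the exact zero contrast;
  a degenerate box `[c, c]` returns the pinned value; a singular normal
  matrix (only possible at `lambda = 0` on rank-deficient stacks) raises
  a solver error suggesting regularization.
* All randomness (phantom texture, noise, weight initialization, batch
  shuffling, splits) flows through explicit integer seeds, and the RNG
  state of the caller is always restored.

## Known limitations

* 2D scalar (TM) model only; no antenna near-field model, no matching
  medium other than a homogeneous background.
* The frequency-independent shared contrast biases the recovered
  conductivity of strongly dispersive targets.
* The refiner is trained per acquisition configuration; a model trained
  on the 32×32 sweep does not transfer to other grids (`refine()` checks
  the shape).
* Reconstruction quality on the strong-scatterer breast classes is poor
  before refinement (relative errors of 65–85%) — consistent with the
  regime this method class operates in, and precisely the gap the learned
  stage closes on held-out phantoms of the same classes. Accuracy on
  anatomies unlike the four generated classes is not claimed.
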