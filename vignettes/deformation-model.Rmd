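---
title: "Modelling continuous flexibility in single-particle cryo-EM with tetraflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continuous flexibility in single-particle cryo-EM with tetraflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-particle cryo-EM averages tens of thousands of noisy 2D projections
into one 3D density map. When the molecule is continuously flexible, every
particle image is a projection of a *different* conformation; rigid
averaging then blurs the moving parts, and their resolution collapses even
though the information is present in the raw images. tetraflex implements a
generative model that explains each image as a *deformation* of a single
canonical map, and uses the learned deformations to put the high-resolution
signal of the moving parts back into register.

## The generative model

Each particle image $I_i$ is modelled as

$$ I_i = C_i \, P(\phi_i)\, D(f_\theta(z_i), V) + \eta, $$

where

* $V$ is the canonical 3D density, a real-space $N^3$ voxel grid
  (`canonical_volume`);
* $z_i \in \mathbb{R}^K$ are per-particle latent coordinates locating the
  particle on the conformational landscape (default $K = 2$, exposed 1-8);
* $f_\theta$ is the **flow generator**: a fully connected network (default
  six layers, 64 hidden units, ReLU, final layer linear and bias-free) that
  maps $z_i$ to a 3D displacement at each vertex of a tetrahedral mesh;
* $D$ is the **convection operator** transporting density along the flow;
* $P(\phi_i)$ projects along the known particle pose and $C_i$ applies the
  known CTF;
* $\eta$ is white Gaussian noise, so the data energy is
  $E_{\text{data}} = \tfrac12 \sum_i \lVert I_i - C_iP(\phi_i)D(f_\theta(z_i),V)\rVert^2$.

Poses and CTFs come from an upstream consensus refinement and are treated as
known throughout. All gradients (through the CTF, projection, convection,
mesh interpolation and the network) are hand-derived adjoints, verified
against central differences; no autodifferentiation framework is involved.

### Density-conserving convection

The flow is a *forward* map from canonical to deformed coordinates:
every canonical voxel $y$ deposits its density at $u(y) = y + d(y)$ through
an interpolation kernel,

$$ W(x) = \sum_y k(x - u(y))\, V(y). $$

Because each voxel's density lands somewhere, total mass is conserved
without evaluating the Jacobian determinant a backward (pull-back) map would
require. With the default trilinear kernel conservation is exact whenever
all mapped positions stay inside the grid; a tricubic (Keys, $a=-0.5$)
kernel is available for smoother gradients. Voxels outside the mesh do not
move — the mesh covers the masked molecule and solvent must stay put.

### The tetrahedral mesh and local rigidity

The deformation is parameterized at the vertices of a tetrahedral mesh
covering the molecule and interpolated with linear finite-element shape
functions. A regular mesh is built from an axis-aligned cube lattice over
the thresholded consensus density; each cube splits into 5 tetrahedra with
parity-alternating orientation so neighboring cubes share faces
(`generate_regular_mesh()`). A segmentation-driven utility
(`build_fused_mesh()`) builds one submesh per subdomain and duplicates
vertices at subdomain interfaces *except* where the user fuses them,
introducing cuts that let domains slide independently.

Within element $j$ of image $i$ the deformation is affine,
$u_{ij}(x) = A_{ij}x + b_{ij}$, solved exactly from the four vertex
positions. Nonrigidity is the deviation of the singular values of $A$ from
one:

$$ E_{\text{rigid}} = \sum_i \sum_j w_j \sum_{\ell=1}^{3}
   (s^{\ell}_{ij} - 1)^2 , $$

and the training loss is $L = E_{\text{data}} + \lambda E_{\text{rigid}}$
with $\lambda = 2$ by default (useful range about 0.5-5; larger $\lambda$
yields stiffer motion). Element weights scale the penalty with local
density: the densest element gets $w_j = 1$, empty elements get
$w_{\min} = 0.5$, linear in mean element density in between. The linear
interpolation between the two anchors is this package's choice; only the
anchors themselves are standard. The gradient of $E_{\text{rigid}}$ uses
the analytic SVD derivative $2\,U\,\mathrm{diag}(s-1)\,V^\top$; degenerate
singular values are perturbed by $10^{-12}$.

### Auto-decoder latent inference

There is no encoder network: each image's latent coordinates are optimized
directly against the generative model (`infer_latents()`), minimizing the
per-image negative log posterior
$\tfrac12\lVert I - \hat I(z)\rVert^2 + \tfrac12 \lVert z \rVert^2$
(a unit-variance Gaussian prior keeps the embedding centered and bounded).
The default method is cyclic per-dimension golden-section search on
$[-4, 4]$ — simple and effective for small $K$; a gradient method with
backtracking is available. A candidate is accepted only when it improves
the objective, so inference never increases it. During generator updates
(only), Gaussian noise is injected into the inferred latents
(s.d. 0.1 decaying linearly to 0.02 by default), which smooths the latent
space in the manner of a fixed-covariance variational family; the
magnitude and schedule are package choices, stated here because no
standard values exist.

### Optimization

`train_flex()` uses minibatch block coordinate descent (Adam by default,
SGD with Nesterov momentum as an alternative), with minibatches of at least
500 images recommended because of the extreme image noise:

1. **Warmup** (5 epochs): update $(\theta, z)$ with $V$ fixed — or $\theta$
   only, when latents were imported (e.g. from a linear subspace analysis).
2. **Alternation**: epochs alternate between updating $V$ and updating
   $(\theta, z)$, a stabilizing schedule that prevents the map and the
   motion model from absorbing each other's residuals.

$V$ is constrained to be low-pass under **frequency marching**: the
band-limit shell starts at $N/8$ and ramps linearly to $N/2$ over the first
half of training (the coarse-to-fine principle is standard; this concrete
schedule is a package default). Every $V$ update re-applies the current
band limit and the solvent mask. A zero-deformation mask pins selected
vertices (e.g. a detergent micelle) to zero displacement exactly, at all
times.

Learning rates are package choices: Adam with $3\times10^{-3}$ for
$\theta$ and a map step of $0.1\,\mathrm{sd}(V_0)$, with several gradient
steps per minibatch visit (`theta_steps_per_batch`, `V_steps_per_batch`,
default 4). At desk scale a training run sees a few dozen epochs rather
than the thousands of minibatch iterations a GPU run would, so the per-step
rates are set correspondingly larger; they are exposed in `train_config()`.
Early stopping triggers when the relative epoch-loss improvement stays
below $10^{-4}$ three epochs in a row; the threshold is deliberately small
because the loss is dominated by the irreducible noise floor
$\tfrac12\sum_i\lVert\eta_i\rVert^2$, against which meaningful model
improvements are relatively tiny.

Runs are bit-reproducible given `seed`. A non-finite loss aborts with the
last finite checkpoint.

## High-resolution reconstruction and validation

Training happens at a small box $N_L$ (Fourier-cropped images), which is
cheap and leaves frequencies beyond the training Nyquist untouched as a
validation resource. `reconstruct_highres()` then freezes $\theta$ and
$z_{1:M}$, transfers the mesh to the full box $N_H$ (vertex coordinates and
displacements scale by $N_H/N_L$; the physical deformation is
scale-invariant), and re-optimizes $V$ *from zero* for each particle
half-set, full-batch, in real space.

Because the frozen-motion objective is exactly quadratic in $V$, the
L-BFGS implementation (memory 10) uses the exact line search
$\alpha = -g^\top p / p^\top Hp$, which satisfies the usual Wolfe
conditions on quadratics and costs one operator pass over the data per
iteration; a damped (`ridge`) variant makes the minimizer unique when the
view geometry leaves null directions. Iterations stop when the gradient
norm has dropped by $10^3$ or at `max_iters`. Unregularized least squares
on noisy data semi-converges — late iterations fit noise at high
frequency — so moderate iteration caps act as the effective regularizer,
exactly the role early stopping plays in conventional reconstruction
packages.

The two half-maps are compared by Fourier shell correlation (`fsc()`):
correlation beyond the training band limit can only come from consistent
signal that the motion model brought into register in both independent
halves, since the model never saw those frequencies during training. This
is the package's central validation logic. Resolution is reported at the
0.143 and 0.5 crossings (0.143 is the gold-standard half-map convention;
the choice is exposed); FSC is computed unmasked by default and optionally
under a user mask, with no noise-substitution correction. For symmetric
molecules whose motion breaks symmetry, `symmetrize_cn()` averages a
half-map over a $C_n$ rotation group post hoc.

## The synthetic test surface

`generate_dataset()` simulates the entire observation model with known
ground truth: a two-domain toy molecule of Gaussian blobs (coarse
domain-scale blobs plus fine secondary-structure-scale blobs, so real
signal extends beyond typical training band limits) whose mobile domain
rotates rigidly about a hinge axis, blended across a connector by a
smoothstep; one scalar latent drives the hinge angle
($z \cdot 20^\circ/3$ at the default maximum swing). Latents are standard
normal, poses uniform over SO(3) (quaternion sampling), shifts uniform
within $\pm 2$ Å, defoci uniform in 8,000-20,000 Å at 300 kV,
$C_s = 2.7$ mm, 7% amplitude contrast.

Two deliberate hygiene choices:

* **No inverse crime.** Clean images are rendered at twice the training box
  through the *analytic* hinge field (not the mesh interpolation) and
  Fourier-cropped down, so the fitted discretization never coincides with
  the simulator's.
* **Exact noise calibration.** Noise is added at the simulation box and
  scaled so that masked clean-signal variance over noise variance at the
  training box equals the requested SNR (default 0.5). Fourier cropping
  zeroes the small box's non-Hermitian Nyquist-edge planes, which makes the
  crop exactly real and the white-noise variance scaling across the crop
  deterministic — the factor $(N_{lo}-1)/N_{hi}$ used in the calibration.

What the simulator does *not* emulate: structured noise (micelles, ice
gradients), pose or CTF estimation error, beam-induced motion,
compositional heterogeneity, dose damage. Passing tests on these fixtures
therefore demonstrate correctness of the estimator under its own model
assumptions, not robustness to every pathology of real micrographs.

## Numerical conventions

* Volumes are cubic, $N$ even; images are $N\times N$ R matrices with the
  first (fastest) index along $+x$, matching the volume's first axis and R's
  column-major layout. The rotation/projection origin is the voxel at
  0-based index $N/2$ on each axis.
* Euler angles are ZYZ intrinsic `(rot, tilt, psi)` in degrees,
  $R = R_z(\text{rot})R_y(\text{tilt})R_z(\text{psi})$, mapping
  canonical-frame coordinates into the microscope frame; shifts are in
  Ångström. These conventions are declared, not inferred: upstream tools
  vary, and `read_particles()` documents exactly what it assumes.
* Projection is rotate-then-sum with trilinear resampling (out-of-grid
  reads are zero), scaled so a constant volume of value $c$ projects to
  $N c$ per interior pixel. The trilinear kernel carries its own frequency
  response (a few percent attenuation at mid-band); a Keys tricubic
  projector (`interp = "tricubic"`) is provided where spectral fidelity
  matters, e.g. for Fourier-slice cross-checks. Training uses the trilinear
  pair because projection and backprojection are then exact adjoints.
* CTF: $\mathrm{CTF}(s) = -[\sqrt{1-w^2}\sin\chi + w\cos\chi]$ with
  $\chi = \pi\lambda s^2 \Delta f(\alpha) - \tfrac{\pi}{2} C_s\lambda^3 s^4
  + \text{phase}$; underfocus positive, relativistic wavelength. The
  operator is real and even, hence self-adjoint — which the backward pass
  uses.
* Low-pass filtering uses a 2-shell raised-cosine rolloff; `canonical_volume`
  records its band limit so re-application at the same shell is the
  identity.
* Convection is flagged as divergent when any displacement exceeds $N/2$.

## Problem sizes used by the test suite

The default hinge fixture follows the conditions stated above: $N_L = 32$
(3 Å voxels), $M = 2000$ particles at SNR 0.5. The full-scale checks train
with $K = 1$ and a single coordinate-descent cycle per visit (the motion
has one true degree of freedom; a second cycle re-runs an identical 1-D
search) for 18 epochs at a band limit of shell 8, with 3 generator and 3
map gradient steps per minibatch visit, and reconstruct half-maps at
$N_H = 64$ from the full 1000-particle halves with 15 L-BFGS iterations.
One band-limited training serves both the latent-recovery and the
half-map-validation studies, since the latter requires a model that never
saw frequencies beyond the band limit. The regularization sweep runs at
$M = 500$. Smaller fixtures (down to $16^3$, a few dozen particles)
exercise every code path in the unit tests. These sizes are the package's
chosen desk-scale study conditions; the estimator itself has no dependence
on them.

## Known limitations

* Poses and CTFs are inputs; there is no re-refinement of either.
* The white-noise likelihood ignores noise coloration; per-dataset scale is
  absorbed into $\lambda$.
* One latent inference pass per minibatch visit with frozen $(\theta, V)$
  means latents lag one update behind the generator within an epoch.
* The mesh is a first-order (linear shape function) discretization;
  deformations rougher than the element size are invisible to it by design.
* Half-map independence holds conditionally on the shared poses, CTFs,
  frozen generator and latents, as in the corresponding large-scale
  workflows; it validates recovered signal, not the upstream consensus.
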