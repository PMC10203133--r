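---
title: "Restoring cryo-electron tomograms by knowledge transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring cryo-electron tomograms by knowledge transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A cryo-electron tomogram is reconstructed from a tilt series that covers
only a limited angular range (typically ±40° to ±60°) at a very low
electron dose. Two artifacts follow. First, the unsampled region of
Fourier space — the *missing wedge* — elongates and distorts every density
along the beam (z) axis. Second, the dose budget leaves the data at an SNR
far below 1, so individual macromolecules are barely recognizable.
Subtomogram averaging recovers both losses by averaging thousands of
aligned copies, but it erases exactly what one often wants to see:
per-particle conformational differences.

`tomorest` implements the knowledge-transfer alternative: build *training
pairs* whose inputs look like real degraded subvolumes and whose targets
are the corresponding high-quality densities, train a 3D U-Net on those
pairs, and apply the learned mapping to a whole tomogram. The ground truth
can come from two sources:

* **Strategy 1 (averaging-based).** A CTF- and wedge-corrected averaged
  map is rotated and shifted into each raw particle's orientation
  (`make_ground_truth_strategy1()`, `build_pairs_strategy1()`); the raw
  particles themselves are the inputs.
* **Strategy 2 (simulation-based).** Conformations generated from a
  (pseudo-)atomic model are rendered as density, randomly oriented, and
  degraded through the full forward model
  (`build_pairs_strategy2()`); the clean rotated densities are the
  targets.

## The forward model

The simulator reproduces the degradation chain of a real experiment:

1. **Rigid placement.** `apply_transform()` resamples a volume with
   trilinear interpolation about its origin voxel. Euler angles are
   intrinsic ZYZ `(rot, tilt, psi)` — the matrix is
   `Rz(rot) Ry(tilt) Rz(psi)` — matching the STAR-dialect columns the
   package reads and writes; the worked-example test pins this convention
   to a literal in-plane rotation. The tilt axis is y and the beam is z.
2. **Projection.** `project()` integrates along z after rotating the
   volume by minus the tilt angle; `tilt_scheme(-60, 60, 2)` expands to
   the 61 angles of a typical collection.
3. **CTF.** `simulate_ctf()` evaluates the standard phase-contrast
   transfer function `-sqrt(1 - A^2) sin(chi) - A cos(chi)` with
   `chi = pi lambda dz f^2 - (pi/2) Cs lambda^3 f^4` and the relativistic
   electron wavelength. Defocus is constant per tilt. `ctf_modulate()`
   multiplies each image by the CTF in Fourier space; phase flipping
   multiplies by its sign afterwards, so the net transfer is `|CTF|`.
4. **Noise.** `add_gaussian_noise()` injects white Gaussian noise at a
   target SNR defined as the variance ratio var(signal)/var(noise) over
   the stack — the convention under which "SNR 0.1" and "SNR 0.01"
   describe realistic tomographic contrast. The simulator's order is
   modulate → add noise → phase-flip.
5. **Reconstruction.** `wbp_reconstruct()` is classic weighted
   back-projection: ramp filter |k| along the axis perpendicular to the
   tilt axis, back-smear along each beam direction (the exact adjoint of
   the projector — an adjointness test holds to 1e-4), sum, and scale by
   pi/(2 n_tilt). The result is then projected onto the scheme's Fourier
   support (`wedge_mask()`): a limited-angle dataset carries no wedge
   information, and discrete finite-support smearing otherwise leaks a few
   percent of spectral power into the wedge as sinc tails. With the
   support projection the simulated inputs show the same empty wedge as
   Fourier-inversion reconstructions of real tilt series. Set
   `enforce_wedge = FALSE` for the raw smear-and-sum volume.

Numerical conventions worth stating: trilinear/bilinear interpolation
everywhere (round trips are validated by correlation, not bit equality);
on an even box the degenerate Nyquist planes are assigned to the sampled
region of the wedge mask; the DC voxel is always sampled; rotations
compose associatively and `invert_transform()` gives the exact inverse
under the rotate-then-shift convention.

## Conformational variability from an elastic network

Strategy 2 becomes interesting when the training set spans a *continuum*
of conformations. `compute_enm_modes()` builds the anisotropic network
model: unit-stiffness harmonic springs between all atom pairs closer than
a cutoff (8 Å suits atomistic models, 16 Å the coarse pseudo-atom toys
used here). The 3N×3N Hessian is symmetric positive semi-definite with
exactly six zero modes for any non-collinear body (five for a collinear
one); eigenvalues are sorted ascending so deformations start at mode 7,
the usual convention. A disconnected spring graph is refused with the
component count, because extra spurious zero modes would silently corrupt
mode indexing.

`displace_along_modes()` adds amplitude-weighted eigenvectors to the
coordinates; amplitudes are in the network's native units (eigenvectors
are unit-norm over 3N coordinates), and `mode_rmsd()` converts an
amplitude to the coordinate RMSD it produces so ranges can be calibrated.
`sample_conformations()` draws independent uniform amplitudes per mode —
the default, modes 7 and 13 with amplitudes in [−250, 250], emulates a
nucleosome whose linker arms sweep through a continuous transition (for
the built-in toy, amplitude 250 on mode 7 corresponds to roughly 17 Å
RMSD). The built-in `disc_with_arms` toy model is exactly that geometry: a
rigid core disc with two flexible arms whose motion dominates the softest
modes; `generate_toy_model()` is deterministic per seed so every fixture
in the test suite is generated by code.

"Conformation selection" is deliberately explicit — a mode-index list plus
an amplitude range — rather than any automatic filtering.

`model_to_density()` renders atoms as isotropic Gaussians with
`sigma = resolution_A / (pi sqrt 2)` (the common pdb-to-map convention),
discretely normalized so each atom contributes exactly its weight to the
voxel sum; rendering is linear in the weights and exactly
shift-equivariant for whole-voxel translations.

## The network

`build_network()` constructs a plain volumetric U-Net: per level two 3³
convolutions + ReLU, 2× average pooling on the way down, nearest-neighbor
upsampling and skip concatenation on the way up, a two-conv bottleneck,
and a final 1³ convolution. There is no deep-learning framework
dependency: the convolutions are im2col-free per-offset GEMM kernels
(float32, BLAS) with hand-derived backpropagation, verified against
central-difference gradients, and an Adam optimizer. Training
(`train_restorer()`) minimizes voxel-wise L2 (L1 available) and is fully
deterministic given the seed — weight init, batch order and the
validation split all derive from it.

Two presets are provided. The `"full"`-scale configuration (depth 3, 32
base channels, 64-voxel patches) mirrors a production setting at 4.44 Å
voxels. The `"desk"` preset (depth 2, 8 base channels, 32-voxel patches)
is the test-suite configuration; it trains in minutes on one CPU. Both
are implementation choices — depth, channel counts, loss, optimizer and
learning rate are exposed in `unet_config()`/`training_config()`.

`restore_volume()` applies tiled prediction: overlapping patches, each
tile contributing only its central region (margin = overlap/2, extended at
the volume faces), so every output voxel comes from exactly one tile and
stitching is bit-reproducible; cosine-window blending is available behind
a flag. Volumes smaller than a patch are zero-padded, predicted and
cropped. Tomograms are z-score normalized before restoration, the same
convention applied to every training pair (per-volume, not per-dataset).

## Evaluation

* **Region-based SNR in dB** (`estimate_snr_db()`): average ten
  consecutive slices into a micrograph (`slice_average()`), choose paired
  signal/background rectangles, and for each pair take
  `10 (log10 v_s − log10 v_b)` where `v_b` is the background variance and
  `v_s` the variance of the signal region after subtracting the
  background mean; the estimate is the mean over (by default ten) pairs,
  with unbiased sample variances. The estimator is exactly invariant to
  global offset and scale. Deterministic pixel constructions reproduce 0
  dB and 10 dB to float precision; a stochastic construction with
  signal-added variance 3 lands at 10·log10(4) ≈ 6.02 dB.
* **Pearson correlation** (`pearson_cc()`): the restoration-fidelity
  metric; errors (not NaN) on zero-variance input.
* **Wedge occupancy** (`wedge_energy_fraction()`): the share of non-DC
  spectral power inside the scheme's missing wedge. Wedge-limited inputs
  score ≈ 0, white noise scores the wedge voxel fraction, and successful
  restoration moves a volume from the former toward the latter.
* **Template matching** (`template_match()`): exhaustive normalized
  cross-correlation over a uniform ZYZ orientation grid, FFT-accelerated
  with exact local contrast normalization, validated against a
  brute-force spatial-domain oracle to 1e-6; greedy non-maximum
  suppression breaks ties by higher cc, then lexicographic coordinate
  order. `offset_statistics()` pairs peaks to ground-truth coordinates
  (greedy by cc, one-to-one, within a radius) and reports per-axis
  offsets. No wedge-weighted correlation is attempted — the point of
  restoration is precisely that plain correlation becomes sufficient.

## The desk-scale study and what it does (not) show

The test suite and `scripts/acceptance.R` run a complete closed loop
chosen to finish in minutes on one CPU: 220 conformations of the toy
nucleosome-like model (spanning modes 7 and 13, amplitudes ±250), 200
training and 20 held-out pairs at 32³ voxels and 8.88 Å (a 2×-binned desk
surrogate of the 64-voxel / 4.44 Å production setting), SNR 0.1, ±40°
coverage, 150 Adam iterations of the desk U-Net at batch 4; plus a
128-voxel tomogram containing 8 particles at SNR 0.1 / ±60° for template
matching, restored with 32-voxel tiles and 8-voxel overlap. Under these
conditions the held-out median correlation to ground truth rises from
roughly 0.2 (raw WBP input) to above 0.9, the wedge occupancy of restored
particles increases for essentially all held-out particles, and all 8
tomogram particles are recovered within 2 voxels with uniformly higher
peak correlations than on the raw tomogram.

The generator emulates the degradations that matter — missing wedge, CTF
with phase flipping, white noise at realistic variance ratios, continuous
conformational heterogeneity, random orientation — and omits others found
in real data: structured/correlated noise, defocus gradients and tilt-
dependent thickness, alignment errors, radiation damage, molecular
crowding, and model mismatch between template and specimen. Passing the
desk-scale suite therefore demonstrates the machinery is correct and that
knowledge transfer works under its stated assumptions; it does not by
itself establish performance on any particular real dataset, for which
the full-scale preset, more pairs and longer training are the intended
route.

## Known limitations

* CPU-only training: the full-scale preset is provided and correct but
  slow without substantial compute; desk-scale sizes are the supported
  fast path.
* Constant defocus per tilt; no dose weighting or motion model.
* Template matching uses plain NCC; heavily wedge-limited *raw* volumes
  are better matched after restoration (which is the package's point) or
  with external wedge-aware tools.
* Strategy-1 targets are taken as the corrected average (the
  `ctf_match_target` question is resolved in favor of the corrected map;
  an `inverse` flag covers the opposite transform convention used by some
  subtomogram-averaging packages).
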