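---
title: "Simulating and reconstructing vascular MR fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing vascular MR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MR vascular fingerprinting estimates sub-voxel microvascular properties —
blood volume fraction (BVf, %), mean vessel radius (R, µm), blood oxygen
saturation (SO~2~, %) and tissue T~2~ (ms) — from the evolution of the MR
signal in each imaging voxel. A gradient-echo sampling of the FID and spin
echo (GESFIDSE) is acquired once before and once after injecting an
ultrasmall superparamagnetic iron oxide (USPIO) contrast agent; the two echo
trains are concatenated into a per-voxel *fingerprint*. A dictionary of
simulated fingerprints, generated over many voxel-scale vascular geometries
and parameter combinations, is then searched (dictionary-based matching,
DBM) or inverted with a learned Bayesian regression (dictionary-based
learning, DBL) to produce parametric maps.

`vascmrf` implements the whole chain: voxel geometry generation, the Fourier
dipole-kernel field solver, the diffusing-isochromat GESFIDSE simulator,
scrambled-Sobol parameter sampling, dictionary construction and persistence,
both reconstruction routes with the physical clipping rules, phantom
generation, ROI statistics, and an end-to-end pipeline.

## Forward model

### Voxel geometries

A voxel is a periodic binary occupancy grid (1 = intravascular) with
micrometre spacing. Three generator families mirror the three dictionary
types:

* **2D disks** (`make_disk_voxel()`): disks of one fixed radius placed
  uniformly at random with periodic wrap, the historical 2D representation.
* **3D cylinders** (`make_cylinder_voxel()`): infinite straight cylinders,
  isotropically oriented, radii drawn from a per-voxel law.
* **Stochastic networks** (`grow_network_voxel()`): tortuous, branching
  capsule chains grown as persistent random walks, a stand-in for
  microscopy-derived voxels. It emulates the *statistics* (BVf, radius
  distribution, tortuosity, branching) of real cortical networks, not their
  anatomy — no flow-consistent topology, no arteriole/venule hierarchy, no
  spatial correlation between neighbouring voxels. Per-segment labels
  support a distributed-oxygenation mode in which each vessel segment gets
  its own SO~2~.

Shapes may overlap; occupancy is the union, which keeps BVf well defined.
Generators add structures until the realized BVf lies within
`max(0.05 pp, 2 % relative)` of the target, rejecting a structure that
overshoots the band and redrawing, with a bounded retry count. For network
growth the running BVf moves in capsule-sized increments, so growth simply
stops once it enters the band. At small grid volumes some (BVf, R)
combinations are geometrically infeasible — realized BVf is quantized by
whole structures — in which case the generators fail explicitly and the
dictionary builder re-draws the target pair, mirroring the fact that
cylinder generation cannot accommodate every combination.

`characterize_voxel()` measures BVf by voxel counting (exact by
construction) and the mean radius as half the mean *minimum Feret diameter*
of per-slice 2D connected components: a tilted vessel's cross-section is an
ellipse whose short axis is the true diameter, so the minimum caliper width
is insensitive to in-plane orientation. Components under 5 cells are treated
as rasterization noise. Detections are averaged with a plain (not
length-weighted) mean over all slices; the aggregation is a documented
choice. `erode_voxel()` applies 6-connected (3D cross) erosion with
periodic boundaries to augment a geometry set towards lower BVf, as done
when thinning segmented microscopy volumes.

### Susceptibility and field

Intravascular cells carry a susceptibility offset

> Δχ = Δχ~deoxy~ · Hct · (1 − SO~2~/100) + Δχ~CA~

with defaults Δχ~deoxy~ = 3.318 ppm (SI, per unit haematocrit, fully
deoxygenated), Hct = 0.42, and Δχ~CA~ = 0.5 ppm after contrast injection —
a standard literature magnitude for steady-state USPIO at vessel-size-
imaging doses, of the same order as the deoxygenation term (0.14–0.91 ppm
across SO~2~ ∈ [35, 90] %). Absolute SO~2~ estimates scale with these
constants, so all are exposed in `physics_constants()`.

The field solver multiplies the susceptibility spectrum by the k-space
dipole kernel `1/3 − (k·b̂)²/|k|²` (B~0~ = 4.7 T along `b̂`), with periodic
boundaries and the k = 0 term set to zero: the mean offset only rotates the
rotating frame and is invisible to magnitude signals. No Lorentz correction
beyond the 1/3 term is applied. For 2D disk voxels the in-plane kernel
`1/2 − (k·b̂)²/|k|²` with B~0~ in-plane is used; its exterior field equals
the perpendicular-cylinder closed form, and its interior constant differs
from the 3D convention only by a uniform offset that magnitude signals
cannot see. Output is an angular-frequency offset in rad/s.

### GESFIDSE signal

The isochromat simulator starts with uniform transverse magnetization and,
per step `dt`, applies the static phase `exp(i·δω·dt)`, then diffusion as a
per-axis convolution of the complex magnetization with a Gaussian kernel of
standard deviation `sqrt(2·ADC·dt)` (ADC = 1000 µm²/s), with periodic wrap
to match the field solver. An ideal instantaneous 180° pulse conjugates the
phase at SE/2 = 30 ms. The signal is the magnitude of the spatial mean at
each echo, times `exp(−t/T2)`: transverse relaxation is a uniform scalar
that commutes with every other operator, so it is applied analytically.
This makes the pure-relaxation limits exact — with δω ≡ 0 every echo equals
`exp(−t/T2)` to rounding, and with ADC = 0 the spin echo refocuses static
dephasing exactly — which the tests exploit as closed-form oracles.

Numerical choices:

* **Step size.** `dt` must divide both the echo spacing (3.3 ms) and the
  refocusing time (30 ms); the default is 0.1 ms, and dictionary builds use
  0.3 ms, the largest admissible divisor, which keeps the per-step phase
  below π/4 for all physiological Δχ at 4.7 T (the simulator refuses to run
  otherwise, naming the required step).
* **Diffusion kernel.** When the per-step displacement σ is smaller than
  the cell size, a sampled Gaussian is a poor quadrature; the solver then
  uses the variance-matched 3-point stencil `(w, 1−2w, w)`,
  `w = σ²/(2h²)` — the classical explicit diffusion stencil, whose
  composition over many steps tends to the correct Gaussian. Taps are
  normalized to sum exactly to one so a uniform magnetization is preserved
  to machine precision. For 2D voxels diffusion and dephasing act in-plane
  only.
* **Echo placement.** Echo *i* is read at `i·ΔTE`; with the default timing
  the echoes span 3.3–105.6 ms and the spin echo at 60 ms falls between
  echoes 18 and 19. The exact placement convention is not uniquely
  determined by the acquisition description and is documented here.

Fingerprints are the concatenated pre/post-contrast echo trains, jointly
L2-normalized (`make_fingerprint()`); the removed norm is kept for
diagnostics. The simulator itself adds no noise — noise is the phantom and
reconstruction modules' concern.

## Dictionaries

`make_dictionary()` draws (BVf, R) targets and (SO~2~, T~2~) samples from a
scrambled Sobol series — SO~2~ ∈ [35, 90] %, T~2~ ∈ [45, 110] ms, one pair
per geometry, all dimensions sampled jointly from one series (the
alternative of two independent 1D series is not used; the joint design is
the documented choice). The Sobol generator is built in (direction numbers
with a seeded random digital shift as the scrambling); no quasi-random
package is assumed. Because the induced field is linear in susceptibility,
each geometry needs a single unit-susceptibility dipole solve, rescaled for
the pre- and post-contrast states, followed by two signal simulations. The
parameter table records the *measured* BVf and mean radius of each
geometry, not its targets. Dictionaries persist to a versioned single-file
container (`save_dictionary()` / `load_dictionary()`), with lossless
round-trips and refusal of corrupt or mismatched files.

Desk-scale problem sizes, chosen as the package's defaults: dictionary
voxels of 32 × 32 × 48 cells at 2.5 µm (80 × 80 × 120 µm³) and 2,000-entry
dictionaries for the cylinder family. These run the full acceptance
analysis in minutes on one core. The realistic-network family needs far
larger dictionaries before estimates stabilize (see *Limitations*).

## Reconstruction

**DBM** (`dbm_match()`) computes the dot product of the L2-normalized query
with every dictionary entry and returns the parameters of the best match,
ties broken by lowest row index. Estimates therefore sit on the dictionary
grid, and their error cannot fall below the grid quantization.

**DBL** (`dbl_train()` / `dbl_predict()`) fits a Gaussian locally linear
mapping: a K-component joint mixture in which component *k* carries a
Gaussian over parameters and an affine parameter→signal map with isotropic
residual noise, estimated by EM in the parameter→signal direction and
inverted analytically. The posterior over parameters given a fingerprint is
again a Gaussian mixture; its mean is the estimate and its standard
deviation the reported uncertainty. Defaults: K = 50, EM tolerance 10⁻⁶
relative log-likelihood, 200 iterations maximum, k-means initialization
under a fixed seed, jittered restarts on degeneracy. The isotropic
per-component noise (the standard "iso" GLLiM variant) was preferred over a
diagonal or low-rank structure: with 2,000 rows and K = 50, a diagonal
signal covariance alone would add 64 free parameters per component and
destabilize EM. Parameters are standardized internally; queries are *not*
re-normalized at prediction time — they must be preprocessed exactly like
the training signals, which fingerprints already are.

Estimates are clipped to physical ranges (`clip_estimates()`): BVf and
SO~2~ to [0, 100] %, R to [0, 250] µm, T~2~ to 0 ms on the lower end only.
Flags record which bounds fired; clipping is idempotent.
`reconstruct_maps()` applies either route voxelwise, leaves masked voxels
as `NA` (never 0), and keeps the match score / posterior sd as a quality
sidecar.

## Phantoms, ROI statistics, pipeline

`make_phantom()` builds a synthetic acquisition through the full forward
chain: every image voxel gets its own fresh geometry realization at its
region's nominal (BVf, R), white Gaussian noise is added to the raw
magnitude samples before normalization — SNR defined on the first
pre-contrast echo — and the ground truth records both nominal and measured
values. The default layout emulates a hyperaemic "tumour" block inside
"contralateral" tissue. Region parameters outside the dictionary ranges
warn rather than fail, because DBL can extrapolate.

`roi_compare()` averages voxels per unit (animal/phantom) first and runs a
two-sided two-sample t-test on the per-unit means (Student by default,
Welch available). Pooled-voxel testing is deliberately not the default: it
treats correlated voxels as independent samples and inflates significance.
Whether the original analyses used Student or Welch is not stated anywhere;
Student is the documented default. `run_pipeline()` chains everything,
stamps every artifact with a content hash of the configuration, writes a
JSON-lines log, and fails cleanly — naming the missing artifact — when a
stage's input is absent.

## What the synthetic data do and do not show

The generators reproduce the study conditions that matter to the method:
voxel-scale binary vascular occupancy, the GESFIDSE timing (TR 4000 ms, 32
echoes, ΔTE 3.3 ms, SE 60 ms), pre/post-contrast concatenation, the Sobol
parameter coverage, and plausible BVf (≈0.5–25 %) and radius (≈2–12 µm)
ranges. They do not reproduce real microscopy anatomy, flow, exchange,
slice profiles, myelin or air–tissue background fields, or in-vivo noise
correlations. Passing tests therefore validate the numerics and the
estimation machinery, not in-vivo accuracy.

One genuinely physical effect dominates the desk-scale error budget:
**realization variability**. Two independent cylinder configurations with
identical (BVf, R, SO~2~, T~2~) differ in fingerprint space by ≈0.045
(unit-norm L2) at the 80 × 80 × 120 µm³ voxel volume — more than the
fingerprint moves when SO~2~ changes by 10 pp (≈0.037) or T~2~ by 5 ms
(≈0.019). With only ~5–20 cylinders per voxel, the orientation and overlap
configuration is a strong confounder; the scatter scales roughly with
1/√(voxel volume) and becomes small at full 248 × 248 × 744 µm³ voxels.
Consequences at desk scale: held-out noiseless recovery errors plateau near
the realization floor (so the tightest recovery gates in the acceptance
suite are expected to stay red, with DBL still strictly beating DBM's
quantization error), and exact-row recovery under SNR-50 noise saturates
below 99 % because the noise norm exceeds the nearest-row spacing. This is
the same phenomenon reported for small realistic dictionaries — signal
patterns vary between voxels with similar vascular parameters — and it is
why the acceptance analysis reports these quantities rather than hiding
them.

## Limitations

* Cylinder rasterization uses minimum-image distances, an approximation to
  the exact periodic union of images; it is exact whenever the radius is
  small relative to half the voxel extent, as here.
* Min-Feret measurement is biased by about one grid spacing for vessels
  thinner than ~3 cells and mis-measures components that wrap across the
  periodic boundary in a slice; both effects are visible in the measured
  radius columns of coarse-grid dictionaries.
* The realistic-network generator matches first-order statistics only; its
  dictionaries inherit the small-dictionary instability noted above.
* The 2D kernel convention, echo placement, SO~2~/T~2~ joint sampling, the
  radius aggregation rule, and the Student-vs-Welch default are all choices
  on points the acquisition description leaves open; each is documented
  where it is made and exposed in configuration.
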