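---
title: "Signal model and reconstruction methods in fsc3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal model and reconstruction methods in fsc3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsc3d)
```

## The imaging problem

fsc3d models a label-free 3D forward-scattering (dark-field) imaging flow
cytometer. Cells flow single-file along the y axis at speed $v_y$ while a
needle-shaped Gaussian laser beam of waist $w$ is swept along x as an ideal
sawtooth at the scan rate $1/T$. A stack of micro-mirrors routes forward-
scattered light from $N$ axial focal planes $z_j$ onto $N$ PMT channels, so
each digitizer sample encodes one voxel: x from the instantaneous beam
position, y from the flow displacement between scans, z from the channel.

The channel-$i$ time series for a scatter intensity field $f$ is

$$P_i(t) = \sum_j \iint \mathrm{d}x\,\mathrm{d}y\;
  M_{ij}(y)\, e^{-2y^2/w^2}\, f(x, v_y t, z_j)\,
  e^{-2(x - x_n(t))^2/w^2},$$

with $x_n(t) = v_x (t - T/2 - nT)$ the centered scan ramp and $M_{ij}(y)$ the
crosstalk matrix coupling scatter from plane $z_j$ into channel $i$ (diagonal
when the mirror assignment is perfect; in practice the off-diagonal entries
are nonzero). At the default operating point $v_x = 8$ m/s,
$T = 5\,\mu$s, $w = 3\,\mu$m, $v_y = 0.16$ m/s, eight planes spaced
2.5 µm give a 40 × 40 × 20 µm field of view.

Both the simulator (`simulate_signals()`) and the reconstructor
(`reconstruct_volume()`) share this model through `fsc_config()` and
`crosstalk_model()`. Scenes are incoherent point-scatterer sets
(`scatter_scene()`); intensities add, there is no phase or speckle.

## Reconstruction

Because $v_x / v_y = 50$, the object's y position is approximately frozen
during one scan ("frozen-y"). Reconstruction proceeds in four steps:

1. **Demultiplex** (`demultiplex()`): sample $k$ of scan $n$ on channel $i$
   becomes pixel (row $n$, column $k$) with pixel sizes
   $\Delta x = \mathrm{scan\ range}/S$ and $\Delta y = v_y T$
   (0.625 µm and 0.8 µm at the defaults).
2. **Beam deconvolution along x** (`deconvolve_x()`): each row's spectrum is
   multiplied by the regularized inverse of the beam transfer function
   $H(k_x)$. Under the ordinary-frequency Fourier convention the transform of
   $e^{-2x^2/w^2}$ is $\propto e^{-\pi^2 w^2 k_x^2/2}$, so the ideal gain is
   $e^{+\pi^2 w^2 k_x^2/2}$; since that gain explodes at high $k_x$, the
   package applies the Wiener form $(1+\varepsilon) H / (H^2 + \varepsilon)$
   with $\varepsilon = 10^{-3}$ by default (the $1+\varepsilon$ factor keeps
   the DC gain exactly 1). $H$ itself is computed as the unit-DC-normalized
   DFT of the pixel-sampled beam profile: at the shipped sampling this equals
   the analytic Gaussian transfer to within $e^{-28}$, it remains the exact
   discrete transfer when the beam is coarsely sampled, and it tends to 1 as
   $w \to 0$.
3. **Axial unmixing per flow-axis frequency** (`invert_axial()`): the y-FFT
   of the deconvolved stack, $V_i(x, k_y)$, relates to the per-plane fields
   through $U_{ij}(k_y) = \mathcal{F}_y\{M_{ij}(y) e^{-2y^2/w^2}\}$
   (`build_u_spectrum()`), an $N \times N$ linear system at every $k_y$.
4. **Inverse y-FFT and calibration**: volumes are scaled by
   $\Delta x\,\Delta y / \hat g(0)$ so an isolated unit scatterer integrates
   to about one; planes are ordered by ascending $z_j$.

Rows are zero-padded to the next power of two past the kernel support
(≈ $6w$) before the y-FFT so the circular convolution never wraps. For
records simulated with continuous flow motion, the known sub-row offset of
column $k$ ($v_y t_k$, up to one row across a scan) is removed with an exact
per-frequency phase before unmixing; records simulated under the frozen-y
assumption carry no such offset.

### Regularizing the axial unmixing

When $M$ does not depend on y (the parametric `diagonal` and
`nearest_neighbor` modes) the system factorizes, $U(k_y) = M\,\hat g(k_y)$,
and the package inverts $M$ exactly — as the bare $U^{-1}$ reconstruction
formula does — while regularizing only the scalar deconvolution
$\hat g / (|\hat g|^2 + \lambda\,|\hat g|_{\max}^2)$ with relative ridge
$\lambda = 10^{-6}$ by default. This choice is deliberate: a full-matrix
Tikhonov ridge shrinks the eigencomponents of $M\hat g$ unequally in the
transition band around the regularization cutoff, and for a point scatterer
(flat y spectrum) that leaks roughly $0.08\,\varepsilon$ of a single-plane
response into the adjacent planes — a few percent ghost at realistic
couplings. Exact channel unmixing removes the coupling to machine precision
(measured ghost ratios $\sim 10^{-15}$) while the scalar ridge still tames
the unbounded deconvolution. For tabulated, y-dependent $M$ the system does
not factorize and the package falls back to Tikhonov least squares
$(U^H U + \lambda\,\sigma_{\max}^2 I)\,f = U^H V$ per $k_y$, with
$\sigma_{\max}$ the *global* largest singular value over all $k_y$ — a
per-frequency relative ridge would amplify model mismatch where the Gaussian
envelope vanishes.

With `ridge = 0` the exact inverse is attempted and a $U(k_y)$ singular to
machine precision is a hard error naming the offending frequency; the same
logic guards the exact beam inverse (`epsilon <= 0`), which is refused on
data carrying energy where the ideal gain exceeds `max_gain`.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `scan_rate` | 200e3 | Hz | sawtooth repetition rate; $T = 1/$`scan_rate` |
| `scan_range` | 40 | µm | sweep length; $v_x =$ range$/T$ |
| `beam_waist_w` | 3 | µm | Gaussian $w$ of $e^{-2r^2/w^2}$; sets x/y resolution |
| `flow_speed_vy` | 0.16 | m/s | flow speed; y pixel $= v_y T$ |
| `n_channels` | 8 | – | detection planes / PMTs |
| `plane_spacing` | 2.5 | µm | z pitch; axial FOV $= N \times$ spacing |
| `sample_rate` | 64/T | Hz | digitizer rate; 64 samples per scan |
| `epsilon` | 1e-3 | – | Wiener level of the x deconvolution |
| `ridge` | 1e-6 | – | relative ridge of the axial unmixing |

A configuration warns when $v_x / v_y < 10$, where the frozen-y
approximation (and hence the demultiplexing geometry) degrades. The forward
error between exact-motion and frozen-y simulation scales linearly with
$v_y/v_x$; the acceptance script verifies a ratio of ≈ 10 between the
operating regime (1/50) and a ten-fold slower flow.

## What the phantoms emulate — and what they do not

- `grid_phantom()`: k point scatterers per focal plane with a minimum
  in-plane separation; xy positions are random under a fixed seed because
  only counts and intensities of the reference objects are published, not
  coordinates.
- `terrace_phantom()`: a printed staircase (default 35 × 8 µm² terraces,
  2.5 µm steps, 1.5 × 1 × 1 µm³ bumps) represented by point scatterers at
  bump centers and terrace edges.
- `bead_shell_phantom()`: a porous bead as a uniform spherical shell of
  surface scatterers plus Poisson-distributed interior "pores".
- `cell_phantom()`: weak cytoplasmic scatterers inside a sphere plus strong
  surface beads; the bead-to-cytoplasm intensity ratio (default 5) is a free
  parameter standing in for the refractive-index contrast between
  polystyrene, cytoplasm and buffer — the package does not compute Mie
  cross-sections from indices.

Passing round-trip tests on these phantoms demonstrates that the inverse
computation is consistent with the forward model under its own assumptions —
ideal sawtooth, parametric Gaussian beam with no axial divergence, incoherent
point scatter, known crosstalk. They do not establish performance on real
detector data, where $M$ must be measured or ray-traced, the beam deviates
from Gaussian, and shot noise is present (available via `add_noise()` but
disabled in the reference reproductions, which are noiseless by design).

## Numerical and design choices

- **Fourier convention.** Ordinary frequency ($e^{-2\pi i k x}$): the only
  convention under which the printed inverse filter
  $e^{+\pi^2 w^2 k_x^2/2}$ exactly inverts the beam's transform.
- **Axial response.** By default a scatterer is assigned wholly to its
  nearest plane; setting `axial_psf_sigma` spreads it across planes with a
  Gaussian weight, a parametric stand-in for the instrument's axial PSF.
- **z-plane centering.** Planes are placed symmetrically about $z = 0$,
  making phantoms and metrics sign-convention free.
- **Negatives.** Deconvolution ringing can be negative; values are kept
  signed through the pipeline and clipped only at thresholding/rendering
  (`threshold_volume()`), because clipping before peak metrics biases
  localization.
- **Peak detection.** Candidate maxima are found per plane (8-neighbourhood
  in x, y) and then pruned by greedy non-maximum suppression at a physical
  3-d distance. The z pitch is ~4× the xy pitch, so an index-space
  26-neighbourhood would let a bright peak on an adjacent plane suppress a
  genuine one several micrometres away.
- **Peak strength.** When comparing peak amplitudes (the graded-intensity
  reproduction), `peak_amplitudes()` integrates the volume over a small ball
  (default radius 2.5 µm; 2 µm in the shipped analyses, below both the peak
  separation and the plane spacing). The single peak-voxel value varies by
  tens of percent with the sub-voxel phase of a point scatterer; the local
  integral is shift-invariant.
- **Detection threshold.** The reference reproductions detect at 0.2 of the
  volume maximum with 2 µm minimum separation: unmixed ghosts sit below 2 %
  while true peaks stay above ~40 % even at worst-case sub-voxel phase, so
  0.2 separates the classes with margin. The package-wide default is 0.5
  with 1.5 µm separation; both are exposed parameters.
- **Flow-speed compensation.** `compensate_flow_speed()` is a plain linear
  rescaling of the y axis by $v_{y,\mathrm{actual}}/v_{y,\mathrm{nominal}}$;
  it restores aspect ratio for constant-speed errors but is only an
  approximation to a full treatment of within-record speed variation.
- **Resampling.** `resample_volume()` is separable (trilinear)
  interpolation, extent-preserving; the conventional rendering size is
  200 × 200 × 100.

## Verification design

Three independent routes check the pipeline:

1. **Closed forms**: the sawtooth geometry, the single-scatterer signal, and
   $U_{jj}(k_y) = w\sqrt{\pi/2}\,e^{-\pi^2 w^2 k_y^2/2}$ for diagonal
   crosstalk are asserted against analytic expressions.
2. **A dense brute-force operator** (`build_dense_operator()`): column $v$
   is the simulated signal of a unit impulse in voxel $v$. Applying it to a
   voxelized scene must reproduce the simulator exactly, and Tikhonov least
   squares against it must agree with the FFT pipeline. The shipped
   comparison uses a 12 × 12 × 4 grid at the demultiplexed pixel pitch,
   frozen-y records (so both routes invert the same model; the motion error
   is measured separately), a smoothly windowed band-limited scene, and a
   narrower verification beam ($w = 1.2$ µm, 4 channels). The narrow beam is
   a verification-design choice: at $w = 3$ µm a 7.5 µm-wide grid's corner
   spatial-frequency modes are numerically null and no double-precision
   ridge lets two differently parameterized regularizers agree there; at
   $w = 1.2$ µm the whole discrete band is well conditioned and the routes
   agree to ~$10^{-9}$ relative L2 (bound asserted: $10^{-4}$).
3. **End-to-end reproductions** at the full instrument scale (8 planes,
   64 samples per scan): 2 scatterers per plane recovered with recall and
   precision 1 within one voxel; 5 graded intensities per plane recovered in
   exact rank order; a 25 µm shell phantom sized to 25 ± 3 µm over five
   seeds; ghost responses ≤ 2 % after unmixing (measured ~$10^{-15}$ for
   parametric crosstalk).

Problem sizes throughout (64 × 64 in-plane sampling, ≤ 12 × 12 × 4 dense
grids, 5 bead seeds, ~300–400 scatterers per phantom) were chosen as the
smallest at which each property is meaningfully exercised; every suite runs
in seconds on one CPU.

## Known limitations

- The crosstalk matrix is an input (parametric or tabulated), never derived
  from mirror geometry; real instruments must measure or ray-trace it.
- The axial PSF is parametric (delta or Gaussian); the supplementary physics
  of angular collection is out of scope.
- No iterative reconstruction (Richardson–Lucy, ADMM) and no streaming mode;
  the pipeline is a direct Fourier method.
- The PMT record container is a plain-text CSV + JSON pair, and volumes are
  written as normalized 32-bit float multi-page TIFF with the affine
  intensity scale and voxel sizes in a JSON sidecar rather than full
  OME-XML.
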