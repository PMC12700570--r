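# fsc3d

Forward simulation and spatiotemporal reconstruction for **3D
forward-scattering imaging flow cytometry** (3D dark-field IFC).

In this modality, cells flow single-file along *y* at speed *v<sub>y</sub>*
while an acousto-optically scanned needle beam (Gaussian waist *w* ≈ 3 µm,
long depth of focus) sweeps along *x* as a 200 kHz sawtooth. A micro-mirror
array routes forward-scattered light from *N* axial focal planes
*z<sub>j</sub>* onto *N* PMT channels, so every digitizer sample encodes one
voxel — *x* from the instantaneous beam position, *y* from the flow
displacement between scans, *z* from the channel. The recorded channel
signals follow

P<sub>i</sub>(t) = Σ<sub>j</sub> ∬ dx dy M<sub>ij</sub>(y) e^(−2y²/w²)
f(x, v<sub>y</sub>t, z<sub>j</sub>) e^(−2(x−x<sub>n</sub>(t))²/w²),

where x<sub>n</sub>(t) = v<sub>x</sub>(t − T/2 − nT) is the scan law and
M<sub>ij</sub>(y) the crosstalk matrix coupling plane *j* into channel *i*.
The package implements both directions of this relation:

- **Forward**: `scatter_scene()` + `fsc_config()` + `crosstalk_model()` →
  `simulate_signals()` → a multi-channel PMT record (with optional Poisson /
  Gaussian noise), plus a brute-force dense operator
  (`build_dense_operator()`) as an independent oracle.
- **Inverse**: `reconstruct_volume()` = demultiplexing (`demultiplex()`) →
  Wiener-regularized Gaussian beam deconvolution along the scan axis
  (`deconvolve_x()`, ideal gain e^(+π²w²k<sub>x</sub>²/2)) → per-spatial-
  frequency axial crosstalk unmixing against
  U<sub>ij</sub>(k<sub>y</sub>) = F<sub>y</sub>{M<sub>ij</sub>(y)e^(−2y²/w²)}
  (`build_u_spectrum()`, `invert_axial()`) → a calibrated 3D volume.
- **Phantoms** replicating the standard validation objects: multi-plane
  point grids, terraced microstructures with bumps, porous bead shells, and
  cells with surface microbeads (`grid_phantom()`, `terrace_phantom()`,
  `bead_shell_phantom()`, `cell_phantom()`).
- **Metrics**: peak detection with non-maximum suppression, greedy matching
  against ground truth, size estimation, ghost/crosstalk suppression ratios
  (`detect_peaks()`, `match_peaks()`, `estimate_diameter()`,
  `crosstalk_suppression()`).
- **I/O and CLI**: scene CSV + JSON, PMT records as CSV + JSON, volumes as
  float multi-page TIFF with voxel-size metadata, and a
  `phantom / simulate / reconstruct / evaluate` command line (`fsc_cli()`,
  shipped as `exec/fsc3d`).

It is aimed at instrument builders and computational microscopists who need
a testable, ground-truthed model of the time-to-space mapping before (or
instead of) touching hardware.

## Worked example

Two point scatterers on each of the eight focal planes, nearest-neighbour
channel crosstalk of 0.2, noiseless — the canonical simulation study:

```r
library(fsc3d)

cfg <- fsc_config()            # 200 kHz over 40 um, w = 3 um, vy = 0.16 m/s
cfg
#> <fsc_config>
#>   scan: 200 kHz over 40 um  (vx = 8 m/s, T = 5 us)
#>   beam waist w = 3 um; flow vy = 0.16 m/s
#>   8 channels, plane spacing 2.5 um (axial FOV 20 um)
#>   sample rate 12.8 MHz (64 samples per scan)

sc  <- grid_phantom(k_per_plane = 2, n_planes = 8, seed = 11)
xt  <- crosstalk_model("nearest_neighbor", epsilon = 0.2)
rec <- simulate_signals(sc, cfg, xt)
rec
#> <pmt_record: 8 channels x 3328 samples @ 12.8 MHz>

vol <- reconstruct_volume(rec)
vol
#> <volume3d: 52 x 64 x 8 (y,x,z), voxels 0.8 x 0.625 x 2.5 um>

peaks <- detect_peaks(vol, threshold = 0.2, min_separation = 2)
head(peaks$peaks, 4)
#>   plane    x_um        y_um  z_um amplitude
#> 1     8 -11.250  -2.9844506  8.75 0.2166478
#> 2     7 -13.125  -0.5844506  6.25 0.2165545
#> 3     1  -6.875 -14.9844506 -8.75 0.2145872
#> 4     2 -12.500  -6.1844506 -6.25 0.2137840

mt <- match_peaks(peaks, sc, max_dist = 2)
sprintf("recall %.2f, precision %.2f, worst localization error %.2f um",
        mt$recall, mt$precision, max(mt$distances))
#> "recall 1.00, precision 1.00, worst localization error 0.51 um"
```

All 16 ground-truth scatterers are recovered (two peaks on every plane) to
within one voxel, with ghost responses from the 20 % channel coupling removed
by the axial unmixing. Peak `amplitude` is in calibrated scene-intensity
units — the scatterers here have unit intensity and the residual ~0.21 peak
voxel value reflects the regularized band limit, not a miscalibration; use
`peak_amplitudes()` for shift-invariant strength estimates.

The same workflow from a shell (the `fsc3d` script lives at `inst/exec/` in
the source tree and under `system.file("exec", package = "fsc3d")` once
installed):

```sh
Rscript inst/exec/fsc3d phantom grid --k 2 --planes 8 --seed 11 --out scene
Rscript inst/exec/fsc3d simulate --scene scene --out rec \
        --crosstalk nearest_neighbor --epsilon 0.2
Rscript inst/exec/fsc3d reconstruct --record rec --out vol.tif \
        --resize 200 200 100 --peaks
Rscript inst/exec/fsc3d evaluate --volume vol.tif --truth scene --out report.json
```

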