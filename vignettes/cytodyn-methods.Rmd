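---
title: "cytodyn: models, parameters and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytodyn: models, parameters and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cytodyn quantifies microglial cytoskeletal and synaptic dynamics from
fluorescence microscopy: molecular diffusion by raster image correlation
spectroscopy (RICS), F-actin flow by particle image velocimetry (PIV),
lamellipodial remodelling by covered-area analysis, cell morphology by 3D
skeleton morphometrics, and synapse turnover by puncta colocalization and
engulfment scoring. This vignette explains each model, the tunable
parameters and their defaults, what the synthetic generators do and do not
emulate, and the numerical choices that were genuinely open.

## RICS: diffusion from raster-scan correlations

A confocal raster scan samples pixel $(x, y)$ of frame $f$ at time
$t = f\,\tau_{frame} + y\,\tau_l + x\,\tau_p$. Because the scan embeds a
time axis into the image, the spatial autocorrelation of the (detrended)
intensity encodes diffusion. `arbitrary_region_acf()` computes

$$G(\xi,\psi) = \frac{\langle \delta I(x,y)\,\delta I(x+\xi, y+\psi)
\rangle}{\langle I \rangle^2},$$

where the averages run over all pixel pairs with *both* endpoints inside a
user mask (so nuclei or neighbouring cells can be excluded), $\delta I$ is
the per-frame deviation from the masked mean, and the normalisation uses
the frame-averaged masked mean. The implementation zero-fills the masked
images, correlates them by FFT, and divides by the mask's own
autocorrelation — the exact per-lag pair count — which is algebraically the
direct pair sum at $O(n \log n)$ cost. The test-suite retains a
quadruple-loop implementation as an oracle and requires agreement to
1e-12.

`fit_rics()` fits the 2D free-diffusion model with a Gaussian focus,

$$G(\xi,\psi) = \frac{\gamma}{N}
\left(1 + \frac{4D|\xi\tau_p + \psi\tau_l|}{\omega_r^2}\right)^{-1}
\exp\left[-\frac{\delta_r^2 (\xi^2 + \psi^2)}
{\omega_r^2 + 4D|\xi\tau_p + \psi\tau_l|}\right] + \text{offset},$$

with shape factor $\gamma = 2^{-3/2}$ fixed, by weighted nonlinear least
squares on $(\log D, \log N, \text{offset})$; weights are per-lag pair
counts.

Parameters that matter:

* `pixel_size_nm` ($\delta_r$, default 50 nm), `dwell_us` ($\tau_p$,
  8.19 µs), `line_ms` ($\tau_l$, 4.92 ms), `frame_s` (1.26 s): the standard
  photon-counting acquisition this package targets.
* `waist_nm` ($\omega_r$): the lateral $1/e^2$ focus radius. It must come
  from a calibration measurement with a freely diffusing dye standard; no
  universal default is defensible, so the synthetic generators use 250 nm
  (a realistic value for a 1.2 NA water objective at 488 nm) and real
  analyses must supply their own.
* `window` of `highpass_detrend()` (default 10 frames): removes slow cell
  and organelle movement before correlation. In simulations, which contain
  no cell movement, a short window subtracts inter-frame-correlated signal
  and biases slow diffusion low; the recovery analyses therefore use
  `window = n_frames`, which degenerates to per-pixel temporal mean
  removal. For real movies the 10-frame default is a sensible compromise
  between drift removal and signal preservation.
* fit window `fit_lag_x`/`fit_lag_y` (defaults ±12 px fast axis, ±6 px
  slow axis). Diffusion information concentrates along the fast axis, but
  simulation showed that the mean-subtracted ACF carries a small negative
  bias at large fast-axis lags that the constant offset cannot fully
  absorb; at ±16/±4 this biased $D = 0.2$ µm²/s low by roughly 30% at the
  64×64/50-frame validation scale, while ±12/±6 brings the median recovery
  error to ~8% (slow) and ~4% (fast). Both half-widths remain exposed.
* The zero-lag point is always excluded: uncorrelated shot noise inflates
  $G(0,0)$ by $1/\langle I \rangle$ (a fact the tests exploit as a
  closed-form check).

Initialisation is $N_0 = \gamma / G$ at the smallest nonzero lag and a
coarse log-grid search for $D_0$; optimisation failures set
`converged = FALSE` rather than raising.

## The diffusion simulator

`simulate_diffusion_raster()` is the ground-truth engine for RICS. It
advances 2D Brownian particles *between consecutive pixel samples* (per
axis Gaussian increments of variance $2 D \Delta t$, with the true
inter-pixel, line-retrace and frame-retrace gaps), because RICS
sensitivity lives precisely in intra-line and intra-frame motion. Particles
live in a periodic box extending 3 waists beyond the field so density
stays stationary; the detected count is Poisson noise on the Gaussian-PSF
expectation (photon-counting detection, no read noise). The per-pixel mean
count obeys the closed form $B\rho\,\pi\omega_r^2/2$, which the tests check
against the simulation within Monte-Carlo error. Not emulated:
photobleaching, triplet photophysics, axial (3D) diffusion, scanner
distortion. A green recovery test therefore establishes correctness of the
estimator chain for ideal 2D diffusion, not robustness to those artefacts.

The validation scale is reduced from the acquisition standard (256×256,
≥100 frames) to 64×64 px and 50 frames so thirty simulations complete in
about half a minute; the reduction raises estimator variance but leaves the
pipeline unchanged.

## PIV of F-actin flow

`multipass_piv()` follows the standard fluorescence-PIV recipe: per-frame
contrast-limited adaptive histogram equalization (20 px tiles) and median
denoising (radius 3 px), then FFT cross-correlation in 32 px interrogation
windows (pass 1) refined at 16 px (pass 2) using the interpolated pass-1
field as predictor, then contrast and outlier filtering. Numerical
choices:

* The zero-padded cross-correlation is normalised by the per-lag overlap
  count (unbiased estimator); without this the triangular support bias
  pulls broad peaks toward zero displacement.
* Subpixel peak location uses the 3-point Gaussian fit per axis, falling
  back to a parabolic fit when a neighbour is non-positive; ties at the
  integer peak break toward the smaller displacement.
* Window deformation is first order: the frame-B window is read at the
  location shifted by the rounded predictor and the result is predictor
  plus residual. When that shift cannot be applied without leaving the
  frame — the tracked material is exiting the field of view — the vector
  is flagged invalid instead of silently measured with a clamped
  predictor.
* "Low contrast" is operationalised as a source-window intensity standard
  deviation below the field's 5th percentile (configurable); an additional
  3×3 normalized-median test (threshold 2, noise floor 0.1 px) removes
  isolated outliers.
* `mean_velocity()` converts the mean valid magnitude to nm/min via the
  pixel size and frame interval.

The phantom generator (`make_shifted_pair()`) produces smoothed broadband
speckle and displaces it in the Fourier domain (band-limited exactness;
integer shifts are literal array rolls). It emulates neither out-of-plane
motion nor intensity turnover between frames, so PIV accuracy on phantoms
is an upper bound for real F-actin movies.

## Lamellipodial coverage and density profiles

`preprocess_stack()` mirrors the classic time-lapse cleanup: radius-1
median filter, rolling-ball background subtraction (radius 30 px,
implemented as grayscale opening with a ball structuring element), then
rigid-body registration of every frame to the first (rotation by bounded
search over the phase-correlation score, translation to subpixel
precision). `binarize_lamella()` applies one global Huang threshold
computed on the temporal mean frame — one threshold per movie keeps the
lamellipodium present in all frames instead of flickering with per-frame
re-thresholding. `coverage()` counts per-interval moving pixels as the
symmetric set difference of consecutive masks and sums them over a 5-min
span. The symmetric difference is the default because both protrusion and
retraction are movement; an additions-only mode is available
(`mode = "additions"`). Note one arithmetic consequence: an object that
simply vanishes contributes exactly its area (every pixel changed state
once), whereas an object that jumps to a disjoint location contributes
twice its area.

`ctcf()` implements corrected total cell fluorescence (integrated cell
intensity minus cell area × mean background), invariant to adding a
constant. `cross_section_profile()` samples intensity along a line,
restricts to the binarized extent, rescales positions to [0, 1] and
averages into bins, normalising the profile to its own mean so shape, not
absolute brightness, is compared.

## Morphometrics

Skeletons are node/edge graphs in µm with a designated soma.
`sholl()` counts crossings by exact segment–sphere intersection (solving
the quadratic per edge), so an edge dipping through a shell counts twice
and the result is independent of edge subdivision — unlike node-distance
binning. Radii start at `step` (default 1 µm), not 0. One degenerate case
is documented rather than resolved: a node lying *exactly* on a sampled
sphere sits on a set of measure zero where the crossing count is
floating-point sensitive; synthetic tests keep branch points off the
sampled radii.

`skeleton_from_mask()` is deliberately basic (dedicated tracing algorithms
are out of scope): topology-preserving 3D thinning (simple-point peeling
with endpoint preservation), 26-neighbour adjacency, minimum spanning
tree, and spur pruning below 2 voxels. Thinning can recede each tip of a
thick bar by about one voxel; length accuracy is at the 1–2 voxel level,
sufficient for phantoms and simple cell shapes.

`motility_index()` counts newly occupied pixels per interval normalised to
cell size. Because cell size itself changes, the normalisation frame is a
flag (`t1` default, `t`, or `mean`); the index is 0 exactly when the mask
series never gains a pixel, and never exceeds 1. `process_speeds()`
classifies maximal monotone runs of the tip–soma distance as extension or
retraction; runs qualify with ≥2 steps or a net excursion ≥0.5 µm (tracking
in the source workflow is manual, so these thresholds are package choices,
both exposed).

## Puncta colocalization and engulfment

`detect_puncta()` thresholds at the top 1.10% *of pixels* (area-fraction
semantics, the convention of percent-style thresholds in common image
software; an intensity-fraction mode is provided), keeps 8-connected
components of ≥4 px, and computes intensity-weighted centroids.
`colocalize()` matches channels one-to-one greedily in increasing
centroid-distance order and admits pairs strictly below 50 nm — a pair at
exactly 50 nm does not count. On instances respecting the generator's
spacing guard (non-pair puncta at least 4× the pair distance apart), greedy
matching provably equals optimal matching; the tests verify this against a
brute-force assignment oracle. `engulfment()` counts a punctum for a cell
only if *every* footprint pixel lies inside that cell's mask — strict
containment, so boundary-straddling puncta are excluded.

The puncta generator plants cross-channel pairs at an exact distance plus
unpaired singles, renders Gaussian spots, and returns the true centroids
alongside the images; detection recovers planted centroids to well under a
nanometre at the default 20 nm rendering grid, but tests of the strict
50 nm boundary use the emitted ground truth directly, since any detector
noise at an exact boundary is undefined behaviour by construction.

## File formats and reproducibility

No TIFF library exists in the target R environment, so the package carries
a minimal baseline TIFF codec: uncompressed, little-endian, grayscale,
8/16-bit unsigned or 32-bit float, multi-page, with calibration and the
RNG seed stored as JSON in the ImageDescription tag. Interoperability is
tested against an independent reader. Skeletons round-trip through
standard 7-column SWC. Every CLI run writes a `run_config.json` sidecar
containing all parameters and the seed; rerunning with the same sidecar
reproduces the outputs byte for byte. All randomness in the generators
flows through explicit integer seeds; generator calls are pure functions
of their spec.

## Known limitations

* RICS: 2D model only (no axial diffusion, photophysics, or
  cross-correlation variants); `waist_nm` must be calibrated externally.
* PIV: first-order window deformation, no ensemble correlation; accuracy
  statements come from rigid-translation phantoms.
* Skeletonization is a thinning substitute for dedicated tracing, intended
  for phantoms and simple shapes; tips recede by ~1 voxel.
* Segmentation of cell bodies and ROIs is an input everywhere, never
  computed.
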