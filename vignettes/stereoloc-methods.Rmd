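---
title: "Depth-resolved localization microangiography with a dual-view camera pair: models and methods"
author: "stereoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved localization microangiography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Widefield fluorescence imaging through scattering tissue loses resolution
rapidly with depth, and a single camera cannot measure depth at all.
`stereoloc` implements a localization-microscopy answer for vascular
imaging: sparse, bright micro-droplets (oil droplets loaded with
short-wave-infrared quantum dots, diameter about 4.73 ± 2.25 µm) flow
through the vasculature and are imaged simultaneously by two cameras tilted
±20° about a common axis. Each droplet is a sub-diffraction point source;
fitting its image in each view gives sub-pixel centroids, the pair of
centroids triangulates to a 3D position, and compounding many tracked
droplets over time builds a super-resolved vascular volume with per-voxel
blood-flow velocities. The package provides every stage — camera model,
stereo calibration, spot localization, cross-view matching, triangulation,
track linking, velocimetry, rendering — plus a forward simulator that
generates dual-view acquisitions with exact ground truth, so the whole
chain is testable at desk scale.

# Camera model and world frame

Each camera is a zero-skew pinhole with two-coefficient radial distortion:
a camera-frame point $(X,Y,Z)$ maps to normalized coordinates
$x = X/Z,\; y = Y/Z$, is distorted by $(1 + k_1 r^2 + k_2 r^4)$ with
$r^2 = x^2 + y^2$, and lands on the sensor at
$u = f_x\,x\,d + c_x$, $v = f_y\,y\,d + c_y$. Pixels are 0-based with
centers at integer coordinates; $u$ is the column, $v$ the row; all world
coordinates are millimetres.

The canonical rig (`make_stereo_rig()`) places the world origin at the
intersection of the two optical axes, $z$ pointing away from the cameras
along the bisector (so $z$ increases with depth into the sample) and $x$
horizontal along the baseline. This makes the disparity–depth relation
explicit: for a near-axis point, displacing it by $\Delta z$ changes the
disparity by $2\sin\theta\,\Delta z / p_\mathrm{obj}$, where
$p_\mathrm{obj}$ is the object-plane pixel (pixel pitch / magnification =
15 µm / 0.37 ≈ 40.5 µm). At $\theta = 20°$ that is ≈ 1.69 px per 100 µm —
the depth encoding the whole method rests on. The default working distance
(185 mm) corresponds to a 50 mm lens at ×0.37 magnification.

Undistortion inverts the radial model by damped fixed-point iteration
(50 iterations maximum, tolerance $10^{-10}$ normalized units).
Rectification rotates both cameras to a shared orientation whose $x$-axis
lies along the baseline and whose $z$-axis is the orthogonalized mean
viewing direction; because both new axes are orthogonal to the baseline,
corresponding rectified points share the vertical coordinate *exactly* in
the noiseless case, reducing matching to a 1D search. Triangulation uses
the midpoint of the shortest segment between the two back-projected rays —
exact for noiseless input — and reports the segment length (ray gap) as a
per-point quality metric. Phantoms immersed in water have their depth
extents multiplied by the refractive index (1.33) below a flat interface;
no ray bending is modeled, matching the scalar rescaling used in practice.

# Stereo calibration

`calibrate_stereo()` is the package's one classical estimator and carries
the matching S3 surface (`print`, `summary`, `coef`, `residuals`).
Initialization is Zhang's method: plane-to-image homographies by
normalized DLT, closed-form zero-skew intrinsics from the absolute-conic
constraints, per-view poses from the homographies, and the inter-camera
pose by chordal rotation averaging of the per-view compositions. All
parameters — both intrinsic sets, both distortion pairs, the relative
pose, and every board pose (axis-angle) — are then refined jointly by
Levenberg–Marquardt on the stacked reprojection residuals
(`minpack.lm::nls.lm`, 200 iterations maximum, tolerance $10^{-10}$).
All corners are weighted equally; no outlier rejection is applied.

One identifiability caveat worth knowing: at the production geometry the
field of view spans only ≈ 0.09 in normalized radius, so the $k_2 r^4$
term moves corners by ≈ 0.01 px — far below realistic corner noise. The
recovered $k_2$ is then arbitrary even though reprojection error, focal
lengths and baseline are excellent. The parameter-recovery tests therefore
exercise a wide-angle variant of the same estimator (30 mm working
distance, normalized radii ≈ 0.5), where $k_1, k_2$ are identifiable to
±0.02; the production-geometry acceptance check uses the reprojection
error, which is the quantity the calibration protocol reports.

Checkerboard corners for image-based calibration are detected as local
maxima of the saddle response $I_{xy}^2 - I_{xx} I_{yy}$ of the smoothed
image, refined by iterating the gradient-orthogonality condition (each
gradient in a window around a saddle is orthogonal to its offset from the
corner), and ordered row-major along the lattice with the first corner
canonicalized to the one nearest the image top-left, so a board imaged
upside down yields a consistent pose.

# Localization

Per camera, the chain is: optional flat-field (non-uniformity) correction
$(I - \mathrm{offset})/\mathrm{gain}$, temporal background subtraction,
à-trous B3-spline wavelet candidate detection, and least-squares fitting
of an isotropic Gaussian plus constant over a 7×7 window.

*Background subtraction.* The static background (autofluorescence, stray
light) is estimated from the acquisition itself and subtracted from every
frame. Two estimators are available. The `mean` image is the default. The
`median` is preferable when per-pixel droplet occupancy is high: in short,
dense acquisitions on small sensors the mean contains a sharp flow-trail
ridge co-located with the spots, and subtracting it distorts fitted widths
enough to lose whole droplets; long in vivo acquisitions dilute this term.
Residuals keep their sign: clipping negatives truncates the noise
distribution, and the heavy one-sided tail of the wavelet planes then
defeats the robust noise scale (we measured an order-of-magnitude increase
in false candidates with clipping on).

*Detection.* The à-trous decomposition uses the B3-spline kernel
$[1,4,6,4,1]/16$ with dyadic holes; detection runs on plane 2, thresholded
at $k\,\hat\sigma$ with $k = 4$ and
$\hat\sigma = 1.4826\,\mathrm{MAD}$ of that plane. Strict 8-neighborhood
maxima are returned, with plateau ties broken by raster order so a spot
centred exactly between pixels still yields exactly one candidate.
The level and threshold were fixed once; they are exposed in the
configuration because real detectors are tuned per camera.

*Fitting.* The fit is rejected — not an error — when the centre leaves the
window, $\sigma \notin [0.3, r_\mathrm{win}]$ px, the amplitude is
non-positive, or the normal equations are singular. The 3 px window radius
reflects the undersampled optics: one object-plane pixel (40.5 µm) exceeds
the ≈ 27.7 µm diffraction-limited spot, so real spots span few pixels.
Localization precision follows the photon-limited $1/\sqrt{N}$ law; with a
strong uniform background the low-photon end becomes background-dominated
and the scaling steepens, so the scaling test measures the shot-noise
regime.

*Single-camera depth.* In scattering media the imaged spot grows with
depth; `diffusion_depth()` inverts a monotone $\sigma(z)$ calibration
table by interpolation, clamping (and flagging) sigmas outside the table.
Its spread is an order of magnitude worse than stereo triangulation of the
same frames — the package reproduces that comparison in its tests — which
is exactly why the dual-view geometry is the primary depth channel.

# Matching and triangulation

After rectification, spots from the same droplet share their vertical
coordinate up to localization noise. A pair is accepted iff each spot is
the *unique* candidate of the other within `y_threshold` (default 1.0 px,
about 3× the rectified residual under 0.1 px localization noise); any spot
with two or more candidates voids all its pairings, because proximity of
several droplets makes identity ambiguous. This reciprocal-uniqueness rule
never accepts a wrong-identity pair on scenes where distinct droplets are
separated by more than the threshold in rectified $v$ — the simulator can
certify that sparsity per scene (`is_sparse_scene()`), which is what makes
the identity tests exact.

Error propagation through midpoint triangulation under iid pixel noise
$\sigma_{px}$ gives axial noise
$\sigma_z = \sqrt{2}\,\sigma_{px}\,p_\mathrm{obj}/(2\sin\theta)$ and
lateral noise $\approx \sigma_{px}\,p_\mathrm{obj}/\sqrt{2}$ (both views
average), hence an axial-to-lateral spread ratio of $1/\sin\theta \approx
2.92$ at 20°. The measured in vivo ratio (3.4/1.4 ≈ 2.4 µm FWHM) sits
between this and the single-view figure $\sqrt2/(2\sin\theta) \approx
2.07$; the static-droplet test asserts the simulated ratio against both
the measured figure (25%) and the propagation oracle.

# Tracking and velocimetry

Linking is frame-to-frame optimal assignment (Hungarian-style linear sum
assignment via `clue::solve_LSAP`, gated at the max linking distance MLD,
maximizing link count then minimizing summed squared distance) rather than
greedy nearest-neighbour: it is deterministic, reduces to nearest-neighbour
in sparse scenes, and is strictly better on crossings — the test suite
checks it against brute-force enumeration for up to 8 points per frame.
MLD bounds the measurable speed at $\mathrm{MLD} \times f$: 300 µm at
40 Hz gives 12 mm/s. MLD is a *scene* parameter: it must exceed the
per-frame step ($v/f$) and stay below the smallest real inter-target gap.
The knot phantom is the canonical example — at 18 Hz and 3 mm/s the step
is 167 µm while the crossing tubes sit 231 µm apart in depth, so MLD
200 µm links correctly where 300 µm would allow identity swaps at the
crossing. Tracks shorter than `min_track_length` (default 5 frames) are
discarded as probable false connections; gap closing defaults to 0.
Velocities are displacement × frame rate per step; the axial component is
signed (positive = away from the cameras), which is what distinguishes
descending arterioles from ascending venules.

# Rendering

Tracks are rasterized into a voxel grid (default 10 µm, ≈ 3× the best
localization SD — a resolution/statistics trade-off) by sampling each
segment at half-voxel steps; visit counts are conserved and additive.
Velocity volumes store per-voxel component-wise means *and* mean speed
(mean of $|v|$), which differ under opposing flow in one voxel.
Maximum-intensity projections, depth-at-maximum maps (quantitative, mm —
colormaps are left to the caller), widefield-equivalent images (sum or max
over frames) and Gaussian-fit line-profile FWHMs support the standard
figures of the method, including the contrast between widefield blur
growth with depth and the depth-stable localization profile.

# The simulator

The simulator is first-class code generating the study conditions, not a
test fixture. Scenes: a static droplet (precision), an axially scanned
checkerboard-corner grid (5 µm steps over 3 mm; depth sensitivity), a
tilted tube (depth linear in lateral position), a knot of two crossing
arcs separated axially by the tube's 231 µm outer diameter, and a
cortical vessel network (spherical-cap surface of 5 mm radius, surface
vessels, descending/ascending penetrating vessels to 600 µm). Tube scenes
carry a lumen radius (68.5 µm, the 137 µm inner diameter): droplets get a
fixed random radial offset within the lumen, which is what makes the
reconstructed tube profile a physical width rather than a line.

Flow is a Poisson arrival process per centerline; droplets advect at
constant speed, positions are sampled at the exposure midpoint (no motion
blur: at ≤ 12 mm/s and 20 ms exposure the blur is ≤ 240 µm and ignored —
a documented limitation). Diameters are lognormal with mean 4.73 µm and
SD 2.25 µm; brightness scales with diameter cubed (encapsulated-emitter
volume).

Rendering projects each droplet through the full distortion model and
draws an isotropic Gaussian whose object-plane sigma follows
$\sigma(z) = \sigma_0 (1 + \beta\,\max(z - z_\mathrm{if}, 0))$ with
$\sigma_0 = 27.7/2.355$ µm (the diffraction limit as a Gaussian sigma) and
whose integral is attenuated as $e^{-\mu z}$; then static background,
Poisson shot noise, Gaussian read noise, 16-bit clipping. The scattering
defaults $\beta = 1.0$/mm and $\mu = 0.55$/mm are simulator choices — the
phantom experiments show qualitative blur/SNR decay without publishing
coefficients — picked once so that a 4 mm-deep target blurs severalfold in
the widefield image while remaining detectable. The rendered sigma is
floored at 0.8 px so Gaussian fitting stays well-posed despite the
physically undersampled spot; a physical mode (floor 0) exists. Identical
seeds give bit-identical ground truth and stacks.

What the simulator does *not* emulate: physical light transport (photon
Monte Carlo, speckle), motion blur, capillary arrest, sample drift,
non-Poisson sensor artifacts, and the heterogeneous scattering of real
tissue. Passing tests therefore demonstrate correctness of the
reconstruction chain under the stated forward model, not performance on
real tissue data.

# Problem sizes and numerical choices

Test and acceptance runs use reduced sensors (64×64 to 256×192 px) and
seconds-long acquisitions; these sizes were chosen so each scene yields
enough droplets for its statistic (for example ≈ 120 tracks per arc for
the knot separation, SE ≈ 5 µm against the 15 µm tolerance) while a full
run of the suite stays in the minutes range. The z-scan and calibration
replicas run at full protocol size (601 layers; 20 views). Determinism:
every stochastic step takes an explicit seed and restores the caller's RNG
state. Degenerate inputs fail loudly and early (zero baseline, behind-
camera points, non-monotone depth calibration, inconsistent acquisition
timing, unknown configuration keys); fit failures are rejections, not
errors, so one bad candidate never aborts a stack.

# Known limitations

- The matching rule discards, never resolves, ambiguity: dense scenes lose
  droplets (the temporal-correlation matching that would recover them is
  out of scope). Ghost pairs can survive when detection dropout removes
  three of the four spots of an ambiguous quartet; the track-length filter
  and MLD gating remove nearly all of them, and the robust (trimmed)
  estimators used in the geometry tests absorb the remainder.
- The refraction correction is a scalar depth rescale below a flat
  interface; curved or layered interfaces are not modeled.
- The PSF is isotropic Gaussian throughout (no astigmatism, no
  maximum-likelihood fitting).
- Single-camera diffusion depth assumes a known, monotone σ(z); in real
  tissue the curve varies spatially, which is precisely why its spread is
  large.
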