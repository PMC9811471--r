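# stereoloc

Depth-resolved super-resolution vascular imaging ("localization
microangiography") with a dual-view short-wave-infrared camera pair.

Fluorescent micro-droplets (≈ 4.7 µm oil droplets loaded with quantum
dots) flowing through vasculature are sparse point emitters. Two cameras
tilted symmetrically by ±20° image them simultaneously; `stereoloc`
localizes each droplet with sub-pixel precision in both views, pairs the
detections across the epipolar-rectified views, triangulates each pair to
a 3D position, links positions over time into trajectories, and compounds
the trajectories into a super-resolved vascular volume with per-voxel
blood-flow velocities.

The geometric heart is the disparity–depth relation of the symmetric
vergence rig: a depth change Δz moves the two projections apart by

    Δd = 2 sin(θ) · Δz / p_obj        [px]

where θ = 20° is the vergence half-angle and p_obj = pixel pitch /
magnification = 15 µm / 0.37 ≈ 40.5 µm is the object-plane pixel. Depth
precision is therefore set by localization precision (∝ 1/√N photons)
divided by 2 sin θ. Tracking uses optimal frame-to-frame assignment gated
at a max linking distance (MLD), which bounds the measurable speed at
MLD × frame rate (300 µm at 40 Hz → 12 mm/s).

The package contains the full chain plus a forward simulator with exact
ground truth (static droplets, axially scanned checkerboards, tilted-tube
and knot phantoms, cortical vessel networks; depth-dependent PSF
broadening, signal attenuation, shot and read noise), so every stage is
testable without hardware.

## Worked example

Simulate a tilted-tube phantom acquisition (tube depth rising along y at
dz/dy = 0.3, droplets at 3 mm/s, 18 Hz, 15 s) and reconstruct it:

```r
library(stereoloc)

cfg <- pipeline_config(acquisition.frame_rate_hz = 18,
                       acquisition.exposure_ms = 50,
                       acquisition.transfer_gap_ms = 1000/18 - 50,
                       localization.bg_method = "median",
                       tracking.mld_um = 250,
                       grid.voxel_size_um = 20)
unlist(derived_constants(cfg))
#> object_pixel_um   frame_rate_hz frame_period_ms  max_speed_mm_s
#>        40.54054        18.00000        55.55556         4.50000

rig   <- make_stereo_rig(optics = optics_config(sensor_size = c(128, 96)))
scene <- build_scene(scene_spec("tilted_tube", length_mm = 3,
                                dz_dy = 0.3, z_start = 0.2))
truth  <- simulate_flow(scene, flow_spec(speed = 3, rate = 1.5),
                        duration = 15, frame_rate = 18, seed = 45)
stacks <- render_stack(truth, rig, seed = 46, frame_rate = 18)

res <- run_pipeline(cfg, stacks[[1]], stacks[[2]], rig)
#> localize: 464 / 447 spots
#> match: 407 pairs (rate 0.91)
#> triangulate: 407 points
#> track: 22 tracks

mean(res$velocity_summary$v_total)
#> [1] 2.99        # mm/s; ground truth 3.00
coef(lm(z ~ y, data = res$points))[2]
#> 0.299           # recovered depth gradient; ground truth 0.300
```

The derived constants are the acquisition arithmetic (object-plane pixel,
frame rate from exposure + transfer gap, maximum trackable speed). The
pipeline messages report per-stage counts; the recovered per-track mean
speed and the depth-vs-lateral-position gradient agree with the simulated
ground truth. `res$volume` holds the compounded localization volume and
`res$velocity` the per-voxel mean-velocity maps; `mip()`,
`depth_coded_map()` and `widefield_equivalent()` produce the standard
projections.

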