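# dxblink

Analysis of time-resolved X-ray diffraction movies from protein-attached
gold nanocrystals, for experiments that watch single-molecule rotational
dynamics inside living samples:

* **DXB — diffracted X-ray blinking** (monochromatic beam). Nanocrystals
  wobble in and out of the Bragg condition, so pixels on the Au(111) powder
  ring flicker. Each pixel trace is summarised by its intensity
  autocorrelation `ACF(τ) = ⟨I(t)I(t+τ)⟩ / ⟨I⟩²`, fitted with
  `A·exp(−Γτ) + y` under the acceptance conditions `A, Γ, y > 0` and
  residual < 1. The decay constant maps to a rotational diffusion
  coefficient via `D_R = φ_θ² Γ / 4`, where `φ_θ` is the angular width of
  the analysed ring in 2θ.
* **DXT — diffracted X-ray tracking** (broadband "pink" beam). Spots stay
  lit and move; the package detects them with sub-pixel centroids, links
  trajectories (greedy nearest neighbour with gap bridging), converts them
  to Bragg-angle/azimuth tracks `(θ, χ)`, and fits Gaussians to
  angular-displacement histograms to extract the peaks `E_θ`, `E_χ`.
* **Group statistics**: the nonparametric Brunner–Munzel test (relative
  effect `P(X<Y) + ½P(X=Y)` with mid-ranks and a Welch-type t reference),
  pooled-variance Student's t, and quartile boxplot summaries.
* **A synthetic movie generator**: rotational Brownian orientation paths
  rendered through a Gaussian rocking curve onto a flat detector, with
  Poisson noise and complete ground truth — so every analysis stage is
  validated by parameter recovery. No beamline data is required anywhere.

Movies are multi-page TIFF (a minimal built-in codec; no external imaging
package needed), tables full-precision CSV, configs YAML, results JSON.

## Worked example

Simulate a blinking movie at a known rotational diffusion coefficient and
recover the decay-constant distribution. The test world is deliberately
angular-scale-inflated so that `d_rot = 0.02 rad²/s` produces blinking
resolvable at 0.2 s frames (the vignette explains the scaling):

```r
library(dxblink)

geom <- detector_geometry(energy_kev = 8.0478, distance_mm = 1,
                          pixel_pitch_mm = 0.77, beam_center = c(8.5, 8.5),
                          shape = c(16, 16))
two_theta <- bragg_two_theta(geom$wavelength, hkl = c(1, 1, 1))  # 0.6666 rad
ring <- ring_mask(geom, two_theta, phi_theta = 0.9, hkl = c(1, 1, 1))
beam <- beam_model("monochromatic", rocking_width = 0.42)

truth <- simulate_orientations(n_crystals = 200, d_rot = 0.02, dt = 0.02,
                               n_steps = 5000, seed = 1, theta0_window = 6)
movie <- render_dxb_movie(truth, geom, ring, beam, photons_per_crystal = 2000,
                          background = 0.5, exposure = 0.2, psf_sigma = 0.43,
                          psf_radius = 2, poisson = TRUE, seed = 2)
movie
#> <diffraction_movie> 16 x 16 px, 500 frames @ 0.2 s (total 1.58568e+07 counts)

dm <- decay_map(movie, ring, max_lag = "adaptive")
dm
#> <decay_map> 20 accepted / 4 rejected pixels; Gamma median 1.391 /s (IQR 0.3311-2.179)

rotational_diffusion(dm$distribution$median, ring$phi_theta)
#> [1] 0.2817233
```

The fitted median decay constant (1.39 s⁻¹) summarises how fast ring
pixels decorrelate; pixels whose fits violate the positivity or residual
conditions are excluded and counted. The last line converts it to a
rotational diffusion coefficient in rad²/s with the ring's stored `φ_θ`;
its absolute scale depends on the `φ_θ` convention (full band width here),
which is why comparative studies work with distributions and ratios. For
tracking, see `detect_spots()`, `link_trajectories()`,
`trajectory_to_angles()`, `angular_displacements()` and
`fit_gaussian_peak()`; for two-sample comparisons, `brunner_munzel()` and
`student_t()`.

A command-line interface wraps the same stages:

```sh
dxpipe simulate --config sim.yaml --seed 7 --out run/
dxpipe dxb --movie run/movie.tif --geom run/geometry.yaml --ring run/ring.tif --out run/dxb/
dxpipe dxt --movie movie.tif --geom geometry.yaml --max-disp 4 --out out/
dxpipe stats --a a.csv --b b.csv --test bm
```

Every stage writes a JSON provenance record (config, seed, versions);
rerunning from it reproduces all outputs byte-for-byte.

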