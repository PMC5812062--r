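# holoshear

Do elongated particles in the coastal ocean — chain-forming diatoms,
marine snow, detritus — align with the flow? In laminar shear a spheroid
of aspect ratio *r* rotates with the Jeffery angular velocity

ω(θ) = S/(r²+1) · (r² sin²θ + cos²θ),  T = (2π/S)(r + 1/r),

slowest when flow-aligned, so long particles dwell near the horizontal
and the dwell asymmetry grows as r². Testing this in the field takes an
in-line holographic imager (per-particle 3D position, size, aspect ratio
and orientation), a point velocimeter (shear and turbulent dissipation
via the inertial-subrange law S(κ) = C ε^{2/3} κ^{−5/3} under Taylor's
hypothesis κ = 2πf/U), and a CTD (stratification, Ri = N²/S²).

`holoshear` implements that entire measurement chain as a tested R
package, with a ground-truthed synthetic-data generator in place of the
instruments:

* **Synthetic scenes & holograms** — `make_scene()`, `render_hologram()`:
  Poisson particle fields with Junge (power-law) sizes, prescribed 3D
  orientation models (angle-uniform, Jeffery occupancy, fixed), opaque
  spheroids and cell chains, angular-spectrum diffraction at 660 nm.
* **Reconstruction & consolidation** — `reconstruct_stack()` (70 planes,
  500 μm steps over a 4 cm path), `consolidate()` (128 px sub-window
  focus selection), per-particle refocusing by local contrast.
* **Segmentation & morphometry** — `segment_composite()` (8-connected,
  ≥ 5 px), `reconnect_chains()`, `resolve_overlaps()` (convex-hull-ratio
  triage, depth-vote splitting), `measure_region()` (filled area,
  D = √(4A/π), extrema-line major axis, aspect ratio, orientation),
  `correct_orientation()` (platform pitch), `process_hologram()`
  end-to-end.
* **Particle statistics** — `concentration_profile()` (Pv = P/nV, 20 cm
  bins), `concentration_by_aspect()`, `build_psd()` + `fit_junge()`
  (log-binned 11.6–1000 μm, segmented slopes around a 250 μm knee),
  `orientation_pdf()` (nine 20° bins, r > 3, low-count flags).
* **Flow diagnostics** — `estimate_spectrum()` (Welch),
  `fit_epsilon()` (ε = [S(f) f^{5/3}/C]^{3/2} · 2π/U with a −5/3
  acceptance guard), `kolmogorov_scale()`, `batchelor_scale()`,
  `shear_profile()`, `buoyancy_frequency()`, `richardson()`.
* **Jeffery model** — `jeffery_orbit()` (RK4 + closed-form oracle),
  `jeffery_pdf()` (occupancy PDF over one period),
  `jeffery_pdf_analytic()` (exact 1/ω law), `sample_jeffery_angles()`.

## Worked example

Render a two-particle scene on a 256 px sensor, process it, and compare
with the ground truth:

```r
library(holoshear)
opt   <- optical_config(sensor_px = c(256L, 256L))
scene <- make_test_scene(2, opt, seed = 42)
round(data.frame(z_mm = scene$z*1e3, theta_deg = scene$theta_2d,
                 r = scene$major/scene$minor), 2)
#>    z_mm theta_deg    r
#> 1 11.66     25.23 4.43
#> 2 30.39      3.40 7.15

parts <- process_hologram(render_hologram(scene, opt), window_size = 64L)
round(parts[, c("z_mm","equiv_diam_um","major_um","aspect_ratio","theta_deg")], 2)
#>   z_mm equiv_diam_um major_um aspect_ratio theta_deg
#> 1 30.5        135.65   385.81         5.82      2.08
#> 2 11.5        202.12   427.49         4.23     25.39
```

Both particles are refocused to within half a 500 μm plane of their true
depths and their orientations recovered to about a degree (in the
200-scene validation study, 99.5% of particles land within one plane and
97.5% within 1°). Dissipation recovery from a synthesized −5/3 velocity
record:

```r
w <- synth_velocity(flow_synth_config(epsilon_true = 1e-7, duration = 60, seed = 1))
fit_epsilon(estimate_spectrum(w, fs = 16), U = 0.05)
#> epsilon = 1.01e-07 m^2 s^-3  (slope -1.69, band 3.20-5.33 Hz, U = 0.050 m/s, C = 0.65)
```

And the modeled orientation PDF for an aspect-ratio-6 particle — the
horizontal bin holds 27 times the density of the vertical bins:

```r
jeffery_pdf(6)
#> Jeffery orientation PDF (r = 6, occupancy)
#>     angle pdf_per_deg
#>  -90..-70   0.0009643
#>  ...
#>  -10..+10   0.0259000
#>  ...
#>  +70..+90   0.0009643
```

See `vignette("holoshear-methods")` for the model descriptions, the
reasoning behind thresholds and defaults, and known limitations.

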