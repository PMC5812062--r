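---
title: "Methods: holographic particle imaging and orientation statistics in oceanic shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: holographic particle imaging and orientation statistics in oceanic shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoshear)
```

## The scientific problem

Elongated particles suspended in a slowly sheared fluid do not tumble at a
uniform rate. A rigid spheroid of aspect ratio $r$ in a laminar shear $S$
rotates with angular velocity

$$\omega(\theta) = \frac{S}{r^2+1}\left(r^2\sin^2\theta + \cos^2\theta\right),$$

slowest when aligned with the flow ($\theta = 0$) and fastest perpendicular
to it, with period $T = (2\pi/S)(r + 1/r)$. Averaged over an orbit, the
particle therefore spends most of its time near the flow direction, and the
dwell asymmetry grows as $r^2$. In coastal waters dominated by
chain-forming diatoms this predicts preferential horizontal alignment
wherever the local turbulence is too weak to randomize orientations — with
consequences for light scattering, remote sensing and possibly light
harvesting by the chains themselves.

Testing this in situ requires simultaneously (i) imaging undisturbed
particles in 3D with enough resolution to measure individual orientations,
(ii) measuring the local shear and turbulent dissipation rate, and (iii)
knowing the stratification. `holoshear` implements that entire measurement
chain at desk scale: a ground-truthed synthetic data generator standing in
for the field instruments, the hologram processing pipeline, the particle
statistics, the turbulence diagnostics, and the Jeffery-orbit reference
model.

## In-line holography and numerical reconstruction

A collimated 660 nm beam traverses a 4 cm sample path and the interference
pattern between light scattered by particles and the undisturbed beam is
recorded on a 2048×2048 sensor at 4.59 μm/pixel (a 9.4×9.4 mm field of
view; 3.53 mL per frame). Numerical refocusing uses the angular-spectrum
transfer function

$$H(f_x,f_y;z) = \exp\!\left(2\pi i z\sqrt{\lambda^{-2}-f_x^2-f_y^2}\right),$$

the exact scalar propagator, which reduces to the Fresnel kernel in the
paraxial limit and is unitary for propagating components — so
back-propagation is the exact inverse of forward propagation, a property
the test suite verifies to $10^{-9}$. Planes are spaced 500 μm apart and
the ten planes within 2.5 mm of either sampling window are discarded to
avoid window boundary layers, leaving 70 planes per hologram.

The synthetic generator (`make_scene()`, `render_hologram()`) renders
particles as opaque amplitude masks: the field is propagated from the far
window toward the sensor, multiplied by each particle's transmission at
its depth, and squared into intensity, with optional Gaussian sensor noise
and a smooth synthetic background. Intensity is normalized by clipping to
[0, 1] so the undisturbed beam has unit intensity. Particles are spheroids
(projected ellipses) or chains of collinear cells with small inter-cell
gaps that deliberately exercise the chain re-connection step. The
generator does *not* emulate phase objects, Mie scattering, bubbles,
sensor nonlinearity, or motion blur; passing tests therefore demonstrate
the correctness of the geometry, focusing, and statistics chain — not
robustness to every optical property of real plankton.

## Focus consolidation and its thresholds

Each reconstructed stack is collapsed to a single composite image by
splitting the frame into 128×128 sub-windows (256 of them at the
instrument format) and choosing, per sub-window, the plane with the most
pixels below a focus threshold; ties go to the lower mean amplitude, then
the smaller depth. Two numerical choices matter here, and both defaults
were set by measuring recovery accuracy on ground-truthed scenes:

* **Focus threshold.** In-focus opaque particles reconstruct as
  near-zero-amplitude silhouettes against an order-unity background, but
  out-of-focus diffraction rings also graze low amplitudes in scattered
  pixels. The default is 0.35 × the median stack amplitude — scale-free
  and low enough that essentially only in-focus silhouette pixels are
  counted. A `mean − k·mad` rule is available (`focus_threshold()`) but
  sits inside the fringe fluctuation band and selects wrong planes.
* **Segmentation threshold.** The composite is smoothed with the smallest
  (2×2 box) kernel and thresholded at 0.45 × its median value. A
  histogram-based Otsu threshold lands between the background and the
  diffraction halo and inflates particle areas several-fold;
  `otsu_threshold()` remains available as an explicit override, as does
  any absolute value.

Per-particle depth does not rely on the sub-window choice. Each segmented
region is refocused individually: the plane maximizing the local amplitude
contrast (variance over the region dilated by 3 px) is its depth, and the
outline is re-extracted from that plane. Mean-darkness profiles — the
obvious alternative — fail for large opaque particles because their
near-field shadow stays dark over many planes; the contrast metric
localizes ~99% of 200 seeded particles to within one plane in the
validation studies.

## Segmentation, morphometry, chains, overlaps

Binary segmentation keeps 8-connected components of at least 5 pixels
(105.3 μm² at 4.59 μm/px, equivalent diameter 11.6 μm). Interior holes are
filled before computing the area $A$ used in the equivalent spherical
diameter $D = \sqrt{4A/\pi}$; both raw and filled pixel counts are kept.
The major axis is the segment between the two mutually farthest boundary
pixels, with the direction taken as the circular mean over all chords
within 1.5 px of the longest one — a tie-break that suppresses single-pixel
digitization jitter and brings orientation recovery to ~1° for particles
longer than ~50 px. The minor axis is the maximal extent perpendicular to
that line; one-pixel-wide regions get a one-pixel minor axis and a
degeneracy flag. Orientation is measured from the image horizontal with a
bottom-left origin, corrected by the platform pitch, and wrapped to
(−90°, +90°].

Diatom chains whose narrow cell linkages segment above threshold are
re-connected by merging regions whose boundary-to-boundary gap (empty
pixels between boundary pixel centres) is at most 30 μm, transitively with
union-find semantics so the merge order is irrelevant. Re-connected chains
legitimately have a high convex-hull-to-filled-area ratio, so they bypass
overlap triage. For all other regions a hull/filled ratio above 1.5 marks
a potential overlap of two particles at different depths: each region
pixel votes for the plane where its local (9×9) contrast peaks, and two
well-separated vote modes trigger a split into two records re-segmented
at their own planes; otherwise both are discarded and counted. The
straight-line major axis of curved chains underestimates arc length; a
flag is set when the skeleton (Zhang–Suen) geodesic exceeds the extrema
chord by more than 10%, but the measured value is never altered.

## Particle statistics

Concentration profiles use 20 cm depth bins and $P_v = P/(nV)$ with $V$ =
3.53 mL. Down-casts are sub-sampled to every third hologram and up-casts
to every second, because the platform advances only 3.3–4 mm between
frames at 15 Hz — less than the 9.4 mm field of view. Size distributions
use 24 logarithmic bins over 11.6–1000 μm, normalized per litre and per
micron of bin width; power-law (Junge) slopes are least-squares fits of
$\log_{10} n(D)$ against $\log_{10} D$ over occupied bins lying entirely
inside the fit range. Bins straddling a range edge are excluded — a bin
containing the ~250 μm knee of a two-segment distribution mixes both
regimes and visibly corrupts the shallow slope. Orientation PDFs use nine
20° bins on (−90°, +90°], are normalized per degree within each depth bin,
consider only particles with $r > 3$, and carry a low-count flag below 30
particles per bin, where one or two stray particles can fabricate an
apparent orientation peak.

The `uniform3D` orientation model draws *both* the polar and azimuthal
angles uniformly on (0°, 180°). This is the conventional random-orientation
null for the projection-bias argument: its 2D projection
$\theta = \tan^{-1}(\cot\theta_p/\cos\theta_a)$ piles up density toward
±90°, so projected data under-represent truly horizontal particles. Note
it is not sphere-isotropic — an isotropic direction distribution projects
to an exactly uniform apparent angle by rotational symmetry, and would
show no bias at all.

## Turbulence and stratification diagnostics

Velocity records are divided into 3 m depth bins (at least 256 samples per
usable bin), and one-sided spectra are estimated by Welch's method
(Hann-windowed 256-sample segments, 50% overlap) scaled so the spectral
integral recovers the variance. Under Taylor's frozen-turbulence
hypothesis $\kappa = 2\pi f/U$, the inertial-subrange law
$S(\kappa) = C\varepsilon^{2/3}\kappa^{-5/3}$ (with $C$ = 0.65 for the
vertical component, 0.49 horizontal) implies per-frequency dissipation
estimates

$$\varepsilon(f) = \left(\frac{S(f)\,f^{5/3}}{C}\right)^{3/2}
\frac{2\pi}{U},$$

which are averaged over the fit band (by default the upper 40% of
frequencies below Nyquist/1.5). This expression is fixed by requiring that
it *exactly* invert the model spectrum — an identity the tests verify over
a grid of $(\varepsilon, U, C)$ to machine precision, which resolves any
ambiguity in how the $U$ factor is typeset in the field literature. A fit
is rejected when the log–log slope deviates from −5/3 by more than 0.3;
the slope itself is estimated on a log-bin-averaged spectrum over a band
extended four-fold toward low frequencies, because a slope estimated over
the narrow fit band alone has a standard error of ~0.4 and would reject a
third of genuinely −5/3 records from estimator noise alone.

Microscales follow the closed forms $\eta = (\nu^3/\varepsilon)^{1/4}$ and
$\lambda_B = (\nu D^2/\varepsilon)^{1/4}$ with $\nu = 1.1\times10^{-6}$
m²/s and $D = 10^{-9}$ m²/s; their ratio $\sqrt{D/\nu}$ is
$\varepsilon$-free. The standard $(\nu D^2/\varepsilon)^{1/4}$ form is
used for $\lambda_B$ as it reproduces the 25–45 μm range quoted for these
conditions. Buoyancy frequency is computed from a 0.25 m-binned density
anomaly profile by centred differences (depth positive down, no sorting),
and the gradient Richardson number $Ri = N^2/S^2$ flags stability at
$Ri \geq 0.25$, with zero-shear bins marked undefined.

The synthetic velocity generator builds series from Fourier modes with
model-spectrum amplitudes and random phases, so its output's one-sided
density matches the prescribed inertial subrange exactly in expectation;
its compensated spectrum is flat to within 10% when averaged over 200
seeds.

## The Jeffery reference model

`jeffery_orbit()` integrates $\dot\theta = \omega(\theta)$ with fixed-step
RK4 at $T/n$ steps ($n$ = 10 000 by default; a guard rejects steps coarser
than $T/1000$). The closed form $\tan\theta = \tan(2\pi t/T + \phi_0)/r$
serves as the oracle. The modeled orientation PDF is the occupancy-time
histogram over exactly one period in the same nine 20° bins as the data;
each RK4 step's duration is apportioned across the bins it traverses by
linear interpolation, giving $O(n^{-2})$ error — the endpoint-binning
alternative has $O(n^{-1})$ error and misses the 0.5%-per-bin agreement
with the analytic law $p(\theta)\propto 1/\omega(\theta)$ in the narrow
edge bins at large $r$. The PDF is independent of $S$ and of the initial
angle, symmetric about zero, uniform (1/180 per degree) for spheres, and
concentrates in the horizontal bin as $r\to\infty$. The model assumes
$Pe \gg 1$, negligible particle inertia and $Re_b \ll 1$; these are
documented constraints, not runtime checks.

## Validation study sizes and known limitations

The test and acceptance studies use a 256×256-pixel sensor for
single-particle round trips (the per-pixel physics is unchanged; only the
field of view shrinks) and 512×512 for multi-particle conservation runs:
200 seeded single-particle scenes with 250–450 μm particles of aspect
ratio 3–8 for depth/orientation recovery, 10-particle scenes for
conservation, 50 seeds for dissipation recovery, and 50 000 draws per
segment for size-slope recovery.

Known limitations, all visible in the validation studies:

* Detection degrades for particles with minor axes below ~8 px imaged
  more than ~30 mm from the sensor — their silhouette contrast falls
  below any workable threshold. This is far-field physics, not a tuning
  artifact.
* Strong fringes occasionally leave a sub-threshold halo fragment that
  segments as a spurious ≥5 px region near a real particle (at most one
  per frame in the conservation study).
* The overlap-separation records measure geometry at a single plane and
  can inherit pixels of the partner particle, biasing the aspect ratio of
  split records.
* The hull-ratio trigger (default 1.5) can flag strongly curved single
  particles; they survive only if their contrast profile shows two depth
  modes, so a small fraction of legitimate curved particles is discarded
  and logged.
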