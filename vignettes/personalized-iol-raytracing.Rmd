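---
title: "Personalized ray-traced eye models for IOL power selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized ray-traced eye models for IOL power selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intraocular lens (IOL) power after cataract surgery is normally chosen
with regression/vergence formulas (SRK/T and relatives) whose corneal
input is keratometry: a single radius read from the central cornea and
converted to power with the fictitious keratometric index 1.3375.  That
conversion encodes the *normal* relationship between the anterior and
posterior corneal surfaces.  Corneal refractive surgery (LASIK) reshapes
only the anterior surface, so keratometry over-reads the post-operative
corneal power and the formulas return falsely low IOL powers — a
well-known clinical failure mode.

`pseudophakia` takes the opposite route: it builds a physical model of
the individual pseudophakic eye from measured corneal elevation
topography and axial biometry, propagates light through it by exact ray
tracing, scores the retinal image, and picks the IOL power that
optimizes that score.  Nothing in the pipeline assumes a normal cornea,
so the same computation serves normal and post-LASIK eyes.

## The model

### Anatomy and base constants

The schematic skeleton is the Liou–Brennan finite eye: media indices at
0.555 µm of 1.376 (cornea) and 1.336 (aqueous and vitreous), a 4.0 mm
pupil stop decentred 0.5 mm from the optical axis, a 5° angle kappa
between visual and optical axis (both in the +x meridian by default, as
the meridian is not individually measured), and a spherical retina of
12 mm radius, concave toward the pupil.  These quantities are retained
at schematic values because they are not measured in routine clinical
practice; everything the clinic does measure is personalized:

* **Corneal surfaces** come from elevation topography: a 59×59 Cartesian
  grid of sag values over a 10 mm diameter per surface.
* **Axial geometry** comes from biometry: corneal thickness, anterior
  chamber depth (endothelium → lens), lens thickness, vitreous depth.
  Their sum is the axial length; the retinal apex sits there.

All ocular media share one empirical dispersion polynomial,
`n(λ) = n₅₅₅ + 0.0512 − 0.1455 λ + 0.0961 λ²` (λ in µm).  The
polynomial has a +4.9×10⁻⁵ residual at its own 0.555 µm anchor; it is
kept as published and not renormalized, which is visible in tests that
compare optical paths at the anchor wavelength.  Air is treated as
non-dispersive (n = 1).

Photopic spectral sensitivity is approximated by three wavelengths —
0.510, 0.555, 0.610 µm with weights 1, 2, 1 — and the Stiles–Crawford
effect as a pupil apodization `I(r) = 10^(−(α/2) r²)`, α = 0.05 mm⁻²,
with r the distance from the pupil centre.

### Corneal surface representation

Each elevation grid is turned into an interpolating bicubic surface:
one-dimensional cubic splines (Forsythe–Malcolm–Moler end conditions)
along every grid row and column supply the nodal first-derivative
fields, and each cell carries the bicubic Hermite patch determined by
corner values and derivatives.  The surface passes through every node
exactly, is C¹, and has analytic partial derivatives, which give the
surface normals the ray tracer needs.  On noiseless conic test corneas
the off-node error over the central 8 mm is below 10⁻⁴ mm (the test
suite asserts this across radii 7.2–8.3 mm and asphericities 0 to
−0.6).

Nodes outside the inscribed circle are masked in the grid file; before
spline fitting they are filled with the sag of the best-fitting sphere
so the rectangular spline is defined everywhere, and evaluation is
restricted to the inscribed circle shrunk by one node ring, so the
filler never enters a traced aperture.

### IOL geometry and position

The governing principle is that the IOL is a physical lens, not a
power in a vergence formula.  The implant family is parameterized by
shape factor, centre thickness and index (defaults: equiconvex,
t = 1.0 mm, n = 1.47 — a generic monofocal acrylic; the commercial
catalogue geometry is proprietary).  Surface radii are solved exactly
from the thick-lens equation in aqueous at 0.555 µm, so the geometry
reproduces the labeled power to numerical precision (a 0.25 D
manufacturing-tolerance check guards the constructor).

The axial IOL position is estimated from pre-operative biometry alone:
the optic is assumed to settle at the crystalline lens equator, a
fraction 0.395 of the lens thickness behind the lens front, giving
`ACD_post = ACD + 0.395·LT` from the endothelium to the IOL front
vertex.  No population regression enters this estimate.  The pupil stop
defaults to the IOL front vertex (configurable iris offset).

### Ray tracing

The engine is sequential exact 3-D tracing: analytic quadric
intersection for conic surfaces (IOL, retina, synthetic corneas),
damped Newton iteration for spline corneas (convergence |f| < 10⁻⁹ mm,
seeded at the vertex-plane crossing), and vector Snell refraction whose
per-surface residual |n₁ sin θ₁ − n₂ sin θ₂| is at machine precision
(asserted < 10⁻¹⁰ over random systems).  Optical path length n·d
accumulates per segment.  Rays are lost — never silently kept — on
aperture misses, stop vignetting, total internal reflection, or
non-convergence; a trace with more than 20 % loss is an error naming
the first failing surface.

The entrance bundle is collimated at the field angle (angle kappa) and
aimed so it fills the decentred stop: probe rays are traced through the
cornea, the launch→stop map is fitted as an affine transform, and the
bundle is launched through its inverse.  The residual footprint error is
below 1 % of the pupil radius (asserted in tests); the row of nodes at
exactly the pupil rim can be vignetted by the sub-micrometre aiming
residual, which only removes zero-measure edge samples.

### Image quality and the merit function

Per wavelength, the pupil function is reconstructed on the bundle's
stop-plane grid: amplitude is the square root of the Stiles–Crawford
weight (zero for lost rays), and the wavefront is the per-ray optical
path minus a least-squares piston-and-tilt reference — equivalent to
centring the reference sphere on the chief-ray retinal point.  Tilt
carries no image-quality information; defocus and all higher
aberrations remain.

The modulation transfer function is evaluated as the normalized complex
autocorrelation of the pupil function — mathematically the Fourier
transform of the incoherent PSF — sampled directly at the requested
retinal frequencies (shift = λ_med·R_ref·ν, with amplitude and the
*unwrapped* wavefront interpolated separately so large defocus cannot
alias).  This direct sampling is why the 0–100 cycles/mm band is
resolved with 51 points without the megapixel FFTs an equivalent
PSF-route would need; the FFT route (`psf_polychromatic`,
`mtf_from_psf`) is also provided and is used for PSF-level checks (Airy
radius, Gaussian Fourier pairs).  Polychromatic combination sums the
per-wavelength complex OTFs with the photopic weights, which equals the
OTF of the weighted PSF sum.  The radial summary is the mean of the two
principal meridians.  A spot-diagram ("geometric") OTF mode exists as a
cross-check; it ranks focus identically in tests but ignores
diffraction.

Image-space geometry approximates the exit pupil by the stop (the only
surface behind it is the IOL back): reference distance R_ref = retina
apex − stop plane, numerical aperture n·a/R_ref.  The same geometry
feeds the closed-form diffraction-limited MTF
`(2/π)(φ − cos φ sin φ)`, φ = arccos(ν/ν_c), so system and limit are
mutually consistent; the absolute frequency axis carries the small
(percent-level) error of that exit-pupil approximation, which affects
both curves identically.

The merit that drives IOL selection is the contrast-sensitivity-
weighted squared deviation of the system MTF from the diffraction
limit over 0–100 cycles/mm (100 cycles/mm ≙ 30 cycles/degree ≙ decimal
acuity 1.0; conversion 0.3 cyc/deg per cyc/mm):

merit = Σ_f CSF(f)·(MTF_DL(f) − MTF(f))² / Σ_f CSF(f)

"Minimize the difference" is implemented as squared error for
smoothness; an absolute-difference mode is selectable.  The neural
weighting defaults to the Mannos–Sakrison photopic CSF
`2.6(0.0192 + 0.114 f)·exp(−(0.114 f)^1.1)` (f in cycles/degree), a
band-pass peaking near 8 cyc/deg ≈ 26 cyc/mm; a flat mode supports
sensitivity analyses.  Wavefront-RMS minimization is deliberately *not*
used as the focus criterion — it is known to retain residual defocus
relative to subjective refraction.

### Power selection and comparators

`optimize_iol_power` evaluates the merit on the 0.5 D lattice of
commercially available powers and returns the minimizer (ties to the
lower power; boundary results flagged).  Everything in front of the IOL
is power-independent, so the corneal trace is cached once per eye and
only the IOL and retina are re-traced per power — this changes no
numerical result, only the cost.  `predicted_refraction` scans a thin
trial lens at the 12 mm spectacle plane (coarse 0.5 D, fine 0.05 D) and
reports the merit-minimizing sphere, negative = myopic.

The clinical comparator is SRK/T, implemented from the original
publication (corneal-height ELP estimate, retinal-thickness-corrected
axial length, keratometric index 1.3375, thin-lens vergence; validity
bounds AL ∈ (18, 32) mm, K ∈ (35, 52) D) and verified against an
independent step-by-step oracle.  Because the synthetic IOL family has
no manufacturer A-constant, the package derives one the way clinics
personalize A-constants: `calibrate_a_constant` zeroes the mean
SRK/T-minus-ray-traced difference over a reference cohort (the test
suite and acceptance script use 50 calibration eyes, the sample size
personalization protocols call for, with a seed independent of any
evaluated cohort).

`compare_methods` provides the comparison statistics: Pearson r, the
linear regression model = B·comparator + A with standard errors, paired
and unpaired t-tests, and mean/median absolute differences.

## The synthetic-data generator

No topography/biometry archive accompanies the method, so the package
carries a first-class generator.

* `synth_conic_grid` emulates a topographer's elevation export for a
  conic cornea (apical radius R, asphericity Q), optionally toric
  (paraxial cylinder along a chosen meridian) and noisy.  Noise is
  white Gaussian sag *blurred to a 1 mm correlation length* and rescaled
  to the requested RMS: reconstructed elevation maps are smooth, and
  per-node independent noise at micrometre amplitude would imply
  ~10 mrad local slope errors no real cornea has.
* `apply_lasik_ablation` subtracts a parabolic Munnerlyn-type profile:
  central depth S²|D|/3 µm for optical zone S mm and correction D,
  tapering to zero at the zone edge, which flattens the front surface
  by ≈ D dioptres.
* `simulate_cohort` draws biometry from the pre-LASIK myopic population
  Gaussians (radius 7.74 ± 0.26 mm, ACD 3.04 ± 0.31 mm, LT
  3.87 ± 0.36 mm, vitreous 16.96 ± 1.05 mm, refraction −3.07 ± 1.95 D),
  truncated at the validation bounds by rejection; corneal thickness is
  fixed at 0.55 mm (not reported as a distribution).  Each eye gets an
  anterior conic grid (Q = −0.18) and a posterior grid that keeps the
  schematic posterior/anterior radius ratio 6.40/7.77 with Q = −0.60 —
  real corneas maintain a near-constant ratio, which is also the
  assumption behind the keratometric index, so fixing the posterior
  while varying the anterior would manufacture spurious
  model-vs-formula disagreement.  Default sag noise is 0.002 mm RMS
  (upper range of a normal cornea's deviation from a best conic).
  Draws are independent across parameters; real biometry is correlated
  (long eyes tend to have deeper chambers and flatter corneas), which
  this generator does not emulate.

What passing tests on this cohort do and do not show: they validate the
whole computational chain (surfaces → tracing → MTF → optimization →
comparison) under realistic magnitudes of biometric spread and corneal
irregularity; they do not validate the model against real measured
corneas, real topographer artefacts (posterior-surface reconstruction
bias, missing data, fixation error), or correlated biometry.

## Numerical choices

* Pupil ray grid: 36 nodes per axis across the 4 mm pupil.  The
  convergence gate (doubling density must change the merit by < 1 % and
  the selected power by 0 steps) fixed this default; 32 was measurably
  unconverged (1.07 %), 36 changes by ≈ 0.1 %.
* Merit frequency grid: 0–100 cycles/mm in 2 cycles/mm steps (51
  samples).
* Spline intersections: Newton with steps clamped to ±2 mm, cap 40
  iterations, convergence 10⁻⁹ mm; non-convergence drops the ray and is
  counted.
* Conic intersections pick the smallest forward root on the apex sheet
  (t > 10⁻⁹ mm, excluding re-hits of the surface just left); the stop
  is placed 10⁻⁹ mm before the IOL vertex when the iris offset is zero
  so an axial ray cannot meet two surfaces at t = 0.
* Best-fit sphere: algebraic (Kåsa) initialization, then BFGS on the
  geometric criterion with the radius profiled out as the mean
  distance; radii beyond 10⁴ mm are treated as degenerate (plane)
  input.  Keratometric radii use a 3 mm fit zone, the region clinical
  keratometry samples.
* Grid files store sag at full double precision, so save/load round
  trips are bit-exact.
* All stochastic code paths take explicit seeds and restore the
  caller's RNG state.

## Known limitations

* The exit pupil is approximated by the stop plane; absolute spatial
  frequencies on the retina carry a percent-level scale error (common
  to system MTF and diffraction limit).
* The crystalline lens is never modelled (pseudophakic calculations
  only); accommodation and pupil-size studies are out of scope (pupil
  fixed at 4 mm, configurable).
* One surface model: conic + smooth irregularity.  Zernike
  decomposition, Placido reconstruction and corneal biomechanics are
  out of scope.
* The Munnerlyn profile here is the parabolic approximation with a hard
  zone edge; transition zones and hyperopic nomograms are not
  emulated.
* The ACD_post formula is implemented as printed
  (endothelium-referenced, `ACD + 0.395·LT`, e.g. 4.569 mm at the
  population means); an apex-referenced reading would add the corneal
  thickness (≈ 5.12 mm at the means), which matches the published
  population summary of the model better, but the printed formula is
  authoritative here and the difference is absorbed by A-constant
  calibration in comparisons.
* Physical ray tracing and SRK/T differ systematically away from
  average biometry (the formula's damped long-eye response; its
  K/AL-only ELP estimate versus measured ACD/LT).  A-constant
  calibration zeroes the mean difference but not these slopes; the
  cohort tests quantify what remains.
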