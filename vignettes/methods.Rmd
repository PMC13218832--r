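---
title: "Models and methods in pattwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pattwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pattwin` is a digital twin of photothermal therapy (PTT) temperature
monitoring in ex vivo tissue: it simulates the physics that generates
photoacoustic (PA) observations of a laser-heated phantom, and implements
the estimator — model-based temperature prediction corrected by a Kalman
filter — that turns those observations into a full internal temperature
field. This vignette records the models, their assumptions, the parameter
choices, and the numerical decisions, so that results produced by the
package can be interpreted and criticized properly.

## The coupled physical model

**Light.** A beam at 808 nm illuminates the tissue surface. The package
computes the fluence Φ(r) by voxel Monte-Carlo photon transport:
Henyey–Greenstein scattering with anisotropy g, scattering distances
sampled against the local μ_s, absorption by continuous weight attenuation
along each intra-voxel segment, and a track-length fluence estimator.
This scheme makes the per-segment energy split exact, so
`sum(mu_a * phi * V) = absorbed_fraction * beam energy` holds to machine
precision (the only stochastic loss is the unbiased roulette termination of
weak photons below weight 1e-4). Boundaries are refractive-index matched:
photons leaving the grid are tallied as escaped (top/lateral) or
transmitted (bottom). A steady-state diffusion solver
(`-div(D grad Phi) + mu_a Phi = L`, D = 1/(3(μ_a + μ_s')), 7-point finite
differences, Dirichlet Φ = 0 at the outer faces, sparse Cholesky) is
provided as a fast alternative valid in scattering-dominated media; the
Monte-Carlo solver is the reference and is what every shipped study uses.

The photothermal heat source is S(r) = μ_a(r) Φ(r). Because the pulsed
(imaging) and continuous (heating) beams are co-aligned with the same
profile and wavelength — the matching-illumination condition — one
transport solution serves both roles, rescaled between pulse energy and
continuous power (`scale_fluence()`).

**Heat.** Temperature evolves by the bioheat equation
ρc_p ∂T/∂t = k_v ∇²T + S. The blood-perfusion and metabolic terms are
omitted: the package models ex vivo tissue, where neither applies. The
solver is explicit Euler with a 7-point Laplacian, stable for
Δt ≤ Δl² ρc_p / (6 k_v) (the package defaults to 0.9× that bound).
Heterogeneous conductivity uses harmonic-mean face values, which preserves
flux continuity across tissue interfaces and conserves energy to 1e-10
relative under adiabatic closure. Boundary conditions are Dirichlet at the
water-bath temperature by default — the phantom sits in a stabilized bath —
with adiabatic available, per axis if needed. The same face-conductivity
coefficients assemble the sparse state-space transition matrix, so explicit
stepping and matrix propagation agree to 1e-10 relative (this equivalence
is a test).

**Sound.** A short laser pulse produces the initial pressure
p₀ = Γ Φ μ_a, with the Grüneisen parameter affine in temperature,
Γ(T) = A + B·T, assumed spatially uniform per tissue type. The forward
acoustic model treats every source voxel as a uniform sphere of equal
volume and superposes the exact N-wave solutions
p(t) = p₀ (r − v_s t)/(2r) on |r − v_s t| ≤ a at each (point-like)
detector. This gives smooth traces with the correct time-derivative
character and 1/r decay without any numerical shell differentiation. A
Gaussian temporal impulse response (default σ = 2 samples at 40 MHz)
models the finite bandwidth of the detection chain and keeps the
back-projection derivative well resolved; an optional Gaussian band-pass
around the 5.5 MHz center frequency models the transducer's band-limit.
Reconstruction is universal back-projection: each voxel accumulates
b(d, t) = p′ − t ∂p′/∂t at its time of flight, weighted by the solid angle
of each element (point detectors with a nominal area and a stored normal)
and normalized per voxel by the total subtended angle. On a closed
spherical aperture this inversion is near-exact (round-trip regression of
reconstruction on source gives R² > 0.99); with the 128-element linear
array it shows the expected limited-view behavior, concentrating on the
interfaces facing the probe.

## Thermometry and fusion

The PA thermometry chain is: reference amplitudes at the start temperature
T₀; relative increments α = (p₀(T) − p₀(T₀))/p₀(T₀); temperature
increments ΔT = α / gain with the composite observation gain
B/(A + B·T₀). Only the composite gain enters the pipeline; it is
calibrated by least squares from a stepped water-bath sweep (30→36 °C in
0.5 °C steps, each step averaging several pulse acquisitions). The shipped
tissue presets choose Γ(36 °C) = 0.25 and B = 0.0354·0.25, so the
composite gain at 36 °C is exactly 0.0354 1/K — the value a careful bench
calibration of this kind of setup produces. Linearity holds only in the
biologically viable range; `delta_T()` warns outside 30–45 °C.

The estimator's state stacks the temperature increments at all region
points with the heat-source intensities at the significant-source points
(TOPs: voxels whose initial pressure reaches 5 % of the field maximum,
the same threshold used to delimit the beam spot; this default is
configurable because "significant PA effect" has no canonical cutoff).
Observable points (AOPs) restrict the TOPs to the aperture's view — in 2-D
imaging mode, a slab of ±1 voxel around the imaging plane. The transition
matrix propagates temperature by conduction and adds Δt/(ρc_p)·S at the
source points; the source block is the identity (constant-power heating).
The observation matrix is the gain times an indicator of the AOP rows: the
measurement vector is α itself, so the calibration is applied exactly once.

The Kalman filter is the standard predict/update recursion on this model.
Measurement noise R is the per-point sample variance of α over static,
non-heating frames (floored at 1e-12 to avoid singular updates). Process
noise is diagonal and scheduled by the commanded laser power: for the
first 30 s after the power step the temperature states use the transient
range (1e-3 per step), afterwards the steady range (1e-4); the source
states carry no process noise — their uncertainty lives in the initial
covariance, which is set large on the source block (5 % of the peak source,
matching the expected calibration error of the optical model) and small on
the temperature block (the run starts at a known bath temperature). Source
deviations therefore converge early and stay put, which both corrects a
systematic source bias and prevents frame-correlated pulse jitter from
leaking into the source estimates.

## The therapy twin and what it does (not) show

`run_ptt_twin()` assembles the full study. Defaults are the study
conditions: a 5 mm strongly absorbing sphere ("simulated tumor",
ink-loaded agarose) with its top 3.2 mm below the surface of a
12 × 12 × 10.5 mm muscle-tissue block at Δl = 0.75 mm, a 3 mm Gaussian
beam, bath and start temperature 36 °C, and 120 s of continuous heating at
0.3 W — chosen so the tumor top rises into the 42–45 °C mild-PTT window
without crossing 45 °C (the run halts and reports if the truth field ever
does). PA frames arrive every model step (≈ 0.65 s, a 1.5 Hz frame rate
well within pulsed-laser repetition limits); each frame's
amplitudes carry a common multiplicative pulse-energy jitter of 0.5 %
(s.d.), sized so the raw PA thermometry error at the observed point peaks
around 0.4 °C over a run — the level a free-running OPO-class pulsed laser
produces. The model branch uses its own Monte-Carlo fluence solution
(independent seed) scaled by a deliberate +5 % source bias, representing
optical power-calibration error; the sub-threshold part of the model source
enters the filter as a known input, mirroring the workflow in which the
simulated heat source fills in detail below the PA detection floor. Errors
are evaluated against the fine-grid truth at four virtual thermocouples:
tumor top (the only one with a PA signal), tumor core, adjacent tissue
below the tumor, and the lateral margin outside the imaging plane.

The fusion region of interest defaults to the simulation grid itself
(N = 3584 states); `decimate` builds a block-decimated ROI with documented
restriction (block means) and injection (trilinear weights) maps for cases
where the covariance recursion must shrink. Decimation adds a
discretization bias of its own at steep source gradients — with the
default opaque tumor, about 0.5 °C at the tumor top for a 2× decimation —
so the default keeps the grids equal and lets the twin isolate the error
sources the filter is designed to handle: sensor noise and source
mis-calibration.

What passing the twin does *not* show about real tissue: the generator
shares its conduction code between truth and model (no unmodeled
convection, no temperature-dependent properties), its Grüneisen model is
exactly affine, the observation jitter is exactly the noise class the
filter assumes, and registration between reconstruction and simulation is
identity. Real data add structured model error in all four places; the
twin quantifies the estimator's behavior under controlled versions of the
first two only.

## The other two studies

`run_depth_attenuation()` rebuilds the energy-integration measurement: a
strongly absorbing plane ("black agarose", absorption 200× muscle, so the
slab intercepts essentially all remaining light) under 0–8 mm of tissue
cover, 10⁶ photons per depth, absorbed energy integrated over the plane
and normalized to the zero-depth reference. Log energy against depth
(2–8 mm) is fitted by least squares; the lateral deposition image at each
depth gets a spot analysis (5 % boundary threshold, intensity-weighted
centroid, FWHM by linear interpolation at half max). The near-surface
region is excluded from the fit because build-up scattering makes decay
non-exponential there.

`run_heat_source_recon()` compares the limited-view reconstruction of the
tumor phantom's initial pressure at the reference temperature against the
simulated heat source, as lateral envelope profiles (maximum over depth)
over the target region — the tumor's bounding box plus a 2 mm margin;
spatial registration is identity in the twin. The reconstruction is in
arbitrary units, so its amplitude is registered to the simulated profile by
a least-squares normalization fit before the trapezoidal envelope integrals
are compared; a `"max"` normalization (each profile scaled to unit maximum)
is also available and is the more sensitive convention for quantifying
limited-view shoulder loss, which with point detectors and the default
linear array amounts to roughly a 10 % integral deficit. The probe sits
1 mm above the surface (a thin coupling layer), maximizing the angular
coverage a contact linear array achieves.

## Numerical choices and edge cases

* Voxelization is by voxel centers, 0-based indices in the compiled code
  and 1-based in R, z increasing with depth; layer thicknesses round to
  the nearest whole voxel (minimum one).
* Monte-Carlo runs are bit-reproducible: the kernel draws from R's RNG
  stream under `withr::with_seed()`, so a seed fully determines the
  result; every driver derives independent sub-seeds from its master seed.
* The Gaussian beam diameter is read as the 1/e² intensity diameter by
  default (`width_convention = "fwhm"` switches), since "spot diameter"
  alone does not fix a convention.
* The covariance recursion runs dense with a compiled `F P Fᵀ + Q` kernel
  (cost 2·nnz(F)·N per step); symmetry is restored at measurement updates.
  The innovation covariance is checked for conditioning before inversion.
* Degenerate inputs fail loudly: zero-thickness layers, spheres that do
  not fit their extent, empty source-point selections, calibration designs
  with fewer than three distinct temperatures, observation references at
  the noise floor, and time steps above the stability bound are all
  rejected with specific messages. The stability contract can be disabled
  only explicitly, to demonstrate the oscillatory divergence above the
  bound.
* Problem sizes shipped as defaults — 16 × 16 × 14 fusion grids, 64-voxel
  reconstruction planes, 10⁶-photon transport runs — are desk-scale
  choices that keep a full three-study reproduction within minutes on one
  CPU while leaving every qualitative behavior (limited view, build-up,
  filter convergence) intact.

## Known limitations

Single sound speed (no acoustic heterogeneity, attenuation or dispersion);
point-detector elements (no aperture directivity or elevation focus);
per-tissue-type uniform Γ with only a single composite gain calibrated
(per-region gains are structurally supported in the observation matrix but
not calibrated); no perfusion, metabolism, or temperature-dependent tissue
properties; explicit time stepping only. These bound the package to the ex
vivo, mild-heating regime it models.
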