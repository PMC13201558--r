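---
title: "Methods: simulating and estimating wall shear stress with ultrafast ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating wall shear stress with ultrafast ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Wall shear stress (WSS) — the tangential traction the flowing blood exerts on
the vessel wall — is a key hemodynamic quantity: chronically low or
oscillatory WSS is associated with endothelial dysfunction, neointimal growth
and stent-strut malapposition complications, while elevated WSS marks
stenotic jets. WSS cannot be measured directly; it must be inferred from the
near-wall velocity field, which makes it exquisitely sensitive to wall
localization and to the velocity estimator's behavior in the last few hundred
micrometers before the wall. `echowss` implements an end-to-end *in silico*
test bench for this problem at coronary scale: parametric phantoms with
closed-form WSS references, a linear ultrafast-ultrasound acquisition model,
the full Doppler estimation chain, and the pseudo-spectral WSS estimator,
plus the comparison metrics used to score the result.

This vignette documents the models and conventions. All lengths are in mm,
velocities in m/s, WSS in Pa, unless a suffix says otherwise.

## 1. Flow phantoms and analytic references

`make_geometry()` builds a 2D longitudinal cut through a vessel of diameter
$D$ (default 3.2 mm) and length 8 mm, with the axial coordinate $z \in [0,
L]$ and the lateral (depth) coordinate $x$ centered on the lumen axis. Three
kinds are supported:

* **straight** — parallel walls at $x = \pm D/2$;
* **stenotic** — a cosine-squared narrowing of severity $s$ (fractional
  diameter reduction, $0 \le s < 1$) over a given length; *eccentric*
  stenoses indent only the upper wall, *concentric* ones indent both;
* **malapposed** — a straight vessel whose upper wall carries stent struts
  standing off the wall by the malapposition offset (default 0.8 mm), pitch
  1 mm, over a 4 mm extent.

`analytic_flow_field()` fills the lumen with steady laminar flow at a
prescribed volumetric rate $Q$. For the straight tube this is the exact
Poiseuille solution; $v_\max = 2Q/(\pi R^2)$ and the wall shear stress is
the closed form

$$\tau_w = \frac{4 \mu Q}{\pi R^3},$$

which for the default conditions ($\mu = 0.9\,$mPa·s, $Q = 20\,$mL/min,
$R = 1.6\,$mm) gives $\tau_w = 0.0933$ Pa. For varying-radius geometries a
quasi-1D model is used: at each axial station the profile is parabolic in
the local lumen with the centerline rescaled to conserve flux, so the
reference WSS scales as $1/r(z)^3$ with an eccentricity correction from the
local wall slope. `analytic_wall_shear()` evaluates these references on both
walls; `fd_wss_oracle()` is an independent finite-difference oracle that
differentiates the sampled velocity field along the inward wall normal
(one-sided second-order stencil), useful for cross-checking the
pseudo-spectral estimator on grids of at least 64 samples per diameter.

**Strut wake shielding.** Behind a malapposed strut the through-gap flow is
slow and recirculating. The phantom models this with a multiplicative
shielding factor on the axial velocity in the gap: $v_z \mapsto v_z\,[1 -
A(z)\,h(d/g)]$, where $d$ is the distance from the upper wall, $g$ is the
malapposition gap, $h(u) = \tfrac12(1 + \cos \pi u)$ is a cosine taper that
is 1 at the wall and 0 at the strut plane, and $A(z)$ oscillates between 0.1
(midway between struts, near reattachment) and 0.9 (immediately behind a
strut, near stagnation) at the strut pitch, with half-pitch ramps at the
ends of the stented extent. The analytic upper-wall reference is multiplied
by $1 - A(z)$ accordingly. The model is deliberately simple — steady,
attached, no recirculation vortices — but reproduces the two signatures that
matter for evaluation: a *lower mean* and a *higher spatial variance* of WSS
along the malapposed segment.

## 2. Acquisition model

`acq_params()` collects the imaging constants. The defaults mirror a
high-frequency ultrafast acquisition: center frequency 23.44 MHz, 2-cycle
pulses, speed of sound 1480 m/s, frame rate 10,000 fps, 1100 frames per
ensemble, 0.05 mm grid. Derived quantities: the pulse-echo axial wavelength
$\lambda_z = c/(2 f_c)$ and the axial Nyquist velocity

$$v_{\mathrm{Nyq}} = \frac{c \, \mathrm{PRF}}{4 f_c} = 15.79\ \mathrm{cm/s},$$

comfortably above the sub-decimeter-per-second velocities of interest here.
A scatterer moving axially at $v$ advances the pulse-echo phase by $4 \pi
f_c v / (c\,\mathrm{PRF})$ per frame.

`seed_scatterers()` converts a microbubble concentration (default $2.5
\times 10^6$/mL) and an elevational slice thickness (0.3 mm) into a planar
scatterer count over the lumen area, with uniform positions and Rayleigh
amplitudes. `simulate_iq_ensemble()` advects the cloud through the flow
field frame by frame (wrap-around at the outlet with randomized lateral
re-entry keeps the concentration stationary) and renders each frame as a
beamformed IQ image: every scatterer deposits a Gaussian point-spread
function carrying the axial carrier $e^{i 2 \pi (2 f_c/c) z}$.

**Two beamformations.** The same scatterer trajectories are rendered twice:

1. a *plain* beamformation with a tight lateral Gaussian
   ($\sigma_{\mathrm{lat}} = 0.05$ mm), used for axial velocity, and
2. a *transverse-oscillation* (TO) beamformation whose PSF is the wider
   Gaussian ($\sigma_{\mathrm{TO}} = 0.1$ mm) multiplied by
   $\cos(2\pi x/\lambda_x)$ with $\lambda_x = 0.25$ mm, which imprints a
   known lateral carrier so lateral motion also produces a measurable phase
   shift.

`add_clutter_and_noise()` then adds a frame-constant (zero-Doppler) clutter
image 40 dB above the blood signal and white complex Gaussian noise at 20 dB
SNR, each with its own seed. If the peak axial velocity in the scene exceeds
$v_{\mathrm{Nyq}}$ the simulator warns and flags `meta$aliasing`; the
estimated velocity then wraps to $v - 2 v_{\mathrm{Nyq}}$, and the package
reproduces this wrap rather than hiding it.

## 3. Doppler estimation

`svd_casorati()` reshapes the ensemble into the Casorati matrix (pixels ×
frames) and computes its SVD; `svd_clutter_filter()` discards the leading
singular components. Frame-constant clutter is exactly rank one in this
basis, so a single discarded component (the default, `n_discard = 1`)
removes 40 dB of static clutter to numerical precision; a purely static
scene is annihilated to residual energy below $10^{-10}$.

`estimate_axial_velocity()` applies the lag-one autocorrelation (Kasai)
estimator to the filtered plain ensemble: $v_z = \frac{c\,\mathrm{PRF}}{4
\pi f_c} \arg \sum_t s_t^{*} s_{t+1}$. For the lateral component,
`make_to_quadrature()` splits the TO ensemble into two single-sideband
branches (`pos`/`neg`) by a lateral Hilbert transform; the branch
autocorrelations have phases $\pm 2\pi v_x/(\lambda_x \mathrm{PRF})$
(plus a common axial term that cancels in the half-difference), from which
`estimate_lateral_velocity()` recovers $v_x$. Averaging lag-one products
over 1100 frames gives sub-percent axial and few-percent lateral bias over
the 0.5–12 cm/s range. `loess_smooth()` applies local quadratic regression
along each velocity profile (span 0.10) to suppress residual speckle noise;
it reproduces constants and quadratics exactly, so it does not bias a
parabolic profile.

## 4. Wall detection and contour fitting

The velocity map goes to zero at the wall over roughly one PSF width, so the
wall cannot be read off as a hard zero crossing. `detect_wall()` uses a
blur-derived two-pass threshold: from the PSF width it computes the velocity
level a half-blurred profile attains at the true wall position, finds the
sub-pixel crossing of that level on each depth line, and then refines each
edge by an *interior-band extrapolation*: a quadratic is fit to the profile
on the band 2σ–8σ inside the provisional wall (where blur no longer biases
the samples) and its root nearest the wall replaces the edge. The refinement
iterates as a fixed-point update (at most 4 passes, each capped at 3σ) and
stops as soon as a pass moves the edge by less than σ — sub-σ corrections
mean the edge already sits at the wall, and pushing further would chase the
slight near-wall velocity sag left by clutter-filter suppression of slow
flow, walking the edge inward.

`fit_wall_contour()` smooths the detected edges with locally weighted
quadratic regression (tricube weights over a 15% window), yielding a
continuous contour with unit tangents and inward normals. On jittered
straight-wall edges the contour RMSE is below half a pixel and the normal
angles are within a few degrees of the true normal.

## 5. Pseudo-spectral wall shear stress

For each contour point, `wall_shear_rate()` casts the inward normal ray to
the opposite wall, giving the local chord length $L$, and samples the
tangential velocity along it (bilinear interpolation). The profile is
expanded in the Fourier sine series

$$u(y) \approx \sum_{k=1}^{K} b_k \sin\!\left(\frac{k \pi y}{L}\right),$$

a basis that enforces no-slip at *both* walls by construction — the single
strongest prior available for internal flows. The fit is linear least
squares; the wall shear rate is the analytic derivative at $y = 0$,
$\sum_k b_k k \pi / L$, and `compute_wss_map()` converts it to stress with
the dynamic viscosity, projecting the full symmetric strain onto the
tangent-normal frame so the reported `wss_pa` is the tangential traction
magnitude.

Conventions and safeguards:

* Samples closer to the wall than `wall_margin` (default $2
  \sigma_{\mathrm{lat}}$) are excluded from the fit — they are the ones
  corrupted by PSF blur and clutter-filter sag — and the series extrapolates
  to the wall through the no-slip constraint. On noise-free fields a 0.1 mm
  margin changes the mean WSS by well under 1%.
* $K = 20$ terms reconstruct a parabola's wall derivative to within 2%; the
  truncation error decreases monotonically with $K$ (checked over $K \in
  \{5, 10, 20, 40\}$), so $K$ trades a small low-pass bias against noise
  amplification. $K$ must stay below the number of profile samples; chords
  too short to support the basis (e.g. at a tight stenotic throat on a
  coarse grid) are dropped from the map rather than aborting it.
* A trailing moving average (3% of the chord) conditions the *normal*
  velocity component, which is noisier than the tangential one.

## 6. Metrics and conventions

`segment_stats()` partitions the axial extent into equal thirds — proximal,
middle, distal — with *right-closed* intervals: a sample exactly on an
interior boundary belongs to the upstream segment, and the origin belongs to
the proximal segment (`segment_stats(1:9, 1:9, 9)$mean` is `2, 5, 8`).
`mape()` excludes near-zero references (count attached as an attribute);
`spearman_rho()` is the Pearson correlation of mid-ranks and refuses
zero-variance rank vectors; `spatial_variance()` is the sample variance of
the WSS magnitudes; `group_test()` is Welch's unequal-variance t-test.
`compare_maps()` resamples the reference to the predicted positions by
nearest neighbor (an optional rigid axial offset search,
`align_offset()`, handles sub-millimeter misregistration) and bundles all of
the above into a `comparison_report` that `write_report()` serializes to
JSON plus a CSV segment table.

## 7. The pipeline

`run_pipeline(config, seed)` chains everything: phantom → analytic field →
scatterers → two beamformations (clutter/noise seeded from `seed + 1` and
`seed + 2`) → SVD filter → axial + TO lateral estimation → loess smoothing →
wall detection → contour → WSS map → comparison against the analytic
reference, writing `velocity.csv`, `wss.csv`, `report.json` and a manifest
with the seed, a configuration hash and per-file MD5 checksums, so a run is
reproducible byte for byte. `default_config()` returns the defaults above as
a nested list; `read_config()` loads and validates a YAML file against it
(unknown keys are errors). A thin command-line wrapper lives at
`inst/cli/echowss.R`.

```{r example}
library(echowss)
cfg <- default_config()
res <- run_pipeline(cfg, seed = 1)
middle_segment_mean(res$wss, cfg$geometry$length_mm)
```

## 8. Known limitations

* The acquisition model is linear and 2D: no multiple scattering, no
  elevational flow, no tissue motion (the clutter is strictly static), no
  attenuation or depth-dependent PSF.
* The quasi-1D stenotic reference ignores flow separation and inertia. On
  the *converging slope* of a tight eccentric stenosis the estimated WSS can
  exceed this crude reference substantially even when the throat itself
  agrees well; pointwise MAPE there is dominated by the reference's own
  modeling error, so the rank correlation and the throat value are the more
  meaningful scores.
* The strut wake model is a steady multiplicative shielding, not a
  recirculating flow; it reproduces the mean-decrease / variance-increase
  signatures of malapposition but not reversed near-wall flow.
* Velocities above the axial Nyquist limit alias; the package flags and
  reproduces the wrap rather than unwrapping it.
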