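---
title: "Methods: confined-perfusion modelling and fluorescence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confined-perfusion modelling and fluorescence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `flowbrush`. It is the package's own account of its
science; every quantitative statement here is one the test suite or
`scripts/acceptance.R` actually computes.

# The reduced-order flow model

A two-aperture perfusion device injects reagent at a volumetric rate
$Q_\mathrm{inj}$ from one micropipette opening while a second opening
aspirates at $Q_\mathrm{asp} > Q_\mathrm{inj}$. We model the resulting
creeping flow as the superposition of a point source and a point sink,

$$\mathbf v(\mathbf x) = \frac{Q_\mathrm{inj}}{4\pi}
  \frac{\mathbf x-\mathbf x_s}{|\mathbf x-\mathbf x_s|^3}
  - \frac{Q_\mathrm{asp}}{4\pi}
  \frac{\mathbf x-\mathbf x_a}{|\mathbf x-\mathbf x_a|^3},$$

optionally adding mirror images across the substrate plane $z=0$ so the
normal velocity vanishes there. This is a potential-flow image system: it
enforces no-penetration, not no-slip, at the wall — a documented
simplification. The model is chosen for analyticity (exact mass
conservation, closed-form velocity gradients for shear, microsecond
evaluation) in place of a wall-resolving finite-element solution.

Coordinates: substrate plane at $z=0$ with $z$ up, source–sink axis along
$x$. Units: lengths in µm, flows in nl/s, volumes in fl (1 fl = 1 µm³),
speeds in µm/s; SI conversions are internal.

Geometry defaults. The aperture pair is described by inner diameters,
wall thickness (default 1 µm) and an in-plane angle (default 35°). The
default tip separation places the outer rims in touching contact,
$(\varnothing_\mathrm{inj}+\varnothing_\mathrm{asp})/2 + 2w$, because the
physical device holds the tips in near-touching contact; the model treats
the openings as points, so the angle documents the arrangement without
entering the field. Default tip height is one aperture diameter;
deposition scenarios lower it to 2 µm (near-contact writing), without
which the no-penetration image flow keeps streamlines too far from the
wall for beads to deposit.

Numerical choices. Streamlines integrate the unit-tangent equation
$d\mathbf x/ds = \mathbf v/|\mathbf v|$ with `deSolve::lsodar` (relative
tolerance $10^{-6}$), stopping on capture (within the aspiration inner
radius of the sink), escape (beyond $R_{max} = 50$ aperture diameters) or
stagnation ($|\mathbf v|$ below $10^{-8}$ of the capture-radius speed).
The exclusion radius around each opening is $0.1\times$ the inner radius;
evaluation inside it is flagged near-singular. Envelope rasterization
uses voxels of $1/50$ aperture diameter by default, with launch
directions drawn isotropically from a seeded RNG.

Envelope construction. The injected-fluid region is the union of all
source streamlines. Because the free-space field is axisymmetric about
the source–sink axis, visited points are collapsed to $(x,\rho)$
coordinates, the occupied region is filled radially (the separatrix
interior is radially simply connected), and the 3D voxel count follows by
revolution. This yields the full separatrix-interior volume rather than
the sampling-dependent count of voxels touched by finitely many curves.
The envelope extent is the maximum in-plane caliper width of the occupied
set — the open definitional question of which caliper direction to use is
resolved in favour of the maximum, which for this geometry is essentially
the axial extent.

What the model does and does not reproduce. Mass conservation is exact
(verified by spherical quadrature to 1%), confinement is complete for
$Q_\mathrm{ratio}\le 0.8$ at both 1 µm and 6 µm apertures, the envelope
boundary is voxel-identical under joint flow scaling (only
$Q_\mathrm{ratio}$ matters), extent grows monotonically with
$Q_\mathrm{ratio}$, and mid-envelope speeds are in the mm/s range at the
device's working flows. However, a free-space monopole emits
isotropically: the injected fluid also occupies an $O(d^3)$ region around
the source bounded by the stagnation point at $1.21\,d$ behind it (for
$Q_\mathrm{ratio}=0.3$), where $d$ is the tip separation. A real walled
aperture directs its jet forward, so wall-resolving simulations confine
the same flow to a far smaller envelope. Consequently the model's
absolute envelope volume for the 1 µm pair is of order $10^2$ fl rather
than the sub-femtoliter scale of wall-resolving solutions, and the mean
speed on its (farther-out) boundary underestimates near-aperture speeds
at the lowest flows. Relative and topological envelope statements are
trustworthy; absolute envelope volume is not.

# Transport regime analysis

Stokes–Einstein sets the analyte diffusivity
$D = k_BT/(3\pi\mu d_p)$ (default water at 22 °C,
$\mu = 0.9544$ mPa s). The Péclet number $Pe = vL/D$ uses the
model-derived characteristic scales $L$ = envelope extent and $v$ =
area-weighted mean boundary speed, recorded in every report for
auditability. The Damköhler number compares surface binding with
transport across the concentration depletion layer; since the depletion
thickness is not printed anywhere, we fix the Lévêque scaling
$\delta_s = L\,Pe^{-1/3}$ and the per-molecule rate
$k'_{on} = k_{on}/(N_A\cdot 1000)$, and record the convention in the
report. For the CTxB–GM1 system ($k_{on} = 3\times10^3\,$M⁻¹s⁻¹, 100
sites/µm², 5 nm probe) this gives $Da \sim 10^{-6}$: deeply
reaction-limited, so adsorption is independent of flow rate. The
Reynolds number stays below 1 across the full three-decade flow range
(0.03–3 nl/s) and is $\sim 10^{-2}$ at the imaging flows, justifying the
Stokes model. Diffusivities are handled in m²/s: the nm-scale particle
sizes quoted alongside imply m²/s magnitudes, and we adopt that unit
consistently.

# Brownian-advective tracers and deposition

Tracers follow the overdamped Euler–Maruyama update
$\mathbf x \leftarrow \mathbf x + \mathbf v\,dt + \sqrt{2D\,dt}\,\xi$,
seeded on the injection opening and absorbed at the aspiration capture
radius. Particle inertia is neglected ($Re \ll 1$) and particles are
points apart from the substrate-contact radius; there are no
hydrodynamic wall corrections. The default step $dt = 10^{-5}$ s matches
the 10 kHz tracking cadence; a step is rejected if the advective move
near an opening would exceed half an aperture radius. Deposition
scenarios release particles continuously while the tip pair translates
along a waypoint path (quasi-static field), stick on substrate contact
($z <$ particle radius) with a configurable probability (default 1,
since carboxylate beads adhere readily), and otherwise reflect
specularly.

A statistical point governs all velocimetry comparisons: a bin's
vector-mean velocity carries a Brownian standard error
$\sqrt{2D/\Delta t}/\sqrt{N}$ per axis, about 240 µm/s for 80 nm
particles at 10 kHz with $N=20$ steps — larger than the true flow speed
over most of the envelope. Agreement with the analytic field is
therefore asserted where it is measurable: bins whose measured speed
exceeds 40 such standard errors agree with the field within 10%
(median ≈ 4%), and the full imaging pipeline (render → detect → link →
map, pooling four releases, 1 ms velocity baselines, tracks ≥ 4 samples)
agrees within 15% at a 15-standard-error cut. The oracle for binned
comparisons is the field vector-averaged over the measured sample
positions; comparing $|\overline{\mathbf v}|$ with the field speed at the
bin center instead mixes in binning curvature and is biased low.

# The synthetic-data generators

The generators produce the statistical structure each analysis stage
assumes, so every stage is testable without external recordings.

* Punctual labeling: an isotropic Gaussian spot with per-axis variance
  $\sigma_0^2 + 2Dt$ and conserved integrated intensity (equivalently,
  width² grows as $4Dt$ when width² means twice the per-axis variance —
  the convention is fixed here and enforced by a finite-difference
  oracle test to < 1%). Default $\sigma_0$ makes the spot FWHM equal the
  1 µm aperture footprint; frames are stamped at mid-exposure, 130 ms
  cadence for the bilayer fixture and 0.7 s for the live-cell fixture.
* FRAP: a uniform prebleach plateau minus an identical diffusing Gaussian
  hole (1 µm bleach spot).
* Extended labeling: a static crescent band at a cell periphery plus
  bright clusters drifting at constant nm/s speeds over ~950 s.
* Two-channel colocalization: equal-width spot channels constructed so
  that, at a fixed threshold of 1% of the convolved spot peak, the
  measured Mander's coefficients equal the designed values; the solved
  spot counts place $k=\mathrm{round}(M_1 n_A/(1-f))$ A-spots exactly on
  B-spots and the rest far away, on a seeded jittered grid that
  guarantees the minimum separation.
* Cluster time lapse: Brownian clusters in a 15 × 15 µm² patch merging
  within a coalescence radius, masses and areas adding.

All generators share a Gaussian PSF $\sigma = 0.21\lambda/\mathrm{NA}$
(Gaussian–Gaussian convolution is applied analytically by adding
variances; hard-edged scene elements are blurred numerically), Poisson
shot noise plus zero-mean Gaussian read noise on a uniform background,
and are bit-reproducible from their seed. Photobleaching during imaging
is off by default — an optional exponential factor could be added, but
none of the analyses model it.

What the fixtures do not emulate: membrane topography and its projection
distortions, anomalous subdiffusion and immobile fractions, spatially
varying background and autofluorescence, detector pixel-response
nonuniformity, and optical sectioning beyond a binary focal slab. Passing
the recovery tests therefore demonstrates estimator correctness under the
stated model, not robustness to every artifact of real recordings. The
live-cell fixtures use brighter photon budgets (peak 2000 counts; bleach
plateau 600, depth 500) than the bilayer ones (peak 200; plateau 150,
depth 120): at $D\sim 0.3$ µm²/s the label dilutes ~40× in area within
the observation window, and a dim budget would leave late frames below
the noise floor. These are one-time realistic confocal choices.

# Diffusion estimation

A shared kernel fits an isotropic 2D Gaussian plus constant background to
every frame by Levenberg–Marquardt least squares. Initialization uses an
edge-renormalized blurred copy of the frame (moments of the raw noisy
frame are dominated by background fluctuations for faint, broad spots);
frames whose blurred amplitude is below four blurred-noise standard
deviations are flagged flat and excluded. Standard errors come from the
linearized covariance with the analytic Jacobian.

Two estimators follow. The width method regresses fitted variance on
time (weights $1/\mathrm{se}^2$), $\hat D$ = slope/2; the constant PSF
contribution is absorbed by the intercept. The amplitude method regresses
$1/A$ on time — linear with slope/intercept $= 2D/(\sigma_0^2 +
\sigma_\mathrm{psf}^2)$, so no PSF knowledge is needed once the width
intercept supplies the initial variance. Both are computed on every call;
if they disagree by more than three joint standard errors the fit is
flagged. A numerically zero or negative width slope yields $\hat D = 0$
with a warning. FRAP series are inverted into an evolving hole (plateau
from prebleach frames; negative wing values retained, since flooring at
zero biases the fit) and analyzed by the same machinery, so
punctual/FRAP agreement is testable by construction; a hole already
indistinguishable from noise by the second frame raises a lower-bound
flag. No immobile-fraction term is fitted by default. The first
post-pulse frame defines $t=0$ with a half-frame (mid-exposure) offset.

Measured performance (recomputed by the acceptance script): ensembles of
30 seeded bilayer series recover 0.048 µm²/s (punctual) and 0.045 µm²/s
(FRAP) to three decimals;
8 live-cell series recover 0.32 µm²/s; the paired punctual/FRAP
difference at shared ground truth is not significant at $\alpha=0.05$;
and the estimator spread shrinks with a fivefold photon-flux increase.

# Image quantification

Spot detection is difference-of-Gaussians band-passing, 8-neighborhood
local maxima above a threshold, and background-subtracted
intensity-weighted centroid refinement (sub-0.1-pixel on clean spots).
Linking is gated greedy nearest-neighbor — assignments accepted in order
of increasing displacement, which implements the minimal-total-
displacement tie-break — with an ambiguity rule: if a competing unused
candidate lies within 25% of the gate of an accepted displacement, the
assignment is voided and both tracks end there. Global-optimization
linking is unnecessary at fixture densities. Kymographs sample bilinear
interpolants at pixel pitch along a polyline, averaging across the
perpendicular line width; ridge speeds come from regressing the windowed
intensity-weighted centroid on time, with the window re-centered each
step and truncation when the ridge SNR drops below 2. Mander's
coefficients use background-subtracted intensities floored at zero and
Otsu thresholds per channel within the ROI by default (the threshold
convention is always recorded; fixed thresholds are available and are
what the packaged design uses, since its construction defines the
threshold). Cluster segmentation uses Otsu or fixed thresholds and
8-connectivity components (a diagonal-merge pass on top of
`EBImage::bwlabel`), with copy numbers from a user-supplied single-unit
intensity. MSD analysis fits the log–log slope of the time-averaged MSD
up to a quarter of the track length.

# Orchestration and problem sizes

`run_scenario()` executes a YAML-described stage list with one seed,
validates stage names before running anything, writes every output as
CSV/JSON/TIFF plus a manifest with parameter hashes and output checksums,
and is byte-reproducible for identical config and seed. Image series
round-trip as 32-bit-float TIFF with a JSON sidecar carrying pixel size,
frame interval and timestamps; a missing sidecar is an explicit error.

Problem sizes were chosen so the whole suite runs on a laptop in a few
minutes: envelopes use 100–500 streamlines in tests (2000 in the
reproduction script; the radial-fill volume is stable well below that),
velocimetry uses 600–1000 tracers, and the diffusion ensembles use
replicate counts typical of such measurements (30 bilayer, 8 live-cell).

# Known limitations

* Free-space monopoles cannot represent walled, directional apertures:
  absolute envelope volumes are overestimated by orders of magnitude and
  boundary speeds at the lowest flows underestimated (details above).
* No-slip is not enforced at the substrate; near-wall shear is
  qualitative. Near the aperture singularities the point model also
  exaggerates shear; sub-pascal boundary stresses hold away from the
  openings.
* The linker is greedy and the detector threshold-based; both are
  adequate at fixture densities but not at high occupancy.
* The synthetic data omit the real-data artifacts listed above, so
  green recovery tests bound estimator error under the model only.
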