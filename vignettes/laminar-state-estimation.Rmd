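---
title: "Estimating the cutter-tip state in laminar bone grinding from CT-derived force templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the cutter-tip state in laminar bone grinding from CT-derived force templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamigrind)
```

## The problem

During laminectomy-style procedures a ball-end cutter grinds the vertebral
lamina thin, layer by layer, close to the spinal cord. Optical navigation
tracks the tool holder, but not the cutting tip itself: bit deflection and
registration drift leave the true tip position uncertain by amounts that
matter at sub-millimetre safety margins. `lamigrind` implements an
estimation framework that needs no extra hardware: the pre-operative CT
volume is turned into a bank of *predicted* milling-force template
sequences along the planned paths, and the intra-operative force/torque
signal is matched against that bank to recover where the tip actually is.

The chain has five stages, mirrored by the package modules:

1. **Planning and voxel extraction** — a rectangular workspace is milled
   in `n_layers` layers of depth $d$, each layer by parallel paths along
   $x$ spaced $w$ along $y$ (`milling_plan()`, `plan_paths()`,
   `extract_grid_grays()`).
2. **CT image–force model** — a mechanistic ball-end milling force model,
   weighted per micro-edge by normalized CT gray, predicts the
   four-channel wrench $(F_x, F_y, F_z, M_z)$ along every path
   (`predict_bank()`).
3. **Segmentation** — the measured signal is cut by a tumbling window of
   `ns` samples; each window corresponds to a grid of physical length
   $l = v_d\,n_s/f_s$ on a path (`tumble_segment()`).
4. **Similarity matching** — each window is compared against every bank
   entry by dynamic time warping (or a Pearson-correlation baseline); the
   most similar grid's landmark is the raw tip estimate
   (`estimate_tip()`, `estimate_track()`).
5. **Robust refinement** — RANSAC fits a 3-D line to each executed path's
   matched landmarks and a second RANSAC stage estimates the rigid
   workspace offsets $(\Delta n_r, \Delta n_l)$ in the step ($y$) and
   depth ($z$) directions (`fit_path_line()`, `estimate_deviation()`,
   `refine_track()`).

## Coordinate conventions

The workpiece coordinate system (WCS) is right-handed with $x$ the feed
direction, $y$ the step direction and $z$ pointing out of the bone; the
workspace origin sits at the start of the first path on the initial
surface, and layer $i$'s tip line lies at $z_0 - i\,d$. Micro-edges are
modelled in a cutter-fixed frame whose origin is the ball centre; a spin
rotation ($\omega t + \phi_0$ about the cutter axis), the feed translation
($v_d t$ along $x$), the incline rotation ($\delta_m$ about $x$) and the
path origin chain the cutter frame to the WCS (`pose_at()`). A rigid
*workspace deviation* — three small rotations about the workspace origin
plus a translation — models the executed workspace's misalignment
relative to the plan (`pose_deviation()`).

Voxel indexing uses the voxel-centre convention: the physical position of
voxel $(i,j,k)$'s centre is `origin + (index - 1/2) * spacing`, and gray
lookup is nearest-voxel (no interpolation), matching the premise that
milling interacts with discrete image voxels.

## The cutter and force model

A four-flute ball-end cutter of radius $R$ carries cutting edges winding
over the hemisphere; the edge of a flute starting at angle $\phi_0$
passes axial position angle $\theta_m$ at circumferential angle
$\phi_m = \phi_0 - \sin\theta_m \tan\beta_G$ with helix angle $\beta_G$.
Edges exist for $\theta_m \in [0, \arccos(h/R)]$, where $h$ is the
edge-to-centre clearance at the apex. The edge is discretized at the
midpoints of $d\theta_m$ bins (midpoint quadrature for the force sum).

Each engaged micro-edge contributes radial/axial/tangential forces from
the two-mechanism (shear + ploughing) model, weighted by the normalized
gray $\lambda$ at the edge position raised to a power $\mu$:

$$dF_\bullet = \lambda^\mu \left( K_{\bullet c}\, t_n\, db +
  K_{\bullet e}\, ds \right), \qquad \bullet \in \{r, a, t\}$$

with chip width $db = R\,d\theta_m$, edge-arc length
$ds = R\sqrt{1 + \cos^4\theta_m \tan^2\beta_G}\,d\theta_m$, and
undeformed chip thickness $t_n$ the projection of the feed per tooth
$v_t = 60 v_d / (nN)$ onto the outward radial direction (clamped at
zero: only the advancing side cuts). The components are rotated into the
instantaneous (non-spinning) cutter frame by the orthonormal matrix of
`micro_force_rotation()` and summed over the engaged edges; the spindle
torque is accumulated as $M_z = \sum R\cos\theta_m\, dF_t$. $M_z$ has no
closed form in the mechanistic literature we follow for the other three
channels; the tangential-moment definition used here is documented as a
package extension.

Two unit conventions in the shipped calibration deserve attention. The
calibration table shipped as the default names two values "Kte" and none
"Krc"; we assign
the large-magnitude $-1203.1$ to the radial *shear* coefficient
(N/mm$^2$) and keep $-75$ and $-199.1$ as radial/tangential *edge*
coefficients (N/mm), the only assignment consistent with the
shear-dominant magnitude ordering of such calibrations. Dimensional
consistency ($t_n\,db$ in mm$^2$, $ds$ in mm) likewise forces the
shear-vs-edge unit split. Both are configurable
(`force_coefficients()`).

Gray normalization is the saturating ramp
$\lambda = \mathrm{clamp}((x - m_\text{min})/(m_\text{max} -
m_\text{min}), 0, 1)$ with defaults $m_\text{min} = 80$,
$m_\text{max} = 1400$, $\mu = 1.815$ (`norm_params()`). Note that
cortical bone above $m_\text{max}$ saturates at $\lambda = 1$: paths
running entirely through dense cortex are *intentionally* harder to tell
apart, a property the validation protocols inherit.

## Engagement geometry

Which micro-edges cut depends on the material removed so far. The
layer-by-layer policy produces five qualitative engagement cases
(`classify_cwe_case()`): first/later path on the top layer, and
first/middle/last path on lower layers. Rather than parameterizing the
engagement boundary curves analytically, the package decides engagement
by a constructive-solid test (`is_engaged()`): a point is engaged iff it
lies inside the original stock (below the initial top surface) and
outside the union of swept volumes of all previously completed paths —
each a cylinder of radius $R$ along the path's centre line with
spherical end caps. This keeps the exact slot geometry, including the
scallop ridges between adjacent paths, and is validated against an
independent voxel-carving oracle (`carve_voxels()`) that rasterizes the
same removal history at 0.1 mm: the two agree on more than 99% of
micro-edge queries in the test suite.

Because a rigid workspace deviation moves all executed paths together,
the removal test is evaluated in the plan frame (where it is
deviation-invariant), while the stock-boundary test and the gray lookup
use the deviated positions. This makes first-layer over/under-cutting
under a depth deviation come out naturally.

## Sampling and numerical choices

* **Sample-centred timestamps.** Samples are stamped
  $t_s = (s - 1/2)/f_s$, so a tumbling window's temporal midpoint
  coincides exactly with its grid's landmark position; the noise-free,
  deviation-free closed loop then has exactly zero per-segment error.
* **Spindle-phase substeps.** At $f_s = 20$ Hz and 800 RPM the
  tooth-passing frequency (53 Hz) aliases badly if the wrench is sampled
  at isolated spindle phases. Each reported sample is therefore the mean
  over `n_sub = 8` spindle-phase substeps spanning one flute period —
  an abstraction of the force sensor's limited bandwidth that also makes
  the trace nearly independent of the (random) initial cutter phase, as
  the phase-insensitivity condition (`check_phase_condition()`,
  feed-per-tooth much smaller than a voxel) promises. With `n_sub = 1`
  the compiled trace reproduces the plain-R single-pose wrench to
  $10^{-9}$, which the tests exercise.
* **Tie-breaking.** Exact similarity ties are resolved toward the
  lexicographically smallest $(i, j, k)$; on phantoms with symmetric
  structure whole paths can tie exactly (see below).
* **Air-cutting gate.** Windows whose mean force magnitude falls below
  `min_signal` (default 0.5 N, an order of magnitude above the default
  sensor noise) carry no localization information and are excluded from
  the RANSAC stages; a window over intact bone produces tens of newtons
  under the shipped coefficients.
* **Degenerate RANSAC guards.** Coincident two-point samples are
  skipped; near-$x$-perpendicular fitted lines fall back to the anchor
  point when read at a plane $x = \text{const}$; the best model is the
  max-inlier one with ties broken by mean inlier residual, then refit by
  total least squares over its inliers.

## Refined estimates and what "deviation" means

Stage-5 outputs are per-path fitted lines and the rigid offsets
$(\Delta n_r, \Delta n_l)$, obtained per RANSAC iteration as the mean
fitted-minus-planned $y$/$z$ difference over `n2` sampled paths (read at
each path's planned midpoint), scored by the joint residual
$\varepsilon_s = \sqrt{(R_y - r_y - \Delta n_r)^2 +
(L_z - l_z - \Delta n_l)^2}$. The refined per-window tip estimate is the
point on the deviation-corrected current path at the window's scheduled
along-path position: the execution schedule pins the along-path
coordinate, and the along-path component of the workspace deviation is
deliberately *not* estimated (it is unobservable from line geometry).
The raw per-window landmark estimate is reported alongside.

For a rotated workspace a single $(\Delta n_r, \Delta n_l)$ is only the
best constant-offset summary; the ground truth used by
`evaluate_run()` is therefore the mean midpoint displacement of the
planned paths under the injected deviation
(`true_deviation_offsets()`), which is what the constant-offset model
can at best recover.

An architectural limit worth stating explicitly: matched landmarks lie
*on planned paths*, so the lateral channel is quantized at the step
$w$ (and the depth channel at $d$). Sub-quantum offsets are recovered
only insofar as matching dithers between neighbouring paths, and the
inlier threshold $t_2$ suppresses exactly that dithering. Lateral
deviations near $w/2$ are therefore the framework's worst case, and the
narrow two-path protocol exhibits this.

## Synthetic phantoms

Two generators make the framework fully testable without patient data.

**Stepped-gradient block** (`make_step_phantom()`): gray constant in
equal-width slabs stepping 0–1400 along one axis; 12 × 12 × 6 mm at
0.25 mm voxels with 10 steps in the reference protocol. Because the
block is homogeneous along $y$ and $z$, paths 2..n of a layer produce
*identical* prediction sequences, and all lower layers repeat each
other: the estimator is exact only up to these structural ties, which
the closed-loop test counts explicitly (a matched grid whose sequence is
bit-identical to the true grid's is a documented tie, not an error).

**Lamina-like block** (`make_lamina_phantom()`): a dense cortical shell
(default 1200 CT units, 1.5 mm thick, 0.25 mm logistic transition) wraps
a cancellous core (default 400), with a seeded Gaussian random texture
superimposed everywhere. The texture correlation scale is the
physiologically motivated parameter: vertebral trabecular separation is
0.5–1 mm, and that sub-millimetre density contrast is precisely what
makes a path's force profile a usable localization landmark. The default
smoothness is therefore 0.6 mm (Gaussian $\sigma$) with amplitude
200 CT units; a much smoother field would leave the per-layer force
amplitudes in the core indistinguishable and depth localization
impossible — not a failure of the estimator but an absence of signal.
What the phantom does *not* emulate: anisotropic trabecular
architecture, marrow-fat gradients, cortical porosity, metal or beam
artefacts, and patient-specific anatomy; passing the packaged protocols
therefore demonstrates the machinery under controlled density
variation, not clinical performance.

In the narrow protocol (11 layers × 2 paths on a 12 × 12 × 13 mm
block) the lateral margins are tight on purpose: a path deviated ~2.4 mm
outward grinds into the phantom's side cortical wall, as it would in a
narrow lamina, and the resulting high-amplitude windows are exactly the
kind of out-of-bank signal the RANSAC stages must survive.

## Validation protocols and problem sizes

Three frozen setups (`study_setup()`) are shared by the test suite and
`scripts/acceptance.R`; all use the reference milling parameters (feed
0.5 mm/s, 800 RPM, depth 0.8 mm, step 2.8 mm, incline 30°, four flutes,
R = 2 mm, h = 0.25 mm, $d\theta_m$ = 4°, $f_s$ = 20 Hz, ns = 15,
$m_\text{min}$ = 80, $m_\text{max}$ = 1400, $\mu$ = 1.815).

* **step** — closed-loop exactness: 3 layers × 4 paths × 8 mm paths,
  no deviation, no noise.
* **feed_sweep** — 10 layers × 4 paths × 6 mm paths on a
  12 × 16 × 12 mm lamina phantom; sinusoidal feed disturbance with
  amplitudes 0.05–0.30 mm/s about 0.5 mm/s (1 Hz, random phase), random
  cutter phase, sensor noise 0.05 N / 0.5 N mm, and small random pose
  deviations (rotations within 0.01 rad, translations within 0.5 mm per
  axis — the milder regime of navigation-grade misalignment; the
  disturbance study targets feed-rate robustness, not gross
  misregistration). Deviation-stage BestNum 30.
* **narrow** — 11 layers × 2 paths × 4.5 mm paths, the eleven printed
  deviation conditions of `narrow_plan_deviations()` (rotations up to
  0.069 rad, translations up to 2.5 mm), BestNum 8.

These sizes keep a full closed-loop run (simulation, matching against a
160–640-entry bank, two RANSAC stages) below ten seconds, so whole
protocol sweeps remain desk-scale; they are stated here as the package's
reference conditions. The acceptance script recomputes the headline
quantities from scratch and writes them as JSON; the test suite asserts
the same properties with the scaled-down tolerance its desk-scale
protocols warrant.

## Known limitations

* Force prediction is template-grade, not metrologically accurate: the
  coefficient calibration is bone-unspecific and the gray–strength power
  law is a proxy. Only time-domain *shape and scale patterns* are used
  downstream, which is the framework's design premise.
* The lateral deviation channel is quantized at the path step (see
  above); depth benefits from the finer layer pitch.
* Cutter runout, tool wear, structural deflection, thermal effects and
  chip evacuation are out of scope, as are streaming/online guarantees;
  the estimator processes complete runs.
* Bi-directional milling is supported by the planner and simulator
  (signed feed), but all packaged protocols mill unidirectionally, where
  valid cutting occurs on the positive-direction stroke.
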