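---
title: "Volume-based partial-arc angle planning: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-based partial-arc angle planning: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbarc)
```

## The problem

Rotational delivery (VMAT) treats a central thoracic target from a full ring
of gantry angles. That buys conformity but sprays low dose through both
lungs: the fraction of lung receiving at least 5 Gy (lung V5) rises with
the angular range of the arc, and lung V5 is a recognized predictor of
radiation pneumonitis. Restricting the arc to anterior and posterior
sectors spares the lateral lungs, but how wide should the sectors be for a
given patient? Answering that per patient during inverse planning is slow;
the volume-based algorithm answers it in closed form from a handful of
geometric measurements taken before optimization.

## The model

All inputs are plain geometry, measurable on the planning CT:

| symbol | meaning | units |
|---|---|---|
| `T` | transverse thorax diameter on the target's axial centroid plane | cm |
| `E` | target (PTV) width on the same plane | cm |
| `Lt` | target axial length on the coronal centroid plane | cm |
| `V_W` | whole-lung volume | cm^3 |
| `V_OW` | lung volume outside the cranio-caudal field extent | cm^3 |
| `V5^exp` | expected (tolerable) fractional lung V5 | - |

The treated corridor is the target width plus a 2 cm field border per
side, so the lateral gap between corridor and body surface on one side has
radius

$$R = \frac{T - E - 4}{2} \quad \text{(cm)}.$$

The lung that the beam never traverses ("restricted volume") is modelled
as a partial cylinder of radius $R$ spanning the field length $Lt + 4$:
when the arc is limited to a total angle $\theta_A$ (split between an
anterior and a posterior sector), the fraction $(360 - \theta_A)/360$ of
that cylinder escapes irradiation. Demanding that the unirradiated lung
equal the complement of the expected V5 gives

$$\pi R^2\,\frac{360 - \theta_A}{360}\,(Lt + 4) + V_{OW}
  = V_W\,(1 - V_5^{exp}),$$

which `solve_opa_angle()` solves in closed form,

$$\theta_A = 360\left[1 -
  \frac{V_W (1 - V_5^{exp}) - V_{OW}}{\pi R^2 (Lt + 4)}\right].$$

At the conventional $V_5^{exp} = 0.55$ the right-hand factor is the
familiar 0.45. Two boundary regimes are classified rather than clamped
silently: when $V_W (1 - V_5^{exp}) \le V_{OW}$ the lungs meet the target
without any restriction (`NEEDS_FULL_ARC`), and when even $\theta_A \to 0$
cannot spare enough lung the case is `INFEASIBLE`; the implied V5 of the
clamped angle is reported either way.

```{r}
g <- geometry_inputs(T_cm = 30, E_cm = 6, Lt_cm = 16,
                     V_W_cm3 = 4000, V_OW_cm3 = 300)
solve_opa_angle(g)
```

### Arc sequencing

The gantry of the assumed linac cannot pass through the 180/-180
meridian, so $\theta_A$ is delivered as six partial arcs -- three
clockwise, three counter-clockwise -- covering an anterior sector of width
$\theta_A/2$ and a posterior sector of the same width, with the last
clockwise arc stopping 1 degree short of 180 (the `sentinel_gap`). The
full-arc baseline is two 359-degree arcs. The collimator is rotated 5
degrees on alternating arcs. Endpoints carry $\theta_A/4$ in full floating
precision and are rounded to 0.1 degree only at serialization.

```{r}
sequence_opa_arcs(110)
```

## The synthetic phantoms

Two generators stand in for patient CT data.

**The realistic thorax** (`build_thorax_phantom()`) is built from quadric
solids: an elliptic-cylinder body (default 30 x 20 cm cross-section), two
lateral ellipsoidal lungs (about 4.5 L combined), a central mediastinal
target of configurable width `E` and length `Lt` (defaults 7 and 18 cm,
giving a target volume near 770 cm^3; clinical target lengths span roughly
6-25 cm), an ellipsoidal heart and a cylindrical cord. Gaussian jitter of
the solid parameters under a fixed seed yields reproducible cohorts. What
it deliberately does *not* emulate: CT intensities, tissue densities, lung
heterogeneity, concave targets, or realistic organ shapes. Tests passing
on it therefore validate the geometry pipeline and the ordinal behaviour
of the dose model, not absolute clinical dosimetry.

**The idealized cylinder** (`build_cylinder_phantom()`) realizes exactly
the solver's volume model: a lung cylinder of radius $R$ centred on the
rotation axis and a thin central target rod, so the treated corridor is
negligibly narrow. It exists so the closed form has a voxel-level oracle:
on this geometry the fraction of lung voxels traversed by no beam aperture
(`geometric_unirradiated_fraction()`) must match the analytic restricted
fraction. At 3 mm voxels the two agree within about 2 percentage points
across the clinically relevant angle range.

The corridor width matters here. The cylinder model ignores the corridor
the beam sweeps across the lung; with the realistic 7 cm target plus 2 cm
margins that corridor is ~11 cm wide, and at wide angles it irradiates
nearly all of two *lateral* lungs. The solver's self-consistency property
(unirradiated fraction $\ge 1 - V_5^{exp}$ within 5 points when
$\theta_A$ comes from the solver) consequently holds on the cylinder
idealization but not on the realistic phantom, where the package checks
the *ordinal* claim instead: the partial-arc plan's simulated lung V5
never exceeds the full-arc plan's, and V5 falls monotonically as
$\theta_A$ shrinks. This is a genuine limitation of the volume model, not
of its implementation.

## The dose simulator

Commercial inverse optimization and convolution dose engines are out of
scope; `simulate_dose()` is a deliberately simple forward model so the
chain is testable end to end. At each control point (4-degree spacing by
default, endpoints always included) a *parallel* beam travels along the
gantry direction and deposits $e^{-\mu d}$ at depth $d$ in a homogeneous
unit-density body ($\mu$ = 0.05 cm^-1 by default, megavoltage order),
inside a beam's-eye-view aperture equal to the target projection dilated
by the 2 cm field margin; scatter outside the aperture is zero. The sum
over control points is scaled so the target mean (or D95) equals the
45 Gy prescription. Parallel beams keep the restricted-volume geometry
exactly cylindrical, matching the solver's premise; divergence,
heterogeneity, MLC modulation, monitor units and delivery time are
non-goals. Dose conclusions drawn from it are ordinal only; nothing in
the package compares simulated organ doses to clinical values.

## Plan metrics

DVHs are cumulative ("volume receiving at least dose d"), binned at
0.05 Gy, volume-weighted by voxel volume. `V_at_dose()` interpolates the
curve linearly; `D_at_volume()` inverts it by finding the first bin whose
coverage falls below the requested volume and interpolating linearly (the
planning system's convention is not published; linear-on-the-curve is the
simplest defensible choice and is exercised against closed forms on ramp
fields). The homogeneity index is $HI = D_{5\%}/D_{95\%}$ (acceptable
1.00-1.40) and the conformity index $CI = V_{RI}/TV$ with the reference
isodose fixed at 100% of prescription (acceptable 0.9-2). Constraint
comparators follow the clinical wording exactly: strict `<` for cord
maximum, heart mean/V40 and lung mean; `<=` for the lung V-levels
(20/30/50/55% for V20/V15/V10/V5).

Gamma comparison (`gamma_index()`) uses the standard composite criterion,
3% global dose difference (of the reference maximum) and 3 mm
distance-to-agreement, a 10% low-dose cutoff, a search radius of 3 DTA
(gamma values capped there) and trilinear interpolation of the evaluated
grid at 10 samples per DTA along each axis -- the details routine QA
software leaves configurable are configurable here too, with those
defaults. The implementation searches offsets in order of increasing
distance and stops as soon as no point can improve, which makes the
identity comparison O(grid). It is n-dimensional: single-slice grids are
compared in-plane, so 2-D measurement planes and 3-D grids use the same
code path. An independent brute-force per-voxel search implementation
lives in the test suite and agrees with it to under half a percentage
point on fixture pairs.

## Numerical choices and degenerate inputs

* Extents are measured centre-to-centre plus one voxel; measured `E`,
  `Lt`, `T` converge to the construction values as spacing shrinks
  (checked at 3 vs 1.5 mm).
* "Out of field" is longitudinal only: lung outside the axial slab
  `[PTV_inf - 2 cm, PTV_sup + 2 cm]`, since the cylinder term already
  accounts for in-slab lateral lung. The 2 cm per-side margin mirrors the
  `+4` totals in the two closed-form equations and is configurable.
* Concave targets: the single-plane measurement is the clinical
  convention and the default; `extent_mode = "bounding_box"` is the
  documented alternative.
* Zero lung volume, an empty target, a target wider than the body, and
  angle requests outside $(0, 360)$ all raise explicit errors naming the
  problem; the solver classifies boundary regimes instead of guessing.
* The angle equation treats both lateral gaps through the single
  $\pi R^2$ term exactly as printed in its source; whether the two sides
  are meant jointly or per-side is ambiguous there, and the package
  implements the formula as stated.
* Determinism: phantoms are pure functions of their spec (jitter included
  via a private RNG stream), the simulator has no randomness, and report
  JSON carries no timestamps -- a rerun with the same seed is
  byte-identical.

## Problem sizes used in the shipped checks

The package's own verification runs use 3 mm voxels where a voxel-level
oracle is compared to the closed form (the cylinder phantom), 5 mm voxels
for the ten-anatomy ordinal sweep of simulated plans, and 6-8 mm voxels
for unit tests of the simulator and pipeline plumbing. These sizes were
chosen so the full suite exercises every claim at meaningful resolution
while remaining comfortable to run repeatedly during development;
measurement-accuracy claims are always stated relative to the voxel size
in use.

## Known limitations

* The cylinder model's corridor-width blindness (above) means the solved
  angle under-restricts for wide targets on realistic anatomy; clinically
  the angle feeds an inverse optimizer that re-balances, which is out of
  scope here.
* The dose model has no scatter, so the restricted region receives
  exactly zero dose; in reality it receives some scatter dose below 5 Gy.
* No DICOM RT Plan export; plan JSON is a research artifact, not a
  deliverable treatment plan.
* Masks are voxel sets; no polygon contours, margins growth or CT
  intensity simulation.
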