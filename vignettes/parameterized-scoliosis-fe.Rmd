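---
title: "Parameterized scoliotic spine finite-element models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterized scoliotic spine finite-element models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adolescent idiopathic scoliosis (AIS) combines a lateral (coronal)
spinal curve with vertebral axial rotation.  Severe curves (Cobb angle
above roughly 40 degrees) are treated with posterior instrumentation —
pedicle screws, longitudinal rods, transverse connectors — which fuses a
block of vertebrae.  The clinical concern addressed by this kind of
model is *adjacent segment degeneration*: after fusion, the mobile
segments next to the construct compensate for the lost motion, and their
discs and endplates see altered loads.

CT gives accurate 3D geometry but at high radiation dose and without
soft tissue; biplanar radiographs are routine and low-dose but are 2D
projections.  `spinefe` implements the middle road: a *parameterized*
finite-element model.  Landmarks digitized on the posterior–anterior
(PA) and lateral views are reduced to a small set of per-vertebra
parameters, and the full C7–L5 model is regenerated from a template
using those parameters, including coronal-plane vertebral deformation
(endplate wedging) that simple beam-element X-ray models cannot
represent.

## Coordinate conventions and the placement chain

Package-wide axes: **X** mediolateral, **Y** anterior–posterior
(anterior positive), **Z** vertical (cranial positive); right-handed.
Flexion is rotation about the mediolateral axis moving anterior points
caudally, and is reported as positive.

Each vertebra is described by (`vertebra_params()`):

* the superior posterior point `p_sup_post` (mm) — the anchor the
  template is translated to;
* body lengths `(Lx, Ly, Lz)` along the three axes (mm);
* the sagittal tilt `theta`, transverse tilt `phi`, and frontal-plane
  rotation `beta` (degrees);
* coronal tilts of the superior and inferior endplates,
  `beta_sup`/`beta_inf` (degrees).

Template coordinates are mapped to the model frame by the Y–X–Z Euler
chain `R = Rz(phi) %*% Rx(theta) %*% Ry(beta)` (`euler_transform()`),
followed by translation.  The chain is a proper rotation (isometry), and
`euler_angles_from_rotation()` inverts it for `|theta| < 90` degrees.

**One body rotation from two endplate tilts.** The coronal inputs are
the two endplate tilts, but the placement chain needs a single body
`beta`.  We use `beta = mean(beta_sup, beta_inf)` and apply the residual
difference as a linear *wedge taper* of the upper and lower halves of
the body before rotation (`morph_and_place()`).  Because a coronal
wedge followed by `Ry(beta)` composes exactly to an endplate tilt of
`beta + wedge`, the built mesh reproduces both endplate angles exactly
while the midline geometry carries the body rotation.  This was an open
design point; the mean+wedge split is the unique choice that reproduces
both tilts with a rigid-plus-taper map.

**Landmark fusion.** The PA view carries (X, Z), the lateral view
(Y, Z).  After per-view mm/px calibration and a shared vertical origin
(registration), each sampling point is fused to 3D (Z averaged across
views; cross-view disagreement beyond a tolerance is a hard error).
Eight points per vertebra (A–H: posterior/anterior midline corners of
both endplates, and the lateral rim points of both endplates) determine
all parameters in closed form; at zero digitization noise the
extraction is exact to floating-point round-off, which the test suite
asserts at 1e-6.

**Axial rotation.** With fused 3D points, `phi` is recovered
geometrically.  Radiographic practice instead grades rotation from the
pedicle shadow (Nash–Moe); `extract_params(nash_moe = ...)` overrides
the geometric angle through an editable table (defaults 0/5/15/25/35
degrees for grades 0–IV, linear inside five equal-width offset-ratio
bins, boundaries assigned to the lower bin).  The table is a
configuration default, not a measured quantity, and reports should state
the table used.

## The mesh

* **Template vertebra** (`build_template()`): an `nx * ny * nz` hex grid
  over a canonical unit box with a superellipse (rounded-rectangle)
  cross-section; the outer element layer is cortical bone, the interior
  cancellous.  Coarse posterior blocks — pedicles, laminae meeting at
  the midline, a spinous process, transverse processes — are extruded
  from the posterior face.  The template is deliberately programmatic
  and resolution-configurable; published node/element counts of
  proprietary templates are descriptive, not targets.
* **Discs** (`build_disc()`): three hex layers between facing endplate
  grids — two thin cartilage endplate layers (default 12% of disc height
  each) bonded to the bony endplates, and a core layer split into
  nucleus pulposus and annulus ground substance.  The nucleus covers a
  target 44% of the cross-section (greedy elliptical growth over cells,
  centred slightly posteriorly); coarse grids match the target as
  closely as their cell areas allow, and the test asserts 0.44 +/- 0.02
  at a resolution where cells are small enough for that to be
  meaningful.  Two criss-cross families of tension-only fiber trusses
  run on the annulus wall at +/-30 degrees to the transverse plane; the
  upper end of each fiber is placed by solving for the exact horizontal
  chord length along the upper ring polygon and tied to the bracketing
  ring nodes with a linear two-master constraint, so the nominal angle
  is met by construction rather than by mesh coincidence.
* **Ligaments** (`attach_ligaments()`): seven sets per segment (ALL,
  PLL, LF x2, ISL, SSL, intertransverse x2, capsular x2), all
  tension-only trusses between named attachment nodes; each ligament's
  tabulated area is divided evenly among its strands.  Facet joints
  carry no contact elements — consistent with restricting the analysis
  to flexion — so posterior elements of adjacent vertebrae interact
  only through ligaments.
* **Instrumentation** (`build_instrumentation()`): screws are beam
  chains from an anchor node at the pedicle centroid to a head node
  offset posteriorly along the vertebra's local posterior direction;
  rods are beam chains through the ipsilateral heads; transverse
  connectors join the two rods at the stated levels.  The anchor is
  tied to the eight pedicle-region nodes by an equal-weight
  translational multi-point constraint; its rotations are carried by
  the screw beam and resisted through the rod construct.  Default
  layout: bilateral screws T10–T11 and L1–L4, unilateral (left) T12,
  connectors at T11/L2/L3; lumbar screws 6.6 mm, thoracic screws and
  rods 5.5 mm, connectors 2 mm.

Node merging uses a 1e-6 mm tolerance — far below any geometric
feature.  Assembly rejects interpenetrating adjacent bodies (lattice of
interior probe points expressed in the neighbour's canonical frame) and
non-monotone caudal-to-cranial ordering.

## Materials

Defaults (`default_materials()`), all linear isotropic: cortical
12000 MPa / 0.3, cancellous 100 / 0.2, posterior elements 3500 / 0.25,
nucleus 1 / 0.499, annulus ground substance 4.2 / 0.46, cartilage
endplate 24 / 0.4; fibers 175 MPa, ligaments (E, total area mm^2):
ALL 7.8/24, PLL 10/14.4, intertransverse 10/3.6, LF 15/40, ISL 10/26,
SSL 8/23, capsular 7.5/30.  Two values are configuration defaults with
no tabulated source: the per-fiber area (0.5 mm^2) and the implant
alloy (titanium, 110000 MPa / 0.3).

## The solver

Linear-static, small-displacement kinematics (the materials are linear
and isotropic; the known consequence is flexion-stiff behaviour
relative to in vitro data, and we do not attempt large-rotation
corrections).  Units are N/mm/MPa internally; stresses are reported in
kPa only at the boundary.

* **Hex8** elements use 2x2x2 Gauss quadrature with *selective reduced
  integration* of the volumetric term for Poisson ratios above 0.49
  (the nucleus), the standard anti-locking treatment.
* **Trusses** are axial elements participating only while in tension:
  the active-set loop solves, removes compressed tension-only members,
  and repeats until stable (cap 50).  Positive load scaling leaves the
  active set invariant, which is why flexion-angle matching converges
  in at most two solves.  If the set cycles, the members that keep
  cycling out are frozen inactive (damped update) and iteration
  continues; the terminal set never contains a compressed tension-only
  member.
* **Beams** are two-node shear-deformable (Timoshenko) elements with
  circular sections (shear factor 6(1+nu)/(7+6nu)).
* **Constraints** (screw anchors, fiber ring ties) are eliminated
  through a sparse transformation `K -> T' K T`, and the reduced
  symmetric system is factorized with a sparse Cholesky
  (`Matrix::Cholesky`).
* **Loads**: the inferior face of the most caudal vertebra is fixed; a
  flexion moment is applied to the most cranial vertebra as an
  equal-and-opposite vertical force couple on the anterior and
  posterior rows of its superior endplate.  A couple avoids rotational
  DOFs on solid meshes; the published description applies a moment
  pre-operatively and an "incremental force" post-operatively, without
  stating the distribution, so we keep the same load type on both sides
  of the comparison and scale its magnitude (`match_flexion_angle()`,
  secant iteration, default tolerance 0.05 degrees on the total flexion
  angle).  "Total flexion" is the sagittal component of the rigid-body
  rotation fit of the most cranial vertebra relative to the fixed base
  (a curve-fit definition would be equally defensible; the rigid fit is
  stated and tested).

## Measures

* **Cobb** angle: coronal-plane projections of the upper end vertebra's
  superior endplate line and the lower end vertebra's inferior endplate
  line, in [0, 90] degrees.  Projection (matching radiographic
  practice) is the default because the 3D vector angle is inflated by
  axial rotation when the two lines are skew; the 3D mode is available
  behind `projected = FALSE` and the suite asserts 3D >= projected in a
  rotated configuration.  End vertebrae are user input, as in clinical
  reading.
* **TLK**: same construction projected onto the sagittal plane; default
  levels T10 superior to L2 inferior (the standard thoracolumbar
  junction definition; configurable).
* **MAE**: per-axis mean of absolute coordinate differences of one
  comparison point per vertebra (the superior posterior point) against
  a reference table.  The defining sum is divided by the number of
  levels: the quantity is named a *mean* absolute error and its
  published magnitudes are only plausible as means.
* **Segmental ROM**: per-vertebra small-rotation rigid fits of nodal
  displacements; a segment's ROM is the difference of sagittal
  components, so ROM is additive over nested blocks (asserted to 1e-6
  degrees).  Mobility shares divide a block's ROM by the total over
  non-overlapping blocks; overlapping block definitions are rejected.
* **Stress maxima**: maximum centroid von Mises stress over a named
  cartilage endplate, or over a segment's annulus (ground substance
  hexes plus fiber trusses), with argmax element and a
  ventral/dorsal-left/right side tag.

## The synthetic world

No imaging is distributed with this package, so `generate_spine()`
produces the test world: 18 vertebrae (L5 to C7), vertebral heights
22 mm lumbar / 18 mm thoracic / 15 mm at C7, 8 mm discs, body widths
tapering 42 to 24 mm and depths 33 to 16 mm cranially — configuration
defaults, not ground truth.  The coronal curve is a raised-cosine
lateral offset spanning L4–T9 (apex near T12/L1, the Lenke-5 pattern);
its amplitude is calibrated by 1D root finding so the ground-truth Cobb
angle meets the target (default 52 degrees, the modelled subject's
curve) within 0.5 degrees.  The default sagittal profile ramps from
+8 degrees above T10 to -12.2 degrees below L2, i.e. a
thoracolumbar kyphosis of 20.2 degrees, the subject's pre-operative
model value.  Axial rotation and endplate wedging default to zero and
are exercised explicitly in tests.  Digitization noise is isotropic
Gaussian on the projected coordinates.  The generator's closed-form
angle formulas are independent of the measurement module's point-based
ones, and the two are cross-checked to 1e-6 degrees.

What the generator does **not** emulate: realistic vertebral shape
variation, double-major curves, pedicle-shadow appearance (Nash–Moe
input is synthesized directly as grades/ratios), posture differences
between standing radiographs and supine CT beyond a configurable rigid
shift, and projective (diverging-beam) distortion — views are
orthographic.  A green end-to-end test therefore establishes pipeline
correctness and directional biomechanics, not patient-specific accuracy.

## What the acceptance surfaces do and do not establish

The single patient's absolute results are not reproducible without the
original imaging and template, so acceptance rests on: (1) the report
module reproducing every published ratio/share/discrepancy exactly from
the published inputs; (2) the property suite (transform oracle, patch
tests, closed-form beam, energy balance, oracle equivalences,
round-trip recovery) at stated tolerances; (3) a scaled-down
directional run: a Cobb-52 synthetic spine, instrumented T10–L4, its
postoperative total flexion matched to the preoperative 10 Nm solve
within 0.05 degrees, asserting that the fused block retains less than
half its mobility and that the cranial unfused share of total mobility
increases.  At the default coarse resolution the preoperative total
flexion is much larger than a real spine's (soft synthetic discs, no
facets, linear kinematics); the directional claims are robust to this,
the absolute angles are not, and nothing asserts them.

One stated property was revised after analysis: "nucleus volumetric
strain < 1% of deviatoric strain" cannot hold for a confined,
pressure-dominated nucleus at nu = 0.499, where
`vol/dev = 3(1-2 nu)/(1+nu) * p/q` and p/q is of order 10-100 precisely
because the nucleus acts as a fluid core.  The suite instead asserts
hydrostatic dominance (volume-weighted q/p < 0.5) and a net core volume
change below 1e-3 — the two statements near-incompressibility actually
guarantees.

## Known limitations

No facet contact (flexion only; extension, lateral bending and axial
rotation are out of scope); linear small-displacement kinematics;
isotropic materials; coarse programmatic template (no mesh-convergence
claim); screw-bone interface idealized as a translational tie (no
pullout/loosening); orthographic projection model for the synthetic
views; single-curve generator.
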