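---
title: "Mapping bony impingement within the prosthetic clearance cone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bony impingement within the prosthetic clearance cone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

After total hip arthroplasty the articulation is a ball joint whose range
of motion is ultimately limited by prosthetic impingement (PI): the stem
neck striking the rim of the liner. Bony contact — femur against pelvis
(BTBI) or stem against pelvis (ITBI) — only matters clinically when it
occurs *before* PI, because motion beyond PI is blocked anyway. The
quantity that formalises "before PI" is the **conical clearance angle**
(CCA): at a given posture, the largest aperture of a hypothetical conical
motion of the femur, about its current axis, that produces no stem–liner
contact at any azimuth. Bony contact occurring within a small fraction of
the posture's CCA is high risk (little clearance is left when it
happens); contact near the full CCA is low risk. The package grades each
contacted surface patch into four bands, 25/50/75/100 % of the
per-posture CCA, coloured red/yellow/green/blue, and a face always keeps
the most severe band it was ever assigned across all postures and
activities — the bands nest (a cone of aperture `a` contains every cone
of smaller aperture), so "smallest fraction wins" is the only
information-preserving collapse.

The search is a grid sweep, not an optimisation: apertures are visited at
`alpha = 0, dt_alpha, 2 dt_alpha, ...` and azimuths at multiples of
`dt_con`, and the first aperture showing PI is reported. Starting at
`alpha = 0` makes a zero CCA meaningful: it encodes that the posture
itself impinges, which is exactly the PI information a clearance box plot
conveys. If no PI is found the search caps at `dt_alpha * (n_alpha - 1)`
and the posture is marked `capped`.

## Conventions the inputs must follow

All meshes (pelvis, femur, stem, liner) are triangle surfaces in
millimetres, co-registered in one frame with the implants at their
planned pose. The joint is modelled as a pure ball joint about
`hip_center`; no translation or subluxation. The anatomical frame is
pelvis-fixed: x antero-posterior (anterior positive), y medio-lateral
(lateral positive for a right hip), z superior. Postures compose in the
fixed order flexion (about y), abduction (about x), then axial rotation
about the current femoral axis; extension and adduction are negative
flexion and abduction, external rotation is negative rotation. These
conventions are a design choice — clinical activity definitions name
angles but not a rotation composition — and they matter only in that the
same convention must describe the activities and the meshes. Left hips
are handled by mirroring about the sagittal plane on load and mirroring
the outputs back, so the internal maths always sees a right hip.

The "femoral axis" at a posture is the line from `hip_center` through the
posture-transformed `femur_axis_point`, a distal point supplied with the
model (a mechanical-axis proxy). Whether a clinical user prefers the
mechanical or the anatomical shaft axis, the choice is encoded entirely
in that one point.

## Collision testing

Surface crossing is detected by treating every mesh edge as a segment and
testing it against the opposing triangles with the Möller–Trumbore
determinant form, in both directions (A edges vs B triangles and B edges
vs A triangles). Determinants below 1e-12 (relative to the edge/triangle
scale) are treated as parallel; segment and barycentric bounds are closed
at exactly 0 and 1; boundary points are deduplicated at 1e-9 mm. A
uniform spatial grid over each mesh's triangles provides the broad phase;
its contract is *equality* with the exhaustive all-pairs test, which the
package keeps as a pure-R reference path (`method = "exhaustive"`) and
the tests assert on generically posed mesh pairs. Exactly symmetric
touching configurations (a vertex grazing a triangle edge with
barycentric coordinates landing exactly on 0 or 1) can differ between the
two paths at the last floating-point bit; such configurations have
measure zero and do not arise for generically posed surfaces.

This is a *surface-crossing* notion of contact: a mesh entirely inside
another without its surface crossing reports no intersection. That
matches the physical reading (surfaces in contact) and keeps the test
meaningful for open segmented bone. For the clearance sweep the whole
aperture/azimuth schedule is evaluated in compiled code against spatial
grids built once per posture; because a rigid pose of mesh A against B is
equivalent to posing B by the inverse against A, both test directions
reuse their static grids.

## Region growing and side selection

The crossing curve marks *crossed vertices* (vertices incident to a
crossed edge, plus vertices of faces pierced by an opposing edge). A face
none of whose vertices is crossed is a *seed*; growth proliferates child
faces across shared edges between seeds and stops at the curve. Faces
touching the curve straddle the boundary and join no cluster, so each
grown region is slightly smaller than the true bounded area — negligible
at fine mesh resolution. The implementation starts from the lowest-index
seed for reproducibility; membership is provably start-independent
(connected components), which the tests assert against an independent
breadth-first-components oracle. Straddling faces are still recorded as
impinged at the band where they crossed — they are literally intersected
— they are only excluded from cluster growth.

Which side of the curve is "impinged" is decided per cluster: the
centroid of the cluster's largest face, offset inward (against the face
normal) by 0.1 × the median edge length, is tested for containment in
the opposing closed mesh by ray parity (rays that graze an edge or vertex
are detected and retried along a different direction). If the opposing
mesh is open — segmented bone need not be watertight — the package falls
back to marking every boundary-adjacent cluster smaller in area than its
neighbour across the straddling band, and warns; the heuristic reflects
that penetrated patches are local, but it is explicitly a fallback, and
the fixtures are all closed so the exact test governs everywhere the
package's accuracy is measured.

For ITBI the *entire* stem is tested against the pelvis. Contacts of the
stem region buried in the femoral canal are geometrically real but
physically impossible (bone covers the stem there); they are exactly the
pelvis faces that the BTBI analysis also flags, so the filter subtracts
the common faces from the ITBI map and leaves the BTBI map unchanged.

## Parameters

| parameter | default | meaning |
|-----------|---------|---------|
| `dt_pos`  | 5° | posture step along an activity |
| `dt_alpha` | 1° | aperture step of the clearance search |
| `n_alpha` | 61 | number of apertures; cap = `dt_alpha * (n_alpha - 1)` = 60° |
| `dt_con`  | 10° | azimuth step of the conical motion (divides 360) |
| fractions | 0.25/0.5/0.75/1 | severity bands, red/yellow/green/blue |
| weld tolerance | 1e-6 mm | vertex merge on STL load |

`dt_pos`, `dt_alpha` and `dt_con` trade accuracy for time: coarser
posture or azimuth grids can only miss contacts (underestimate the
impinged area), and a coarser aperture grid quantises the CCA upward by
at most one step. The 60° cap bounds the sweep; any posture reaching it
is reported `capped` rather than silently truncated. The examples,
tests and the acceptance script run with `dt_con` of 10–90° and fixture
mesh edges of 2.5–3 mm, sizes chosen so each sweep completes in seconds
while staying within the fixtures' derived angular error bounds;
clinical-resolution runs simply use the defaults and finer meshes.

## The fixture generator

Patient geometry cannot ship with a package, so the test bed is a
parametric model of the same mechanical situation with closed-form
contact angles:

* **liner**: spherical-cap shell, inner radius $R$, opening half-angle
  $\beta$ about the cup axis ($-z$), closed by a rim annulus;
* **stem**: ball (radius < $R$, concentric — it can never cross the
  liner) plus a cylindrical neck of radius $r$ along $-z$;
* **femur proxy**: a cylindrical shaft segment on the femoral axis;
* **pelvis proxy**: a flat plate facing the joint beyond the shaft's
  swept reach, optionally carrying a spherical prominence ("bump").

Tilting the neck by $t$ towards any azimuth, the inner rim circle point
at that azimuth subtends angle $\beta - t$ with the neck axis, so
contact occurs at

$$t^\* = \beta - \arcsin(r / R),$$

azimuth-independent by symmetry. A bump sphere (radius $r_b$, centre at
distance $D$ and polar angle $\gamma$ from the neutral axis) is first
met by the shaft (radius $r_s$) at

$$t_\mathrm{reach} = \gamma - \arcsin\big((r_s + r_b) / D\big),$$

with a sentinel when the contact point falls outside the shaft's axial
span. Both formulas are validated in the tests by dense brute-force pose
sweeps before being used as oracles. Choosing $\gamma$ places the bump
in any clearance band, which is how band assignment is tested
end-to-end. Meshing perturbs the contact angles: facet chords inscribe
the smooth cylinder and the rim polygon's chord midpoints sit radially
inward of the rim circle. The tests bound this by the two closed-form
perturbed contact angles (inscribed-radius and chord-midpoint variants)
plus 0.2° for second-order terms, so the clearance recovery tolerance is
`dt_alpha` + a derived mesh term (≈0.5° at 2.5 mm edges), not a fitted
number.

What the fixtures do *not* emulate: real acetabular and femoral shape
(incongruent surfaces, osteophyte geometry), mesh noise from
segmentation, open boundaries, and non-concentric planned poses. Passing
tests therefore demonstrate the correctness of the geometry engine and
the sweep logic under known ground truth, not clinical accuracy on
patient anatomy.

## Numerical choices and degenerate inputs

* Zero-area facets are rejected at load with the facet named; duplicated
  STL corners are welded at 1e-6 mm (STL carries no connectivity and
  region growing needs shared edges).
* An empty liner (or stem) makes `check_pi` false and the clearance
  search cap — useful for "no implant" what-ifs.
* A zero CCA posture sweeps only `alpha = 0`; its contacts are red by
  the band rule (the smallest fraction containing 0).
* Severity ratios compare as `ratio <= fraction + 1e-9` so binary
  fractions of exact grid apertures never misclassify by rounding.
* The aperture sweep includes `alpha = CCA` itself (band IV is *100 %* of
  the clearance), consistent with grading contact that occurs exactly at
  the prosthetic limit as lowest risk rather than ignoring it.
* Face colours serialise to binary little-endian PLY with per-face uchar
  RGB and double-precision vertices, so write–read round trips are
  exact; STL (which cannot carry colour) is used for geometry input.

## Design choices that were genuinely open

* **Severity collapse order.** Looping bands ascending and never
  overwriting is equivalent to "smallest flagged fraction wins"; the
  package stores the per-face minimum aperture ratio, from which any
  band's pre-collapse face set can be recovered (`itf_faces()`), and the
  nesting of those sets is a tested invariant.
* **Accumulation across activities.** All activities contribute to one
  map; per-activity attribution is preserved in the map's provenance
  table rather than in separate maps.
* **Deterministic start for region growing.** A random start triangle
  and the lowest-index seed give identical clusters; the deterministic
  choice makes whole-pipeline byte-identical reruns possible, which the
  run manifest promises.
* **Femur-side BTBI recording.** Crossing faces are recorded
  symmetrically on the femur so the femur can be rendered too;
  resection guidance usually targets the pelvis, but the information is
  free.

## Limitations

* Contact is detected at discrete sweep samples; no continuous collision
  detection between samples, no penetration depth, no contact force.
* The joint model ignores pelvic tilt dynamics, translation/subluxation
  and soft tissue.
* Pre-/post-operative comparison assumes co-registered inputs and
  compares band *areas*, not face correspondences; registration and
  segmentation error therefore leak into reduction percentages, including
  negative reductions, which are reported with a warning rather than
  clipped.
* Osteophyte versus genuine bone is not classified; the maps say where
  contact happens, not what the tissue is.
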