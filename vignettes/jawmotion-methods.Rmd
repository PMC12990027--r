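---
title: "From four static occlusal records to a continuous jaw-motion file: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From four static occlusal records to a continuous jaw-motion file: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawmotion)
```

## The problem

Prosthetic restorations are routinely designed against static occlusal
relationships, then adjusted chairside because they interfere during
functional excursions. Virtual articulators in dental CAD can simulate
excursions, but commonly from average anatomical parameters, and
patient-specific jaw-tracking hardware is costly and vendor-locked. A
low-cost alternative: capture, with any intraoral scanner, four *static*
interocclusal records of the mandibular arch — maximum intercuspation
(MIP; for edentulous cases, centric occlusion at the planned vertical
dimension plays the role of MIP), right laterotrusive, left laterotrusive,
and full protrusive — all re-registered against the same fixed maxillary
arch, and reconstruct a continuous motion trajectory between these border
positions in software. `jawmotion` implements that reconstruction and its
export to a CAD-consumable XML motion file.

## The model

The mandible is treated as a single rigid body. Its pose at any instant is
an element of SE(3), stored as a unit quaternion plus a translation in
millimetres; the fixed maxillary arch defines the world frame, and the MIP
record defines the reference pose (identity). The whole pipeline is then:

1. estimate one rigid transform per excursive record (mapping the MIP mesh
   onto it),
2. interpolate poses between MIP and each excursive endpoint,
3. serialize the pose sequence.

### Pose estimation

All four records are assumed to already sit in the maxillary-anchored
frame. (If a scanner anchored on the mandible instead — so the "motion"
appears on the maxilla — `rebase_anchor()` applies the group inverse,
rotation conjugated and translation negated-and-rotated, to re-express it.)

Two estimation routes, selected per record by `check_correspondence()`:

* **Corresponded** (equal vertex/facet counts and identical facet index
  triples — what duplicating a scanner project and re-exporting the same
  mandibular mesh in each pose produces): the closed-form least-squares fit
  (Kabsch). Center both point sets on their centroids, take the SVD
  \(U D V^\top\) of the cross-covariance \(P_c^\top Q_c\), and set
  \(R = V\,\mathrm{diag}(1, 1, \det(V U^\top))\,U^\top\),
  \(t = \bar q - R\bar p\). The determinant correction flips the smallest
  singular direction whenever the unconstrained optimum would be a
  reflection, so the result is always a proper rotation. By default all
  shared vertices are tracked; an index subset can be supplied, but no
  particular landmark subset is assumed. Collinear degenerate
  configurations are solved anyway and flagged in provenance — a real
  dental arch is never collinear, so the flag only guards synthetic edge
  cases.
* **Uncorresponded** (remeshed or decimated exports): iterative closest
  point — alternate brute-force nearest-neighbour pairing with the Kabsch
  fit until the pairing RMS stabilizes. ICP is initialized by centroid
  alignment (which absorbs the bulk translation) and otherwise at the
  identity rotation: in the shared maxillary frame the records differ only
  by millimetre-scale excursions, so no global search is attempted.
  Failure to converge returns the best transform with a flag, not an
  error. Nearest-neighbour search is plain matrix algebra: arch meshes are
  O(10³) vertices, so the quadratic pairing costs milliseconds and avoids
  a spatial-index dependency.

Which route produced each pose, its residual RMS, and degeneracy and
convergence flags are recorded in the returned `pose_set`'s provenance.

### Interpolation: "quantified points"

Between two poses, rotation is interpolated by shortest-arc spherical
linear interpolation of the quaternions (constant angular speed; signs
aligned so the quaternion dot product is non-negative — excursive rotations
are a few degrees, nowhere near the antipodal ambiguity, but alignment is
enforced anyway) and translation linearly and independently. A
screw-motion (coupled) interpolation was considered and rejected: the
decoupled model is the simplest one consistent with treating per-point
transition vectors independently, and at these magnitudes the paths differ
negligibly.

Each segment emits a user-defined count *n* of transitional frames — the
"quantified points" — at fractions \(t_k = k/(n+1)\), *strictly between*
the records: the static records themselves are emitted once as keyframes,
bit-identical to the estimated transforms. So a 100-point interpolation
between MIP and protrusion yields exactly 100 intermediate poses, and the
default closed envelope
MIP → protrusive → MIP → right → MIP → left → MIP with shared junction
keyframes gives \(6 \times 100 + 7 = 607\) frames. The playback order is
configurable (any MIP-anchored sequence); whether return strokes are
included is a user choice, and the default includes them so the envelope
closes.

Time is parameterized at a uniform frame interval (default 0.01 s, i.e.
100 Hz — typical motion-capture rate). No velocity profile or easing is
applied: the source records carry no temporal information, so any profile
would be invented. This linearity is a stated limitation, consistent with
the approach not capturing the nonlinear character of true mandibular
movement.

### Export format

The vendor `.jawMotion` schema is proprietary and unpublished, so the
package defines an open, documented XML dialect
(`inst/extdata/jawmotion-schema.md`): a mandatory schema version, metadata
entries, and one record per frame holding the time and a row-major 4×4
homogeneous matrix (CAD ecosystems consume matrices; quaternions stay
internal). Readers re-validate everything: orthonormal rotation block with
determinant +1 (reflections rejected, naming the frame), exact
`(0,0,0,1)` bottom row, strictly increasing times, and no silent default
for a missing schema version. The `.jawMotion` extension mode writes a
byte-identical payload; a vendor-specific mapping can be added as a
dialect once the vendor schema is known — guessing element names was
deliberately avoided.

Numbers are printed with 12 significant digits. A 9-digit format was
considered (smaller files) but round-trips a 10–100 mm translation only to
about 5·10⁻⁹ mm, violating the 10⁻⁹ round-trip contract the tests enforce;
12 digits restore it with ~20 % larger files.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_per_segment` | 100 | frames | the worked-example density: 100 quantified points between MIP and protrusion |
| `frame_interval` | 0.01 | s | 100 Hz playback; no temporal data exists in the records |
| `sequence` | MIP→P→MIP→R→MIP→L→MIP | — | closed envelope, protrusive first; any MIP-anchored order is allowed |
| `icp_max_iterations` | 50 | — | excursions are small; ICP converges in ~10–20 iterations on fixtures |
| `icp_tol` | 1e-10 | mm | RMS-change stopping criterion, far below scan noise |
| smoothness witness | 5° / 2 mm | per frame | `validate_trajectory()` bound; generous vs the ~0.1°/0.08 mm steps at defaults |

## The synthetic world

`generate_arch_mesh()` builds a horseshoe band — a parabolic arch 56 mm
wide and 45 mm deep swept with a 9 mm bumped profile imitating cusps, plus
0.05 mm seeded vertex jitter — non-planar and of full affine rank, so
registration on it is well posed. `generate_pose_records()` poses it:
protrusion as pure translation (default 8 mm anterior advance with a 2 mm
inferior drop as an incisal-guidance proxy) and laterotrusion as pure yaw
(default 10°) about a vertical axis through a condylar proxy 50 mm lateral
of the midline. These magnitudes are clinically plausible placeholders
chosen once — the source workflow reports no kinematic magnitudes — and
they were fixed before any acceptance measurement. Per-vertex Gaussian
noise (seeded per record) emulates scan noise.

What the generator does **not** emulate: real tooth morphology, occlusal
contacts, Bennett side-shift, condylar-path curvature, partial overlap
between scans, or scanner artifacts such as holes and normals noise. A
green test therefore establishes the *geometric pipeline* — registration
recovers generating transforms (to 10⁻⁹ noiseless; translation error well
under σ at 0.05 mm noise, shrinking like σ/√n), interpolation is exact and
uniform, serialization is lossless — not clinical accuracy of any
particular scanner's records, which only validation against physical jaw
tracking could establish.

## Numerical choices

* Quaternions are kept unit-norm and sign-canonicalized (first nonzero
  component positive) so pose comparisons are well defined.
* SLERP switches to normalized linear interpolation below a 10⁻¹²
  quaternion-dot gap from 1, where the sine ratio loses precision;
  `t = 0`/`t = 1` return the endpoint objects exactly, which is what makes
  keyframe equality a zero-tolerance property.
* STL vertex merging uses exact bit-equality (via full-precision decimal
  keys), never a tolerance: tolerance merging could collapse distinct
  vertices and would break the identical-ordering property corresponded
  registration relies on. Zero-area facets are kept — registration uses
  vertices, and dropping facets would break correspondence.
* Binary STL stores float32; tests budget `4 · 2⁻²³ · max|coordinate|`
  for that quantization. ASCII output prints 9 significant digits, which
  over-covers float32.
* Reading an STL normalizes vertex order to first occurrence in the facet
  soup; geometry round-trips exactly (per-facet corners), and a second
  write/read is order-stable bit for bit.

## Known limitations

Rigid-body, decoupled, constant-speed interpolation between four border
records: no condylar guidance geometry, no neuromuscular dynamics, no
contact detection between arches, and accuracy bounded by the static
records' precision. The exported dialect is open but not yet mapped to any
vendor's native schema.
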