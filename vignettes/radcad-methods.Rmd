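---
title: "Methods: volumes, reconstruction, annotation and the plug-in contract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumes, reconstruction, annotation and the plug-in contract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radcad` is a desk-scale workbench for CAD (computer-assisted
detection/diagnosis) software development: it covers the path from DICOM
series to gold-standard voxel annotations, sandboxed plug-in execution
and structured radiologist feedback. This vignette records the models,
conventions and numerical choices the package commits to, and what its
validation does and does not demonstrate.

## Volume model and coordinate conventions

A `cad_volume` is a 3D scalar grid with spacing (mm), origin and
orientation. Conventions, fixed once and used everywhere:

* Voxel indices are **0-based**, in `(x, y, z)` order with x fastest in
  memory; `data[x + 1, y + 1, z + 1]` is voxel `(x, y, z)`.
* Patient coordinates follow the DICOM **LPS** convention. The mapping is
  `mm = origin + R · (index · spacing)` where the columns of `R` are the
  row and column direction cosines and their cross product (the slice
  normal). Direction cosines must be unit length and orthogonal, so the
  inverse map is a transpose — `voxel_to_mm()` and `mm_to_voxel()` are
  mutually inverse to better than 1e-9.
* DICOM `PixelSpacing` is `(row spacing, column spacing)`, i.e.
  `(dy, dx)`; the loader swaps it into `(sx, sy)`.

Slices are ordered by the projection of `ImagePositionPatient` onto the
slice normal, ascending, with `InstanceNumber` only as a tie-break:
positions are geometry-authoritative while instance numbers can be
renumbered by intermediate systems. The slice spacing is the mean
adjacent-position difference; a gap deviating by more than 1e-3 relative
is an **error** naming the offending pair, never a silent resample — the
plug-in contract (below) guarantees a regular grid, so an irregular
series must not enter the store. A single-slice series takes its slice
spacing from `SliceThickness`, falling back to 1 mm.

The DICOM dialect is deliberately narrow: Explicit VR Little Endian,
monochrome, single-frame, no sequences; everything else is an explicit
rejection. The same philosophy governs the MetaImage codec:
uncompressed, little-endian, local raw file, `MET_SHORT`/`MET_USHORT`/
`MET_UCHAR` only. Floating-point header fields are written with `%.17g`
so doubles survive the ASCII round trip bit-exactly.

## The synthetic series generator

The generator is first-class, tested code, not a fixture dump: it emits
complete DICOM payloads (the same bytes a scanner-derived series would
present to the loader) for a grid of chosen size and spacing, with
Gaussian background noise and planted spherical lesions. A voxel belongs
to a lesion when its centre lies within the lesion radius of the lesion
centre, distances in mm (spacing-aware), and lesion voxels are *set* to
the stated intensity, so ground truth (centre, voxel count, mean
intensity) is known exactly. One integer seed drives a single PRNG
stream and is recorded in the emitted `SeriesDescription`; a fixed seed
yields byte-identical payloads.

Default study conditions used throughout the validation: 40×40×24
voxels at 1 mm isotropic spacing, background 50, lesion intensity 400,
radii 2–3.5 mm, lesion centres on a coarse lattice (12 mm pitch) so
components can never merge under 26-connectivity; end-to-end recovery
runs use noise_sd = 0 so that exact-count recovery is a well-defined
target. These sizes keep a full multi-replicate validation in seconds on
one core while preserving the structure of the clinical inputs
(thin-slice series of a few hundred kilobytes to a few megabytes); the
in-plane matrix is smaller than clinical 512×512 series, which changes
nothing about the code paths exercised, only the constant factors.

What the generator does **not** emulate: anatomy and texture, partial
volume effects, scanner reconstruction kernels, non-spherical lesions,
orientation other than axial-identity, and compressed transfer
syntaxes. Passing tests therefore demonstrate the correctness of the
*infrastructure* (geometry, formats, contracts, bookkeeping), not
clinical detection performance of any algorithm.

## The reconstruction kernel

One deterministic kernel serves every consumer, so a section computed
for a viewer, a candidate snapshot or a test is always the same array.

* **Orthogonal sections** are exact grid-plane copies — no
  interpolation, lossless by construction.
* **Oblique sections**: output pixel `(i, j)` samples patient space at
  exactly `origin + i·u + j·v` (sample-at-corner; no half-pixel offset —
  stated explicitly because half-pixel conventions are the classic
  source of off-by-half bugs). Trilinear interpolation uses the 8
  neighbouring voxels with product weights; nearest-neighbour rounds
  half-up per axis.
* **Boundary policy**: a sample exactly on a voxel boundary uses the
  mathematical weights, so a zero-weight neighbour contributes nothing
  even when it lies outside the grid — volume faces are sampled without
  fill bleeding. Samples within 1e-9 voxel of the boundary are snapped
  onto it before interpolation; this guards planes constructed to lie
  exactly on the grid against floating-point noise in the patient-space
  arithmetic, and is far below any clinically meaningful scale (1e-9 of
  a millimetre-scale voxel). Samples genuinely outside the volume yield
  the fill value, which defaults to the volume minimum.
* **Window/level**: `round(clamp((v − (L − W/2))/W, 0, 1) · 255)` with
  round-half-up, so the window centre maps to display grey 128. The map
  is monotone non-decreasing.

The interpolation scheme for oblique planes is an assumption (trilinear
as the standard viewer-quality choice), not a reconstruction of any
particular viewer's code; orthogonal sections are kept lossless.

## Annotation data model

Cases group one or more series under a project; projects fix the
attribute schemas. The supported schema subset is `type`
(object/string/number/integer/boolean), `properties`, `required`,
`enum`, `minimum`, `maximum` on flat objects; any other keyword is an
explicit "unsupported keyword" rejection so a schema is either fully
enforced or refused. Validation is deterministic and order-independent
over document keys, one violation record per failing constraint.

Revisions are **append-only with copy semantics**: a revision is an
immutable snapshot of case attributes plus per-series label lists, and a
correction is always a new revision. Copy semantics (rather than
reference sharing between revisions) is the simplest arrangement that
makes immutability structural; at annotation scale the duplication cost
is negligible. Timestamps are clamped non-decreasing. The series list of
a case can never shrink.

Voxel labels are sparse binary masks with an offset bounding box, kept
**tight** on every mutation (every face of the box touches a set voxel);
an all-empty label is legal with size `(0,0,0)` — a named-but-unpainted
label. The brush is spherical with its radius in mm, so painting is
spacing-aware and an anisotropic grid receives an ellipsoidal voxel
footprint. Brushes currently materialise the full grid internally, which
is exact and fine up to typical label-editing sizes; series of clinical
matrix sizes are edited label-by-label, not whole-volume. Labels are
run-length encoded inside JSON documents and exported as uint8 0/1
full-grid MetaImage volumes for bit-exact interchange. 2D geometric
annotations (ellipse/rectangle, mm bounds on an orthogonal plane) are
stored and round-tripped but never rasterized to voxels — no
rasterization semantics are defined for them.

Content integrity: each series gets a SHA-256 fingerprint over the slice
count plus per-slice pixel buffers at case creation.
`series_integrity_check()` warns iff current content differs — a single
changed pixel or an added slice both fire; geometry metadata does not
enter the fingerprint. Case ids are random 160-bit hex strings;
collision is treated as impossible at any realistic store size.

## Anonymization

The PHI tag list is configuration (`inst/extdata/phi_tags.txt`, one
keyword per line): names, identifiers, birth date, address, physician
and institution, and private tags (odd group numbers) are always
stripped in addition. Anonymization removes tags rather than replacing
them with placeholders, is idempotent, and touches metadata only — pixel
data never passes through it. The same list is subtracted (last) from
the tag set exposed to plug-ins and applied to case exports. The default
list is a documented choice, not a reconstruction of any site's policy;
deployments with stricter rules extend the file.

## The plug-in contract and job manager

Jobs run strictly one at a time, FIFO. The work directory layout is the
bit-exact contract:

```
series/<i>/volume.mhd     # MetaImage header
series/<i>/volume.raw     # voxel buffer, x-fastest, little-endian
series/<i>/metadata.txt   # "key = value" lines, selected tags only
out/                      # writable; results.json + display files
```

Plug-ins never receive DICOM files (so they never parse DICOM and never
see PHI); the selected-tag list is modality, geometry and acquisition
parameters only, with the PHI list subtracted last. Two runtimes satisfy
one executor contract: an in-process R function and a subprocess runner
whose working directory is the job's work directory. A container runtime
with a single bind mount and no network would satisfy the same contract;
it is not bundled because the package targets environments without a
container daemon, and the contract itself — no DICOM, no PHI, work_dir
as the only writable path — is what the tests pin down.

`results.json` (schema version 1) is
`{"candidates": [{"rank", "location_voxel", "confidence",
"volume_mm3"?}], "displays": [...]}` with ranks unique and contiguous
from 1 and locations inside the volume; violations, nonzero exits and
missing files all fail the job with the reason recorded and the queue
proceeding to the next job.

The bundled **toy blob detector** (threshold, 26-connected components,
size filter, rank by descending voxel count with ties broken by
ascending centroid z/y/x, location = rounded centroid, confidence = mean
intensity) is a deliberately simple stand-in that makes the end-to-end
pipeline verifiable against planted ground truth: on noise-free
fixtures it must recover every planted sphere above threshold exactly,
with centroids within one voxel. It is not a clinical detector and sets
no performance baseline.

Feedback uses four classes — known TP (lesion the reader also found),
missed TP (lesion the reader overlooked), FP, pending — plus
false-negative location marks. An entry is accepted only when complete
(every displayed candidate classified, classes from the four, marks
inside the volume); feedback is append-only per user, several readers
may submit on one job, and no consensus is computed. Summaries are flat
recounts and therefore conserve under any partition of the jobs.

## Store, access control and CLI

Persistence is a directory of JSON documents plus the image repository
tree; attribute documents are stored verbatim, so project-specific
schemas need no migrations. Writes are write-to-temp + atomic rename,
making the store crash-consistent at single-document granularity.
Access control is by **domain**: a string on every stored series; a user
sees exactly the series whose domain is in their domain set, admins see
all. Roles are a minimal three-role model (annotator / operator /
admin); storing series requires operator or admin. The CLI
(`inst/cli/radcad`) is a thin wrapper over the exported functions and
takes the user context as flags — token-based authorization is out of
scope for a desk-scale tool.

## Validation sizes and limitations

The shipped validation (test suite plus `scripts/acceptance.R`) uses:
100 random (volume ≤ 16³, oblique plane) pairs against an independent
brute-force resampler (agreement to < 1e-9); ≥ 50 randomized MetaImage
round trips across all element types plus 10 case-archive round trips;
5 randomized jobs checked for DICOM payloads and PHI leaks; 20
end-to-end replicates with 0–5 planted lesions (exact count, centroids
within one voxel); 1000 randomized revision mutations with serialized
snapshots; and 100 random partitions for feedback conservation. These
sizes were chosen as the smallest that exercise every code path with
meaningful randomization headroom.

Known limitations: no DICOM network services or compressed transfer
syntaxes; no multi-frame or colour DICOM; oblique-plane interpolation is
trilinear/nearest only; 2D annotations are never voxelised; the job
manager is sequential by design (concurrency would need an external
orchestrator); and the store is single-writer — concurrent multi-user
editing is out of scope.
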