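---
title: "Methods: segmenting multi-specimen collection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting multi-specimen collection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `drawerseg`'s methods work, which choices were
genuinely open when the package was designed, and what its synthetic tests
do and do not demonstrate about real scans.

## The document model

A *document* is the persistent unit: the path to a full-resolution scan, a
reduced-width JPEG thumbnail on which all interactive and algorithmic work
happens, and an ordered list of boxes. Each box stores normalized
coordinates in [0, 1] relative to the scan, a clockwise rotation restricted
to multiples of 90°, and a map of metadata fields. Normalization is what
lets one set of boxes serve two resolutions: segmentation runs on the
thumbnail, cropping on the full-resolution file, and neither needs to know
the other's pixel dimensions.

Persistence choices that were ours to make: the sidecar is JSON
(`<scan-stem>.inselect`) because it is human-inspectable, diff-able, and
order-preserving; coordinates are stored with 6 decimal places, which is
sub-pixel down to scans ~500,000 px wide; thumbnails are written at JPEG
quality 85 (a fixed quality makes file sizes reproducible across runs); and
a thumbnail is never upscaled — when the scan is already narrower than the
target width the pixels pass through unscaled, since a "lower-resolution
working copy" upscaled would be a contradiction. The default thumbnail
width is 4,096 px, overridable per template or per call.

## Automatic segmentation

The pipeline is: sRGB → CIELAB; Gaussian blur per channel; Sobel gradients
in x and y on the lightness channel; combined gradient magnitude,
thresholded into a binary edge map; connected-component tracing; bounding
rectangles, processed recursively for edges-within-edges.

Parameters, all exposed through `seg_params()` so runs are pinned and
reproducible:

| parameter | default | units | role |
|---|---|---|---|
| `blur_kernel` | 5 | px (odd) | Gaussian window; noise suppression |
| `blur_sigma` | 0 → derived | px | 0 means σ = 0.3((k−1)/2 − 1) + 0.8 |
| `edge_threshold` | 40 | 0–255 gradient units | edge/no-edge cut |
| `min_box_fraction` | 1e-5 | fraction of image area | discards noise specks |
| `max_box_fraction` | 0.5 | fraction of image area | container trigger |
| `max_depth` | 2 | levels | drawer → tray → specimen |

Numerical choices worth recording:

* **Gradient scale.** "Rescaled to 0–255" is ambiguous between per-image
  max-normalization and a fixed scale. We use a fixed scale: lightness is
  normalized to [0, 1], each Sobel response is bounded by 4 (the kernel's
  weight sum), and magnitude is multiplied by 255/4 and clipped at 255. A
  uniform image then maps to zero without a 0/0, and a given threshold
  means the same contrast in every image. A full black-to-white step lands
  near 255; the default threshold 40 corresponds to a lightness step of
  roughly 0.16 before blurring.
* **Which channels feed Sobel.** Only L. The a/b chroma channels take part
  in blurring but not in the gradient; this is a documented simplification —
  specimens against drawer backgrounds separate almost entirely by
  lightness.
* **Connectivity.** Edge contours are thin and frequently diagonal, so
  components are 8-connected. The labelling is EBImage's 4-connected
  `bwlabel` plus a union-find pass merging labels that touch diagonally.
* **Convolution boundary.** Replicate padding, so image borders do not
  manufacture edges.
* **Container recursion.** With flat connected components, everything a
  container encloses is already in the component list; "re-processing a
  container's interior" therefore means: a rectangle whose area fraction
  exceeds `max_box_fraction` and which encloses other rectangles is dropped
  in favour of the enclosed ones, applied once per recursion level so nested
  containers unwrap one level at a time. At depth 1 the output is exactly
  the area-filtered component rectangles, which is what the flood-fill
  oracle in the test suite checks.
* **Ordering.** The method itself defines no box order, but deterministic
  CSV rows and crop numbering need one. Boxes are sorted in reading order:
  rows grouped top-to-bottom (a box joins the current row when its top edge
  lies within half the row-opening box's height), then left-to-right.
* **No non-maximum suppression.** Overlapping detections are kept;
  imperfect boxes on overlapping specimens are refined by a human, not
  silently merged.

Degenerate inputs: images smaller than the blur kernel are rejected as
parameter errors; an empty edge mask yields zero boxes, which is a valid
result, not an error.

## Sub-segmentation by marker-seeded watershed

One box containing several touching specimens is split from user markers.
The gradient magnitude of the blurred lightness channel (same preprocessing
as segmentation) inside the parent rectangle is treated as a topographic
surface, quantized to integer levels 0–255. Flooding is iterative
marker-region growing by ascending level: at each level, every marker
region repeatedly absorbs unassigned 4-neighbour pixels whose level has
been reached, all regions growing one pixel layer per sweep so fronts
advance at equal speed and meet midway. Contested pixels go to a fixed
neighbour precedence (up, left, down, right), making the result fully
deterministic. Each marker's catchment yields one bounding rectangle
clipped to the parent — exactly one box per marker, each containing its
marker by construction.

Two consequences worth knowing: with a single marker the catchment is the
whole parent (there is nothing to divide), and the basin boundary between
equal-contrast specimens falls at the midline between markers, not at the
specimens' physical boundary — the returned boxes are seeds for refinement,
not perfect outlines.

## Metadata templates and validation

Templates are YAML with top-level keys `name`, `thumbnail_width`,
`crop_filename` and `fields`; each field has `name`, `mandatory`,
`choices`, `parser`, `pattern`. The key names are this package's own (the
format needed a concrete schema; the behaviours they drive — mandatory
flags, choice lists, the five parsers, regex validation — are the
interface). Decisions:

* Regex validation is anchored to the full string even when the pattern has
  no anchors: the canonical nine-digit catalog-number rule `^[0-9]{9}$`
  must reject leading/trailing whitespace, and an unanchored user pattern
  silently matching substrings would be a trap.
* Metadata keys not present in the template are *violations*
  (`unknown-field`), not silently carried along — in unattended batch runs
  a template/document mismatch should surface, not pass.
* Validation is non-blocking on export: rows are written with a `valid`
  column rather than dropped, because a batch run must not lose specimens
  over a missing catalog number.
* The Simple Darwin Core term list is vendored as a plain-text resource
  (source URL and vocabulary generation noted in its header) so builds are
  offline-reproducible; all its fields are optional free text.
* Whether choice-list fields should also accept free text was undecidable
  from the interface description; we enforce the choice list strictly,
  which is the safer default for controlled vocabularies.

## Export

Crops are taken from the full-resolution scan (loaded once per document),
with the box's rotation applied; boxes reaching past the image edge are
clamped to the boundary rather than padded — no invented pixels. Crop file
names come from the template's `crop_filename` fields joined by `_`,
falling back to the zero-padded box index when a value is missing;
separators, whitespace and control characters sanitize to `-`; collisions
get `-1`, `-2`, … suffixes. CSV exports have a fixed leading schema (file
stem, box index, normalized coordinates, rotation) followed by template
fields, chosen for stable diffs; one CSV per document (a per-batch combined
CSV would couple independent documents, and concatenating per-document
CSVs is trivial). Crops default to JPEG quality 95 with TIFF as an option.

## Batch tools and CLI

The four unattended stages (`batch_ingest`, `batch_segment`,
`batch_save_crops`, `batch_export_metadata`) walk a directory, continue
past per-file failures, and return a report accounting for every candidate
(processed + skipped + failed). Reruns are idempotent: ingest skips scans
that already have documents, segment skips documents that already contain
boxes, unless forced. Exit codes in the CLI wrapper: 0 clean, 1 usage
error, 2 partial failure. The CLI's optional config file is YAML
(`drawerseg.yml`; flag > config > default) — YAML was chosen over other
config formats since templates already use it and the parser is a hard
dependency.

## Synthetic fixtures: what they emulate, and what they do not

The generators produce the two layouts the method targets. Drawers: dark
elliptical bodies with a pin line and a bordered white label beneath, on a
light drawer bottom, optionally grouped into unit trays (white card
interiors with a dark rim) and optionally overlaid with a low-contrast
rhombus tiling in empty areas, emulating the printed tiling paper found in
real drawer scans. Slide grids: filled slide regions with a frosted label
band and a faint coverslip, at the standard 6 × 12 (72-socket) and
large-slide 6 × 8 layouts, with seeded socket occupancy.

Contrasts were fixed once, by measuring each feature's edge response on the
0–255 gradient scale against the default threshold 40: specimen bodies
(shade 40 on background 200) respond at ≈100, well above threshold; slide
bodies respond at ≈80; plain white labels respond at only ≈30, which is why
labels carry a 1-px dark border, as printed labels do; the tiling
distractor (Δ6) and the coverslip (Δ8) respond below ≈4 and ≈10
respectively — present in the image, deliberately invisible to the default
threshold, so they stress the thresholding exactly as low-contrast paper
patterns do. Drawing is integer-only with no anti-aliasing, and all
randomness is seeded, so fixtures are byte-identical across platforms.

What the fixtures do *not* model: photographic texture (setae, wing
venation, specular pins), uneven illumination, stitching artefacts,
parallax, depth-of-field blur, damaged or overlapping specimens, and
handwriting on labels. Passing the recovery tests (precision and recall
≥ 0.9 at IoU 0.5 on default drawers) therefore demonstrates that the
pipeline's operator chain and bookkeeping are correct on well-separated,
well-contrasted material — it does not certify performance on difficult
real drawers, where boxes are expected to need human refinement.

Default fixture conditions, chosen once as realistic thumbnail-scale
material: 1600 × 1200 px drawers with 12 specimens of 60–120 px and ≥20 px
spacing, background shade 200, pixel noise sd 2; slide grids at ~1100 × 850
px. The test suite exercises drawers at n ∈ {5, 12, 40} over seeds 0–4,
property oracles on arrays up to 64 × 64, and the slide grids at full 72-
and 48-socket occupancy.

## Scoring

The scorer is the package's benchmarking harness: greedy one-to-one
matching on descending IoU (ties broken by reading order), a pair counting
as a true positive at IoU ≥ threshold (default 0.5, parameterized because
no canonical match criterion exists for this task). Greedy matching can in
principle fall short of the maximum bipartite matching on adversarial
cross-overlap configurations; on realistic instances — disjoint truths with
perturbed, dropped or added predictions — it attains the maximum, which the
test suite verifies against an exhaustive-assignment oracle on instances
with up to six boxes a side. Edge conventions: precision is defined as 0
when there are no predictions, recall as 1 when there is no truth.

## Known limitations

* Segmentation parameters are a single hard-coded default set; no
  auto-tuning. Material with very low lightness contrast (chroma-only
  separation) will under-segment because Sobel sees only L.
* The watershed returns axis-aligned bounding rectangles of catchments, not
  outlines; touching specimens of unequal contrast bias the basin boundary
  toward the weaker rim.
* Container recursion keys on area fraction alone; a legitimate specimen
  occupying more than half the image would be treated as a container if
  anything lies inside its rectangle.
* Barcode reading and OCR are out of scope; the segmenter registry is the
  hook where such plugins attach.
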