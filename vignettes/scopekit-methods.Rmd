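---
title: "scopekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scopekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scopekit is a headless control core for bespoke microscope acquisition,
built simulation-first: every workflow — snapping images, compiling and
running multi-channel Z-stack time-lapse experiments, expanding-spiral
mosaics, and nucleus detection — runs with zero hardware against simulated
devices. This vignette records the model behind each component, the
tunable parameters and their defaults, and the design choices made where
more than one reasonable convention existed.

## Devices, handlers and the depot

A *device* maps to one physical instrument; *handlers* are its
individually addressable control facets. An XY stage device exposes one
handler per axis; a laser exposes a light-source handler (on/off) and a
light-power handler (intensity). The *depot* aggregates every handler on
the system and is the only object the rest of the stack talks to, so
devices can be added or removed by editing the configuration alone.

Configuration uses an INI dialect: one `[section]` per device, a `type`
key selecting the constructor from an in-process registry, remaining keys
passed through as settings. Handler names are formed mechanically as
`<device>:<facet>` (e.g. `stage:x`), which guarantees uniqueness. Digital
and analogue trigger lines are exclusive: two handlers claiming the same
line index is a configuration error. A device may expose zero handlers;
this is allowed with a warning, since it usually indicates a
misconfiguration rather than an error.

## The simulated optical train

In simulation mode the "sample" is a stored multi-channel 16-bit image
(`source_sample`). A camera frame is:

1. the sensor-shaped subregion of the channel selected by the filter
   wheel, centred at the stage (x, y) position;
2. convolved with an isotropic Gaussian of sigma
   `blur_coeff * |z - focus_z|` pixels (defocus);
3. scaled linearly by `light_power * exposure_ms / 100 ms` and clipped to
   the 16-bit ceiling.

Choices worth recording, because the behaviour is conventional rather
than forced:

* **Defocus law.** Only *that* defocus blurs the image is inherent to the
  simulation concept; the law is ours. A linear Gaussian
  (`sigma = blur_coeff * |dz|`, default `blur_coeff` 0.5 px/µm) is the
  simplest model that is monotone in defocus, which is the property the
  tests rely on (image variance non-increasing in |dz|). It is not a
  physical PSF.
* **Coordinate convention.** Stage +x runs along image columns, +y along
  rows; pixel (0, 0) is top-left; the stage position addresses the sensor
  *centre* pixel `(floor(h/2), floor(w/2))`. Every module (acquisition,
  mosaics, pixel-to-stage transforms) uses this one convention.
* **Edges.** Regions outside the source sample are zero-filled rather
  than an error, so mosaics may overrun the sample boundary.
* **Gain.** Unit gain is defined at 100 ms exposure and full light power;
  at sigma 0 and unit gain a frame equals the source crop bit for bit,
  which gives the test suite an exact oracle (independent index
  arithmetic).
* **Noise.** The synthetic sample generator adds seeded Gaussian noise at
  generation time; acquisition itself is deterministic. This keeps every
  downstream artefact byte-reproducible from one seed, at the cost of not
  modelling shot noise per frame.

### The synthetic sample generator

`generate_synthetic_sample()` emulates the demonstration image used by a
simulated microscope: channel 0 carries anti-aliased filled disks
("nuclei", intensity `peak` over a background of 200 counts with Gaussian
noise, default sd 50) at known positions; further channels carry a
smooth sinusoidal texture so defocus is observable everywhere. Ground
truth travels with the sample, which is what makes planted-recovery
experiments possible. It does **not** emulate: shot noise, photobleaching,
uneven illumination, textured nuclei interiors, touching or overlapping
nuclei, or out-of-focus light from other Z planes. Passing the recovery
tests therefore demonstrates the pipeline's correctness on its stated
model, not segmentation performance on real DAPI images.

## Nested stages

The stage mover aggregates possibly-nested axes (e.g. a coarse Z stage
plus a fine piezo) into one macro XYZ position: each coordinate is the sum
of its member axis positions. Moves are all-or-nothing: target positions
for every axis are computed first and committed only if all are within
their soft limits; a rejected move changes nothing and names the offending
dimension.

The split policy between nested axes is a design choice (the fast piezo is
preferred): if the delta fits in the finest axis's remaining travel, only
that axis moves; otherwise the fine axis is re-centred mid-range — which
maximises travel available to subsequent fine moves — and the coarse axis
absorbs the remainder. If the coarse axis would exceed its limits it
clamps and the residual returns to the fine axis, so every target within
the combined travel is reachable. Moves are instantaneous in simulation;
settle time exists only in experiment compilation.

## Experiments and action tables

An experiment (channels × Z-slices × timepoints) compiles to an *action
table*: a time-ordered list of digital levels and analogue values on named
trigger lines, the form a hardware timing device would replay. Here a
software executor replays the same table on a virtual clock, so timing is
a pure function of the table and reproducible on any host.

Timing decisions (the loop structure is standard practice; none of the
constants is dictated by the problem):

* **Time base**: integer microseconds; durations round half-up to 1 µs.
* **Nesting**: timepoint → Z slice → channel (channel innermost), the
  common order that minimises stage motion.
* **Per slice**: one analogue Z event, then a settle wait (default
  1000 µs, configurable on the executor device); per channel: filter-wheel
  and light-power analogue events, then simultaneous light and camera
  rising edges, both falling after the channel exposure, then a readout
  wait (default 10 000 µs).
* **Light phase**: the light window exactly brackets the camera exposure —
  the simplest contract consistent with hardware triggering.
* **Interval semantics**: `interval_ms` is start-to-start; when a volume
  takes longer than the interval the next timepoint starts immediately and
  compilation warns.

`validate_table()` is report-based: monotone times, type-correct values,
strictly paired rising/falling digital edges, every line ending low, and
(given a depot) only registered lines. Execution applies all events
sharing a timestamp before any camera trigger at that timestamp, so a
frame always sees the state its simultaneous events establish. Exposure at
execution time is recovered from the rise-to-fall interval on the camera
line itself, not from the experiment spec — the table is the single source
of truth.

## The '.dv' container

Datasets are 5D `(T, C, Z, Y, X)` unsigned-16-bit arrays stored in a
documented dialect of the MRC2014 format: a 1024-byte main header
(`nz = Z*C*T`, mode 6, `MAP ` magic, little-endian machine stamp), an
extended header of one 32-byte record per plane (stage x/y/z in µm,
timestamp in s, plane min/max/mean, one reserved float), then plane data
with x fastest. Plane order is Z fastest, then channel, then time,
recorded in a header field and enforced on read. Wavelengths and
exposures for up to five channels live in the header's extra words; cell
spacing is expressed in micrometres. The writer is deterministic — the
same dataset produces a byte-identical file — which is what makes
whole-pipeline determinism testable. Reading accepts both endiannesses via
the machine stamp and degrades gracefully on plain MRC2014 mode-6 files
(no extended header → single-channel, single-timepoint, empty optical
metadata). Everything else is rejected with a message naming the
offending field or byte offset.

## Mosaics

Tiles are acquired in an expanding spiral: first offset (0, 0), first
step east, then a counter-clockwise ring walk (run lengths 1, 1, 2, 2,
...). Handedness is arbitrary and fixed for determinism; the tests check
the sequence against an independent closed-form ring enumerator. Tile
centres step by `sensor_extent * (1 - overlap_fraction)` (default overlap
0, i.e. abutting tiles placed purely by stage coordinates — there is no
image-based registration). Z is held at the start position throughout a
mosaic.

The tile store is append-only across mosaics: starting a new mosaic never
removes earlier tiles, and marked points survive everything. A mosaic
saves as a '.dv' stack (one plane per tile, stage positions in the
extended header) plus a text sidecar of tab-separated
`seq, x_um, y_um, z_um` lines at three decimals. `render_region()` is a
CPU composite — tiles painted in acquisition order, later over earlier,
nearest-neighbour resampled — standing in for the interactive GPU texture
map of a full GUI.

## Nucleus detection

The detection pipeline is, in order: Gaussian blur (default sigma 2 px) →
binarise (Otsu by default; a fixed threshold is available for tests) →
circular Hough transform over the configured radius range. The
accumulator for radius r is the fraction of the circle's perimeter covered
by boundary pixels of the binary mask (computed by convolution with a
1-px-wide ring kernel), so scores are comparable across radii; peaks are
taken greedily with a non-maximum-suppression radius of `radius_min_px`.

Candidate filtering:

* radius within `[radius_min_px, radius_max_px]`;
* accumulator score at least `hough_accumulator_threshold` (default 0.35
  of the perimeter);
* circularity `4*pi*area/perimeter^2` of the supporting thresholded
  component at least `circularity_min` (default 0.7);
* supporting-component coherence: the circle interior must be at least
  60 % foreground and the component area within 0.4–2.5 of `pi*r^2`.
  Without this an Otsu threshold of a *nucleus-free* tile — which always
  splits the noise somewhere — yields occasional well-scoring phantom
  circles;
* edge policy: circles extending beyond the tile are dropped, so nuclei
  straddling tile boundaries can be missed. This is an acknowledged
  limitation of the approach, not a defect the tests hide.

Centres are refined to the centroid of mask pixels inside the circle,
giving sub-pixel accuracy (typically < 0.5 px on planted disks). Pixel
positions convert to stage coordinates through the sensor-centre
convention above. During a scanning run each detection is appended to the
marked-point list as `nucleus-<k>`; detections within one radius of an
existing nucleus mark (re-detections in overlapping tiles) merge into the
existing mark. All defaults are overridable; there is no claim that they
are optimal beyond the synthetic scenes they are documented against.

## Problem sizes and numerical checks

The test suite exercises, among others: the spiral against the
brute-force enumerator up to 101 × 101 offsets; 200 random experiment
specs (T ≤ 5, C ≤ 4, Z ≤ 20) for the counting invariants; a
2 × 3 × 8 × 64 × 64 experiment with byte-identical '.dv' round trip; 100
random in-bounds acquisitions against the exact crop oracle; 1000 random
nested-stage moves conserved to 1e-9 µm; and a seeded 2048 × 2048 scene
with 12 interior disks (radius 15–25 px, peak 3000 over noise sd 100)
scanned as a 3 × 3 mosaic, recovering all 12 with centroid error under
1 µm and no spurious marks. These sizes keep the full suite around a
minute or two on one CPU while still covering every contract end to end.

## Known limitations

* The optical model is a crop-plus-Gaussian; no PSF, shot noise, camera
  read noise, or photobleaching.
* Stage moves are instantaneous; there are no velocity profiles or
  positioning-error models.
* The '.dv' dialect documents its own extended-header layout; it is
  MRC2014-compatible at the main-header level but does not reproduce any
  vendor's full metadata catalogue.
* Detection is a fixed classical pipeline tuned by explicit parameters;
  nuclei at tile edges are unreliable by construction.
* Everything is single-process; distributing devices over a network is
  out of scope.
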