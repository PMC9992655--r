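---
title: "Methods: lattice detection and volumetric eye morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice detection and volumetric eye morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records how the package's two pipelines work, the assumptions
they make, and the numerical choices behind every tunable — the things a
maintainer or a skeptical user would want written down.

## The 2D detector

A compound eye's facets tile the image as a (locally) regular hexagonal
lattice with center spacing *D* pixels. In the 2D Fourier domain that
lattice concentrates its energy in three fundamental gratings whose
orientations differ by 60° and whose common radial frequency is the
reciprocal-lattice magnitude `2/(sqrt(3) D)` cycles/px — note this is the
reciprocal of the lattice *row* spacing `sqrt(3)/2 * D`, not of *D* itself.
The detector:

1. subtracts the image mean and computes the centered power spectrum
   (`compute_reciprocal()`). The power spectrum is the Fourier transform of
   the spatial autocorrelation (Wiener–Khinchin), which amplifies periodic
   structure relative to the amplitude spectrum. The spectrum used for peak
   *search* applies a 2D Hann window first; the raw transform is retained
   for reconstruction. The window matters: a lattice patch that ends inside
   the frame is the product of an infinite lattice with a rect envelope,
   and the envelope's sinc sidelobes otherwise line up along the lattice
   axes at *lower* frequency than the fundamentals, exactly where a
   "closest significant maximum to DC" search will trip over them.
2. finds the fundamental gratings (`find_fundamentals()`,
   `significant_peaks()`). A candidate is a local maximum of the
   log-scaled spectrum that (a) lies outside the DC exclusion radius
   `4/min(dim)` (the windowed DC lobe spans several bins), (b) exceeds
   `median + k_mad * MAD` of the raw power in its radial frequency band,
   and (c) reaches at least `rel_threshold` (default 1%) of the strongest
   significant peak. The defaults were chosen from the statistics of the
   two regimes rather than from any one test image: on featureless noise
   the extreme order statistics of a spectral band sit near 12 MADs above
   its median (the band power is approximately exponential), while genuine
   lattice fundamentals sit hundreds to millions of MADs above theirs, so
   `k_mad = 25` separates the regimes with a wide margin on both sides.
   The MAD criterion is deliberately applied to the *raw* power: after
   log-scaling the two distributions overlap (a log compresses exactly the
   tail that distinguishes a peak) and no threshold works. The relative
   threshold removes leakage structure that is locally significant but
   orders of magnitude below the lattice. Harmonics — candidates whose
   frequency vector is within 10% of an integer multiple (2x, 3x) of an
   accepted peak's — are rejected; the lowest-frequency peaks win.
   `n_fundamentals = 2` handles square lattices and noisy images where the
   third axis is unreliable.
3. reconstructs a smoothed image (`lowpass_reconstruct()`) keeping
   frequencies up to `cutoff_factor = 1.25` times the largest fundamental:
   the fundamentals and DC pass, the first harmonics at 2f do not.
4. reads centers off the local maxima (`detect_centers()`), suppressing
   maxima closer than `min_distance_factor = 0.25` of the FFT-derived
   diameter. Equal-valued plateaus collapse to their centroid; among
   conflicting maxima the brighter wins, then the top-left-most —
   a fixed, deterministic order. When a mask is given, masked-out
   candidates are dropped *before* suppression, so ringing outside the eye
   silhouette cannot shadow facets just inside it. Optional quadratic
   sub-pixel refinement is off by default.

Per-facet lens diameter is the median distance to lattice neighbors
(centers within 1.5 fft-diameters), not `1/f`: for a hexagonal lattice
`1/f` equals the row spacing, about 0.87 of the center spacing, so it is
used only to set search and neighbor radii. For square lattices the
neighbor ball contains the four nearest and the four diagonal neighbors,
so the median sits between the spacing and `sqrt(2)` times it — a known
property of the definition, acceptable because square lattices are the
exception the 2-fundamental mode exists for.

## The degradation benchmark

`degrade_resolution()` bin-averages into `bin x bin` blocks (partial edge
blocks are dropped so every output pixel is an exact mean);
`degrade_contrast()` rescales intensities affinely about the mean to a
target RMS contrast — defined as the standard deviation of intensities
after normalizing the 8-bit range to [0, 1] — and re-quantizes to 8 bits.
`benchmark_sweep()` runs the detector at each level and records relative
count and diameter against reference values; detector failures count as a
relative count of zero, not an error. `threshold_resolution()` reports the
lowest resolution (px per lens diameter) whose relative count still exceeds
50% of the sweep's maximum. The analogous diameter rule is stated
ambiguously in the field (a diameter below half its baseline is a failure,
not a success); this package implements "relative-diameter deviation from
baseline below 50%" and documents the choice rather than guessing another
convention. The Nyquist floor — two pixels per lens diameter — emerges from
the sweep rather than being asserted anywhere.

## The volumetric pipeline

Input is a point cloud of crystalline-cone voxels (density-filtered with an
explicit `density_range`, replacing interactive picking; coordinates are
voxel indices times `voxel_size_um`). The stages:

* **Sphere fit** (`fit_sphere()`): linear (Kasa) algebraic fit plus one
  Gauss–Newton refinement pass on the radial residuals. Near-coplanar
  clouds raise a typed error rather than returning a huge sphere.
* **Eye frame**: the cloud is rotated so the sphere center sits at the
  origin and the cloud centroid faces +x (elevation 0, azimuth 0), keeping
  the eye far from the spherical-coordinate poles. Elevation is measured
  from the equatorial plane in [-90°, 90°], azimuth in (-180°, 180°].
* **Cross-section** (`make_cross_section()`): point radius is modeled as a
  smoothed function of (elevation, azimuth) on a regular grid — per-cell
  means, neighbor-filled, twice 3x3-smoothed, evaluated bilinearly. The
  grid step is half the expected angular lens diameter when a guess is
  available, otherwise chosen so cells average about 20 points. Members
  are the points whose residual falls in the central 50% band (25th–75th
  percentile, ties broken by point index); if the surface fit fails the
  sphere radius is used with a warning.
* **Raster detection** (`rasterize_and_detect()`): the cross-section is
  processed in angular segments (default 90°, configurable), each
  recentered toward the projection pole before forming a 2D
  (elevation, azimuth) count histogram that the 2D detector processes. The
  histogram bin is a quarter of the expected angular lens diameter, or
  1/256 of the segment if no guess is given. Segments are rasterized with
  a margin (two lens diameters) and a detection belongs to the segment
  whose core contains it, which keeps segment joins free of duplicated or
  clipped centers; remaining duplicates closer than half a lens diameter
  are merged. Detected maxima map back to 3D via the nearest cross-section
  point.
* **Clustering** (`assign_clusters()`): *every* cloud point — both residual
  halves, so clusters are whole cones — is labeled by its nearest center in
  the projected (elevation, azimuth) plane; centroids are recomputed in 3D.
  The anatomical axis below is the principal axis of the cluster point
  ellipsoid, and only a full-length cone constrains it well; measured on
  half-cones the skewness noise floor roughly doubles.
* **Cluster correction** (`correct_problem_clusters()`): a cluster is
  problematic when ≥ 10% of its points have their nearest neighboring
  point in a different cluster. For each such cluster the neighborhood of
  its 6 nearest clusters is re-partitioned by nearest centroid in a
  projection plane whose orientation (two angles) is optimized by a small
  seeded differential-evolution search (rand/1/bin, reflection at bounds;
  population 15, 20 generations by default). The objective is the mean
  projected point-to-center distance plus the mean aspect ratio of the
  *projected* clusters: cones are elongated along their longitudinal axes,
  so the minimum sits at the plane orthogonal to them, where footprints
  are round and tight. (An aspect ratio measured in 3D would instead
  penalize the correct partition — whole cones are maximally elongated —
  and the optimizer would never accept anything.) A correction is kept
  only if the re-partitioned neighborhood ends with fewer than 5%
  misneighbored elements.
* **Measurements** (`measure_ommatidia()`, `measure_io_pairs()`):
  adjacency is mutual proximity below 1.5x the median nearest-centroid
  distance (robust at eye borders, where Delaunay would connect across the
  rim). Lens diameter is the mean distance to adjacent centroids. The
  ideal axis of a cluster averages the outward-oriented normals of all
  centroid triplets among the cluster and its adjacent neighbors,
  *area-weighted* (the raw cross products are summed): thin, nearly
  collinear triplets carry noisy normals and the weighting suppresses them
  — on synthetic zero-skew eyes it roughly halves the median axis error.
  Skewness is the angle between ideal and anatomical axes; the adjusted
  diameter is `D cos(skew)`. For interommatidial angles each anatomical
  axis is replaced by the average over clusters within
  `neighborhood_radius` lens diameters (default 5); the *raw* axes feed
  the field-of-view projection, because the averaging pulls border axes
  inward and would shrink the FOV. The neighborhood radius should be small
  relative to the eye's angular extent: 5 diameters suits scans with many
  thousands of ommatidia, while the desk-scale oval-eye analyses in the
  test suite use 2 on eyes only ~17 columns wide — at radius 5 half such
  an eye is border.
  Pair components are the unsigned angles between the averaged axes
  projected onto the horizontal (x–y) and vertical (x–z) planes of the eye
  frame, bookkept in half-overlapping slabs one lens diameter wide
  (`section_width`); the total angle is their hypotenuse, and the pair's
  orientation on the eye surface (0° = horizontal) comes from the
  centroid displacement in the local tangent basis.
* **Summary**: pairs with a total angle above 5x the median are excluded
  from summary statistics (but retained in the exported tables); angular
  summaries are reported as median (IQR) since the distributions are
  skewed.

## Optics helpers

`spherical_io_angle()` / `radius_from_io()` implement `Δφ = D/R` exactly
both ways. `oval_eye_analysis()` locates the three orientation modes of the
adjacent-pair distribution by kernel-smoothed circular histogram
peak-picking (period 180°, 5° kernel, modes at least 30° apart), selects
pairs within ±15° of each mode, and combines components the way the lattice
geometry dictates: horizontal pairs span two lattice columns, so their
horizontal angle is `2 Δφ_h`, while diagonal pairs carry `(Δφ_h, Δφ_v)`.
Two radius summaries are reported: per-mode intersection radii from the
mode's mean *total* angle via `R = D/Δφ`, and axis radii from the
components (`R_h = D / 2Δφ_h` since columns are `D` apart;
`R_v = (sqrt(3)/2) D / Δφ_v` since rows are `(sqrt(3)/2) D` apart). On a
generated oval eye with `R_v = 3 R_h` the axis-radius ratio recovers the
factor 3; the per-mode total-angle radii differ by `sqrt(3)` in the ideal
hexagonal case, which is what the diagonal/horizontal radius comparison
measures. `world_project()` intersects each raw anatomical axis ray with a
sphere of `projection_radius` (default 10 cm, far enough that the result is
insensitive to the exact radius) about the eye center and reports the
angular extent of the hit directions.

## What the generators emulate — and what they do not

`make_hex_lattice_image()` renders Gaussian bright spots (the specular
reflection at each facet center) on a hexagonal lattice, with overscan —
nodes just outside the frame still contribute their tails, as in a cropped
micrograph — plus optional Gaussian pixel noise; it returns the exact
center list and a matching silhouette mask. `make_synthetic_eye3d()`
places cones at hexagonal angular spacing on a spherical or oval surface
patch (`Δaz = D/R_h` within rows, `Δel = (sqrt(3)/2) D / R_v` between
rows, alternate rows offset — the construction that makes horizontal axes
converge at distance `R_h` and vertical at `R_v`), renders each cone as a
noisy line-segment point cluster along its axis, and supports a skew field
(tilt toward a target point or toward the central viewing direction).
Generators are bit-reproducible per seed, and their ground truth shares
units and frames with pipeline outputs.

What they do *not* emulate: uneven illumination and vignetting, lattice
defects and acute zones where spacing varies across the eye, curvature
foreshortening in 2D images of strongly curved eyes, non-cone tissue and
staining artifacts in scans, and anisotropic voxel noise. Passing recovery
tests therefore demonstrates the algorithmic chain is correct and
calibrated, not that every real scan will segment cleanly — real data still
need the diagnostic plots and the density-range/config choices.

## Problem sizes and determinism

The test and validation workloads are sized for a single CPU: 2D images of
256–512 px; a spherical validation eye of ~1150 cones (D = 20 µm,
R = 800 µm, 45°x45°, 12 points per cone, 1 µm noise); an oval eye
(R_h = 400 µm, R_v = 1200 µm, 50°x25°) of ~530 cones; a 20°-skew eye of
~180 cones for the correction test; a voxelized eye at 3 µm voxels for the
stack-loading round trip. Noise levels (1 µm positional jitter on ~40 µm
cones, 10% image noise) sit in the range a well-stained benchtop scan or a
clean micrograph produces. All randomness flows from explicit seeds —
generators, optimizer, noise — so identical configurations yield
byte-identical outputs.

## Known limitations

* Eyes whose lens diameter varies strongly across the image violate the
  single-fundamental assumption; process such images in windows.
* The anatomical axis needs at least 4 points per cluster and honest
  elongation; at coarse voxel sizes skewness estimates degrade before
  counts or diameters do.
* Anatomical skewness here ignores refraction, so aperture reductions are
  lower bounds and the angles are anatomical, not functional.
* The cluster correction repairs projection overlap from moderate skew; at
  extreme skew (cones nearly tangential) segmentation needs a different
  decomposition of the volume than a single spherical cross-section.
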