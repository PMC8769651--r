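---
title: "Models and methods behind fibclem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibclem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibclem)
```

fibclem implements the computational core of an automated cryo-FIB lamella
preparation workflow guided by three-dimensional correlative light and
electron microscopy (3D-CLEM). This vignette explains the models the package
implements, the assumptions they rest on, the tunable parameters and their
defaults, and the design decisions taken where the methods literature leaves
choices open. It also describes what the synthetic-data generators emulate
and, consequently, what a passing test suite does and does not demonstrate
about real data.

## Coordinate conventions

All image and volume coordinates are 0-based and refer to pixel centers,
with x running right, y running down, and z the slice index of a stack.
Conversions to physical units go exclusively through a `pixel_grid()`
(pixel pitch and slice thickness in nm), so no function silently assumes a
calibration. Angles are degrees at every interface and radians internally,
matching how beam geometries are quoted on the instruments (52&deg;
inter-beam angle, 45&deg; shuttle pre-tilt, 16&ndash;20&deg; stage tilt).

## Fiducial detection and localization

Fluorescent microbeads (~1 &micro;m) are visible in fluorescence, SEM and
FIB imaging and anchor every cross-modality transform. `detect_beads()`
scores each pixel with the product of three maps, each min&ndash;max
normalized to [0, 1] before multiplication so that no single detector
dominates on account of its scale:

1. normalized cross-correlation with a Gaussian template whose sigma is the
   user-supplied bead radius;
2. a circle-Hough accumulator built from Canny edges, evaluated over radii
   `radius * multiplier * (0.8 .. 1.2)` in five steps and max-pooled, which
   makes the detector tolerant to slightly out-of-focus or coated beads;
3. a soft mask obtained by thresholding (Otsu, mean, or a fixed value),
   dilation with a disk of one bead radius, and Gaussian blurring with the
   same sigma.

Peaks are local maxima under non-maximum suppression at `min_separation`
(default one bead radius), with a border of one bead radius excluded --
partial beads at the image edge localize poorly and the published behavior
at borders is unspecified. Ties and ordering are resolved deterministically
(score descending, then y, then x). A small absolute floor (`min_score`,
default 1e-6) discards peaks that exist only as floating-point residue of
the three-way product.

Subpixel centers come from `fit_center_gaussian()`: alternating 1-D
Gaussian fits along each axis through the current center and a 2-D
elliptical Gaussian fit in-plane, iterated until the center moves less than
0.01 px (at most 20 iterations). A constant background is fitted jointly in
every fit because SEM images have a nonzero baseline; a flat or
non-converging profile raises a `fit_failed` condition rather than
returning a spurious center. For 3-D input the z-center comes from the 1-D
fit along z, reflecting the much coarser axial sampling of confocal stacks.
On noise-free blobs the sweep tests show recovery better than 0.05 px for
arbitrary subpixel ground truth.

Centroids of segmented organelles (`extract_centroids()`) use
26-connectivity connected-component labeling and the unweighted mean of
member voxels, the convention used when lipid droplets serve as internal
fiducials in FIB-SEM volumes.

## Correlation transforms (3-D fluorescence to 2-D image)

The transform model is a rigid rotation plus isotropic scale plus
translation (7 degrees of freedom), not a full affine: the model the
established 3-D correlation workflow fits between a fluorescence stack and
a single SEM/FIB view. The image-plane prediction drops z after
transformation; the retained third coordinate is the depth of a point
above or below the image plane, in the same pixel units (scale applied).

Because only the 2-D residuals constrain the fit, the z-component of the
translation is a gauge freedom; it is fixed at 0, so depths are reported
relative to the rotated, scaled fluorescence frame. Optimization combines a
closed-form 2-D similarity initialization with a fixed grid of 29
out-of-plane starting rotations, quasi-Newton refinement from each start,
and a final Levenberg&ndash;Marquardt polish; the start grid makes recovery
global in practice (the suite checks exact recovery, rms below 1e-6 px, on
hundreds of random draws) and the procedure is fully deterministic.

`predict_fib_positions()` implements the coincidence-geometry shortcut for
finding fiducials in the ion-beam view: fit a total-least-squares plane to
the correlated fiducial positions, rotate about the axis through a
user-chosen reference point parallel to the image x-axis (the tilt axis
shared by the two beams at coincidence height) by the inter-beam angle, and
translate so the reference point lands on its user-matched FIB counterpart.
Two open choices were resolved as follows: the rotation acts on the 3-D
correlated coordinates (not on their 2-D projections), which is the only
reading under which out-of-plane fiducials move differently from in-plane
ones as they visibly do; and the rotation sign defaults to moving +y points
away from the viewer, with a `rotation_sign` argument because the
convention depends on the instrument's scan orientation.

## Lamella masks and virtual slices

A lamella drawn as a polygon on the SEM image plus one point on the milled
lamella in the FIB image defines a slab in the fluorescence frame. A voxel
belongs to the mask iff (a) its SEM-correlation projection falls inside the
polygon (even&ndash;odd rule, boundary inclusive, so edge handling is
deterministic) and (b) its physical distance to the lamella plane -- the
set of fluorescence-frame points whose FIB-image y equals the anchor's y --
is at most half the lamella thickness. The slab is taken along the plane
normal measured in nm (anisotropic voxels handled through the chain rule),
the literal reading of a slab "centered on" the lamella plane. A
sub-picometer tolerance guards the slab boundary against round-off in the
transform arithmetic. Masks are reproduced exactly by a brute-force
per-voxel oracle in the tests.

`masked_projection()` renders the masked volume by inverse mapping with
trilinear interpolation (out-of-bounds reads 0) and takes the maximum
intensity along the output z-axis. Only the z-range covered by the
transformed volume corners is evaluated, and the computation proceeds in
output-raster tiles; both are pure cost knobs -- the suite asserts
bit-identical output for any patch size. `virtual_slice_series()` shifts
the plane anchor in FIB-image pixels (the natural unit for comparing
against post-milling FIB images) and re-renders, producing the height scan
used to find which fluorescence plane best matches a milled lamella.

## 3-D affine registration of fluorescence and FIB-SEM volumes

Between two 3-D volumes a full 12-parameter affine is appropriate: it
absorbs the axial compression of cryo-fluorescence stacks acquired with dry
objectives (refractive-index mismatch between air and ice) and shear
introduced by stage drift during serial acquisition. Points are expected in
physical nm (`pixels_to_nm()`), and residuals are reported in the same
units.

`fit_affine()` exposes three strategies, all driven by a single seed:

* **ransac** -- 4-point minimal samples, inlier counting at a distance
  threshold, refit on the consensus set. Breakdown tests plant 30% gross
  outliers at a 3-sigma threshold and require full exclusion.
* **multistart_local** -- L-BFGS-B refinement from the closed-form
  least-squares solution plus rigid-plus-scale hypotheses built from random
  point triples (scale from pairwise-distance ratios, rotation from triad
  alignment), a correspondence-based seeding in the spirit of certifiable
  registration initializers.
* **basinhopping** -- Metropolis-accepted perturbation cycles around
  L-BFGS-B local minima, with translation steps of 10% of the point-cloud
  extent.

For the least-squares objective on clean correspondences all three coincide
with the closed-form optimum (checked to 1e-6); they differ on contaminated
or ambiguous data, so `fit_affine_best()` runs all three and reports each
strategy's rms alongside the minimum. Fitted objects support `tidy()`
(per-point residuals and inlier flags) and `glance()`.

## FIB-SEM stack postprocessing

Defaults follow the parameters quoted for cryo-FIB-SEM volume processing:
de-curtaining sigma 6, charging blur sigma 35 with two erosion steps, CLAHE
clip slope 3.

**De-curtaining.** Curtaining appears as vertical streaks behind dense
inclusions. The image is decomposed with a multilevel orthogonal 2-D
wavelet transform (db4, periodized; depth `floor(log2(height)) - 3` by
default) and the vertical-detail band of every level is filtered with a
Gaussian notch of width `decurtain_sigma` frequency samples applied to its
y-spectrum. The reasoning: stripes are constant along y, so in this band
their energy concentrates at low y-frequency *whatever their x-period* --
including stripe periods that alias onto the band's x-DC after decimation,
which no smoothing along x can reach -- while genuine texture varying along
y passes through. The notch depth is scaled by `1 - exp(-sigma^2/2)` so
that sigma -> 0 is an exact identity, giving the filter a clean continuous
dial from "off" to full stripe suppression. Detail coefficients have zero
DC gain, so the global image mean is preserved exactly.

**Charging compensation.** A background mask is built by Gaussian blurring
(sigma 35 px) followed by two grayscale erosions with a disk of radius 5 px
(the published step count; the element size is a package default), then
subtracted; the result is shifted to a non-negative range so integer image
writers stay valid. The erosion makes the mask hug the background below
bright structures, at the cost of slightly under-subtracting the hill peak:
the tests quantify a planted sigma-60 hill's residual at about 12&ndash;14%
of its amplitude, within the 20% attenuation target, while pure texture
passes through with correlation above 0.99.

**Contrast.** CLAHE via EBImage with the clip slope and a tile size in
pixels; constant images pass through unchanged.

**Drift alignment.** Slice-to-slice translations are estimated by phase
correlation with matrix-multiply upsampled-DFT refinement (default 10x,
i.e. 0.1 px grid). Two numerical choices matter. First, the cross-power
spectrum is normalized by the square root of its magnitude: full spectral
whitening weights noise-only frequencies equally with signal and fails on
smooth, low-contrast content, while no whitening lets bright stationary
structure dominate; the symmetric 0.5 exponent is robust to both (plus a
1% regularization floor). Second, drift is estimated on high-passed copies
of the slices (cutoff one eighth of the image size), because stationary
low-frequency residues -- e.g. incompletely removed charging -- otherwise
pull the correlation toward zero drift; the estimated shifts are applied to
the original slices. Translation-only drift is the modeled effect; the
published workflow used a general-purpose feature-based aligner for this
step, but the drift component is translational and phase correlation is
deterministic and dependency-free.

**Foreshortening.** Images acquired at the inter-beam angle are stretched
in y by `1/sin(angle)` (1.2690 at 52&deg;) with linear interpolation; the
new height is `round(old * factor)`.

`postprocess_stack()` chains the stages (default order crop, decurtain,
decharge, clahe, align, stretch), any subset of which can be selected or
reordered, and logs what ran.

## Milling protocols, pattern sequences and session accounting

Protocols are line-oriented `key: value` text with one `[step]` block per
milling step (current, time, pattern gap, pattern height, and an overtilt
angle kept as metadata only -- divergence compensation is never computed).
The grammar is diff-friendly and round-trips losslessly through
`parse_protocol()` / `write_protocol()`. Pattern sequences are tibbles of
milling commands (shape, center offsets in &micro;m relative to a reference
point, size, time, current, scan direction) serialized one command per
tab-separated line.

`compile_lamella_patterns()` places, per step, one rectangle above and one
below the lamella center with inner edges at half the pattern gap, outer
edges clipped at the extreme milling points that protect grid bars; the
upper pattern scans top-to-bottom and the lower bottom-to-top so material
is always removed toward the lamella face. Micro-expansion joints are two
narrow relief cuts flanking the lamella; their default dimensions (0.5
&micro;m wide, offset 2 &micro;m beyond the lamella edge) are package
choices, configurable, as the published workflow refers to external joint
designs. Lift-out trenches form the horseshoe layout: two parallel
trenches (40 x 15 &micro;m) flanking a 20 &micro;m block plus a
perpendicular 10 x 40 &micro;m trench whose center sits 15 &micro;m to the
left of the block center -- the description of the side-trench offset
leaves the reference edge ambiguous, and this convention is the one that
reproduces the printed 20 x 20 &micro;m extractable block.

Dose accounting uses `dose = current * dwell * line_integration /
(e * pixel_area)`:

```{r dose}
electron_dose(50, 1, 16, 10.377)   # e/A^2 per image, Sum159 conditions
electron_dose(13, 0.25, 64, 3.4)   # C. reinhardtii conditions
```

Session statistics mirror the five-cell-type on-grid benchmark
(`ongrid_session_counts()`, 64 lamellae from 77 sites, 83.1%), and
`session_time_budget()` books fine-milling time against a 1-hour budget
with ice condensation accrued at 50 nm/hr, the instrument's quoted
condensation rate.

## The simulated microscope

The simulator exists to close the loop on realignment and session logic
without an instrument API. Its conventions, chosen once and used throughout:

* The virtual specimen is a voxel label array `[y, x, z]` with z along the
  ion-beam axis; material is removed front-to-back within a pattern
  footprint until the removed volume reaches `mill_rate * current * time`
  (a constant volumetric rate per material -- a calibration constant of the
  virtual specimen, not a sputtering model).
* Pattern coordinates are true specimen &micro;m, so a protocol's final
  pattern gap equals the milled lamella thickness up to voxel quantization.
* Rendering is orthographic surface shading (depth-shaded material
  reflectance times a frozen-surface texture) -- sufficient for
  registration and realignment tests, with no claim to SEM contrast
  physics. The FIB view compresses y by `sin(inter_beam_angle)` relative
  to the SEM view, consistent with the `1/sin(52deg)` stretch used in
  postprocessing. Rendering resamples through an anti-aliasing filter, and
  all translations use cyclic interpolation: the field of view is a window
  onto a larger, statistically uniform surface, so content enters from
  off-screen rather than exposing black borders.
* The instrument state carries a stage-recall error (fresh seeded draw per
  stage move), a linear drift velocity in nm/min (specifications quote up
  to 60 nm/min), an optional per-current beam-offset table (synthetic by
  construction), and an optional Poisson rendering noise; a single seed
  drives everything and every operation is logged.
* Stored positions may carry their own stage coordinates (`stage_positions`
  in `sim_driver()`), in which case each position images and mills its own
  viewport of the specimen -- without this, milling one site would corrupt
  the realignment references of every other site, which has no counterpart
  on a real grid where positions are distinct squares.
* The session clock advances by each command's milling time before material
  is removed: under drift, the last material removed defines the final
  face, so an uncorrected session displaces the lamella by approximately
  the drift integral over the stage (about 1.8 &micro;m for 60 nm/min over
  30 min), which the tests verify.

`run_lamella_session()` mirrors the staged automation flow: per-position
reference images, rough milling for all positions, then fine milling for
all positions; realignment against the stored reference on every recall
and before every step (stage moves beyond 10 &micro;m, beam shifts below),
plus beam-shift-only realignment across current changes. With realignment
the placement error stays below 2 rendering pixels for drifts up to
120 nm/min; without it the drift integral wins.

## What the synthetic data does and does not show

The generators produce: bead fields with known subpixel centers and
enforced minimum separation; fluorescence volumes of anisotropic Gaussian
blobs (the elongated axial PSF of dry-objective confocal imaging);
sinusoidal vertical stripes with seeded phase; broad Gaussian charging
hills; and drifted stacks with exact per-slice offsets. These capture the
geometric and spectral structure of the artifacts but not: non-Gaussian
bead shapes or coating halos, depth-dependent PSF asymmetry, curtaining
with spatially varying amplitude and orientation jitter, charging that
correlates with local topography, or elastic specimen deformation during
milling (which the 3D-CLEM experiments identify as a real failure mode and
which no rigid or affine model corrects). Passing tests therefore
demonstrate correctness of the implemented models and robustness at
realistic noise levels -- not that the models suffice for every specimen.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path with comfortable margins: fiducial images of
100&ndash;200 px, fluorescence volumes up to about 48^3, mask oracles on
volumes up to about 20^3 (the brute-force check is an explicit triple
loop), registration with 10&ndash;24 points and 50&ndash;200 random
transform draws, postprocessing rasters of 128&ndash;400 px, and simulated
specimens of 240 x 240 x 60 voxels at 100 nm. Results quoted in the README
come from these sizes.

## Known limitations

* The correlation model is similarity-only by design; strong anisotropic
  optical distortion needs the 3-D affine route.
* De-curtaining assumes stripes aligned with the image y-axis (the milling
  direction); rotated curtaining is out of scope.
* The simulator's milling is purely subtractive with a constant volumetric
  rate; redeposition, beam tails and material-dependent sputter physics
  are not modeled.
* `masked_projection()` evaluates the full transformed z-range per output
  pixel; it is exact but not optimized for very large volumes
  (single-threaded; the `workers` argument exists for interface
  compatibility and does not parallelize).
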