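---
title: "Methods: topology-preserving voxel skeletons of plant architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology-preserving voxel skeletons of plant architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Living architecture — structures grown by shaping and fusing trees, such as
aerial-root bridges and grafted tree pavilions — forms *anastomotic*
networks: shoots and roots inosculate, so the structure's connectivity
graph contains cycles. A skeletal abstraction of a surveyed point cloud is
only useful for downstream mechanics or growth modelling if it preserves
that connectivity exactly. `voxelskel` therefore treats topology — the
Betti triple (`b0` components, `b1` loops, `b2` cavities) of the voxel
object — as the invariant the whole pipeline is built around, and accepts
the costs that come with it (a semi-automated hole-filling step, voxel-size
trade-offs, modest geometric smoothness).

## Pipeline model and assumptions

The input is a point cloud in metres sampling the *visible surface* of an
approximately tubular solid. Processing assumes:

* the cloud's density is high enough that, at the chosen voxel size, every
  surface patch puts at least one point in each voxel it crosses (the
  voxel size is the user's instrument for trading precision against hole
  closure and noise tolerance);
* internal cavities are not physically present (a survey cannot see them),
  so every void region not 6-connected to the outside may be filled;
* elements are roughly vertical after PCA orientation — volume
  reconstruction builds sections in the global xy plane stepped along z,
  so strongly horizontal elements (a flat-lying ring, say) are
  under-reconstructed. This in-plane limitation is inherited deliberately;
  local-tangent-plane sections are out of scope.

## Thinning: templates and deletion criteria

Thinning erodes the filled solid voxel by voxel until only a curve skeleton
remains. Safety and shape are separated:

* **Deletion criteria carry the topology guarantee.** A candidate `x` is
  deleted only if (a) its 26-adjacent object voxels form a single
  26-connected component and (b) its 18-adjacent void voxels form a single
  6-connected component (6-adjacency evaluated inside the 3×3×3 block).
  Together with the guaranteed void face neighbour these are a sufficient
  condition for `x` being a *simple point*: deleting it cannot change the
  Betti triple. Note (b) is stricter than the exact simple-point
  characterisation (which only constrains the void component touching a
  face): the stricter form errs on the safe side. Criteria (c) and (d)
  handle simultaneity: when several candidates are deleted at once, (c)
  demands an object witness `z` adjacent to both `x` and any 26-adjacent
  co-candidate `y`, and (d) demands a void unit square across any
  6-adjacent co-candidate — preventing two mutually-supporting voxels from
  deleting each other. The witness `z` may be any object voxel, including
  another candidate; this relaxation is what lets the erosion reach a
  one-voxel-thick skeleton instead of stalling at two-voxel slabs.
* **Templates carry the directionality.** Four base masks — a face border,
  a convex edge/diagonal ridge, a convex corner, and a plate-rim /
  strand-side pattern — expand under the 24 proper cube rotations to
  6 + 12 + 8 + 12 = 38 unique configurations (enforced by test). Each
  thinning cycle runs them as sub-passes in family order (all rotations of
  the face family first), which keeps erosion symmetric and the skeleton
  centred. The masks assign some neighbourhood positions to *object* and
  some to *void* and leave the rest free. We experimented with fully
  specified 26-position masks and found them unable to erode realistic
  neighbourhoods (each such mask matches exactly one of the 2^26
  configurations); partial masks with free positions are the only workable
  reading, with all safety delegated to the criteria above.
* **Curve ends are protected by candidacy, not by mask shape.** A voxel
  with at most one 26-adjacent object voxel is never a candidate, so
  terminal branches survive. With partial masks this has to be an explicit
  rule: a chain tip matches the face-border mask, and criteria (c)/(d) are
  vacuous for it because its neighbour is not a co-candidate.
* **One shell per cycle.** The candidate pool of a cycle is frozen to the
  voxels already face-exposed at cycle start; voxels exposed mid-cycle are
  returned to the set for the next iteration. Without this, later
  sub-passes eat into freshly exposed material and a cycle removes about
  two shells, destroying the proportionality between the exposure
  iteration and local radius (measured during development: a radius-4
  cylinder logged `I2 = 2` without freezing, `I2 = 4` with it; a solid
  5×5 bar logs `I2 = 2` either way at its centre only with freezing).

## Iterations of exposure and reconstruction

The cycle at which a voxel's *n*-th face first becomes void-adjacent is
`I_n` (faces exposed in the input count as 0). A chain voxel has four
exposed faces, so `I1..I4` are recorded; the rare junction voxel with a
face-attached branch has only three, and reconstruction falls back to its
largest recorded exposure. Circular reconstruction marks every cell of the
voxel's xy-plane within `radius_scale * I_n` voxel widths. `radius_scale`
defaults to 1.0 because, with the frozen candidate pool, one cycle erodes
one voxel shell.

For flattened cross-sections the minor axis is exhausted early (small
`I1`, `I2`) while the major axis keeps eroding (`I3`, `I4` large), so the
ratio `I4:I1` tracks the section's elliptical ratio ER = major/minor.
`fit_ellipse_ratio_model()` fits ER on a chosen exposure ratio by ordinary
least squares and reports R² for all candidate predictors (`I2:I1`,
`I3:I1`, `I4:I1`, mean ratio). Elliptical reconstruction then enlarges the
major axis (for conservative `I1`/`I2` sections) or shrinks the minor axis
(for generous `I3`/`I4` sections). Numerical guards: predictions are
clamped to ≥ 1 (an ER below 1 is meaningless) and capped (default 6; the
linear model extrapolates absurdly on outlier ratios); voxels with
`I1 = 0` but later exposure have an undefined ratio and fall back to
circular sections, counted in the result. The major-axis direction is the
in-plane cardinal direction whose opposing faces were exposed latest, with
never-exposed counting as latest and ties going to x — the information a
radius proxy built from face exposures can support; oblique section axes
are not representable.

## What the phantom generator emulates — and what it does not

`make_cylinder()`, `make_elliptical_tube()`, `make_torus()` and
`make_y_junction()` produce lattice solids with exact ground truth
(centerline, radius profile, Betti triple). `sample_surface_cloud()`
emulates a photogrammetric survey: points uniformly distributed over
*exposed voxel faces* (what cameras see), Poisson counts at a density
defaulting to 10 points per face area (chosen once, from the workflow rule
that the voxel size is picked so even sparse regions have at least one
point per voxel), optional spherical-cap holes (occlusions), and i.i.d.
Gaussian coordinate noise with σ expressed in voxel widths.

Two modelling notes matter when interpreting green tests:

* Phantom surfaces lie exactly on lattice planes. A real survey's octree
  is in generic position relative to the surveyed surface; an aligned
  lattice is a measure-zero degeneracy in which *any* noise splatters
  every face across two cell layers. The canonical phantom pipeline
  (`prepare_phantom_run()`) therefore voxelizes on a lattice offset by
  half a voxel — the one distinguished generic value — and all robustness
  results are stated in that frame.
* The generator does not emulate bark texture, view-dependent density
  variation, registration error between surveys, or non-elliptical
  ('inverted-T'/'I') cross-sections. A green phantom suite establishes
  that the algorithms are correct on clean tubular geometry with
  controlled noise and holes; it does not certify survey-specific failure
  modes.

Free tube ends are a phantom-specific stress: real branches either taper
or are capped at the model-space boundary, while a flat-capped cylinder
end erodes axially until curve-end protection engages, shortening the
skeleton by roughly one radius per end and (at junction-free ends) leaving
the cap's own medial segment. Lateral centering is unaffected; tests
measure centeredness against the axis, not tip-to-tip coverage.

## Tunable parameters

| parameter | where | default | units | why |
|---|---|---|---|---|
| `voxel_size` / `depth` | `voxelize()` | user | m / levels | the precision-vs-robustness dial of the whole workflow |
| `min_object_face_neighbors` | `suggest_holes()` | 4 | faces | a 1-cell puncture in a flat surface has 4 object face-neighbours |
| `radius_scale` | reconstruction | 1.0 | voxel widths / cycle | one cycle erodes one shell |
| `n` (exposure index) | reconstruction | 2 | — | `I1` misses volume, `I4` over-fills; `I2` balances |
| `cap` | `predict.er_model()` | 6 | — | bounds linear extrapolation |
| `points_per_unit_area` | `sampling_spec()` | 10 per face | m⁻² | survey-like density, fixed a priori |
| `noise_sigma_ratio` | `sampling_spec()` | 0 | voxel widths | robustness experiments |

## Degenerate inputs and tie-breaks

* A tie for the largest component in `denoise()` fails loudly by default
  (`keep_first = TRUE` opts into column-major order) — ties are
  pathological on real data and silence would hide bugs.
* Joint-cluster centroid ties resolve to the lowest column-major index and
  are logged.
* PCA orientation rejects collinear/coincident clouds (degenerate
  covariance) and fixes the eigenvector sign by requiring non-negative
  skewness along +z, keeping the rotation proper.
* `thin()` guards against non-termination (more cycles than the largest
  grid dimension raises an internal error).
* Voxelisation uses half-open cell boxes, so boundary points belong to
  exactly one cell, and pads one void layer on every face so an external
  void always exists and out-of-grid cells can uniformly count as void.

## Known limitations

* Reconstruction is in-plane (xy sections along z); flat-lying elements
  are under-reconstructed.
* Thinness is one voxel everywhere except busy junctions, where a joint
  voxel can keep three face-attached neighbours (and then exposes only
  three faces).
* The thinning is sequential by design; the sub-pass order affects which
  of several equally centred skeletons is returned, and free branch tips
  may differ in length between orientations (rotational-invariance checks
  therefore use closed asymmetric phantoms).
* Wall-clock scalability is reported (`scalability_report()`), never
  asserted: it is hardware-dependent.
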