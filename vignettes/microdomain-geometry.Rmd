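---
title: "Quantifying ER-PM and ER-mitochondria contact geometry in segmented volume EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER-PM and ER-mitochondria contact geometry in segmented volume EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Focused ion beam / scanning electron microscopy (FIB/SEM) produces aligned
stacks of block-face images at nanometre resolution — typically a few nm per
pixel in-plane and a 20 nm milling step between sections. After manual
segmentation, each cell becomes a 3D label volume: plasma membrane (PM),
endoplasmic/sarcoplasmic reticulum (ER/SR), per-instance mitochondria,
caveolae, optionally the nucleus. The biological question this package
serves is geometric: *how close, and over how much area, do calcium-handling
organelles approach each other in the sub-micrometre neighbourhood of a
caveola?* Caveolae act as hubs of local Ca²⁺ signalling in gut-wall cells
(smooth muscle cells, interstitial cells of Cajal, PDGFRα⁺ cells), and the
relevant geometry is the ER-PM separation, the local ER volume, and the
mitochondria-associated-membrane (MAM) contact area within a spherical
microdomain centred on each caveola.

The pipeline stages map directly onto that question:

1. **I/O** — `read_label_volume()` / `write_label_volume()` for multi-page
   TIFF (+ JSON sidecar) or HDF5 label stacks with anisotropic spacing.
2. **Meshing** — `mesh_from_labels()` extracts a triangle surface per
   structure, in physical nm.
3. **Microdomains** — `extract_caveola_seeds()` draws caveola centroids;
   `crop_mesh()` / `crop_labels()` restrict surfaces and voxels to a 400 nm
   sphere.
4. **Contacts** — `asd()` for the PM-to-ER average surface distance,
   `proximity_events()` for sub-20 nm ER-PM approaches, `mam_patches()` for
   sub-20 nm ER-mitochondria contact area.
5. **Statistics** — `summarize_metric()` / `report_microdomains()` with the
   MAM-positive-only inclusion rule.

`analyze_microdomains()` chains all of it.

## The average surface distance

With $S(PM)$ and $S(ER)$ the vertex sets of the two polygon meshes, the
per-vertex distance and its average are

$$d(p, S(ER)) = \min_{s \in S(ER)} \lVert p - s \rVert, \qquad
ASD(PM, ER) = \frac{1}{\lvert S(PM) \rvert} \sum_{p \in S(PM)} d(p, S(ER)).$$

Three properties of this definition matter in practice and are preserved
deliberately:

* **Vertex-to-vertex, not point-to-surface.** The statistic is defined on
  mesh vertices. A point-to-triangle variant is available
  (`asd(..., mode = "surface")`) and is a lower bound of the vertex mode,
  but it is not the default and is never mixed into the reported ASD.
* **One-directional.** The sum runs over PM vertices only. `asd(er, pm)` is
  the reverse direction; the two are not averaged.
* **Vertex density sensitivity.** Because the statistic lives on vertices,
  any resampling of the meshes changes it. `mesh_from_labels()` therefore
  applies no smoothing or decimation, and the vertex density is whatever
  the isosurfacer produces at the acquisition's voxel size. Comparisons
  between datasets should use the same voxel size and meshing route.

Nearest-neighbour queries go through an exact kd-tree (RANN). The test
suite checks on random mesh pairs that the tree changes nothing but speed
relative to the all-pairs computation, to 1e-9 relative.

## Isosurface extraction

No isosurfacer was available among the installed R packages, so the package
carries its own in compiled code: a table-free marching-cubes variant that
runs marching squares on each grid-cell face, chains the resulting crossing
segments into closed loops, and fan-triangulates each loop from its
centroid. Grid points sit at voxel centres, the binary mask is padded with
one background layer, and crossings interpolate the 0/1 field at level 0.5
(edge midpoints). Face rules depend only on the face's own corner values —
ambiguous diagonal faces always separate the two inside corners — so
adjacent cells agree on shared faces and every output mesh is closed,
crack-free and consistently outward-oriented. The suite verifies
watertightness, orientation (no repeated directed edge), and convergence of
area and enclosed volume toward analytic values on digitized balls.

Two numerical biases of binary-mask isosurfacing are worth knowing:

* **Surface area staircase.** On a digitized ball at isotropic 10 nm
  voxels the mesh area overestimates $4\pi r^2$ by several percent (the
  suite bounds it at 10%, decreasing with voxel size); anisotropic spacing
  pushes it somewhat higher. This is intrinsic to level-0.5 isosurfaces of
  binary data (reference implementations behave the same) and it cancels
  in distance statistics, which depend on vertex positions, not face
  areas. Contact areas inherit a few percent of it.
* **Sub-resolution features.** An isolated foreground voxel meshes to the
  octahedron through its six face midpoints — one sixth of the voxel
  volume. Structures thinner than about two voxels are positioned
  correctly but their meshed volume is unreliable; voxel counting
  (`measure_morphometry()`) is the canonical volume for exactly this
  reason, with the mesh-enclosed volume reported alongside as a
  consistency check when the mesh is watertight.

## Microdomains and cropping

A microdomain is the 400 nm sphere around a caveola centre, the scale of
reported local Ca²⁺ flux hotspots; the radius is a parameter
(`radius`, `--radius-nm`) with that default. Caveola centres are instance
centroids — reproducible, though not distinguishable from "neck" or "bulb"
conventions the source data might prefer; alternative centres can be
supplied as a `seed_points()` table.

Cropping rules, chosen so cropped quantities converge to their analytic
values:

* Meshes: triangles fully inside are kept; crossing triangles are clipped
  with exact edge-sphere intersection points (chord approximation of the
  boundary arc); fully-outside triangles are dropped, except the rare case
  where the ball pokes through a large triangle's interior, which is
  approximated by an inscribed 24-gon of the intersection disc. Keeping
  whole boundary triangles instead would bias areas upward.
* Voxels: a voxel is inside iff its centre is, with no partial-volume
  weighting — at r = 400 nm against tens-of-nm voxels the boundary layer
  is a negligible, unbiased fraction.
* Neighbouring caveolae inside a sphere remain part of the scene but spawn
  no nested analyses.

The suite checks the disc area of a centred plane crop against $\pi r^2$,
monotonicity of cropped ER volume in the radius, and agreement between a
direct crop at $r_1$ and a re-crop of the $r_2 > r_1$ scene.

## Contact detection

**MAM.** A MAM contact is an apposition of less than 20 nm between the
mitochondrial surface and the ER (threshold configurable). Faces whose
vertices all lie under the threshold belong to patches; mixed faces
contribute the sub-threshold fraction of their area by linear interpolation
of vertex distances, making the total area continuous and monotone in the
threshold. Patches are connected components over shared mesh edges. Areas
are measured on the mitochondrial side by default — patches are compact on
the convex mitochondrial surface — and the ER-side area is available by
swapping the arguments; on hand-segmented data the two differ by the local
vertex densities, and which side a human annotator's "MAM structure"
represents is genuinely ambiguous. Note that a reported MAM area includes
every part of the source surface within threshold of the target — for a
flat apposition facet that is the facet plus a rim strip of the adjoining
side walls (the strip where a wall point is still within 20 nm of the ER),
plus the isosurface's area inflation on curved surfaces. Parameter-recovery
tests on constructed facets therefore use a 15% band rather than exact
equality.

**ER-PM proximity events.** PM vertices closer than 20 nm to the ER vertex
set, merged into events by mesh-edge adjacency. Events are flagged
`near_caveola` when their centroid lies within 200 nm (Euclidean) of a
seed; the 200 nm neighbourhood is a pragmatic configuration default, not a
measured quantity.

## Summary statistics and the omission rule

Per-metric summaries report n, mean, median, sample SD (n − 1; a
population-SD switch exists for sensitivity checks) and the coefficient of
variation CV = SD / mean. Microdomains without a mitochondrion inside the
sphere cannot show MAM; their MAM area is *missing*, not zero, and the MAM
summary row counts only MAM-positive spheres. Treating absent organelles
as zero contact would drag the mean toward zero and conflate "no
mitochondrion nearby" with "mitochondrion present but not apposed". With a
single value the SD and CV are reported missing; with a zero mean the CV is
missing. Reports are byte-stable: rerunning with the same inputs and seed
reproduces identical CSVs, with provenance (radius, seed, thresholds,
package version) in a JSON sidecar.

## The phantom generator

No public segmentation accompanies the study regime this pipeline targets,
so `generate_phantom()` builds label volumes whose geometry is known in
continuous coordinates *before* rasterisation; `GroundTruth` is computed
analytically from those continuous shapes and never read back from voxels,
which keeps parameter-recovery tests genuine. Three archetypes emulate the
peripheral-ER architectures of the three cell types:

* `SMC` — a tube cell; peripheral SR as discrete longitudinal ribbons
  beneath the PM (pairwise disconnected, as the connected-component test
  verifies), a central nucleus with a perinuclear ER shell, mitochondria
  aggregated near the axis away from the caveola band.
* `ICC` — a rounded cell; a complete peripheral ER shell at the configured
  ER-PM gap plus interior sheets attached to it (one connected component),
  mitochondria apposed to the shell beneath caveolae.
* `PDGFRA` — parallel ER sheets stacked through the cytoplasm, with flat
  box mitochondria apposed beneath a sheet.

Key defaults and their reasoning:

* spacing (10, 10, 20) nm — finer in-plane pixels than the 20 nm milling
  step, matching the acquisition style and deliberately stressing metric
  isotropy;
* `er_pm_gap` 100 nm, `er_thickness` 30 nm — the peripheral ER regime the
  microdomain statistics target; with these, the analytic per-sphere ER
  volume of the study-scale scene falls in the 10⁷ nm³ decade;
* caveola flask: bulb radius 35 nm, neck radius 15 nm, depth 70 nm —
  typical caveolar dimensions from the general ultrastructure literature,
  not fitted to any dataset; a ±15 nm depth jitter varies the spheres;
* `mito_er_gap` 10 nm, facet 300 × 180 nm — a MAM-scale apposition with an
  analytically known facet area;
* SMC ribbons 600 nm wide — wide enough that the PM patch inside a 400 nm
  microdomain centred over a ribbon is fully backed by SR, so the ASD of
  such a sphere measures the gap rather than ribbon spacing. Real SR
  tubules are narrower; the phantom trades that realism for a clean
  recovery target.

ICC mitochondria are bricks in spherical shell coordinates — their
apposition face follows the ER shell's curvature at a constant gap, so the
facet area is exactly the configured a × b. A flattened-ellipsoid
mitochondrion against a curved shell cannot hold both the gap and the facet
area constant, which would make the ground truth approximate; the curved
brick keeps it exact.

Rasterisation uses half-open membership windows and snaps interior sheet
thicknesses and box depths to whole numbers of sections, so rasterised
volumes match the analytic ground truth within 5% for all structures
larger than a few voxels (asserted by the suite). Caveola flasks (35 nm
bulbs against 20 nm sections) are intentionally sub-resolution — the suite
holds them to a looser 15% band at the default spacing and verifies the
error shrinks at finer spacing.

What the phantoms do **not** emulate: membrane roughness and segmentation
noise, true SR tubule calibre, the porosity statistics of the ICC ER
network, partial-volume and alignment artefacts of real FIB/SEM stacks.
Passing recovery tests therefore demonstrates correctness of the geometry
pipeline, not robustness to segmentation error.

## Problem sizes

The test suite and the acceptance script run phantoms of 600-800 nm cell
radius for unit-level checks and a 1500 nm study-scale scene (≈ 2 × 10⁷
voxels, nine microdomains) for the end-to-end run; these sizes were chosen
so the full geometry — shell, sheets, nine caveolae, five apposed
mitochondria — is present while a complete analysis remains a
few-minute desk computation. All quantities scale with geometry, not with
array size, so larger volumes change cost only.

## Known limitations

* ASD inherits the ~half-voxel positioning uncertainty of binary-mask
  isosurfaces and a bias of order half the membrane-label thickness (PM
  vertices on the outer membrane face are farther from the ER than those
  on the inner face). Phantom recovery at the acquisition spacing is
  within one voxel diagonal, shrinking as spacing halves — matching what
  one should expect on real data only insofar as the segmentation is
  membrane-thin.
* Mesh surface areas carry the staircase inflation discussed above.
* The "surface" distance mode preselects candidate triangles by nearest
  face centroids (`surface_k`); it is exact when the target has no more
  faces than `surface_k`, else a tight approximation.
* HDF5 support requires the rhdf5 package; the TIFF + JSON sidecar
  container has no extra dependency.
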