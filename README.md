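# microdomain3d

Quantitative 3D geometry of organelle contact sites in segmented volume
electron microscopy.

FIB/SEM serial sectioning turns a cell into an aligned stack of label
images: plasma membrane (PM), ER/SR, mitochondria, caveolae. This package
measures the Ca²⁺-relevant geometry of the sub-micrometre neighbourhoods
around caveolae in such data — for electron microscopists and quantitative
cell biologists who have segmentations and want reproducible numbers
instead of interactive-software measurements:

* **ASD** — the average surface distance from the PM mesh to the ER,

  $$ASD(PM, ER) = \frac{1}{|S(PM)|}\sum_{p \in S(PM)} \min_{s \in S(ER)} \lVert p - s\rVert,$$

  computed vertex-to-vertex over the polygon meshes, one-directional,
  with an exact kd-tree;
* **microdomains** — spherical ROIs (default radius 400 nm) around
  randomly selected caveola centroids, with meshes clipped at the sphere
  and voxel volumes counted inside it;
* **MAM area** — ER–mitochondria contact patches under a < 20 nm
  apposition criterion, measured on the mitochondrial surface;
* **proximity events** — clustered PM vertices within 20 nm of the ER,
  flagged when they sit near a caveola;
* **summaries** — per-metric n, mean, median, sample SD and coefficient of
  variation (CV = SD/mean), with microdomains lacking mitochondria
  *omitted* from (not zeroed in) the MAM summary;
* **phantoms** — synthetic label volumes with analytic ground truth for
  three peripheral-ER archetypes (smooth muscle strands, ICC network,
  PDGFRα⁺ sheets), so every stage is testable without microscope data.

Label volumes are read from multi-page TIFF (+ JSON sidecar) or HDF5, with
anisotropic voxel spacing in nm (the in-plane pixel size is always
required; the section step defaults to a 20 nm milling step only when
metadata is absent). Meshes export to PLY/STL; per-vertex distance maps to
PLY for external rendering.

## Worked example

Generate a rounded-cell phantom (ICC archetype: peripheral ER shell 100 nm
beneath the PM, one mitochondrion apposed at 10 nm beneath one of three
caveolae) and analyse its microdomains:

```r
library(microdomain3d)

ph  <- generate_phantom(phantom_spec("ICC", cell_radius = 800,
                                     caveola_count = 3, mito_count = 1,
                                     rng_seed = 7))
res <- analyze_microdomains(ph$volume, n_spheres = 3, rng_seed = 7)
print(res)
#> microdomain analysis: 3 sphere(s), radius 400 nm
#>  sphere_id   asd_nm n_pm_vertices er_volume_nm3 has_mito mam_area_total_nm2 n_proximity_events
#>          1 107.9635         19131      12946000    FALSE                 NA                  0
#>          2 107.7297         19083      12834000     TRUE           68749.99                  0
#>          3 107.8495         19272      13458000    FALSE                 NA                  0
#> er_volume_nm3 [all]: n = 3, mean = 1.308e+07, median = 1.295e+07, sd = 3.327e+05, cv = 0.03
#> asd_nm [all]: n = 3, mean = 107.8, median = 107.8, sd = 0.1169, cv = 0.00
#> mam_area_nm2 [mam_positive_only]: n = 1, mean = 6.875e+04, median = 6.875e+04, sd = NA, cv = NA
```

Reading the numbers: the phantom's true ER–PM gap is 100 nm and the ASD
recovers it at ≈ 108 nm — the excess is the membrane-label thickness plus
the half-voxel positioning of binary-mask isosurfaces, within one voxel
diagonal (≤ 24.5 nm at 10 × 10 × 20 nm voxels). Each 400 nm sphere holds
≈ 1.3 × 10⁷ nm³ of ER (the analytic shell-lens value for this geometry).
Only sphere 2 contains a mitochondrion, so it alone carries a MAM area —
the constructed 300 × 180 nm facet (5.4 × 10⁴ nm²) plus the rim strip of
side wall that is genuinely within 20 nm of the ER — and the MAM summary
counts n = 1 while ASD and ER-volume summaries count all three spheres.
`report_microdomains(res$per_sphere, "results/")` writes per-sphere and
summary CSVs plus a provenance JSON; reruns are byte-identical.

A thin CLI over the same functions lives in `inst/scripts/microdomain3d.R`
(`simulate` writes a phantom volume + ground-truth manifest, `analyze`
runs the pipeline on any label volume).

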