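#' End-to-end microdomain analysis
#'
#' Runs the full pipeline on one segmented volume: select caveola seeds,
#' build whole-volume meshes once, then per microdomain crop the scene and
#' compute ER voxel volume, PM-to-ER average surface distance, sub-threshold
#' ER-PM proximity events and (for spheres containing a mitochondrion) MAM
#' contact area on the mitochondrial side. Spheres without mitochondria get a
#' missing MAM area and are excluded from the MAM summary; spheres where the
#' cropped PM or ER mesh is empty get a missing ASD.
#'
#' @param vol a [label_volume()] with PM and ER labels (MITO and CAVEOLA as
#'   available).
#' @param seeds optional [seed_points()]; when NULL, `n_spheres` caveola
#'   centroids are drawn with [extract_caveola_seeds()] under `rng_seed`.
#' @param n_spheres number of caveolae to draw when `seeds` is NULL.
#' @param radius microdomain radius in nm (default 400).
#' @param rng_seed seed for the caveola selection.
#' @param mam_threshold MAM apposition threshold in nm (default 20).
#' @param proximity_threshold ER-PM proximity threshold in nm (default 20).
#' @param caveola_neighbourhood `near_caveola` radius for proximity events.
#' @return A `microdomain_analysis` list: `per_sphere` (data.frame),
#'   `summaries` (list of [summarize_metric()] results), `scenes` (list of
#'   `cropped_scene`), `params`.
#' @export
analyze_microdomains <- function(vol, seeds = NULL, n_spheres = 3,
                                 radius = 400, rng_seed = 1L,
                                 mam_threshold = 20,
                                 proximity_threshold = 20,
                                 caveola_neighbourhood = 200) {
  if (is.null(seeds)) {
    seeds <- extract_caveola_seeds(vol, n = n_spheres, rng_seed = rng_seed)
  }
  roles <- intersect(c("PM", "ER", "MITO"), unique(as.character(vol$label_map)))
  meshes <- stats::setNames(lapply(roles, function(r) mesh_from_labels(vol, r)),
                            roles)

  rows <- list()
  scenes <- list()
  for (s in seq_len(nrow(seeds))) {
    roi <- sphere_roi(c(seeds$x_nm[s], seeds$y_nm[s], seeds$z_nm[s]),
                      radius = radius, sphere_id = s,
                      provenance = list(rng_seed = attr(seeds, "rng_seed"),
                                        caveola_label = seeds$caveola_label[s]))
    scene <- crop_scene(vol, roi, meshes = meshes, roles = roles)
    scenes[[s]] <- scene

    pm <- scene$meshes[["PM"]]
    er <- scene$meshes[["ER"]]
    mito <- scene$meshes[["MITO"]]
    ok_asd <- !is.null(pm) && !is.null(er) && !is_empty_mesh(pm) &&
      !is_empty_mesh(er)
    dres <- if (ok_asd) asd(pm, er) else NULL

    hm <- has_mitochondria(scene)
    mam_area <- NA_real_
    if (hm && !is.null(mito) && !is_empty_mesh(mito)) {
      mam_area <- if (!is.null(er) && !is_empty_mesh(er)) {
        mam_patches(mito, er, threshold = mam_threshold)$total_area_nm2
      } else 0
    }

    nev <- if (ok_asd) {
      nrow(proximity_events(pm, er, threshold = proximity_threshold,
                            seeds = seeds[s, , drop = FALSE],
                            neighbourhood = caveola_neighbourhood))
    } else NA_integer_

    rows[[s]] <- data.frame(
      sphere_id = s,
      asd_nm = if (ok_asd) dres$asd_nm else NA_real_,
      n_pm_vertices = if (ok_asd) dres$n_vertices else 0L,
      er_volume_nm3 = er_volume_in_scene(scene),
      has_mito = hm,
      mam_area_total_nm2 = mam_area,
      n_proximity_events = nev)
  }
  per_sphere <- do.call(rbind, rows)
  structure(list(per_sphere = per_sphere,
                 summaries = summarize_microdomains(per_sphere),
                 scenes = scenes,
                 params = list(radius = radius, rng_seed = rng_seed,
                               mam_threshold = mam_threshold,
                               proximity_threshold = proximity_threshold,
                               caveola_neighbourhood = caveola_neighbourhood)),
            class = "microdomain_analysis")
}

#' @export
print.microdomain_analysis <- function(x, ...) {
  cat(sprintf("microdomain analysis: %d sphere(s), radius %g nm\n",
              nrow(x$per_sphere), x$params$radius))
  print(x$per_sphere, row.names = FALSE)
  for (s in x$summaries) print(s)
  invisible(x)
}
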