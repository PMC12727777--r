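#' Triangle surface mesh
#'
#' Vertices are physical coordinates in nm; faces index vertices (1-based).
#' An empty mesh (no foreground) has zero rows in both. Construction drops
#' degenerate (zero-area) faces and checks index validity.
#'
#' @param vertices numeric `n x 3` matrix, columns x, y, z (nm).
#' @param faces integer `m x 3` matrix of vertex indices.
#' @param role the structure role the mesh represents (see
#'   [STRUCTURE_ROLES]), or `NA`.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, role = NA_character_) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    a <- face_areas(vertices, faces)
    faces <- faces[a > 0, , drop = FALSE]
  }
  if (nrow(vertices) > 0 && nrow(vertices) < 3) {
    stop("non-empty mesh needs at least 3 vertices")
  }
  structure(list(vertices = vertices, faces = faces, role = role),
            class = "surface_mesh")
}

empty_mesh <- function(role = NA_character_) {
  surface_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3),
               role = role)
}

is_empty_mesh <- function(mesh) nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh (%s): %d vertices, %d faces, area %.4g nm^2\n",
              ifelse(is.na(x$role), "unassigned", x$role),
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Mesh surface area and enclosed volume
#'
#' `mesh_area` is the sum of triangle areas. `mesh_enclosed_volume` uses the
#' divergence theorem over outward-oriented faces; it is only meaningful for
#' watertight meshes (all faces of [mesh_from_labels()] output are).
#'
#' @param mesh a [surface_mesh()].
#' @return Scalar nm^2 / nm^3 (0 for an empty mesh).
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh$vertices, mesh$faces))
}

#' @rdname mesh_area
#' @export
mesh_enclosed_volume <- function(mesh) {
  if (is_empty_mesh(mesh)) return(0)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
          a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
          a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6)
}

#' Is every mesh edge shared by exactly two faces?
#'
#' @param mesh a [surface_mesh()].
#' @return Logical; `TRUE` for an empty mesh.
#' @export
is_watertight <- function(mesh) {
  if (is_empty_mesh(mesh)) return(TRUE)
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(tabulate(factor(key)) == 2L)
}

#' Extract an isosurface mesh for one structure
#'
#' Runs marching cubes at level 0.5 on the binary mask of `role` (or of a
#' single instance `label`), with grid points at voxel centres and the
#' anisotropic spacing applied, so vertices come out in physical nm. The mask
#' is implicitly padded with background, so structures touching the array
#' boundary are closed off at it and every output mesh is watertight and
#' outward-oriented. No smoothing or decimation is applied: the average
#' surface distance is defined on mesh vertices, and resampling would change
#' vertex density and therefore the statistic.
#'
#' @param vol a [label_volume()].
#' @param role structure role to mesh (all labels with that role merged).
#' @param label optional single label value; overrides `role`.
#' @return A [surface_mesh()]; empty if the mask has no foreground.
#' @examples
#' a <- array(0L, c(12, 12, 6)); a[4:9, 4:9, 3:4] <- 1L
#' vol <- label_volume(a, voxel_spacing(10, 10, 20), c("1" = "ER"))
#' m <- mesh_from_labels(vol, "ER")
#' @export
mesh_from_labels <- function(vol, role = NULL, label = NULL) {
  if (is.null(label) && !is.null(role) &&
      !role %in% as.character(vol$label_map)) {
    stop("role '", role, "' not present in this volume's label map")
  }
  mask <- mask_for_role(vol, role = role, label = label)
  out_role <- if (!is.null(label)) {
    r <- vol$label_map[[as.character(label)]]
    if (is.null(r)) NA_character_ else r
  } else role
  if (!any(mask)) return(empty_mesh(out_role))
  res <- .mc_isosurface(as.logical(mask), dim(mask), as.numeric(vol$spacing))
  surface_mesh(res$vertices, res$faces, role = out_role)
}

#' Morphometry of one structure
#'
#' The canonical volume is voxel counting (`n * dx * dy * dz`): it is exact
#' for what the segmentation defines, whereas the mesh-enclosed volume
#' inherits the isosurface's smoothing of voxel corners and is reported
#' alongside (when the mesh is watertight) as a consistency check. Surface
#' area is the sum of the mesh's triangle areas.
#'
#' @param vol a [label_volume()].
#' @param role structure role to measure.
#' @param mesh optional [surface_mesh()] already built for this role;
#'   computed via [mesh_from_labels()] when missing.
#' @param label optional single label value; overrides `role`.
#' @return List of class `morphometry_record`: `role`, `n_voxels`,
#'   `volume_nm3` (voxel counting), `mesh_volume_nm3` (NA when not
#'   watertight), `surface_area_nm2`.
#' @export
measure_morphometry <- function(vol, role = NULL, mesh = NULL, label = NULL) {
  mask <- mask_for_role(vol, role = role, label = label)
  if (is.null(mesh)) mesh <- mesh_from_labels(vol, role = role, label = label)
  n <- sum(mask)
  structure(list(
    role = if (!is.null(role)) role else mesh$role,
    n_voxels = n,
    volume_nm3 = n * voxel_volume_nm3(vol$spacing),
    mesh_volume_nm3 = if (is_watertight(mesh)) mesh_enclosed_volume(mesh)
                      else NA_real_,
    surface_area_nm2 = mesh_area(mesh)
  ), class = "morphometry_record")
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf(
    "morphometry (%s): %d voxels, volume %.4g nm^3 (mesh %.4g), area %.4g nm^2\n",
    x$role, x$n_voxels, x$volume_nm3, x$mesh_volume_nm3, x$surface_area_nm2))
  invisible(x)
}
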