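#' Structure roles understood by the pipeline
#'
#' Each integer label in a segmented volume maps to one of these roles.
#' `MITO` and `CAVEOLA` labels are per-instance: several labels may carry the
#' same role, one per organelle instance. Background is always label 0 and
#' never appears in the label map.
#'
#' @format Character vector of role names.
#' @export
STRUCTURE_ROLES <- c("PM", "ER", "MITO", "CAVEOLA", "NUCLEUS")

#' Segmented label volume
#'
#' Container for a 3D integer label array with physical voxel spacing and a
#' label-to-role map. The array is laid out `[j, i, k]` (`dim = c(ny, nx,
#' nz)`); see [voxel_to_physical()] for the coordinate convention.
#'
#' Validation enforces that every non-zero value present in `data` has an
#' entry in `label_map` (error) and, for per-instance roles (`MITO`,
#' `CAVEOLA`), that each instance label forms a single 6-connected component
#' (warning only: hand segmentations occasionally split an organelle across
#' sections).
#'
#' @param data 3D array of non-negative integers, `dim = c(ny, nx, nz)`.
#' @param spacing a [voxel_spacing()] (or numeric length-3 `c(dx, dy, dz)`).
#' @param label_map named list or vector mapping label integers (names) to
#'   roles from [STRUCTURE_ROLES] (values), e.g. `c("1" = "PM", "2" = "ER")`.
#' @param check_instances validate 6-connectivity of instance labels
#'   (default TRUE; skip for speed on large volumes).
#' @return A `label_volume` object (list with `data`, `spacing`,
#'   `label_map`).
#' @examples
#' a <- array(0L, c(8, 8, 4))
#' a[3:6, 3:6, 2:3] <- 1L
#' vol <- label_volume(a, voxel_spacing(10, 10, 20), c("1" = "ER"))
#' @export
label_volume <- function(data, spacing, label_map = NULL,
                         check_instances = TRUE) {
  if (length(dim(data)) != 3) stop("`data` must be a 3D array")
  if (is.double(data)) {
    if (any(data != floor(data), na.rm = TRUE)) {
      stop("`data` must contain integers")
    }
    storage.mode(data) <- "integer"
  }
  if (anyNA(data) || min(data) < 0L) {
    stop("`data` must be non-negative integers without NA")
  }
  spacing <- as_voxel_spacing(spacing)
  label_map <- normalize_label_map(label_map)

  present <- sort(unique(as.vector(data)))
  present <- present[present != 0L]
  unknown <- setdiff(present, as.integer(names(label_map)))
  if (length(unknown) > 0) {
    stop("labels present in volume but absent from label_map: ",
         paste(unknown, collapse = ", "))
  }

  vol <- structure(list(data = data, spacing = spacing,
                        label_map = label_map),
                   class = "label_volume")
  if (check_instances) validate_instances(vol)
  vol
}

normalize_label_map <- function(label_map) {
  if (is.null(label_map) || length(label_map) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  lm <- unlist(label_map)
  labs <- suppressWarnings(as.integer(names(lm)))
  if (anyNA(labs)) stop("label_map names must be integer labels")
  if (any(labs == 0L)) stop("label 0 is reserved for background")
  if (anyDuplicated(labs)) stop("duplicated labels in label_map")
  roles <- as.character(lm)
  bad <- setdiff(roles, STRUCTURE_ROLES)
  if (length(bad) > 0) {
    stop("unknown roles in label_map: ", paste(unique(bad), collapse = ", "),
         " (expected one of ", paste(STRUCTURE_ROLES, collapse = ", "), ")")
  }
  stats::setNames(roles, as.character(labs))
}

validate_instances <- function(vol) {
  inst <- labels_for_role(vol, c("MITO", "CAVEOLA"))
  for (lab in inst) {
    mask <- vol$data == lab
    if (!any(mask)) next
    cc <- .label_components_6(as.logical(mask), dim(vol$data))
    ncc <- max(cc)
    if (ncc > 1) {
      warning(sprintf(
        "instance label %d (%s) has %d 6-connected components (expected 1)",
        lab, vol$label_map[[as.character(lab)]], ncc))
    }
  }
  invisible(vol)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume: %d x %d x %d voxels (y, x, z)\n", d[1], d[2], d[3]))
  print(x$spacing)
  ext <- physical_extent(x)
  cat(sprintf("physical extent (nm): %g x %g x %g (x, y, z)\n",
              ext[1], ext[2], ext[3]))
  if (length(x$label_map) == 0) {
    cat("no foreground labels\n")
  } else {
    for (lab in names(x$label_map)) {
      n <- sum(x$data == as.integer(lab))
      cat(sprintf("  label %s -> %s (%d voxels)\n", lab, x$label_map[[lab]], n))
    }
  }
  invisible(x)
}

#' Physical bounding box of a label volume
#'
#' @param vol a [label_volume()].
#' @return Length-3 numeric, extent in nm along (x, y, z).
#' @export
physical_extent <- function(vol) {
  d <- dim(vol$data)
  c(d[2] * vol$spacing[["dx"]], d[1] * vol$spacing[["dy"]],
    d[3] * vol$spacing[["dz"]])
}

#' Labels carrying a given role
#'
#' @param vol a [label_volume()].
#' @param role one or more roles from [STRUCTURE_ROLES].
#' @return Integer vector of label values (possibly empty).
#' @export
labels_for_role <- function(vol, role) {
  as.integer(names(vol$label_map)[vol$label_map %in% role])
}

#' Binary mask of one role (or one specific label)
#'
#' @param vol a [label_volume()].
#' @param role a role from [STRUCTURE_ROLES]; all labels with that role are
#'   merged.
#' @param label optional single label value; overrides `role`.
#' @return Logical array of the same dimensions as `vol$data`.
#' @export
mask_for_role <- function(vol, role = NULL, label = NULL) {
  if (!is.null(label)) {
    mask <- vol$data == as.integer(label)
  } else {
    if (is.null(role)) stop("supply `role` or `label`")
    if (!role %in% STRUCTURE_ROLES) stop("unknown role: ", role)
    labs <- labels_for_role(vol, role)
    mask <- array(vol$data %in% labs, dim(vol$data))
  }
  mask
}

#' Voxel volume in nm^3
#' @param spacing a [voxel_spacing()].
#' @return nm^3 per voxel.
#' @export
voxel_volume_nm3 <- function(spacing) {
  spacing <- as_voxel_spacing(spacing)
  prod(as.numeric(spacing))
}
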