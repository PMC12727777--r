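#' Physical voxel spacing
#'
#' Anisotropic voxel size in nanometres. `dz` is the section (milling) step
#' along the z axis; FIB/SEM acquisitions commonly mill at 20 nm, which is the
#' default used when a file carries no spacing metadata and the user does not
#' override it. In-plane pixel size has no universal default and must always
#' be supplied.
#'
#' @param dx,dy nm per voxel along x and y (in-plane pixel size).
#' @param dz nm per section along z; defaults to 20.
#' @return A `voxel_spacing` object: numeric vector `c(dx, dy, dz)`.
#' @examples
#' voxel_spacing(10, 10)         # 10 nm pixels, 20 nm sections
#' voxel_spacing(17.3, 17.3, 20)
#' @export
voxel_spacing <- function(dx, dy = dx, dz = 20) {
  sp <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("voxel spacing components must be strictly positive and finite")
  }
  structure(sp, class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing (nm): dx = %g, dy = %g, dz = %g\n",
              x[["dx"]], x[["dy"]], x[["dz"]]))
  invisible(x)
}

as_voxel_spacing <- function(x) {
  if (inherits(x, "voxel_spacing")) return(x)
  x <- as.numeric(x)
  if (length(x) != 3) stop("spacing must have three components (dx, dy, dz)")
  voxel_spacing(x[1], x[2], x[3])
}

#' Voxel index / physical coordinate conversion
#'
#' The single coordinate convention used throughout the package: the voxel at
#' 1-based array index `(j, i, k)` (array layout `[y, x, z]`) is centred at
#' `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)` nm, so a structure's centroid
#' is unbiased by array orientation.
#'
#' @param idx integer matrix with columns `j, i, k` (1-based array indices).
#' @param xyz numeric matrix with columns `x, y, z` in nm.
#' @param spacing a [voxel_spacing()].
#' @return `voxel_to_physical`: an `n x 3` matrix of `(x, y, z)` nm;
#'   `physical_to_voxel`: an `n x 3` integer matrix of `(j, i, k)` indices.
#' @export
voxel_to_physical <- function(idx, spacing) {
  spacing <- as_voxel_spacing(spacing)
  idx <- matrix(as.numeric(idx), ncol = 3)
  cbind(x = (idx[, 2] - 0.5) * spacing[["dx"]],
        y = (idx[, 1] - 0.5) * spacing[["dy"]],
        z = (idx[, 3] - 0.5) * spacing[["dz"]])
}

#' @rdname voxel_to_physical
#' @export
physical_to_voxel <- function(xyz, spacing) {
  spacing <- as_voxel_spacing(spacing)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  cbind(j = as.integer(floor(xyz[, 2] / spacing[["dy"]]) + 1),
        i = as.integer(floor(xyz[, 1] / spacing[["dx"]]) + 1),
        k = as.integer(floor(xyz[, 3] / spacing[["dz"]]) + 1))
}
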