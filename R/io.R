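#' Read a segmented label volume
#'
#' Two containers are supported: a multi-page TIFF stack (uint8/uint16, one
#' page per section) with a JSON sidecar `<path>.json` holding `spacing_nm`
#' and `label_map`, or an HDF5 file with a `labels` dataset carrying
#' attributes `spacing_nm` (3 floats, z, y, x order) and `label_map` (JSON
#' string). The format is chosen by extension (`.h5`, `.hdf5` for HDF5,
#' anything else TIFF).
#'
#' Spacing is resolved in priority order: explicit `spacing_override` >
#' file metadata > nothing. There is no silent in-plane default: if neither
#' source provides dx/dy the read fails, because wrong-scale spacing corrupts
#' every downstream metric. A missing dz alone falls back to the 20 nm
#' FIB/SEM milling step via [voxel_spacing()].
#'
#' @param path file path.
#' @param spacing_override optional [voxel_spacing()] taking precedence over
#'   file metadata.
#' @return A [label_volume()].
#' @seealso [write_label_volume()]
#' @export
read_label_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_hdf5_path(path)) {
    read_label_volume_h5(path, spacing_override)
  } else {
    read_label_volume_tiff(path, spacing_override)
  }
}

#' Write a segmented label volume
#'
#' Inverse of [read_label_volume()]; the round trip reproduces data, spacing
#' and label map exactly. TIFF output is 8-bit when all labels fit, 16-bit
#' otherwise, with the JSON sidecar written next to it.
#'
#' @param vol a [label_volume()].
#' @param path output path (`.tif`/`.tiff` or `.h5`/`.hdf5`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  if (is_hdf5_path(path)) {
    write_label_volume_h5(vol, path)
  } else {
    write_label_volume_tiff(vol, path)
  }
  invisible(path)
}

is_hdf5_path <- function(path) {
  grepl("\\.(h5|hdf5|he5)$", path, ignore.case = TRUE)
}

sidecar_path <- function(path) paste0(path, ".json")

read_label_volume_tiff <- function(path, spacing_override) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  data <- array(0L, c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]]

  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::fromJSON(sidecar_path(path))
  }
  spacing <- resolve_spacing(spacing_override, meta$spacing_nm, path)
  label_map <- meta$label_map
  label_volume(data, spacing, label_map, check_instances = FALSE)
}

write_label_volume_tiff <- function(vol, path) {
  maxlab <- max(0L, max(vol$data))
  bits <- if (maxlab < 256L) 8L else 16L
  if (maxlab > 65535L) stop("labels exceed 16-bit TIFF range")
  denom <- 2^bits - 1
  nz <- dim(vol$data)[3]
  pages <- lapply(seq_len(nz), function(k) vol$data[, , k] / denom)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) stop("TIFF write failed: ",
                                          conditionMessage(e)))
  sp <- vol$spacing
  jsonlite::write_json(
    list(spacing_nm = list(dx = sp[["dx"]], dy = sp[["dy"]], dz = sp[["dz"]]),
         label_map = as.list(vol$label_map)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_label_volume_h5 <- function(path, spacing_override) {
  require_rhdf5()
  data <- rhdf5::h5read(path, "labels")
  storage.mode(data) <- "integer"
  at <- rhdf5::h5readAttributes(path, "labels")
  spacing_meta <- NULL
  if (!is.null(at$spacing_nm)) {
    s <- as.numeric(at$spacing_nm) # stored (z, y, x)
    spacing_meta <- c(dx = s[3], dy = s[2], dz = s[1])
  }
  label_map <- NULL
  if (!is.null(at$label_map)) {
    label_map <- jsonlite::fromJSON(as.character(at$label_map))
  }
  spacing <- resolve_spacing(spacing_override, spacing_meta, path)
  label_volume(data, spacing, label_map, check_instances = FALSE)
}

write_label_volume_h5 <- function(vol, path) {
  require_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(vol$data, path, "labels")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, "labels")
  on.exit(rhdf5::H5Dclose(did), add = TRUE)
  sp <- vol$spacing
  rhdf5::h5writeAttribute(c(sp[["dz"]], sp[["dy"]], sp[["dx"]]), did,
                          "spacing_nm")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(as.list(vol$label_map), auto_unbox = TRUE)),
    did, "label_map")
  invisible(path)
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("HDF5 support requires the rhdf5 package; ",
         "use the TIFF + JSON sidecar container instead")
  }
}

resolve_spacing <- function(override, meta, path) {
  if (!is.null(override)) return(as_voxel_spacing(override))
  if (!is.null(meta)) {
    m <- unlist(meta)
    if (!is.null(names(m)) && all(c("dx", "dy") %in% names(m))) {
      dz <- if ("dz" %in% names(m)) m[["dz"]] else 20
      return(voxel_spacing(m[["dx"]], m[["dy"]], dz))
    }
    if (length(m) == 3) return(as_voxel_spacing(m))
  }
  stop("no voxel spacing for ", path,
       ": supply spacing_override (in-plane pixel size has no default)")
}

#' Caveola seed points
#'
#' Build a seed-point set from physical coordinates, e.g. to supply microdomain
#' centres other than caveola centroids.
#'
#' @param xyz numeric matrix or data.frame with columns x, y, z in nm.
#' @param caveola_label optional integer vector, the caveola instance each
#'   point came from.
#' @param rng_seed optional integer recorded as selection provenance.
#' @return A `seed_points` data.frame with columns
#'   `x_nm, y_nm, z_nm, caveola_label`.
#' @export
seed_points <- function(xyz, caveola_label = NA_integer_, rng_seed = NA_integer_) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  df <- data.frame(x_nm = as.numeric(xyz[, 1]), y_nm = as.numeric(xyz[, 2]),
                   z_nm = as.numeric(xyz[, 3]),
                   caveola_label = as.integer(caveola_label))
  attr(df, "rng_seed") <- as.integer(rng_seed)
  class(df) <- c("seed_points", "data.frame")
  df
}

#' Randomly select caveola centres as microdomain seeds
#'
#' Caveola instances are the per-instance `CAVEOLA` labels when the
#' segmentation separates them, or the 6-connected components of a single
#' merged `CAVEOLA` label otherwise. Each instance's seed is the physical
#' centroid of its voxels. `n` instances are drawn uniformly without
#' replacement with the Mersenne-Twister generator under `rng_seed`, which is
#' recorded in the result for provenance; a fixed seed reproduces the
#' selection exactly.
#'
#' @param vol a [label_volume()] containing caveola labels.
#' @param n number of caveolae to select (the study design draws 3 per cell).
#' @param rng_seed integer seed for the selection.
#' @return A [seed_points()] data.frame of `n` centroids.
#' @export
extract_caveola_seeds <- function(vol, n = 3, rng_seed = 1L) {
  cents <- caveola_centroids(vol)
  if (nrow(cents) < n) {
    stop(sprintf("requested %d caveolae but only %d available", n, nrow(cents)))
  }
  pick <- with_seed(rng_seed, sample.int(nrow(cents), n))
  seed_points(cents[pick, c("x_nm", "y_nm", "z_nm"), drop = FALSE],
              caveola_label = cents$caveola_label[pick], rng_seed = rng_seed)
}

#' Centroids of all caveola instances
#'
#' @param vol a [label_volume()].
#' @return data.frame `caveola_label, x_nm, y_nm, z_nm, n_voxels` (one row per
#'   instance; empty when the volume has no caveolae).
#' @export
caveola_centroids <- function(vol) {
  labs <- labels_for_role(vol, "CAVEOLA")
  out <- data.frame(caveola_label = integer(0), x_nm = numeric(0),
                    y_nm = numeric(0), z_nm = numeric(0),
                    n_voxels = integer(0))
  if (length(labs) == 0) return(out)
  if (length(labs) == 1L) {
    mask <- vol$data == labs
    cc <- .label_components_6(as.logical(mask), dim(vol$data))
    ncc <- max(cc)
    if (ncc == 0) return(out)
    for (m in seq_len(ncc)) {
      idx <- which(array(cc == m, dim(vol$data)), arr.ind = TRUE)
      xyz <- voxel_to_physical(idx, vol$spacing)
      out <- rbind(out, data.frame(caveola_label = labs,
                                   x_nm = mean(xyz[, 1]), y_nm = mean(xyz[, 2]),
                                   z_nm = mean(xyz[, 3]), n_voxels = nrow(idx)))
    }
  } else {
    for (lab in labs) {
      idx <- which(vol$data == lab, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      xyz <- voxel_to_physical(idx, vol$spacing)
      out <- rbind(out, data.frame(caveola_label = lab,
                                   x_nm = mean(xyz[, 1]), y_nm = mean(xyz[, 2]),
                                   z_nm = mean(xyz[, 3]), n_voxels = nrow(idx)))
    }
  }
  out
}

#' Read / write seed-point CSVs
#'
#' CSV layout: header `x_nm,y_nm,z_nm,caveola_label`.
#'
#' @param path file path.
#' @param seeds a [seed_points()] data.frame.
#' @return `read_seed_points`: a [seed_points()] data.frame.
#' @export
read_seed_points <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df))) {
    stop("seed CSV must have columns x_nm, y_nm, z_nm")
  }
  lab <- if ("caveola_label" %in% names(df)) df$caveola_label else NA_integer_
  seed_points(df[, need], caveola_label = lab)
}

#' @rdname read_seed_points
#' @export
write_seed_points <- function(seeds, path) {
  utils::write.csv(
    data.frame(x_nm = seeds$x_nm, y_nm = seeds$y_nm, z_nm = seeds$z_nm,
               caveola_label = seeds$caveola_label),
    path, row.names = FALSE)
  invisible(path)
}

# evaluate expr under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}
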