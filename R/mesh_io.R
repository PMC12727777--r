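#' Mesh export and import
#'
#' ASCII PLY and STL writers, units nm (stated in a header comment where the
#' format allows). PLY optionally carries one scalar per vertex as the
#' standard `quality` property, which is how per-vertex distance maps travel
#' to external viewers; [read_mesh_ply()] round-trips it.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @param scalar optional numeric vector, one value per vertex (written as
#'   vertex `quality`).
#' @return `path` (writers) or a [surface_mesh()] with attribute `scalar`
#'   (reader), invisibly for writers.
#' @export
write_mesh_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (!is.null(scalar) && length(scalar) != nv) {
    stop("scalar must have one value per vertex")
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           "comment units nm",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (!is.null(scalar)) hdr <- c(hdr, "property double quality")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (nv > 0) {
    vm <- mesh$vertices
    if (!is.null(scalar)) vm <- cbind(vm, scalar)
    writeLines(apply(format(vm, digits = 17, trim = TRUE, scientific = FALSE),
                     1, paste, collapse = " "), con)
  }
  if (nf > 0) {
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not a PLY file (no end_header): ", path)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)))
  vprops <- sub("^property \\S+ ", "",
                grep("^property (double|float) ", hdr, value = TRUE))
  has_quality <- "quality" %in% vprops
  vlines <- lines[end + seq_len(nv)]
  vm <- if (nv > 0) {
    do.call(rbind, lapply(strsplit(vlines, " +"), as.numeric))
  } else matrix(numeric(0), ncol = 3 + has_quality)
  flines <- lines[end + nv + seq_len(nf)]
  fm <- if (nf > 0) {
    do.call(rbind, lapply(strsplit(flines, " +"),
                          function(x) as.integer(x[2:4]) + 1L))
  } else matrix(integer(0), ncol = 3)
  mesh <- surface_mesh(vm[, 1:3, drop = FALSE], fm)
  if (has_quality) attr(mesh, "scalar") <- vm[, 4]
  mesh
}

#' @rdname write_mesh_ply
#' @export
write_mesh_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh_nm", con)
  if (nrow(mesh$faces) > 0) {
    v <- mesh$vertices
    f <- mesh$faces
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c <- v[f[, 3], , drop = FALSE]
    e1 <- b - a
    e2 <- c - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
    fmt <- function(m) apply(format(m, digits = 9, trim = TRUE), 1, paste,
                             collapse = " ")
    writeLines(paste0("facet normal ", fmt(n), "\n outer loop\n  vertex ",
                      fmt(a), "\n  vertex ", fmt(b), "\n  vertex ", fmt(c),
                      "\n endloop\nendfacet"), con)
  }
  writeLines("endsolid mesh_nm", con)
  invisible(path)
}
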