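#' Average surface distance (ASD) between two meshes
#'
#' For every vertex p of the source mesh (PM), the distance d(p, S(target))
#' is the minimum Euclidean distance to the target mesh's vertex set (ER),
#' and the ASD is the arithmetic mean of these per-vertex distances:
#' \deqn{ASD(PM, ER) = \frac{1}{|S(PM)|} \sum_{p \in S(PM)} \min_{s \in S(ER)} \|p - s\|}
#' The statistic is deliberately one-directional (PM to ER) and is not
#' symmetrised; call `asd(er, pm)` for the reverse direction. Nearest
#' neighbours are found with an exact kd-tree, which changes speed only, not
#' results; ties among equidistant target vertices do not affect the
#' distance and no nearest-vertex identity is reported.
#'
#' `mode = "surface"` measures point-to-triangle distance to the target
#' surface instead, a lower bound of the vertex mode (candidate triangles are
#' preselected by nearest face centroids; exact when the target has at most
#' `surface_k` faces).
#'
#' @param pm source [surface_mesh()] (distances measured from its vertices).
#' @param er target [surface_mesh()].
#' @param mode `"vertex"` (vertex-to-vertex, the definition above; default)
#'   or `"surface"` (point-to-triangle).
#' @param surface_k candidate faces per query vertex in surface mode.
#' @return A `distance_result`: list with `per_vertex_nm`, `asd_nm`,
#'   `n_vertices`.
#' @examples
#' g <- expand.grid(x = seq(0, 100, 20), y = seq(0, 100, 20))
#' plane <- function(z) surface_mesh(cbind(g$x, g$y, z),
#'   matrix(c(1, 2, 8, 1, 8, 7), ncol = 3, byrow = TRUE))
#' asd(plane(0), plane(100))$asd_nm  # 100
#' @export
asd <- function(pm, er, mode = c("vertex", "surface"), surface_k = 32L) {
  mode <- match.arg(mode)
  if (is_empty_mesh(pm)) stop("source (PM-side) mesh is empty")
  if (is_empty_mesh(er)) stop("target (ER-side) mesh is empty")
  d <- if (mode == "vertex") {
    nearest_vertex_distances(pm$vertices, er$vertices)
  } else {
    point_to_surface_distances(pm$vertices, er, surface_k)
  }
  structure(list(per_vertex_nm = d, asd_nm = mean(d),
                 n_vertices = nrow(pm$vertices), mode = mode),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("ASD = %.2f nm over %d source vertices (%s mode); range [%.2f, %.2f]\n",
              x$asd_nm, x$n_vertices, x$mode, min(x$per_vertex_nm),
              max(x$per_vertex_nm)))
  invisible(x)
}

nearest_vertex_distances <- function(query, target) {
  as.numeric(RANN::nn2(target, query, k = 1, treetype = "kd",
                       searchtype = "standard")$nn.dists)
}

point_to_surface_distances <- function(query, mesh, k) {
  f <- mesh$faces
  v <- mesh$vertices
  cents <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  k <- min(k, nrow(f))
  nn <- RANN::nn2(cents, query, k = k)$nn.idx
  vapply(seq_len(nrow(query)), function(i) {
    min(vapply(nn[i, ], function(fi) {
      point_triangle_distance(query[i, ], v[f[fi, 1], ], v[f[fi, 2], ],
                              v[f[fi, 3], ])
    }, numeric(1)))
  }, numeric(1))
}

# exact point-triangle distance (projection onto plane, then clamp to edges)
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + t * ab))^2)))
  }
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  denom <- va + vb + vc
  vv <- vb / denom
  w <- vc / denom
  sqrt(sum((p - (a + vv * ab + w * ac))^2))
}

#' Sub-threshold ER-PM proximity events
#'
#' Finds PM vertices closer than `threshold` to the ER vertex set and merges
#' vertices adjacent on the PM mesh into connected events. Such points mark
#' putative ER-PM junctions; with the 20 nm threshold they correspond to the
#' tether scale of STIM/Orai-type contacts and are observed particularly
#' beneath caveolae. An event is flagged `near_caveola` when its centroid
#' lies within `neighbourhood` (Euclidean) of any seed point; 200 nm is a
#' pragmatic default, not a measured quantity.
#'
#' @param pm,er [surface_mesh()]es in the same frame.
#' @param threshold distance threshold in nm (default 20).
#' @param seeds optional [seed_points()] of caveola centres.
#' @param neighbourhood caveola neighbourhood radius in nm (default 200).
#' @return data.frame, one row per event: `event_id, n_vertices,
#'   min_distance_nm, x_nm, y_nm, z_nm` (location of the closest vertex),
#'   `near_caveola`. Zero rows when nothing is below threshold.
#' @export
proximity_events <- function(pm, er, threshold = 20, seeds = NULL,
                             neighbourhood = 200) {
  if (threshold <= 0) stop("threshold must be > 0")
  empty <- data.frame(event_id = integer(0), n_vertices = integer(0),
                      min_distance_nm = numeric(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0),
                      near_caveola = logical(0))
  if (is_empty_mesh(pm) || is_empty_mesh(er)) return(empty)
  d <- nearest_vertex_distances(pm$vertices, er$vertices)
  hit <- which(d < threshold)
  if (length(hit) == 0) return(empty)

  comp <- cluster_on_mesh(pm$faces, hit, nrow(pm$vertices))
  ev <- lapply(seq_along(comp), function(ci) {
    vs <- comp[[ci]]
    best <- vs[which.min(d[vs])]
    centroid <- colMeans(pm$vertices[vs, , drop = FALSE])
    near <- FALSE
    if (!is.null(seeds) && nrow(seeds) > 0) {
      dd <- sqrt((seeds$x_nm - centroid[1])^2 + (seeds$y_nm - centroid[2])^2 +
                 (seeds$z_nm - centroid[3])^2)
      near <- any(dd <= neighbourhood)
    }
    data.frame(event_id = ci, n_vertices = length(vs),
               min_distance_nm = d[best], x_nm = pm$vertices[best, 1],
               y_nm = pm$vertices[best, 2], z_nm = pm$vertices[best, 3],
               near_caveola = near)
  })
  do.call(rbind, ev)
}

# connected components of a vertex subset under mesh-edge adjacency
cluster_on_mesh <- function(faces, subset, n_vertices) {
  in_set <- logical(n_vertices)
  in_set[subset] <- TRUE
  ed <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  ed <- ed[in_set[ed[, 1]] & in_set[ed[, 2]], , drop = FALSE]
  remap <- integer(n_vertices)
  remap[subset] <- seq_along(subset)
  g <- igraph::graph_from_edgelist(matrix(remap[ed], ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(subset) - igraph::vcount(g)))
  mem <- igraph::components(g)$membership
  split(subset, mem[seq_along(subset)])
}

#' Mitochondria-associated membrane (MAM) contact patches
#'
#' A MAM contact is an apposition of less than `threshold` (default 20 nm)
#' between a mitochondrial surface and the ER. Faces of the source mesh all
#' of whose vertices lie under the threshold (distance to the target vertex
#' set) belong to patches; faces with a mixed vertex status contribute the
#' sub-threshold fraction of their area by linear interpolation of vertex
#' distances, so patch areas vary continuously and monotonically with the
#' threshold. Patches are connected components over shared mesh edges.
#'
#' The source is conventionally the mitochondrial mesh (patches are compact
#' on its convex surface); swap the arguments to measure the ER-side area.
#'
#' @param mito source [surface_mesh()] (areas are measured on it).
#' @param er target [surface_mesh()]; an empty target yields no patches (a
#'   microdomain may contain a mitochondrion but no ER).
#' @param threshold apposition threshold in nm (default 20).
#' @return A `mam_result`: list with `patches` (data.frame `patch_id,
#'   n_faces, area_nm2`), `total_area_nm2`, `threshold`.
#' @export
mam_patches <- function(mito, er, threshold = 20) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (is_empty_mesh(mito)) stop("source (mitochondrial) mesh is empty")
  empty <- structure(list(
    patches = data.frame(patch_id = integer(0), n_faces = integer(0),
                         area_nm2 = numeric(0)),
    total_area_nm2 = 0, threshold = threshold), class = "mam_result")
  if (is_empty_mesh(er)) return(empty)

  d <- nearest_vertex_distances(mito$vertices, er$vertices)
  f <- mito$faces
  below <- d < threshold
  nb <- below[f[, 1]] + below[f[, 2]] + below[f[, 3]]
  member <- which(nb > 0)
  if (length(member) == 0) return(empty)

  areas <- face_areas(mito$vertices, f)
  frac <- numeric(length(member))
  for (ii in seq_along(member)) {
    fi <- member[ii]
    dv <- d[f[fi, ]]
    frac[ii] <- subthreshold_area_fraction(dv, threshold)
  }

  # patch connectivity over shared edges among member faces
  g <- face_adjacency_graph(f, member)
  mem <- igraph::components(g)$membership
  patch_area <- tapply(areas[member] * frac, mem, sum)
  patch_n <- tapply(rep(1L, length(member)), mem, sum)
  ord <- order(-as.numeric(patch_area))
  patches <- data.frame(patch_id = seq_along(ord),
                        n_faces = as.integer(patch_n[ord]),
                        area_nm2 = as.numeric(patch_area[ord]))
  structure(list(patches = patches,
                 total_area_nm2 = sum(patches$area_nm2),
                 threshold = threshold),
            class = "mam_result")
}

#' @export
print.mam_result <- function(x, ...) {
  cat(sprintf("MAM (< %g nm): %d patch(es), total area %.4g nm^2\n",
              x$threshold, nrow(x$patches), x$total_area_nm2))
  invisible(x)
}

# fraction of a triangle's area where the linearly-interpolated vertex
# distance field is below t
subthreshold_area_fraction <- function(dv, t) {
  below <- dv < t
  nb <- sum(below)
  if (nb == 3L) return(1)
  if (nb == 0L) return(0)
  s <- sort(dv)
  if (nb == 1L) {
    (t - s[1])^2 / ((s[2] - s[1]) * (s[3] - s[1]))
  } else {
    1 - (s[3] - t)^2 / ((s[3] - s[1]) * (s[3] - s[2]))
  }
}

face_adjacency_graph <- function(faces, member) {
  fsub <- faces[member, , drop = FALSE]
  m <- nrow(fsub)
  ed <- rbind(fsub[, 1:2], fsub[, 2:3], fsub[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  fid <- rep(seq_len(m), 3)
  sp <- split(fid, key)
  pairs <- do.call(rbind, lapply(sp[lengths(sp) > 1], function(x) {
    cbind(x[1], x[-1])
  }))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  g
}

#' Export a per-vertex distance map with its mesh
#'
#' Writes the source mesh as ASCII PLY with the per-vertex distances in the
#' standard `quality` property, for external rendering of distance heatmaps.
#'
#' @param result a `distance_result` from [asd()].
#' @param pm the [surface_mesh()] the result was computed from.
#' @param path output PLY path.
#' @return `path`, invisibly.
#' @export
export_distance_map <- function(result, pm, path) {
  if (length(result$per_vertex_nm) != nrow(pm$vertices)) {
    stop("distance result does not match this mesh")
  }
  write_mesh_ply(pm, path, scalar = result$per_vertex_nm)
  invisible(path)
}
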