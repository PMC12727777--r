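#' Phantom specification
#'
#' Parameters for a synthetic segmented volume emulating the three
#' peripheral-ER architectures seen in gut-wall cells: `"SMC"` (smooth
#' muscle cell: a tube-shaped cell whose peripheral SR forms discrete
#' longitudinal strands beneath the PM, a central nucleus with perinuclear
#' ER, and mitochondria aggregated near the nucleus), `"ICC"` (interstitial
#' cell of Cajal: a rounded cell with a connected ER network — peripheral
#' shell plus interior sheets — and mitochondria apposed to the ER near
#' caveolae) and `"PDGFRA"` (parallel ER sheets stacked through the
#' cytoplasm).
#'
#' All geometry is defined in continuous nm coordinates first; the ground
#' truth returned by [generate_phantom()] is derived from these continuous
#' shapes, never read back from the rasterised voxels, so parameter-recovery
#' tests are genuine.
#'
#' The caveola flask defaults (bulb radius 35 nm, neck radius 15 nm, depth
#' 70 nm) are typical caveolar dimensions from the general ultrastructure
#' literature, exposed here as configuration.
#'
#' @param archetype `"SMC"`, `"ICC"` or `"PDGFRA"`.
#' @param spacing a [voxel_spacing()]; the default (10, 10, 20) emulates a
#'   FIB/SEM acquisition with finer in-plane pixels than the 20 nm milling
#'   step, deliberately stressing metric isotropy.
#' @param cell_radius cell radius in nm (tube radius for SMC).
#' @param margin background margin around the cell in nm.
#' @param er_pm_gap ground-truth offset of the peripheral ER/SR from the PM
#'   inner surface, nm.
#' @param er_thickness peripheral ER sheet/shell thickness, nm.
#' @param caveola_count number of caveolae (placed on the equator for
#'   ball-shaped cells, along the strands for SMC).
#' @param caveola_bulb_radius,caveola_neck_radius,caveola_depth flask
#'   geometry in nm.
#' @param caveola_depth_jitter uniform jitter (+/- nm) applied per caveola.
#' @param mito_count number of mitochondrion instances.
#' @param mito_er_gap ground-truth ER-mitochondrion apposition gap, nm.
#' @param mito_facet facet dimensions `c(a, b)` in nm of the constructed
#'   apposition facet (defaults 300 x 180).
#' @param mito_depth mitochondrion extent away from the facet, nm.
#' @param smc_strand_count,smc_strand_width peripheral SR strand layout for
#'   the SMC archetype (width in nm along the circumference).
#' @param sheet_pitch sheet spacing for the PDGFRA archetype, nm.
#' @param rng_seed integer seed controlling all stochastic placement jitter.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(archetype = c("ICC", "SMC", "PDGFRA"),
                         spacing = voxel_spacing(10, 10, 20),
                         cell_radius = NULL,
                         margin = 200,
                         er_pm_gap = 100,
                         er_thickness = 30,
                         caveola_count = 9,
                         caveola_bulb_radius = 35,
                         caveola_neck_radius = 15,
                         caveola_depth = 70,
                         caveola_depth_jitter = 15,
                         mito_count = NULL,
                         mito_er_gap = 10,
                         mito_facet = c(300, 180),
                         mito_depth = 300,
                         smc_strand_count = 6,
                         smc_strand_width = 600,
                         sheet_pitch = 250,
                         rng_seed = 1L) {
  archetype <- match.arg(archetype)
  spacing <- as_voxel_spacing(spacing)
  if (is.null(cell_radius)) {
    cell_radius <- switch(archetype, ICC = 1500, SMC = 1200, PDGFRA = 1200)
  }
  if (is.null(mito_count)) {
    mito_count <- switch(archetype, ICC = 5, SMC = 2, PDGFRA = 2)
  }
  spec <- structure(list(
    archetype = archetype, spacing = spacing, cell_radius = cell_radius,
    margin = margin, er_pm_gap = er_pm_gap, er_thickness = er_thickness,
    caveola_count = caveola_count,
    caveola_bulb_radius = caveola_bulb_radius,
    caveola_neck_radius = caveola_neck_radius,
    caveola_depth = caveola_depth,
    caveola_depth_jitter = caveola_depth_jitter,
    mito_count = mito_count, mito_er_gap = mito_er_gap,
    mito_facet = mito_facet, mito_depth = mito_depth,
    smc_strand_count = smc_strand_count,
    smc_strand_width = smc_strand_width,
    sheet_pitch = sheet_pitch,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  sp <- as.numeric(spec$spacing)
  vmax <- max(sp)
  if (spec$er_pm_gap < 0) stop("er_pm_gap must be >= 0")
  if (spec$er_pm_gap > 0 && spec$er_pm_gap < 2 * vmax) {
    stop(sprintf("er_pm_gap %g nm is not resolvable at spacing up to %g nm (needs >= 2 voxels)",
                 spec$er_pm_gap, vmax))
  }
  if (spec$er_thickness < vmax) {
    stop(sprintf("er_thickness %g nm below one voxel (%g nm)",
                 spec$er_thickness, vmax))
  }
  if (spec$cell_radius < 4 * (spec$er_pm_gap + spec$er_thickness)) {
    stop("cell_radius too small for the requested peripheral geometry")
  }
  if (spec$mito_count > 0 && spec$mito_er_gap < min(sp)) {
    warning(sprintf("mito_er_gap %g nm is below one in-plane voxel (%g nm); rasterised gaps will be quantized",
                    spec$mito_er_gap, min(sp)))
  }
  if (spec$caveola_count > 0 && spec$caveola_neck_radius < min(sp)) {
    warning("caveola neck radius below one voxel; necks may rasterise discontinuously")
  }
  if (spec$caveola_depth - spec$caveola_depth_jitter - spec$caveola_bulb_radius < 0) {
    stop("caveola bulb does not fit inside the flask depth")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s, cell radius %g nm, ER-PM gap %g nm, %d caveolae, %d mitochondria, seed %d\n",
              x$archetype, x$cell_radius, x$er_pm_gap, x$caveola_count,
              x$mito_count, x$rng_seed))
  invisible(x)
}

# label scheme shared by all archetypes
PHANTOM_LABELS <- list(PM = 1L, ER = 2L, NUCLEUS = 3L,
                       MITO_BASE = 10L, CAVEOLA_BASE = 100L)

#' Generate a synthetic phantom volume with analytic ground truth
#'
#' Rasterises the continuous geometry described by a [phantom_spec()] onto
#' the voxel grid (a voxel belongs to a structure iff its centre does) and
#' returns the label volume together with ground truth computed from the
#' continuous geometry before rasterisation: true ER-PM gap, per-structure
#' volumes, per-mitochondrion apposition-facet areas, analytic caveola
#' centres and (ICC) per-microdomain ER volumes.
#'
#' Deterministic for a fixed `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `volume` (a [label_volume()]) and
#'   `ground_truth` (list).
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec("ICC", cell_radius = 800,
#'                                     caveola_count = 3, mito_count = 1))
#' ph$ground_truth$true_er_pm_gap
#' }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, {
    switch(spec$archetype,
           ICC = generate_ball_phantom(spec, interior = "sheets_polar"),
           PDGFRA = generate_ball_phantom(spec, interior = "sheets_stacked"),
           SMC = generate_smc_phantom(spec))
  })
}

# ---------------------------------------------------------------------------
# ball-shaped cells (ICC, PDGFRA)

generate_ball_phantom <- function(spec, interior) {
  sp <- as.numeric(spec$spacing)
  R <- spec$cell_radius
  t_pm <- max(sp)
  g <- spec$er_pm_gap
  t_er <- spec$er_thickness
  R_er_out <- R - g
  R_er_in <- R_er_out - t_er

  half <- R + t_pm + spec$margin
  nx <- ceiling(2 * half / sp[1]); ny <- ceiling(2 * half / sp[2])
  nz <- ceiling(2 * half / sp[3])
  cx <- nx * sp[1] / 2; cy <- ny * sp[2] / 2; cz <- nz * sp[3] / 2
  x <- (seq_len(nx) - 0.5) * sp[1]
  y <- (seq_len(ny) - 0.5) * sp[2]
  z <- (seq_len(nz) - 0.5) * sp[3]

  rho2 <- outer(outer((y - cy)^2, (x - cx)^2, "+"), (z - cz)^2, "+")
  data <- array(0L, c(ny, nx, nz))
  lm <- c()

  # peripheral ER shell
  data[rho2 > R_er_in^2 & rho2 <= R_er_out^2] <- PHANTOM_LABELS$ER

  # interior ER sheets; thickness snapped to a whole number of sections so
  # the z-quantized rasterisation matches the analytic volume exactly
  t_sheet <- ceiling(t_er / sp[3]) * sp[3]
  truth_sheets <- list()
  if (interior == "sheets_polar") {
    offsets <- c(-900, -650, 650, 900) * (R / 1500)
  } else {
    offsets <- seq(-R_er_in + spec$sheet_pitch, R_er_in - spec$sheet_pitch,
                   by = spec$sheet_pitch)
  }
  offsets <- offsets[abs(offsets) + t_sheet < R_er_in]
  for (z0 in offsets) {
    zin <- z - cz > z0 & z - cz <= z0 + t_sheet
    slab <- array(rep(zin, each = ny * nx), c(ny, nx, nz)) &
      rho2 <= R_er_out^2
    data[slab] <- PHANTOM_LABELS$ER
    truth_sheets[[length(truth_sheets) + 1]] <- z0
  }
  lm["ER"] <- PHANTOM_LABELS$ER

  # caveolae on the equator
  n_cav <- spec$caveola_count
  cav <- place_equator_caveolae(spec, n_cav)
  cav_centres <- matrix(numeric(0), ncol = 3)
  for (m in seq_len(n_cav)) {
    th <- cav$theta[m]
    depth <- cav$depth[m]
    u <- c(cos(th), sin(th), 0)
    bc <- c(cx, cy, cz) + (R - depth + spec$caveola_bulb_radius) * u
    lab <- PHANTOM_LABELS$CAVEOLA_BASE + m
    data <- rasterise_flask(data, sp, bc, u, spec, R, c(cx, cy, cz), lab)
    cav_centres <- rbind(cav_centres, bc)
  }

  # mitochondria. ICC: spherically-curved bricks facing the ER shell inner
  # surface beneath caveolae 1..mito_count (constant gap, exact facet area).
  # PDGFRA: flat boxes apposed beneath an interior sheet (flat-flat facet).
  rho_f <- R_er_in - spec$mito_er_gap
  a <- spec$mito_facet[1]; b <- spec$mito_facet[2]
  mam_truth <- numeric(0)
  mito_truth_vol <- numeric(0)
  if (interior == "sheets_polar") {
    n_mito <- min(spec$mito_count, n_cav)
    if (spec$mito_count > n_cav) {
      warning("mito_count reduced to caveola_count for apposition placement")
    }
    for (m in seq_len(n_mito)) {
      th <- cav$theta[m]
      lab <- PHANTOM_LABELS$MITO_BASE + m
      depth_in <- min(spec$mito_depth, rho_f - 0.3 * R)
      data <- rasterise_curved_brick(data, sp, c(cx, cy, cz), th, rho_f,
                                     depth_in, a, b, lab)
      alpha <- a / (2 * rho_f)
      mam_truth[as.character(lab)] <-
        if (spec$mito_er_gap < 20) a * b else 0
      mito_truth_vol[as.character(lab)] <-
        alpha * b * (rho_f^2 - (rho_f - depth_in)^2)
    }
  } else {
    n_mito <- spec$mito_count
    mid_sheet <- offsets[which.min(abs(offsets))]
    depth_eff <- min(spec$mito_depth,
                     spec$sheet_pitch - t_sheet - spec$mito_er_gap - 50)
    depth_eff <- floor(depth_eff / sp[3]) * sp[3] # exact on the z lattice
    for (m in seq_len(n_mito)) {
      lab <- PHANTOM_LABELS$MITO_BASE + m
      xoff <- (m - (n_mito + 1) / 2) * (a + 200)
      ztop <- cz + mid_sheet - spec$mito_er_gap
      ctr <- c(cx + xoff, cy, ztop - depth_eff / 2)
      rng <- bbox_ranges(ctr, max(a, b, depth_eff) / 2 + 2 * max(sp), sp,
                         dim(data))
      yc <- (rng$j - 0.5) * sp[2] - cy
      xc <- (rng$i - 0.5) * sp[1] - (cx + xoff)
      sel_j <- yc > -b / 2 & yc <= b / 2
      sel_i <- xc > -a / 2 & xc <= a / 2
      zc <- (rng$k - 0.5) * sp[3]
      sel_k <- zc > ztop - depth_eff & zc <= ztop
      data[rng$j[sel_j], rng$i[sel_i], rng$k[sel_k]] <- lab
      mam_truth[as.character(lab)] <-
        if (spec$mito_er_gap < 20) a * b else 0
      mito_truth_vol[as.character(lab)] <- a * b * depth_eff
    }
  }

  # PM shell last among large structures
  data[rho2 > R^2 & rho2 <= (R + t_pm)^2] <- PHANTOM_LABELS$PM
  lm["PM"] <- PHANTOM_LABELS$PM

  label_map <- c(stats::setNames("PM", PHANTOM_LABELS$PM),
                 stats::setNames("ER", PHANTOM_LABELS$ER))
  for (m in seq_len(n_mito)) {
    label_map[as.character(PHANTOM_LABELS$MITO_BASE + m)] <- "MITO"
  }
  for (m in seq_len(n_cav)) {
    label_map[as.character(PHANTOM_LABELS$CAVEOLA_BASE + m)] <- "CAVEOLA"
  }
  vol <- label_volume(data, spec$spacing, label_map, check_instances = FALSE)

  # analytic volumes
  v_shell <- 4 / 3 * pi * (R_er_out^3 - R_er_in^3)
  v_sheets <- sum(vapply(unlist(truth_sheets), function(z0) {
    zone_volume(R_er_in, z0, z0 + t_sheet)
  }, numeric(1)))
  flask_vol <- vapply(seq_len(n_cav), function(m) {
    flask_volume(spec$caveola_bulb_radius, spec$caveola_neck_radius,
                 cav$depth[m], R, R - cav$depth[m] + spec$caveola_bulb_radius)
  }, numeric(1))
  true_volumes <- c(
    PM = 4 / 3 * pi * ((R + t_pm)^3 - R^3),
    ER = v_shell + v_sheets,
    prefixed(mito_truth_vol, "MITO."),
    prefixed(stats::setNames(flask_vol,
                             PHANTOM_LABELS$CAVEOLA_BASE + seq_len(n_cav)),
             "CAVEOLA."))

  # per-microdomain ER volume: spherical-shell / sphere lens difference.
  # Exact for ICC, whose interior sheets sit outside the equatorial
  # microdomains; not available in closed form for the stacked-sheet
  # archetype (sheets cross the microdomains).
  per_sphere <- if (interior == "sheets_polar") {
    vapply(seq_len(n_cav), function(m) {
      d <- R - cav$depth[m] + spec$caveola_bulb_radius
      sphere_sphere_intersection_volume(R_er_out, 400, d) -
        sphere_sphere_intersection_volume(R_er_in, 400, d)
    }, numeric(1))
  } else rep(NA_real_, n_cav)

  gt <- list(
    archetype = spec$archetype,
    true_er_pm_gap = g,
    true_mam_area_per_mito = mam_truth,
    true_volumes = true_volumes,
    caveola_centres = seed_points(cav_centres,
                                  caveola_label = PHANTOM_LABELS$CAVEOLA_BASE +
                                    seq_len(n_cav),
                                  rng_seed = spec$rng_seed),
    per_sphere_er_volume_nm3 = per_sphere,
    mito_under_caveola = seq_len(n_mito),
    n_er_components = 1L)
  list(volume = vol, ground_truth = gt)
}

place_equator_caveolae <- function(spec, n_cav) {
  if (n_cav == 0) return(list(theta = numeric(0), depth = numeric(0)))
  base <- 2 * pi * (seq_len(n_cav) - 1) / max(n_cav, 1)
  jitter <- runif(n_cav, -0.5, 0.5) * (0.2 * 2 * pi / max(n_cav, 1))
  depth <- spec$caveola_depth +
    runif(n_cav, -1, 1) * spec$caveola_depth_jitter
  list(theta = base + jitter, depth = depth)
}

# flask = bulb sphere + neck cylinder from the bulb centre to the PM inner
# surface, rasterised over its bounding box
rasterise_flask <- function(data, sp, bc, u, spec, R, cen, lab) {
  rb <- spec$caveola_bulb_radius
  rn <- spec$caveola_neck_radius
  neck_len <- R - sqrt(sum((bc - cen)^2)) # bulb centre to PM inner surface
  pad <- rb + 2 * max(sp)
  reach <- max(rb, neck_len) + pad
  rng <- bbox_ranges(bc, reach, sp, dim(data))
  if (any(lengths(rng) == 0)) return(data)
  xs <- (rng$i - 0.5) * sp[1]; ys <- (rng$j - 0.5) * sp[2]
  zs <- (rng$k - 0.5) * sp[3]
  px <- rep(xs, each = length(rng$j))
  py <- rep(ys, times = length(rng$i))
  grid_xy_x <- matrix(px, nrow = length(rng$j))
  grid_xy_y <- matrix(py, nrow = length(rng$j))
  for (kk in seq_along(rng$k)) {
    dzv <- zs[kk] - bc[3]
    dxv <- grid_xy_x - bc[1]
    dyv <- grid_xy_y - bc[2]
    d2 <- dxv^2 + dyv^2 + dzv^2
    axial <- dxv * u[1] + dyv * u[2] + dzv * u[3]
    rad2 <- d2 - axial^2
    in_bulb <- d2 <= rb^2
    in_neck <- axial > 0 & axial <= neck_len & rad2 <= rn^2
    sel <- in_bulb | in_neck
    if (any(sel)) {
      sl <- data[rng$j, rng$i, rng$k[kk]]
      sl[sel] <- lab
      data[rng$j, rng$i, rng$k[kk]] <- sl
    }
  }
  data
}

# mitochondrion as a brick in spherical shell coordinates: outer face on the
# sphere of radius rho_f (constant gap to the ER shell inner surface), arc
# length a along the equator direction, b along z, extending depth inward
rasterise_curved_brick <- function(data, sp, cen, theta, rho_f, depth,
                                   a, b, lab) {
  alpha <- a / (2 * rho_f)
  mid <- cen + (rho_f - depth / 2) * c(cos(theta), sin(theta), 0)
  reach <- depth / 2 + a / 2 + b / 2 + 3 * max(sp)
  rng <- bbox_ranges(mid, reach, sp, dim(data))
  if (any(lengths(rng) == 0)) return(data)
  xs <- (rng$i - 0.5) * sp[1]; ys <- (rng$j - 0.5) * sp[2]
  zs <- (rng$k - 0.5) * sp[3]
  dxm <- matrix(rep(xs, each = length(rng$j)), nrow = length(rng$j)) - cen[1]
  dym <- matrix(rep(ys, times = length(rng$i)), nrow = length(rng$j)) - cen[2]
  phi <- atan2(dym, dxm) - theta
  phi <- atan2(sin(phi), cos(phi)) # wrap to (-pi, pi]
  rxy2 <- dxm^2 + dym^2
  for (kk in seq_along(rng$k)) {
    dzv <- zs[kk] - cen[3]
    rho <- sqrt(rxy2 + dzv^2)
    sel <- rho <= rho_f & rho > rho_f - depth &
      phi > -alpha & phi <= alpha & dzv > -b / 2 & dzv <= b / 2
    if (any(sel)) {
      sl <- data[rng$j, rng$i, rng$k[kk]]
      sl[sel] <- lab
      data[rng$j, rng$i, rng$k[kk]] <- sl
    }
  }
  data
}

bbox_ranges <- function(centre, reach, sp, dims) {
  j <- max(1L, floor((centre[2] - reach) / sp[2])):min(dims[1],
       ceiling((centre[2] + reach) / sp[2]))
  i <- max(1L, floor((centre[1] - reach) / sp[1])):min(dims[2],
       ceiling((centre[1] + reach) / sp[1]))
  k <- max(1L, floor((centre[3] - reach) / sp[3])):min(dims[3],
       ceiling((centre[3] + reach) / sp[3]))
  list(j = j, i = i, k = k)
}

# ---------------------------------------------------------------------------
# SMC: tube cell with longitudinal peripheral SR strands

generate_smc_phantom <- function(spec) {
  sp <- as.numeric(spec$spacing)
  R <- spec$cell_radius
  t_pm <- max(sp)
  g <- spec$er_pm_gap
  t_er <- spec$er_thickness
  R_er_out <- R - g
  R_er_in <- R_er_out - t_er

  half_yz <- R + t_pm + spec$margin
  len_x <- max(2 * half_yz,
               (spec$caveola_count + 1) * 500 + 2 * spec$margin)
  nx <- ceiling(len_x / sp[1])
  ny <- ceiling(2 * half_yz / sp[2]); nz <- ceiling(2 * half_yz / sp[3])
  cx <- nx * sp[1] / 2; cy <- ny * sp[2] / 2; cz <- nz * sp[3] / 2
  x <- (seq_len(nx) - 0.5) * sp[1]
  y <- (seq_len(ny) - 0.5) * sp[2]
  z <- (seq_len(nz) - 0.5) * sp[3]

  # cylindrical radius about the x axis, as a (y, z) field broadcast over x
  ryz2 <- outer((y - cy)^2, (z - cz)^2, "+") # (ny, nz)
  phi_yz <- atan2(matrix(rep(z - cz, each = ny), ny),
                  matrix(rep(y - cy, times = nz), ny))

  data <- array(0L, c(ny, nx, nz))
  expand_yz <- function(mask_yz) {
    # (ny, nz) -> (ny, nx, nz)
    aperm(array(rep(mask_yz, times = nx), c(ny, nz, nx)), c(1, 3, 2))
  }

  # peripheral SR strands (pairwise disconnected ribbons along x)
  ns <- spec$smc_strand_count
  halfang <- (spec$smc_strand_width / 2) / R_er_out
  if (ns * 2 * halfang >= 2 * pi) {
    stop("smc strands overlap: reduce smc_strand_count or smc_strand_width")
  }
  strand_angles <- 2 * pi * (seq_len(ns) - 1) / ns
  strand_mask_yz <- matrix(FALSE, ny, nz)
  in_band_yz <- ryz2 > R_er_in^2 & ryz2 <= R_er_out^2
  for (ph in strand_angles) {
    dphi <- atan2(sin(phi_yz - ph), cos(phi_yz - ph))
    strand_mask_yz <- strand_mask_yz | (in_band_yz & abs(dphi) <= halfang)
  }
  data[expand_yz(strand_mask_yz)] <- PHANTOM_LABELS$ER

  # nucleus (ellipsoid along the tube axis) + perinuclear ER shell
  nuc_a <- min(0.3 * len_x, 800); nuc_b <- 0.35 * R; nuc_c <- 0.35 * R
  peri_in <- 1.15; peri_out <- 1.25
  m2 <- outer(outer((y - cy)^2 / nuc_b^2, (x - cx)^2 / nuc_a^2, "+"),
              (z - cz)^2 / nuc_c^2, "+")
  data[m2 > peri_in^2 & m2 <= peri_out^2] <- PHANTOM_LABELS$ER
  data[m2 <= 1] <- PHANTOM_LABELS$NUCLEUS

  # mitochondria: boxes aggregated near the cell axis at the tube ends,
  # far from the caveola band and away (>> 20 nm) from all ER
  mito_truth_vol <- numeric(0)
  for (m in seq_len(spec$mito_count)) {
    ph <- strand_angles[1 + (m - 1) %% ns] + pi / ns
    rho_mid <- 300
    xend <- len_x / 2 - spec$margin - 250 -
      ((m - 1) %/% 2) * (spec$mito_depth + 150)
    ctr <- c(cx + xend * (-1)^m,
             cy + rho_mid * cos(ph), cz + rho_mid * sin(ph))
    lab <- PHANTOM_LABELS$MITO_BASE + m
    half_dims <- c(spec$mito_depth, spec$mito_facet[1],
                   spec$mito_facet[2]) / 2
    rng <- bbox_ranges(ctr, max(half_dims) + 2 * max(sp), sp, dim(data))
    yc <- (rng$j - 0.5) * sp[2] - ctr[2]
    xc <- (rng$i - 0.5) * sp[1] - ctr[1]
    zc <- (rng$k - 0.5) * sp[3] - ctr[3]
    sel_j <- yc > -half_dims[2] & yc <= half_dims[2]
    sel_i <- xc > -half_dims[1] & xc <= half_dims[1]
    sel_k <- zc > -half_dims[3] & zc <= half_dims[3]
    data[rng$j[sel_j], rng$i[sel_i], rng$k[sel_k]] <- lab
    mito_truth_vol[as.character(lab)] <- prod(2 * half_dims)
  }

  # caveolae along the strands
  n_cav <- spec$caveola_count
  depth <- spec$caveola_depth +
    runif(n_cav, -1, 1) * spec$caveola_depth_jitter
  cav_centres <- matrix(numeric(0), ncol = 3)
  for (m in seq_len(n_cav)) {
    ph <- strand_angles[1 + (m - 1) %% ns]
    xoff <- cx + (ceiling(m / ns) - 1) * 500 - 250 * (n_cav > ns)
    u <- c(0, cos(ph), sin(ph))
    bc <- c(xoff, cy, cz) + (R - depth[m] + spec$caveola_bulb_radius) * u
    lab <- PHANTOM_LABELS$CAVEOLA_BASE + m
    data <- rasterise_flask_tube(data, sp, bc, u, spec, R, c(cx, cy, cz), lab)
    cav_centres <- rbind(cav_centres, bc)
  }

  # PM tube shell
  data[expand_yz(ryz2 > R^2 & ryz2 <= (R + t_pm)^2)] <- PHANTOM_LABELS$PM

  label_map <- c(stats::setNames("PM", PHANTOM_LABELS$PM),
                 stats::setNames("ER", PHANTOM_LABELS$ER),
                 stats::setNames("NUCLEUS", PHANTOM_LABELS$NUCLEUS))
  for (m in seq_len(spec$mito_count)) {
    label_map[as.character(PHANTOM_LABELS$MITO_BASE + m)] <- "MITO"
  }
  for (m in seq_len(n_cav)) {
    label_map[as.character(PHANTOM_LABELS$CAVEOLA_BASE + m)] <- "CAVEOLA"
  }
  vol <- label_volume(data, spec$spacing, label_map, check_instances = FALSE)

  v_strands <- ns * (2 * halfang / (2 * pi)) * pi *
    (R_er_out^2 - R_er_in^2) * len_x
  v_peri <- 4 / 3 * pi * nuc_a * nuc_b * nuc_c * (peri_out^3 - peri_in^3)
  flask_vol <- vapply(seq_len(n_cav), function(m) {
    flask_volume(spec$caveola_bulb_radius, spec$caveola_neck_radius,
                 depth[m], R, R - depth[m] + spec$caveola_bulb_radius)
  }, numeric(1))
  true_volumes <- c(
    PM = pi * ((R + t_pm)^2 - R^2) * len_x,
    ER = v_strands + v_peri,
    NUCLEUS = 4 / 3 * pi * nuc_a * nuc_b * nuc_c,
    prefixed(mito_truth_vol, "MITO."),
    prefixed(stats::setNames(flask_vol,
                             PHANTOM_LABELS$CAVEOLA_BASE + seq_len(n_cav)),
             "CAVEOLA."))

  gt <- list(
    archetype = "SMC",
    true_er_pm_gap = g,
    true_mam_area_per_mito = stats::setNames(
      rep(0, spec$mito_count),
      as.character(PHANTOM_LABELS$MITO_BASE + seq_len(spec$mito_count))),
    true_volumes = true_volumes,
    caveola_centres = seed_points(cav_centres,
                                  caveola_label = PHANTOM_LABELS$CAVEOLA_BASE +
                                    seq_len(n_cav),
                                  rng_seed = spec$rng_seed),
    n_peripheral_strands = ns,
    n_er_components = ns + 1L, # strands + perinuclear shell
    mito_under_caveola = integer(0))
  list(volume = vol, ground_truth = gt)
}

# flask for the tube cell: radial direction u lies in the (y, z) plane
rasterise_flask_tube <- function(data, sp, bc, u, spec, R, cen, lab) {
  rb <- spec$caveola_bulb_radius
  rn <- spec$caveola_neck_radius
  rho_bc <- sqrt(sum(((bc - cen) * c(0, 1, 1))^2))
  neck_len <- R - rho_bc
  reach <- max(rb, neck_len) + rb + 2 * max(sp)
  rng <- bbox_ranges(bc, reach, sp, dim(data))
  xs <- (rng$i - 0.5) * sp[1]; ys <- (rng$j - 0.5) * sp[2]
  zs <- (rng$k - 0.5) * sp[3]
  for (kk in seq_along(rng$k)) {
    dzv <- zs[kk] - bc[3]
    dxv <- matrix(rep(xs - bc[1], each = length(rng$j)), nrow = length(rng$j))
    dyv <- matrix(rep(ys - bc[2], times = length(rng$i)),
                  nrow = length(rng$j))
    d2 <- dxv^2 + dyv^2 + dzv^2
    axial <- dyv * u[2] + dzv * u[3]
    rad2 <- d2 - axial^2
    sel <- (d2 <= rb^2) | (axial > 0 & axial <= neck_len & rad2 <= rn^2)
    if (any(sel)) {
      sl <- data[rng$j, rng$i, rng$k[kk]]
      sl[sel] <- lab
      data[rng$j, rng$i, rng$k[kk]] <- sl
    }
  }
  data
}

# ---------------------------------------------------------------------------
# analytic helpers

prefixed <- function(x, prefix) {
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(x), paste0(prefix, names(x)))
}

#' Volume of the intersection of two balls
#'
#' Closed-form lens volume for balls of radii `r1`, `r2` with centres `d`
#' apart; used to derive analytic per-microdomain ER volumes for shell
#' phantoms.
#'
#' @param r1,r2 ball radii (nm).
#' @param d centre separation (nm).
#' @return Intersection volume in nm^3.
#' @export
sphere_sphere_intersection_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
}

# volume of a ball slice between planes z = a and z = b (centre at 0)
zone_volume <- function(R, a, b) {
  a <- max(a, -R); b <- min(b, R)
  if (b <= a) return(0)
  f <- function(u) pi * (R^2 * u - u^3 / 3)
  f(b) - f(a)
}

# flask volume: union of bulb sphere (radius rb at the origin of the axial
# coordinate) and neck cylinder (radius rn, axial range (0, neck_len]),
# integrated over the axial coordinate
flask_volume <- function(rb, rn, depth, R, rho_bc) {
  neck_len <- R - rho_bc
  ds <- 0.05
  s <- seq(-rb + ds / 2, max(rb, neck_len), by = ds)
  area <- vapply(s, function(si) {
    bulb <- if (abs(si) < rb) pi * (rb^2 - si^2) else 0
    neck <- if (si > 0 && si <= neck_len) pi * rn^2 else 0
    max(bulb, neck)
  }, numeric(1))
  sum(area) * ds
}

#' Generate a study-scale ICC scene
#'
#' An ICC phantom dimensioned to the regime of the FIB/SEM study: 400 nm
#' microdomains around nine equatorial caveolae, peripheral ER shell 100 nm
#' beneath the PM (per-sphere analytic ER volumes of order 10^7 nm^3),
#' mitochondria apposed at 10 nm beneath five of the nine caveolae so the
#' MAM-positive / MAM-negative omission logic is exercised.
#'
#' @param rng_seed integer seed.
#' @param spacing optional [voxel_spacing()] (default (10, 10, 20)).
#' @return As [generate_phantom()]: list with `volume` and `ground_truth`.
#' @export
generate_study_scale_scene <- function(rng_seed = 1L,
                                       spacing = voxel_spacing(10, 10, 20)) {
  spec <- phantom_spec("ICC", spacing = spacing, cell_radius = 1500,
                       caveola_count = 9, mito_count = 5,
                       er_pm_gap = 100, er_thickness = 30,
                       mito_er_gap = 10, mito_facet = c(300, 180),
                       rng_seed = rng_seed)
  generate_phantom(spec)
}
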