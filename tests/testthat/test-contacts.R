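test_that("ASD of a mesh against itself is zero and errors name the empty side", {
  m <- make_plane_mesh(n = 6, pitch = 50)
  expect_equal(asd(m, m)$asd_nm, 0)
  emp <- surface_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
  expect_error(asd(emp, m), "source")
  expect_error(asd(m, emp), "target")
})

test_that("aligned parallel planes return exactly the gap", {
  for (gap in c(50, 100, 150)) {
    pm <- make_plane_mesh(n = 11, pitch = 100, z0 = 0)
    er <- make_plane_mesh(n = 11, pitch = 100, z0 = gap)
    res <- asd(pm, er)
    expect_equal(res$asd_nm, gap, tolerance = 1e-9)
    expect_true(all(abs(res$per_vertex_nm - gap) < 1e-9))
    # invariants of the distance result
    expect_equal(res$asd_nm, sum(res$per_vertex_nm) / res$n_vertices)
    expect_lte(res$asd_nm, max(res$per_vertex_nm))
    # brute-force oracle agrees
    expect_equal(res$asd_nm, brute_asd(pm, er)$asd_nm, tolerance = 1e-12)
  }
})

test_that("accelerated ASD equals the all-pairs oracle on random meshes", {
  for (s in 1:6) {
    pm <- rand_mesh(150 + 10 * s, seed = s)
    er <- rand_mesh(120 + 7 * s, seed = 100 + s, shift = c(80, -40, 60))
    fast <- asd(pm, er)
    slow <- brute_asd(pm, er)
    expect_equal(fast$per_vertex_nm, slow$per_vertex_nm, tolerance = 1e-12)
    expect_equal(fast$asd_nm, slow$asd_nm, tolerance = 1e-12)
  }
})

test_that("ASD is invariant under rigid transforms of both meshes", {
  pm <- rand_mesh(180, seed = 11)
  er <- rand_mesh(140, seed = 12, shift = c(100, 0, -50))
  base <- asd(pm, er)$asd_nm
  for (s in 1:4) {
    R <- random_rotation(20 + s)
    tr <- c(1000, -200, 333) * s
    rot <- function(m) surface_mesh(sweep(m$vertices %*% t(R), 2, tr, "+"),
                                    m$faces)
    expect_equal(asd(rot(pm), rot(er))$asd_nm, base,
                 tolerance = 1e-6)
  }
})

test_that("refining the target vertex set can only shrink distances", {
  pm <- rand_mesh(100, seed = 31)
  er_coarse <- rand_mesh(80, seed = 32, shift = c(50, 50, 50))
  extra <- matrix(runif(90, 0, 500), ncol = 3)
  er_fine <- surface_mesh(rbind(er_coarse$vertices, extra + c(50, 50, 50)),
                          er_coarse$faces)
  d0 <- asd(pm, er_coarse)$per_vertex_nm
  d1 <- asd(pm, er_fine)$per_vertex_nm
  expect_true(all(d1 <= d0 + 1e-12))
})

test_that("surface mode bounds vertex mode from below", {
  pm <- rand_mesh(60, seed = 41)
  er <- make_plane_mesh(n = 8, pitch = 100, z0 = 700)
  dv <- asd(pm, er, mode = "vertex")$per_vertex_nm
  ds <- asd(pm, er, mode = "surface", surface_k = 200)$per_vertex_nm
  expect_true(all(ds <= dv + 1e-9))
})

test_that("proximity events find local approaches and flag caveola vicinity", {
  pm <- make_plane_mesh(n = 21, pitch = 50, z0 = 100)
  er <- make_plane_mesh(n = 21, pitch = 50, z0 = 0)
  # 100 nm apart everywhere: nothing under 20 nm
  expect_equal(nrow(proximity_events(pm, er, threshold = 20)), 0)
  # press a dimple to 15 nm in the PM around (500, 500)
  v <- pm$vertices
  r2 <- (v[, 1] - 500)^2 + (v[, 2] - 500)^2
  v[, 3] <- 100 - 85 * exp(-r2 / (2 * 80^2))
  dimpled <- surface_mesh(v, pm$faces)
  ev <- proximity_events(dimpled, er, threshold = 20)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$min_distance_nm, 20)
  expect_equal(c(ev$x_nm, ev$y_nm), c(500, 500))
  # seed 100 nm away with a 200 nm neighbourhood: near; far seed: not near
  near <- proximity_events(dimpled, er, threshold = 20,
                           seeds = seed_points(cbind(600, 500, 0)),
                           neighbourhood = 200)
  far <- proximity_events(dimpled, er, threshold = 20,
                          seeds = seed_points(cbind(5000, 500, 0)),
                          neighbourhood = 200)
  expect_true(near$near_caveola)
  expect_false(far$near_caveola)
})

test_that("two separated dimples give two events", {
  pm <- make_plane_mesh(n = 41, pitch = 50, z0 = 100)
  er <- make_plane_mesh(n = 41, pitch = 50, z0 = 0)
  v <- pm$vertices
  for (cx in c(400, 1600)) {
    r2 <- (v[, 1] - cx)^2 + (v[, 2] - 1000)^2
    v[, 3] <- v[, 3] - 85 * exp(-r2 / (2 * 60^2))
  }
  ev <- proximity_events(surface_mesh(v, pm$faces), er, threshold = 20)
  expect_equal(nrow(ev), 2)
})

test_that("MAM patches recover a constructed flat apposition facet", {
  # 100 x 100 nm mitochondrial facet hovering 5 nm over a wide ER sheet
  er <- make_plane_mesh(n = 21, pitch = 10, z0 = 0)
  mito <- make_plane_mesh(n = 11, pitch = 10, z0 = 5, origin = c(50, 50))
  mp <- mam_patches(mito, er, threshold = 20)
  expect_equal(nrow(mp$patches), 1)
  expect_lt(abs(mp$total_area_nm2 / 1e4 - 1), 0.10)
  # everything at 25 nm: no patches
  v <- er$vertices
  mito25 <- surface_mesh(cbind(v[, 1], v[, 2], 25), er$faces)
  expect_equal(mam_patches(mito25, er, threshold = 20)$total_area_nm2, 0)
  # empty ER is legal and gives no patches; empty mito is an error
  emp <- surface_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
  expect_equal(nrow(mam_patches(mito, emp)$patches), 0)
  expect_error(mam_patches(emp, er), "mitochondrial")
})

test_that("MAM area agrees with a direct per-face computation", {
  ph <- pdgfra_mam()
  mito <- mesh_from_labels(ph$volume, "MITO")
  er <- mesh_from_labels(ph$volume, "ER")
  mp <- mam_patches(mito, er, threshold = 20)
  # independent route: all-pairs vertex distances, then the same face rule
  d <- vapply(seq_len(nrow(mito$vertices)), function(i) {
    sqrt(min(colSums((t(er$vertices) - mito$vertices[i, ])^2)))
  }, numeric(1))
  f <- mito$faces
  areas <- microdomain3d:::face_areas(mito$vertices, f)
  frac <- vapply(seq_len(nrow(f)), function(fi) {
    microdomain3d:::subthreshold_area_fraction(d[f[fi, ]], 20)
  }, numeric(1))
  expect_equal(mp$total_area_nm2, sum(areas * frac), tolerance = 1e-9)
})

test_that("MAM area grows monotonically with the threshold", {
  er <- make_plane_mesh(n = 15, pitch = 20, z0 = 0)
  set.seed(7)
  v <- er$vertices
  mito <- surface_mesh(cbind(v[, 1], v[, 2], runif(nrow(v), 5, 45)), er$faces)
  areas <- vapply(seq(5, 50, by = 5), function(th) {
    mam_patches(mito, er, threshold = th)$total_area_nm2
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_equal(areas[length(areas)], mesh_area(mito), tolerance = 1e-9)
})
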