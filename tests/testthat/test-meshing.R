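test_that("isolated voxel meshes to the exact octahedron of its voxel cell", {
  a <- array(0L, c(5, 5, 5))
  a[3, 3, 3] <- 1L
  vol <- label_volume(a, voxel_spacing(20, 20, 20), c("1" = "ER"))
  m <- mesh_from_labels(vol, "ER")
  # level-0.5 crossings sit at half-spacing: the octahedron with semi-axes
  # (dx/2, dy/2, dz/2), volume dx*dy*dz/6 -- an isolated voxel is below the
  # mesher's support and keeps only a sixth of its voxel volume
  expect_true(is_watertight(m))
  expect_equal(mesh_enclosed_volume(m), 20 * 20 * 20 / 6, tolerance = 1e-12)
  expect_equal(mesh_area(m), 8 * sqrt(3) / 4 * (sqrt(2) * 10)^2,
               tolerance = 1e-12)
  expect_gt(mesh_area(m), 0)
})

test_that("empty masks give empty meshes and zero morphometry", {
  vol <- label_volume(array(0L, c(6, 6, 4)), voxel_spacing(10, 10, 20),
                      c("1" = "ER"))
  m <- mesh_from_labels(vol, "ER")
  expect_equal(nrow(m$vertices), 0)
  rec <- measure_morphometry(vol, "ER", mesh = m)
  expect_equal(rec$volume_nm3, 0)
  expect_equal(rec$surface_area_nm2, 0)
  expect_error(mesh_from_labels(vol, "MITO"), "role")
})

test_that("cuboid voxel volume is exact and its mesh volume close", {
  a <- array(0L, c(12, 12, 8))
  a[4:7, 2:6, 3:5] <- 1L # 4 x 5 x 3 voxels (j, i, k)
  vol <- label_volume(a, voxel_spacing(10, 10, 20), c("1" = "ER"))
  rec <- measure_morphometry(vol, "ER")
  expect_equal(rec$volume_nm3, 5 * 4 * 3 * 2000)
  # solid cube at isotropic spacing: enclosed mesh volume within 5%
  cube <- label_volume(array(1L, c(10, 10, 10)), voxel_spacing(10, 10, 10),
                       c("1" = "ER"))
  mc <- mesh_from_labels(cube, "ER")
  expect_lt(abs(mesh_enclosed_volume(mc) / 1e6 - 1), 0.05)
  expect_equal(measure_morphometry(cube, "ER", mesh = mc)$mesh_volume_nm3,
               mesh_enclosed_volume(mc))
})

test_that("digitized ball recovers analytic volume and area", {
  vol <- ball_volume(300, c(10, 10, 10))
  rec <- measure_morphometry(vol, "ER")
  v_true <- 4 / 3 * pi * 300^3
  a_true <- 4 * pi * 300^2
  expect_lt(abs(rec$volume_nm3 / v_true - 1), 0.05)
  expect_lt(abs(rec$surface_area_nm2 / a_true - 1), 0.10)
  expect_lt(abs(rec$mesh_volume_nm3 / v_true - 1), 0.05)
})

test_that("mesh area and volume errors shrink with voxel size", {
  v_true <- 4 / 3 * pi * 300^3
  a_true <- 4 * pi * 300^2
  err <- sapply(c(20, 10), function(h) {
    rec <- measure_morphometry(ball_volume(300, c(h, h, h)), "ER")
    c(vol = abs(rec$mesh_volume_nm3 / v_true - 1),
      area = abs(rec$surface_area_nm2 / a_true - 1))
  })
  expect_lt(err["vol", 2], err["vol", 1])
  expect_lt(err["area", 2], err["area", 1])
})

test_that("meshes are watertight and consistently oriented for varied masks", {
  masks <- list()
  a <- array(0L, c(14, 14, 10)); a[3:10, 3:12, 2:8] <- 1L
  masks$slab <- a
  b <- array(0L, c(14, 14, 10)); b[3:10, 3:12, 2:8] <- 1L; b[5:7, 5:9, 4:6] <- 0L
  masks$hollow <- b
  d <- array(0L, c(14, 14, 10)); d[2:5, 2:5, 2:4] <- 1L; d[9:13, 9:13, 6:9] <- 1L
  masks$two_blobs <- d
  for (nm in names(masks)) {
    vol <- label_volume(masks[[nm]], voxel_spacing(10, 10, 20), c("1" = "ER"))
    m <- mesh_from_labels(vol, "ER")
    expect_true(is_watertight(m), info = nm)
    ed <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
    expect_false(any(duplicated(paste(ed[, 1], ed[, 2]))), info = nm)
    # voxel-count volume is the oracle for the enclosed volume
    rec <- measure_morphometry(vol, "ER", mesh = m)
    expect_lt(abs(rec$mesh_volume_nm3 / rec$volume_nm3 - 1), 0.2, )
  }
})

test_that("surface_mesh drops degenerate faces and checks indices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  m <- surface_mesh(v, rbind(c(1, 2, 3), c(1, 1, 2)))
  expect_equal(nrow(m$faces), 1)
})
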