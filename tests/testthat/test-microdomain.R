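test_that("sphere ROI validates and reports the analytic volume", {
  roi <- sphere_roi(c(0, 0, 0), 400)
  expect_equal(sphere_volume(roi), 4 / 3 * pi * 400^3)
  expect_equal(sphere_volume(roi) / 1e8, 2.6808, tolerance = 1e-4)
  expect_error(sphere_roi(c(0, 0, 0), -1), "radius")
  p <- file.path(withr::local_tempdir(), "rois.csv")
  write_roi_csv(list(roi, sphere_roi(c(1, 2, 3), 200, "b")), p)
  back <- read_roi_csv(p)
  expect_length(back, 2)
  expect_equal(back[[2]]$radius, 200)
})

test_that("mesh cropping keeps, clips and drops triangles correctly", {
  roi <- sphere_roi(c(500, 500, 0), 400)
  # fine plane through the sphere centre: cropped disc area ~ pi r^2
  plane <- make_plane_mesh(n = 101, pitch = 10)
  disc <- crop_mesh(plane, roi)
  expect_lt(abs(mesh_area(disc) / (pi * 400^2) - 1), 0.05)
  # every cropped vertex lies inside the sphere (clip points on it)
  d <- sqrt(rowSums(sweep(disc$vertices, 2, roi$centre)^2))
  expect_true(all(d <= 400 + 1e-9))
  # mesh entirely inside: unchanged
  inner <- make_plane_mesh(n = 4, pitch = 20, origin = c(450, 450))
  expect_equal(crop_mesh(inner, roi)$vertices, inner$vertices,
               ignore_attr = TRUE)
  # mesh entirely outside: empty
  outer <- make_plane_mesh(n = 4, pitch = 20, origin = c(5000, 5000))
  expect_equal(nrow(crop_mesh(outer, roi)$faces), 0)
})

test_that("a large triangle grazing the ball is still clipped", {
  roi <- sphere_roi(c(0, 0, 0), 100)
  # huge triangle in the z = 50 plane, all vertices far outside
  tri <- surface_mesh(rbind(c(-5000, -5000, 50), c(5000, -5000, 50),
                            c(0, 8000, 50)),
                      rbind(c(1, 2, 3)))
  cropped <- crop_mesh(tri, roi)
  expect_gt(mesh_area(cropped), 0)
  # area bounded by the disc the plane cuts from the ball
  expect_lt(mesh_area(cropped), pi * (sqrt(100^2 - 50^2))^2 * 1.01)
})

test_that("voxel cropping matches the digitized-sphere oracle", {
  vol <- ball_volume(600, c(10, 10, 20), role = "ER")
  ext <- physical_extent(vol)
  roi <- sphere_roi(ext / 2, 400)
  cl <- crop_labels(vol, roi)
  expect_lt(abs(sum(cl$volume_nm3[cl$role == "ER"]) /
                (4 / 3 * pi * 400^3) - 1), 0.03)
  # empty volume: all zeros
  emp <- label_volume(array(0L, c(10, 10, 10)), voxel_spacing(50, 50, 50),
                      c("1" = "ER"))
  cle <- crop_labels(emp, sphere_roi(c(250, 250, 250), 100))
  expect_equal(sum(cle$volume_nm3), 0)
  expect_error(crop_labels(vol, sphere_roi(c(-10, 0, 0), 100)), "outside")
})

test_that("a shell wholly outside the radius contributes nothing", {
  # ER shell between 350 and 450 nm radius; crop at 300 -> zero
  n <- c(100, 100, 50)
  sp <- c(10, 10, 20)
  cen <- n * sp / 2
  x <- (seq_len(n[1]) - 0.5) * sp[1]
  y <- (seq_len(n[2]) - 0.5) * sp[2]
  z <- (seq_len(n[3]) - 0.5) * sp[3]
  d2 <- outer(outer((y - cen[2])^2, (x - cen[1])^2, "+"), (z - cen[3])^2, "+")
  a <- array(0L, c(n[2], n[1], n[3]))
  a[d2 > 350^2 & d2 <= 450^2] <- 1L
  vol <- label_volume(a, voxel_spacing(10, 10, 20), c("1" = "ER"))
  roi <- sphere_roi(cen, 300)
  expect_equal(sum(crop_labels(vol, roi)$volume_nm3), 0)
  expect_gt(sum(crop_labels(vol, sphere_roi(cen, 500))$volume_nm3), 0)
})

test_that("cropped ER volume is monotone in radius and crops nest", {
  ph <- icc_small()
  vol <- ph$volume
  s <- ph$ground_truth$caveola_centres
  cen <- c(s$x_nm[1], s$y_nm[1], s$z_nm[1])
  radii <- c(150, 250, 350, 450)
  vols <- sapply(radii, function(r) {
    cl <- crop_labels(vol, sphere_roi(cen, r))
    sum(cl$volume_nm3[cl$role == "ER"])
  })
  expect_true(all(diff(vols) >= 0))

  # nested-crop consistency: direct r1 metrics == r2 scene re-cropped to r1
  er_full <- mesh_from_labels(vol, "ER")
  roi1 <- sphere_roi(cen, 250)
  roi2 <- sphere_roi(cen, 400)
  direct <- crop_mesh(er_full, roi1)
  nested <- crop_mesh(crop_mesh(er_full, roi2), roi1)
  expect_equal(mesh_area(nested), mesh_area(direct), tolerance = 1e-8)
  # and the nested mesh stays within the inner radius
  dn <- sqrt(rowSums(sweep(nested$vertices, 2, cen)^2))
  expect_true(all(dn <= 250 + 1e-9))
})

test_that("mitochondrion presence uses the voxel-centre-in-sphere rule", {
  a <- array(0L, c(10, 60, 4))
  a[5, 1, 2] <- 11L # centre x = 5
  vol <- label_volume(a, voxel_spacing(10, 10, 20), c("11" = "MITO"))
  mk_scene <- function(dist) {
    crop_scene(vol, sphere_roi(c(5 + dist, 45, 30), 400), meshes = list())
  }
  expect_true(has_mitochondria(mk_scene(399)))
  expect_false(has_mitochondria(mk_scene(401)))
  b <- array(0L, c(10, 60, 4))
  volb <- label_volume(b, voxel_spacing(10, 10, 20), c("11" = "MITO"))
  expect_false(has_mitochondria(
    crop_scene(volb, sphere_roi(c(300, 45, 30), 400), meshes = list())))
})
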