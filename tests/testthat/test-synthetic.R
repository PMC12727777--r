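test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_phantom(phantom_spec("ICC", cell_radius = 600,
                                    caveola_count = 2, mito_count = 1,
                                    rng_seed = 21))
  b <- generate_phantom(phantom_spec("ICC", cell_radius = 600,
                                    caveola_count = 2, mito_count = 1,
                                    rng_seed = 21))
  expect_identical(a$volume$data, b$volume$data)
  expect_equal(a$ground_truth, b$ground_truth)
  c2 <- generate_phantom(phantom_spec("ICC", cell_radius = 600,
                                     caveola_count = 2, mito_count = 1,
                                     rng_seed = 22))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("unresolvable geometry is rejected", {
  expect_error(phantom_spec("ICC", er_pm_gap = 30), "not resolvable")
  expect_error(phantom_spec("ICC", er_thickness = 5), "below one voxel")
  expect_error(phantom_spec("ICC", cell_radius = 300), "too small")
  expect_warning(phantom_spec("ICC", mito_er_gap = 4), "quantized")
})

test_that("rasterised volumes match analytic ground truth", {
  for (ph in list(icc_small(), smc_small())) {
    vv <- voxel_volume_nm3(ph$volume$spacing)
    tv <- ph$ground_truth$true_volumes
    for (nm in names(tv)) {
      if (grepl(".", nm, fixed = TRUE)) {
        lab <- as.integer(sub(".*[.]", "", nm))
        n <- sum(ph$volume$data == lab)
      } else {
        labs <- as.integer(names(which(ph$volume$label_map == nm)))
        n <- sum(ph$volume$data %in% labs)
      }
      tol <- if (grepl("^CAVEOLA", nm)) 0.15 else 0.05
      expect_lt(abs(n * vv / tv[[nm]] - 1), tol,
                label = sprintf("%s rasterised/analytic volume error", nm))
    }
  }
})

test_that("caveola flask rasterisation improves at finer spacing", {
  err_of <- function(ph) {
    vv <- voxel_volume_nm3(ph$volume$spacing)
    tv <- ph$ground_truth$true_volumes
    nm <- grep("^CAVEOLA", names(tv), value = TRUE)[1]
    lab <- as.integer(sub(".*[.]", "", nm))
    abs(sum(ph$volume$data == lab) * vv / tv[[nm]] - 1)
  }
  coarse <- generate_phantom(phantom_spec("ICC", cell_radius = 600,
                                          caveola_count = 1, mito_count = 0,
                                          caveola_depth_jitter = 0,
                                          rng_seed = 3))
  fine <- generate_phantom(phantom_spec("ICC", spacing = voxel_spacing(5, 5, 10),
                                        cell_radius = 600, caveola_count = 1,
                                        mito_count = 0,
                                        caveola_depth_jitter = 0,
                                        rng_seed = 3))
  expect_lt(err_of(fine), err_of(coarse))
})

test_that("archetype ER topology matches its ground truth", {
  # ICC: one connected ER component (shell + sheets attached to it)
  icc <- icc_small()
  erm <- mask_for_role(icc$volume, "ER")
  cc <- microdomain3d:::.label_components_6(as.logical(erm), dim(erm))
  expect_equal(max(cc), icc$ground_truth$n_er_components)
  # SMC: peripheral strands pairwise disconnected + perinuclear component
  smc <- smc_small()
  erm <- mask_for_role(smc$volume, "ER")
  cc <- microdomain3d:::.label_components_6(as.logical(erm), dim(erm))
  expect_equal(max(cc), smc$ground_truth$n_er_components)
  expect_equal(smc$ground_truth$n_peripheral_strands + 1L,
               smc$ground_truth$n_er_components)
})

test_that("caveola centroids extracted from voxels match analytic centres", {
  ph <- icc_small()
  gt <- ph$ground_truth$caveola_centres
  got <- caveola_centroids(ph$volume)
  expect_equal(nrow(got), nrow(gt))
  got <- got[match(gt$caveola_label, got$caveola_label), ]
  d <- sqrt((got$x_nm - gt$x_nm)^2 + (got$y_nm - gt$y_nm)^2 +
            (got$z_nm - gt$z_nm)^2)
  # voxel centroid vs analytic bulb centre: within ~one voxel diagonal plus
  # the neck's outward pull
  expect_true(all(d < 35))
})

test_that("the study-scale scene exercises the omission logic by design", {
  ph <- cached("study_scene", generate_study_scale_scene(rng_seed = 11))
  gt <- ph$ground_truth
  expect_gte(nrow(gt$caveola_centres), 9)
  expect_true(length(gt$mito_under_caveola) >= 1)
  expect_true(length(gt$mito_under_caveola) < nrow(gt$caveola_centres))
  # per-sphere analytic ER volumes inside the stated generator band
  expect_true(all(gt$per_sphere_er_volume_nm3 > 5e6))
  expect_true(all(gt$per_sphere_er_volume_nm3 < 2.5e7))
  # rasterised per-sphere ER volume tracks the analytic lens values
  seeds <- gt$caveola_centres
  for (m in c(1, 5, 9)) {
    roi <- sphere_roi(c(seeds$x_nm[m], seeds$y_nm[m], seeds$z_nm[m]), 400)
    cl <- crop_labels(ph$volume, roi)
    got <- sum(cl$volume_nm3[cl$role == "ER"])
    expect_lt(abs(got / gt$per_sphere_er_volume_nm3[m] - 1), 0.08)
  }
})

test_that("constructed MAM facets carry their analytic area in ground truth", {
  ph <- pdgfra_mam()
  expect_equal(unname(ph$ground_truth$true_mam_area_per_mito), 300 * 200)
  far <- generate_phantom(phantom_spec("PDGFRA", cell_radius = 700,
                                       caveola_count = 1, mito_count = 1,
                                       mito_er_gap = 30, rng_seed = 3))
  expect_equal(unname(far$ground_truth$true_mam_area_per_mito), 0)
})
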