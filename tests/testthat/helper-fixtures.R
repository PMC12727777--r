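# shared fixtures and independent oracles for the suite

# O(n * m) brute-force ASD oracle (all-pairs distances, no spatial index)
brute_asd <- function(pm, er) {
  q <- pm$vertices
  t <- er$vertices
  d <- vapply(seq_len(nrow(q)), function(i) {
    sqrt(min(colSums((t(t) - q[i, ])^2)))
  }, numeric(1))
  list(per_vertex_nm = d, asd_nm = mean(d))
}

# regular triangulated grid in the z = z0 plane: n x n vertices, pitch nm
make_plane_mesh <- function(n = 11, pitch = 100, z0 = 0, origin = c(0, 0)) {
  g <- expand.grid(x = origin[1] + (0:(n - 1)) * pitch,
                   y = origin[2] + (0:(n - 1)) * pitch)
  v <- cbind(g$x, g$y, z0)
  idx <- function(i, j) (j - 1) * n + i
  f <- list()
  for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  surface_mesh(v, do.call(rbind, f))
}

# random vertex cloud with random (non-degenerate) faces
rand_mesh <- function(n = 200, seed = 1, scale = 500, shift = c(0, 0, 0)) {
  set.seed(seed)
  v <- matrix(runif(3 * n, 0, scale), ncol = 3)
  v <- sweep(v, 2, shift, "+")
  f <- matrix(sample.int(n, 3 * (2 * n), replace = TRUE), ncol = 3)
  f <- f[f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3], , drop = FALSE]
  surface_mesh(v, f)
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m))
}

# digitized ball mask, voxel-centre rule, centred in its array
ball_volume <- function(r, sp, role = "ER", pad = 2) {
  n <- ceiling(2 * (r + pad * sp) / sp)
  cen <- n * sp / 2
  x <- (seq_len(n[1]) - 0.5) * sp[1]
  y <- (seq_len(n[2]) - 0.5) * sp[2]
  z <- (seq_len(n[3]) - 0.5) * sp[3]
  d2 <- outer(outer((y - cen[2])^2, (x - cen[1])^2, "+"), (z - cen[3])^2, "+")
  data <- array(0L, c(n[2], n[1], n[3]))
  data[d2 <= r^2] <- 1L
  label_volume(data, voxel_spacing(sp[1], sp[2], sp[3]),
               stats::setNames(role, "1"))
}

# cached phantoms so expensive scenes build once per test run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

icc_small <- function() cached("icc_small", {
  generate_phantom(phantom_spec("ICC", cell_radius = 800, caveola_count = 3,
                                mito_count = 1, rng_seed = 7))
})

icc_small_analysis <- function() cached("icc_small_analysis", {
  analyze_microdomains(icc_small()$volume, n_spheres = 3, rng_seed = 7)
})

icc_fine <- function() cached("icc_fine", {
  generate_phantom(phantom_spec("ICC", spacing = voxel_spacing(5, 5, 10),
                                cell_radius = 600, caveola_count = 2,
                                mito_count = 0, rng_seed = 7))
})

smc_small <- function() cached("smc_small", {
  generate_phantom(phantom_spec("SMC", cell_radius = 1000, caveola_count = 3,
                                rng_seed = 5))
})

pdgfra_mam <- function() cached("pdgfra_mam", {
  generate_phantom(phantom_spec("PDGFRA", spacing = voxel_spacing(5, 5, 10),
                                cell_radius = 700, caveola_count = 1,
                                mito_count = 1, mito_er_gap = 10,
                                mito_facet = c(300, 200), rng_seed = 3))
})
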