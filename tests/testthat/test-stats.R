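test_that("CV reproduces the printed ER-PM worked example", {
  # n = 3 values constructed to have mean 107.0 and sample SD 20.41 exactly
  values <- 107.0 + 20.41 * c(-1, 0, 1)
  s <- summarize_metric(values)
  expect_equal(s$mean, 107.0)
  expect_equal(s$sd, 20.41)
  expect_equal(round(s$cv, 2), 0.19)
})

test_that("degenerate inputs are handled explicitly", {
  s <- summarize_metric(c(5, 5, 5))
  expect_equal(s$sd, 0)
  expect_equal(s$cv, 0)
  s1 <- summarize_metric(42)
  expect_true(is.na(s1$sd) && is.na(s1$cv))
  s0 <- summarize_metric(c(-1, 1))
  expect_true(is.na(s0$cv)) # zero mean
  expect_error(summarize_metric(c(1, 2), "mam_positive_only",
                                mam_positive = c(FALSE, FALSE)),
               "mam_positive_only")
})

test_that("the MAM-positive-only rule filters before any statistic", {
  s <- summarize_metric(c(1, 2, 3, 4), "mam_positive_only",
                        mam_positive = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(s$n, 3)
  expect_equal(s$mean, 8 / 3)
  expect_equal(s$median, 3)
})

test_that("summaries match a brute-force reference on random inputs", {
  ref <- function(x) {
    n <- length(x)
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / (n - 1))
    xs <- sort(x)
    med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    list(mean = m, sd = s, med = med, cv = s / m)
  }
  set.seed(99)
  for (rep in 1:10) {
    x <- rnorm(sample(3:40, 1), mean = 50, sd = 12)
    s <- summarize_metric(x)
    r <- ref(x)
    expect_equal(s$mean, r$mean, tolerance = 1e-12)
    expect_equal(s$sd, r$sd, tolerance = 1e-12)
    expect_equal(s$median, r$med, tolerance = 1e-12)
    expect_equal(s$cv, r$cv, tolerance = 1e-12)
    expect_true(s$median >= min(x) && s$median <= max(x))
  }
})

test_that("CV is scale invariant and the population switch works", {
  set.seed(5)
  x <- runif(12, 10, 100)
  for (k in c(0.01, 1, 250)) {
    expect_equal(summarize_metric(k * x)$cv, summarize_metric(x)$cv,
                 tolerance = 1e-12)
  }
  sp <- summarize_metric(x, sd_type = "population")
  expect_equal(sp$sd, sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  expect_lt(sp$sd, summarize_metric(x)$sd)
})

test_that("reports apply the omission rule and rerun byte-identically", {
  per <- data.frame(
    sphere_id = 1:9,
    asd_nm = seq(90, 130, length.out = 9),
    n_pm_vertices = rep(1000L, 9),
    er_volume_nm3 = seq(8e6, 18e6, length.out = 9),
    has_mito = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    mam_area_total_nm2 = c(5e4, 6e4, NA, 4e4, NA, 8e4, NA, 3e4, NA),
    n_proximity_events = rep(0L, 9))
  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  report_microdomains(per, d1, provenance = list(radius = 400, seed = 1))
  report_microdomains(per, d2, provenance = list(radius = 400, seed = 1))
  sum1 <- read.csv(file.path(d1, "summary.csv"))
  expect_equal(sum1$n[sum1$metric == "mam_area_nm2"], 5)
  expect_equal(sum1$n[sum1$metric == "asd_nm"], 9)
  expect_equal(sum1$n[sum1$metric == "er_volume_nm3"], 9)
  expect_equal(sum1$inclusion_rule[sum1$metric == "mam_area_nm2"],
               "mam_positive_only")
  for (f in c("per_sphere.csv", "summary.csv", "provenance.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # single-sphere report: sd and cv are empty, not fabricated
  one <- report_microdomains(per[1, ], file.path(d1, "one"))
  s1 <- read.csv(file.path(d1, "one", "summary.csv"))
  expect_true(all(is.na(s1$sd)))
})
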