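test_that("discretization follows the equal-width floor rule", {
  expect_equal(discretize(c(0, 100), 2), c(1L, 2L))
  expect_equal(discretize(rep(5, 10), 8), rep(1L, 10))
  set.seed(5)
  x <- rnorm(100, sd = 300)
  n_bins <- 8L
  got <- discretize(x, n_bins)
  # independent floor-formula oracle, max clamped to the top bin
  rng <- range(x)
  want <- pmin(floor(n_bins * (x - rng[1]) / (rng[2] - rng[1])) + 1, n_bins)
  expect_equal(got, as.integer(want))
  expect_true(all(got >= 1 & got <= n_bins))
})

test_that("volume and mass follow the HU-density calibration", {
  v <- image_volume(array(0, c(10, 10, 10)))
  m <- roi_mask(array(1, c(10, 10, 10)), v)
  g <- global_features(v, m)
  expect_equal(g$volume_ml, 1.0)        # 1000 voxels of 1 mm3
  expect_equal(g$mass_g, 1.0)           # 0 HU = water = 1 g/cm3

  set.seed(9)
  v2 <- image_volume(array(rnorm(1000, -100, 400), c(10, 10, 10)),
                     spacing = c(0.5, 0.5, 2))
  g2 <- global_features(v2, m2 <- roi_mask(array(1, c(10, 10, 10)), v2))
  # per-voxel summation oracle
  vox_ml <- 0.5 * 0.5 * 2 / 1000
  mass <- sum(pmax((as.vector(v2$data) + 1000) / 1000, 0)) * vox_ml
  expect_equal(g2$mass_g, mass)
  expect_equal(g2$volume_ml, 1000 * vox_ml)
})

test_that("histogram statistics match direct-formula oracles", {
  h <- histogram_features(c(0, 0, 100, 100))
  expect_equal(h$energy, 0.5)
  expect_equal(h$range, 100)
  expect_equal(h$p50, 50)

  hc <- histogram_features(rep(7, 20))
  expect_equal(hc$energy, 1)
  expect_equal(hc$range, 0)
  expect_equal(hc$iqr, 0)
  expect_equal(hc$entropy, 0)
  expect_true(is.na(hc$kurtosis) && is.na(hc$skewness))

  set.seed(21)
  x <- rnorm(500, 30, 150)
  h2 <- histogram_features(x)
  o <- brute_histogram_stats(x)
  expect_equal(h2$mean, o$mean)
  expect_equal(h2$sd, sqrt(o$m2 * 500 / 499))
  expect_equal(h2$skewness, o$skewness)
  expect_equal(h2$kurtosis, o$kurtosis)
  expect_equal(h2$range, max(x) - min(x))
  expect_equal(h2$p25, quantile(x, 0.25, names = FALSE))
  expect_equal(h2$iqr, unname(diff(quantile(x, c(0.25, 0.75)))))
  # energy/entropy from an explicitly tabulated histogram
  p <- as.vector(table(discretize(x, 32))) / 500
  expect_equal(h2$energy, sum(p^2))
  expect_equal(h2$entropy, -sum(p * log2(p)))
})

test_that("histogram features are invariant to voxel ordering", {
  set.seed(3)
  x <- rnorm(200)
  expect_equal(histogram_features(x), histogram_features(sample(x)))
})

test_that("entropy is zero iff energy is one iff the ROI is constant", {
  set.seed(8)
  for (x in list(rep(3, 12), rnorm(50), runif(30, -900, 100))) {
    h <- histogram_features(x)
    is_const <- length(unique(x)) == 1
    expect_equal(h$entropy == 0, is_const)
    expect_equal(h$energy == 1, is_const)
  }
})

test_that("MPP averages strictly positive voxels and is missing otherwise", {
  expect_equal(mpp(c(-100, 50, 150)), 100)
  expect_true(is.na(mpp(c(-5, 0, -800))))
  set.seed(13)
  x <- rnorm(300, 0, 50)
  expect_equal(mpp(x), mean(x[x > 0]))
  lcs <- lung_cancer_specific_features(c(-10, -20, -1000))
  expect_true(is.na(lcs$mpp))
  expect_equal(lcs$positive_pixel_fraction, 0)
})
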