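# closed form for any cube: A = 6 s^2, V = s^3, so spherical disproportion
# = 6 s^2 / (4 pi (3 s^3 / 4 pi)^(2/3)) is scale-free
cube_spherical_disproportion <- function() {
  6 / (4 * pi * (3 / (4 * pi))^(2 / 3))
}

test_that("single voxel and cube match closed-form surface and disproportion", {
  m1 <- make_box_mask(c(5, 5, 5), c(3, 3, 3), c(3, 3, 3))
  s1 <- shape_features(m1)
  expect_equal(s1$surface_area_mm2, 6)
  expect_equal(s1$max_3d_diameter_mm, 0)
  expect_equal(s1$spherical_disproportion, cube_spherical_disproportion(),
               tolerance = 1e-12)

  m10 <- make_box_mask(c(14, 14, 14), c(3, 3, 3), c(12, 12, 12))
  s10 <- shape_features(m10)
  expect_equal(s10$surface_area_mm2, 600)
  expect_equal(s10$spherical_disproportion, cube_spherical_disproportion(),
               tolerance = 1e-12)
  expect_equal(s10$sphericity * s10$spherical_disproportion, 1)
  expect_equal(s10$surface_to_volume, 600 / 1000)
})

test_that("max 3D diameter is the Euclidean span of voxel centres", {
  d <- c(6, 6, 6)
  m <- array(0L, d); m[1, 1, 1] <- 1L; m[4, 5, 1] <- 1L  # 3-4-5 triangle
  v <- image_volume(array(0, d))
  s <- shape_features(roi_mask(m, v))
  expect_equal(s$max_3d_diameter_mm, 5)
})

test_that("shape features are translation invariant", {
  s_a <- shape_features(make_box_mask(c(12, 12, 12), c(2, 2, 2), c(5, 6, 7)))
  s_b <- shape_features(make_box_mask(c(12, 12, 12), c(5, 4, 3), c(8, 8, 8)))
  expect_equal(s_a, s_b)
})

test_that("spacing scales volume as k^3, area as k^2, diameter as k", {
  d <- c(10, 10, 10)
  base <- array(0L, d); base[3:7, 3:6, 3:5] <- 1L
  v1 <- image_volume(array(0, d), spacing = c(1, 1, 1))
  v2 <- image_volume(array(0, d), spacing = c(2, 2, 2))
  s1 <- shape_features(roi_mask(base, v1))
  s2 <- shape_features(roi_mask(base, v2))
  g1 <- global_features(v1, roi_mask(base, v1))
  g2 <- global_features(v2, roi_mask(base, v2))
  expect_equal(g2$volume_ml, 8 * g1$volume_ml)
  expect_equal(s2$surface_area_mm2, 4 * s1$surface_area_mm2)
  expect_equal(s2$max_3d_diameter_mm, 2 * s1$max_3d_diameter_mm)
  expect_equal(s2$spherical_disproportion, s1$spherical_disproportion)
  expect_equal(s2$sphericity, s1$sphericity)
})

test_that("digitized ball volume converges to (4/3) pi r^3 and the
           face-count disproportion stabilizes", {
  disp <- numeric(0)
  for (r in c(8, 12, 16, 20)) {
    d <- rep(2 * r + 5, 3)
    ctr <- (d - 1) / 2
    co <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
    inside <- ((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2) <= r^2
    m <- array(as.integer(inside), d)
    v <- image_volume(array(0, d))
    msk <- roi_mask(m, v)
    g <- global_features(v, msk)
    if (r == 20)
      expect_lt(abs(g$volume_ml * 1000 - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
                0.05)
    disp <- c(disp, shape_features(msk)$spherical_disproportion)
  }
  # staircase limit: successive values stabilize
  expect_lt(abs(disp[4] - disp[3]), abs(disp[2] - disp[1]) + 0.05)
  expect_lt(diff(range(disp)), 0.2)
})
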