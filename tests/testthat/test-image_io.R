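test_that("NIfTI round trip preserves values exactly and spacing to 1e-6 mm", {
  set.seed(11)
  v <- image_volume(array(rnorm(10 * 10 * 10, sd = 200), c(10, 10, 10)),
                    spacing = c(0.7, 0.7, 2.5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$data, v$data, tolerance = 0)
  expect_lt(max(abs(r$spacing - c(0.7, 0.7, 2.5))), 1e-6)
  expect_equal(prod(dim(r$data)), 1000)
})

test_that("degenerate volumes are rejected with explicit messages", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(2, 2, 2, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "expected 3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  expect_error(image_volume(array(c(NA, rep(0, 7)), c(2, 2, 2))), "finite")
  expect_error(image_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("masks binarize, validate geometry and reject spacing mismatch", {
  v <- image_volume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
  m255 <- array(0, c(10, 10, 10)); m255[1:5, 1, 1] <- 255
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(m255); RNifti::pixdim(img) <- c(1, 1, 1)
  RNifti::writeNifti(img, f)
  mk <- read_mask(f, v)
  expect_setequal(unique(as.vector(mk$data)), c(0L, 1L))
  expect_equal(sum(mk$data), 5)

  # wrong shape
  img9 <- RNifti::asNifti(array(1, c(10, 10, 9)))
  f9 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img9, f9)
  expect_error(read_mask(f9, v), "shape")

  # wrong spacing beyond tolerance
  imgsp <- RNifti::asNifti(m255); RNifti::pixdim(imgsp) <- c(1.001, 1, 1)
  fsp <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(imgsp, fsp)
  expect_error(read_mask(fsp, v), "spacing")
})

test_that("roi_voxels enumerates exactly the foreground in lexicographic order", {
  v <- image_volume(array(seq_len(125), c(5, 5, 5)))
  m <- array(0, c(5, 5, 5)); m[2, 3, 4] <- 1
  v$data[2, 3, 4] <- -50
  vox <- roi_voxels(v, roi_mask(m, v))
  expect_equal(nrow(vox), 1)
  expect_equal(unlist(vox[1, ]), c(i = 2, j = 3, k = 4, hu = -50))

  m2 <- array(0, c(5, 5, 5)); m2[1:2, 1:2, 1:2] <- 1
  vox2 <- roi_voxels(v, roi_mask(m2, v))
  expect_equal(nrow(vox2), 8)
  # lexicographic over (i, j, k)
  key <- vox2$i * 100 + vox2$j * 10 + vox2$k
  expect_equal(key, sort(key))

  expect_error(roi_voxels(v, roi_mask(array(0, c(5, 5, 5)), v)), "empty ROI")
})

test_that("roi_voxels order equals nested-loop enumeration on random masks", {
  set.seed(42)
  for (rep in 1:5) {
    d <- c(6, 6, 6)
    v <- image_volume(array(rnorm(prod(d)), d))
    m <- array(rbinom(prod(d), 1, 0.4), d)
    if (sum(m) == 0) m[1, 1, 1] <- 1
    vox <- roi_voxels(v, roi_mask(m, v))
    expect_equal(nrow(vox), sum(m))
    # brute-force enumeration, i outermost then j then k
    oracle <- list()
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      if (m[i, j, k] == 1)
        oracle[[length(oracle) + 1]] <- c(i, j, k, v$data[i, j, k])
    oracle <- do.call(rbind, oracle)
    expect_equal(unname(as.matrix(vox)), unname(oracle))
  }
})
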