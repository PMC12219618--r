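# Box-counting and fractal-dimension estimation.

test_that("box_count matches closed forms and the brute-force enumerator", {
  # one voxel: a single occupied box at every scale
  m <- array(FALSE, c(8, 8, 8)); m[3, 4, 5] <- TRUE
  expect_equal(box_count(m, c(4, 2, 1))$counts, c(1L, 1L, 1L))

  # solid cube: N(s) = (8/s)^3 exactly
  cube <- make_shape("solid_cube", 8)
  expect_equal(box_count(cube, c(8, 4, 2, 1))$counts, c(1L, 8L, 64L, 512L))

  # random blobs: equal to explicit box enumeration
  for (seed in 1:4) {
    arr <- random_blob(seed = seed)
    sizes <- default_sizes(arr)
    expect_equal(box_count(arr, sizes)$counts, brute_box_count(arr, sizes))
  }
})

test_that("box_count validates its inputs", {
  m <- array(FALSE, c(6, 6, 6))
  expect_error(box_count(m, c(2, 1)), "empty")
  m[2, 2, 2] <- TRUE
  expect_error(box_count(m, c(1, 2)), "strictly decreasing")
  expect_error(box_count(m, c(7, 2, 1)), "7")
})

test_that("Menger sponge occupancy and counts follow the recursion", {
  sp2 <- make_shape("menger_sponge", 9, level = 2)
  expect_identical(sp2$data, brute_menger(2))
  expect_equal(sum(sp2$data), 400L)
  expect_equal(box_count(sp2, c(9, 3, 1))$counts, c(1L, 20L, 400L))

  sp3 <- make_shape("menger_sponge", 27, level = 3)
  expect_equal(box_count(sp3, c(27, 9, 3, 1))$counts, 20L^(0:3))
  fd3 <- fit_fd(box_count(sp3, c(27, 9, 3, 1)))
  expect_lt(abs(fd3$fd - log(20) / log(3)), 0.05)
})

test_that("default_sizes floor-halves from the bounding box", {
  arr <- array(FALSE, c(70, 90, 70)); arr[1:64, 1:80, 1:64] <- TRUE
  expect_equal(default_sizes(arr), c(64L, 32L, 16L, 8L, 4L, 2L, 1L))
  arr2 <- array(FALSE, c(12, 12, 12)); arr2[1:9, 1:12, 1:10] <- TRUE
  expect_equal(default_sizes(arr2), c(9L, 4L, 2L, 1L))
  arr3 <- array(TRUE, c(3, 3, 3))
  expect_error(default_sizes(arr3), "pad or reject")
})

test_that("fit_fd recovers exact power laws with perfect fits", {
  pl <- make_shape("plane", 16)
  f2 <- fit_fd(box_count(pl, c(8, 4, 2, 1)))
  expect_equal(f2$fd, 2, tolerance = 1e-12)
  expect_gt(f2$fit_r2, 1 - 1e-9)

  ln <- make_shape("line", 16)
  f1 <- fit_fd(box_count(ln, c(8, 4, 2, 1)))
  expect_equal(f1$fd, 1, tolerance = 1e-12)

  cube <- make_shape("solid_cube", 8)
  f3 <- fit_fd(box_count(cube, c(8, 4, 2, 1)))
  expect_equal(f3$fd, 3, tolerance = 1e-12)
  expect_gt(f3$fit_r2, 1 - 1e-9)

  expect_error(fit_fd(fractaldbs:::new_box_count_curve(c(3, 2), c(2, 4))),
               ">= 3")
})

test_that("region_fd is translation-invariant and mode-sensitive", {
  cube <- make_shape("solid_cube", 32)
  v1 <- embed_mask(cube, c(64, 64, 64), c(5, 5, 5))
  v2 <- embed_mask(cube, c(64, 64, 64), c(10, 8, 12))
  r1 <- region_fd(v1, 1); r2 <- region_fd(v2, 1)
  expect_identical(r1$curve$counts, r2$curve$counts)
  expect_identical(r1$fd, r2$fd)
  expect_equal(r1$fd, 3, tolerance = 0.1)

  rb <- region_fd(v1, 1, mode = "boundary")
  expect_lt(rb$fd, r1$fd)   # a shell is strictly simpler than the bulk
  expect_gt(rb$fd, 2)       # but coarse scales see a 3D envelope

  expect_error(region_fd(v1, 7), "available labels")
})

test_that("counts never decrease along the halving schedule", {
  for (seed in 1:10) {
    arr <- random_blob(grid = 20, n_balls = 4, seed = 100 + seed)
    bc <- box_count(arr, default_sizes(arr))
    expect_true(all(diff(bc$counts) >= 0))
    expect_true(all(bc$counts >= 1))
  }
})

test_that("boundary-mode fd of a perturbed sphere grows with amplitude", {
  mean_fd <- vapply(c(0.1, 0.3, 0.5), function(A) {
    mean(vapply(1:10, function(s) {
      sp <- make_shape("sphere", 48, perturbation_amplitude = A, seed = s)
      b <- fractaldbs:::boundary_voxels(sp$data)
      fit_fd(box_count(b, c(16, 8, 4, 2, 1)), "boundary")$fd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fd) >= 0))
})

test_that("extract_cohort_fd builds, logs degenerate regions, round-trips", {
  cube <- make_shape("solid_cube", 16)
  mk <- function(extra_degenerate = FALSE) {
    vol <- array(0L, c(40, 40, 40))
    vol[2:17, 2:17, 2:17] <- 1L
    vol[20:35, 20:35, 2:17] <- 2L
    vol[2:17, 20:35, 20:35] <- 3L
    if (extra_degenerate) vol[39, 39, 39] <- 4L  # 1-voxel region
    label_volume(vol)
  }
  tab <- extract_cohort_fd(list(s1 = mk(), s2 = mk()))
  expect_equal(nrow(tab), 6L)
  expect_true(all(is.finite(tab$fd)))

  expect_message(tab2 <- extract_cohort_fd(list(s1 = mk(TRUE))), "skipped")
  expect_equal(sum(is.finite(tab2$fd)), 3L)
  expect_equal(nrow(attr(tab2, "missing")), 1L)

  expect_error(extract_cohort_fd(stats::setNames(list(mk(), mk()), c("a", "a"))),
               "duplicate")

  path <- tempfile(fileext = ".tsv")
  write_fd_table(tab, path)
  expect_equal(read_fd_table(path)$fd, tab$fd)
})

test_that("NIfTI round trip preserves labels and spacing", {
  vol <- embed_mask(make_shape("solid_cube", 8), c(20, 20, 20), c(3, 3, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_identical(back$data, vol$data)
  expect_equal(back$spacing, vol$spacing)
})

test_that("anisotropic volumes warn and can be resampled", {
  vol <- label_volume(array(1L, c(10, 10, 10)), spacing = c(0.5, 0.5, 1.0))
  expect_warning(region_fd(vol, 1), "anisotropy")
  iso <- resample_isotropic(vol)
  expect_equal(iso$spacing, rep(0.5, 3))
  expect_equal(dim(iso$data), c(10L, 10L, 20L))
})
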