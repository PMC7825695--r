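make_textured_volume <- function(dims = c(32, 32, 16), spacing = c(2, 2, 2),
                                 mean = 100, sd = 15, seed = 1) {
  set.seed(seed)
  image_volume(array(stats::rnorm(prod(dims), mean, sd), dim = dims), spacing)
}

test_that("bias correction leaves a constant volume constant and preserves the mean", {
  v <- image_volume(array(42, dim = c(16, 16, 8)), c(2, 2, 2))
  out <- correct_bias_field(v)
  expect_equal(out$voxels, v$voxels, tolerance = 1e-10)

  tex <- make_textured_volume(seed = 3)
  m <- roi_mask(array(as.integer(seq_len(prod(dim(tex$voxels))) %% 3 == 0),
    dim = dim(tex$voxels)
  ), tex$spacing)
  out2 <- correct_bias_field(tex, mask = m)
  rel <- abs(mean(out2$voxels[m$voxels == 1]) - mean(tex$voxels[m$voxels == 1])) /
    mean(tex$voxels[m$voxels == 1])
  expect_lt(rel, 1e-9)
})

test_that("smooth-divide removes a known long-wavelength multiplicative field", {
  clean <- make_textured_volume(dims = c(48, 48, 24), spacing = c(2, 2, 2), seed = 11)
  d <- dim(clean$voxels)
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * clean$spacing[ax])
  # amplitude 0.3, wavelengths a few times the field-of-view
  f <- 1 + 0.3 * outer(
    outer(sin(2 * pi * co[[1]] / 240), cos(2 * pi * co[[2]] / 280), "+"),
    sin(2 * pi * co[[3]] / 200), "+"
  ) / 3
  biased <- image_volume(clean$voxels * f, clean$spacing)
  out <- correct_bias_field(biased, sigma_mm = 25)
  corr_in <- stats::cor(as.vector(biased$voxels / clean$voxels), as.vector(f))
  corr_out <- stats::cor(as.vector(out$voxels / clean$voxels), as.vector(f))
  expect_gt(corr_in, 0.9)
  expect_lt(abs(corr_out), 0.2)
})

test_that("bias correction refuses non-positive intensities", {
  v <- image_volume(array(c(-1, rep(1, 127)), dim = c(8, 4, 4)))
  expect_error(correct_bias_field(v), "positive")
})

test_that("histogram matching is the identity on itself and maps quantiles to the reference", {
  v <- make_textured_volume(seed = 21)
  self <- match_histogram(v, v)
  expect_lt(
    max(abs(self$voxels - v$voxels)) / diff(range(v$voxels)), 1e-6
  )

  ref <- make_textured_volume(mean = 300, sd = 40, seed = 22)
  out <- match_histogram(v, ref, n_landmarks = 64)
  probs <- seq(0, 1, length.out = 64)
  expect_equal(
    unname(stats::quantile(out$voxels, probs, type = 7)),
    unname(stats::quantile(ref$voxels, probs, type = 7)),
    tolerance = 0.02
  )
  # monotone: intensity ordering preserved
  o <- order(v$voxels)
  expect_true(!is.unsorted(out$voxels[o]))
})

test_that("a two-landmark map recovers the inverse affine transform", {
  ref <- make_textured_volume(seed = 31)
  shifted <- image_volume(2.5 * ref$voxels + 17, ref$spacing)
  out <- match_histogram(shifted, ref, n_landmarks = 2)
  expect_equal(out$voxels, ref$voxels, tolerance = 1e-9)
})

test_that("histogram matching rejects a constant reference", {
  v <- make_textured_volume()
  flat <- image_volume(array(1, dim = c(8, 8, 4)))
  expect_error(match_histogram(v, flat), "constant")
})

test_that("resampling to the native spacing is the identity", {
  v <- make_textured_volume(dims = c(20, 16, 12), spacing = c(1.5, 1.5, 3), seed = 41)
  m <- roi_mask(array(1L, dim = dim(v$voxels)), v$spacing)
  rs <- resample_volume(v, m, c(1.5, 1.5, 3))
  expect_equal(rs$volume$voxels, v$voxels, tolerance = 1e-9)
  expect_identical(rs$mask$voxels, m$voxels)
})

test_that("resampling reproduces constants and linear ramps exactly", {
  const <- image_volume(array(7, dim = c(16, 16, 8)), c(1, 1, 1))
  m <- roi_mask(array(1L, dim = c(16, 16, 8)), c(1, 1, 1))
  rs <- resample_volume(const, m, c(2, 2, 2))
  expect_equal(max(abs(rs$volume$voxels - 7)), 0, tolerance = 1e-9)
  expect_true(all(rs$mask$voxels %in% c(0L, 1L)))

  # linear ramp along x at 1 mm, resampled to 2 mm: cubic B-splines
  # reproduce linear functions, so interior values match the analytic ramp
  d <- c(21, 8, 8)
  ramp <- image_volume(
    array(rep((0:20) * 3 + 5, times = 64), dim = d), c(1, 1, 1)
  )
  m2 <- roi_mask(array(1L, dim = d), c(1, 1, 1))
  rs2 <- resample_volume(ramp, m2, c(2, 1, 1))
  got <- rs2$volume$voxels[2:10, 4, 4]
  want <- ((2:10 - 1) * 2) * 3 + 5
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("resampling errors when the mask vanishes", {
  v <- make_textured_volume(dims = c(12, 12, 6), spacing = c(1, 1, 1))
  mv <- array(0L, dim = c(12, 12, 6))
  mv[2, 2, 2] <- 1L
  m <- roi_mask(mv, c(1, 1, 1))
  expect_error(resample_volume(v, m, c(8, 8, 8)), "vanish")
})
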