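test_that("intensity normalization maps the clip window onto [-1, 1]", {
  cl <- intensity_domain("clinical")
  mi <- intensity_domain("micro")
  expect_equal(cl$clip_low, -1000)
  expect_equal(cl$clip_high, 2500)
  expect_equal(mi$clip_low, 0)
  expect_equal(mi$clip_high, 15000)
  # endpoints, clipping, and the interval midpoints
  expect_equal(normalize_intensity(2500, cl), 1.0)
  expect_equal(normalize_intensity(-1500, cl), -1.0)  # clipped to -1000 first
  expect_equal(normalize_intensity(750, cl), 2 * (750 + 1000) / 3500 - 1)
  expect_equal(normalize_intensity(750, cl), 0.0)
  expect_equal(normalize_intensity(7500, mi), 2 * 7500 / 15000 - 1)
  expect_error(normalize_intensity(c(1, NaN), cl), "index 2")
  expect_error(intensity_domain("clinical", clip_low = 5, clip_high = 5))
})

test_that("denormalization inverts normalization exactly on the clipped range", {
  for (dn in c("clinical", "micro")) {
    d <- intensity_domain(dn)
    grid <- seq(-1, 1, length.out = 101)
    native <- denormalize_intensity(grid, d)
    expect_equal(normalize_intensity(native, d), grid, tolerance = 1e-12)
    expect_equal(denormalize_intensity(1, d), d$clip_high)
    expect_equal(denormalize_intensity(-1, d), d$clip_low)
  }
  expect_error(denormalize_intensity(1.1, intensity_domain("micro")),
               "outside")
})

test_that("average pooling averages non-overlapping blocks", {
  expect_equal(average_pool_downsample(matrix(c(0, 1, 1, 0), 2, 2), 2),
               matrix(0.5))
  cimg <- matrix(0.7, 12, 12)
  for (f in c(1, 2, 3, 4, 6))
    expect_equal(average_pool_downsample(cimg, f),
                 matrix(0.7, 12 / f, 12 / f))
  expect_error(average_pool_downsample(matrix(0, 5, 5), 2), "divisible")
  # preserves the global mean and the [-1,1] range
  set.seed(1)
  m <- matrix(runif(64, -1, 1), 8, 8)
  p <- average_pool_downsample(m, 4)
  expect_equal(mean(p), mean(m))
  expect_true(all(p >= -1 & p <= 1))
})

test_that("nearest upsampling replicates pixels and composes multiplicatively", {
  expect_equal(nearest_upsample(matrix(3), 2), matrix(3, 2, 2))
  m <- rand_mat(3, seed = 2)
  expect_identical(nearest_upsample(m, 1), m)
  for (r in list(c(2, 3), c(2, 2), c(3, 2)))
    expect_equal(nearest_upsample(nearest_upsample(m, r[1]), r[2]),
                 nearest_upsample(m, r[1] * r[2]))
  expect_equal(mean(nearest_upsample(m, 4)), mean(m))
  expect_error(nearest_upsample(m, 0))
})

test_that("pooling is the left inverse of nearest upsampling, not the right", {
  for (r in c(2, 4, 8)) {
    x <- rand_mat(4, seed = r)
    expect_equal(average_pool_downsample(nearest_upsample(x, r), r), x,
                 tolerance = 1e-14)
  }
  # f-up(f-down(x)) != x in general: checkered 2x2 counterexample
  chk <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_false(isTRUE(all.equal(
    nearest_upsample(average_pool_downsample(chk, 2), 2), chk)))
})

test_that("bicubic resampling matches the direct 4x4 Keys oracle", {
  set.seed(5)
  img <- matrix(runif(144, -1, 1), 12, 12)
  # downsample and upsample against the independent weighted-sum oracle
  for (os in list(c(6, 6), c(24, 24), c(9, 15))) {
    out <- bicubic_resample(img, os)
    for (i in 3:(os[1] - 2)) for (j in 3:(os[2] - 2)) {
      sy <- (i - 0.5) * 12 / os[1] - 0.5
      sx <- (j - 0.5) * 12 / os[2] - 0.5
      if (floor(sy) - 1 >= 0 && floor(sy) + 2 <= 11 &&
          floor(sx) - 1 >= 0 && floor(sx) + 2 <= 11)
        expect_equal(out[i, j], bicubic_oracle_pixel(img, i, j, os),
                     tolerance = 1e-10)
    }
  }
})

test_that("interior bicubic samples depend on exactly 16 source pixels", {
  n <- 16L
  base <- matrix(0, n, n)
  out0 <- bicubic_resample(base, c(2 * n, 2 * n))
  # perturb each source pixel; count which ones move one interior output pixel
  target <- c(16L, 16L)               # interior output sample
  affected <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pert <- base; pert[i, j] <- 1
    o <- bicubic_resample(pert, c(2 * n, 2 * n))
    if (abs(o[target[1], target[2]] - out0[target[1], target[2]]) > 1e-300)
      affected <- affected + 1L
  }
  expect_identical(affected, 16L)
})

test_that("bicubic preserves constants and degree-1 ramps", {
  for (os in list(c(3, 3), c(17, 5), c(32, 32)))
    expect_equal(bicubic_resample(matrix(0.4, 8, 8), os),
                 matrix(0.4, os[1], os[2]), tolerance = 1e-12)
  # linear ramp reproduced at interior pixels when upsampling
  ramp <- outer(seq_len(16), rep(1, 16)) / 16
  up <- bicubic_resample(ramp, c(32, 32))
  expected <- ((seq_len(32) - 0.5) * 16 / 32 + 0.5) / 16
  for (i in 5:28)
    expect_equal(up[i, 16], expected[i], tolerance = 1e-6)
  expect_error(bicubic_resample(ramp, c(0, 4)))
})

test_that("lung mask recovers known lung regions from a body phantom", {
  # disk body at 0 H.U. in -1000 air, two -800 elliptical lungs with +100
  # vessel holes; ground truth mask = the ellipses including the vessels
  n <- 48
  cx <- matrix(rep(seq_len(n), each = n), n, n)
  cy <- matrix(rep(seq_len(n), times = n), n, n)
  body <- (cy - 24)^2 + (cx - 24)^2 <= 21^2
  lung1 <- ((cy - 24) / 8)^2 + ((cx - 15) / 6)^2 <= 1
  lung2 <- ((cy - 24) / 8)^2 + ((cx - 33) / 6)^2 <= 1
  v1 <- (cy - 24)^2 + (cx - 15)^2 <= 2^2
  v2 <- (cy - 22)^2 + (cx - 33)^2 <= 2^2
  sl <- matrix(-1000, n, n)
  sl[body] <- 0
  sl[lung1 | lung2] <- -800
  sl[(v1 | v2)] <- 100
  vol <- ct_volume(aperm(array(sl, c(n, n, 3)), c(3, 1, 2)),
                   spacing = c(0.6, 0.625, 0.625),
                   domain = intensity_domain("clinical"))
  m <- lung_mask(vol)
  truth <- aperm(array(lung1 | lung2, c(n, n, 3)), c(3, 1, 2))
  expect_identical(m$data, truth)
  # idempotent under a second hole-filling pass
  refill <- m$data
  for (z in 1:3) refill[z, , ] <- srcycle:::fill_holes_slice(refill[z, , ])
  expect_identical(refill, m$data)
})

test_that("all-air volumes yield no lung region", {
  vol <- ct_volume(array(-1000, c(2, 20, 20)), c(1, 1, 1),
                   intensity_domain("clinical"))
  expect_error(lung_mask(vol), "no lung region")
})

test_that("patch extraction is seeded, sized, and mask-respecting", {
  set.seed(9)
  vol <- ct_volume(array(runif(4 * 40 * 40, -1000, 300), c(4, 40, 40)),
                   c(1, 1, 1), intensity_domain("clinical"))
  p1 <- extract_patches(vol, size = 8, n = 50, seed = 11)
  p2 <- extract_patches(vol, size = 8, n = 50, seed = 11)
  expect_length(p1, 50)
  expect_true(all(vapply(p1, function(p) all(dim(p$data) == c(8, 8)), TRUE)))
  expect_identical(lapply(p1, `[[`, "data"), lapply(p2, `[[`, "data"))
  expect_true(all(vapply(p1, function(p)
    min(p$data) >= -1 && max(p$data) <= 1, TRUE)))
  # all-true mask draws the identical sample as no mask under the same seed
  allmask <- binary_mask(array(TRUE, dim(vol$data)))
  p3 <- extract_patches(vol, size = 8, n = 50, seed = 11, mask = allmask)
  expect_identical(attr(p3, "manifest"), attr(p1, "manifest"))
  # restrictive mask: >= 50% coverage always holds
  half <- array(FALSE, dim(vol$data)); half[, 1:20, ] <- TRUE
  p4 <- extract_patches(vol, size = 8, n = 40, seed = 3,
                        mask = binary_mask(half))
  man <- attr(p4, "manifest")
  cov <- vapply(seq_len(nrow(man)), function(i)
    mean(half[man$z[i], man$y[i]:(man$y[i] + 7), man$x[i]:(man$x[i] + 7)]),
    0)
  expect_true(all(cov >= 0.5))
  # impossible mask errors with an acceptance rate
  none <- array(FALSE, dim(vol$data))
  expect_error(extract_patches(vol, size = 8, n = 2, seed = 3,
                               mask = binary_mask(none)),
               "acceptance rate")
})

test_that("patch positions are uniform over valid top-left positions", {
  vol <- ct_volume(array(0, c(1, 12, 12)), c(1, 1, 1),
                   intensity_domain("clinical"))
  p <- extract_patches(vol, size = 8, n = 4000, seed = 5)
  man <- attr(p, "manifest")
  # 5x5 valid positions; chi-square goodness of fit on the 25 cells
  cells <- table(factor(paste(man$y, man$x),
                        levels = as.vector(outer(1:5, 1:5, paste))))
  pval <- stats::chisq.test(as.vector(cells))$p.value
  expect_gt(pval, 1e-4)
})

test_that("patch sets round-trip through 16-bit TIFF + manifest", {
  dir <- withr::local_tempdir()
  ps <- lapply(1:3, function(i)
    image_patch(round(rand_mat(8, seed = i) * 32767) / 32767.5,
                intensity_domain("micro")))
  mp <- write_patch_set(ps, dir, seed = 1)
  back <- read_patch_set(mp)
  expect_length(back, 3)
  for (i in 1:3)
    expect_lt(max(abs(back[[i]]$data - ps[[i]]$data)), 2 / 65535)
})
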