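test_that("global SSIM has the defining identity, symmetry and hand value", {
  set.seed(7)
  x <- matrix(runif(64, -1, 1), 8, 8)
  expect_equal(ssim_global(x, x), 1.0)
  for (i in 1:5) {
    a <- matrix(runif(36, -1, 1), 6, 6)
    b <- matrix(runif(36, -1, 1), 6, 6)
    expect_equal(ssim_global(a, b), ssim_global(b, a))
    expect_lte(ssim_global(a, b), 1)
  }
  # hand-computed example at data range 1: means 0.5, variances 0.25,
  # covariance 0 -> C2 / (0.5 + C2)
  a <- matrix(c(0, 1, 0, 1), 2, 2)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  c1 <- ssim_constants(data_range = 1)
  expect_equal(ssim_global(a, b, c1), 0.0009 / 0.5009, tolerance = 1e-12)
  expect_equal(ssim_global(a, b, c1), 0.001797, tolerance = 1e-3)
  expect_error(ssim_global(a, matrix(0, 3, 3)), "mismatch")
})

test_that("SSIM loss vanishes on its two zero-cases and matches the moment oracle", {
  set.seed(8)
  x <- matrix(runif(16, -1, 1), 4, 4)
  # G1 form: x_sr = f_up(x) => f_down(x_sr) = x => loss 0
  expect_equal(ssim_loss(x, nearest_upsample(x, 2)), 0)
  # G2 form on a constant image
  y <- matrix(0.3, 8, 8)
  expect_equal(ssim_loss(y, average_pool_downsample(y, 2)), 0)
  # independent moment-formula oracle on a random pair
  x_sr <- matrix(runif(64, -1, 1), 8, 8)
  d <- average_pool_downsample(x_sr, 2)
  mu_a <- mean(x); mu_b <- mean(d)
  va <- mean((x - mu_a)^2); vb <- mean((d - mu_b)^2)
  vab <- mean((x - mu_a) * (d - mu_b))
  cst <- ssim_constants()
  oracle <- 1 - ((2 * mu_a * mu_b + cst$C1) * (2 * vab + cst$C2)) /
    ((mu_a^2 + mu_b^2 + cst$C1) * (va + vb + cst$C2))
  expect_equal(ssim_loss(x, x_sr), oracle, tolerance = 1e-12)
  expect_gte(ssim_loss(x, x_sr), 0)
  expect_lte(ssim_loss(x, x_sr), 2)
  expect_error(ssim_loss(x, matrix(0, 7, 7)), "integer scale")
})

test_that("downsample loss is the MSE against the pooled SR image", {
  expect_equal(downsample_loss(matrix(0.5), matrix(0.5, 2, 2)), 0)
  expect_equal(downsample_loss(matrix(0), matrix(1, 2, 2)), 1.0)
  set.seed(9)
  x <- matrix(runif(16, -1, 1), 4, 4)
  xsr <- matrix(runif(64, -1, 1), 8, 8)
  expect_equal(downsample_loss(x, xsr),
               mean((x - average_pool_downsample(xsr, 2))^2))
  # quadratic form: scaling both images by a scales the loss by a^2
  expect_equal(downsample_loss(0.5 * x, 0.5 * xsr),
               0.25 * downsample_loss(x, xsr))
})

test_that("upsample loss is the MSE against the nearest-upsampled LR image", {
  expect_equal(upsample_loss(matrix(0.2, 4, 4), matrix(0.2)), 0)
  expect_equal(upsample_loss(matrix(c(0, 0, 1, 1), 2, 2), matrix(0.5)), 0.25)
  set.seed(10)
  y <- matrix(runif(64, -1, 1), 8, 8)
  ylr <- matrix(runif(16, -1, 1), 4, 4)
  expect_equal(upsample_loss(y, ylr),
               mean((y - nearest_upsample(ylr, 2))^2))
  expect_gte(upsample_loss(y, ylr), 0)
})

test_that("least-squares adversarial losses follow the stated form", {
  expect_equal(adversarial_loss(NULL, matrix(1, 3, 3), "generator"), 0)
  expect_equal(adversarial_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2),
                                "discriminator"), 0.25)
  # generator loss decreases monotonically as D(fake) -> 1
  ls <- sapply(seq(0, 1, by = 0.25), function(v)
    adversarial_loss(NULL, matrix(v, 2, 2), "generator"))
  expect_true(all(diff(ls) < 0))
  expect_error(adversarial_loss(NULL, matrix(NaN), "generator"))
  # bce variant is finite and positive on logits
  expect_gt(adversarial_loss(matrix(1), matrix(-1), "discriminator", "bce"), 0)
})

test_that("cycle loss is the summed per-pixel MSE of both round trips", {
  x <- matrix(0.1, 3, 3)
  y <- matrix(-0.4, 6, 6)
  expect_equal(cycle_loss(x, x, y, y), 0)
  expect_equal(cycle_loss(matrix(0), matrix(1), y, y), 1.0)
  set.seed(11)
  xr <- matrix(runif(9, -1, 1), 3, 3); yr <- matrix(runif(36, -1, 1), 6, 6)
  expect_gte(cycle_loss(x, xr, y, yr), 0)
  expect_equal(cycle_loss(x, xr, y, yr),
               mean((x - xr)^2) + mean((y - yr)^2))
  expect_error(cycle_loss(x, matrix(0, 2, 2), y, y), "mismatch")
})

test_that("MMSR combines its four terms with the default weights", {
  w <- loss_weights()
  expect_equal(unlist(w[1:7], use.names = FALSE),
               c(1.0, 1.0, 0.7, 0.3, 1.0, 1.0, 1.0))
  # zero at the joint zero-case
  x <- matrix(0.25, 4, 4)
  expect_equal(mmsr_loss(x, nearest_upsample(x, 2),
                         nearest_upsample(x, 2), x, w), 0)
  # unit component losses with the default weights sum to 3.0
  expect_equal(w$lambda1 * 1 + w$lambda2 * 1 + w$lambda3 * 1 + w$lambda4 * 1,
               3.0)
  # dropping the pixel terms leaves exactly the two SSIM terms
  set.seed(12)
  xs <- matrix(runif(16, -1, 1), 4, 4)
  xsr <- matrix(runif(64, -1, 1), 8, 8)
  ys <- matrix(runif(64, -1, 1), 8, 8)
  ylr <- matrix(runif(16, -1, 1), 4, 4)
  w0 <- loss_weights(lambda3 = 0, lambda4 = 0)
  expect_equal(mmsr_loss(xs, xsr, ys, ylr, w0),
               ssim_loss(xs, xsr) + ssim_loss(ys, ylr))
  expect_error(loss_weights(lambda3 = -1))
})

test_that("total loss equals its breakdown and is linear in each weight", {
  set.seed(13)
  x <- matrix(runif(16, -1, 1), 4, 4)
  xsr <- matrix(runif(64, -1, 1), 8, 8)
  y <- matrix(runif(64, -1, 1), 8, 8)
  ylr <- matrix(runif(16, -1, 1), 4, 4)
  xrec <- matrix(runif(16, -1, 1), 4, 4)
  yrec <- matrix(runif(64, -1, 1), 8, 8)
  d1 <- matrix(runif(9), 3, 3); d2 <- matrix(runif(4), 2, 2)
  w <- loss_weights()
  bd <- total_loss(x, xsr, y, ylr, xrec, yrec, d1, d2, w)
  recomputed <- w$lambda1 * bd$LS1 + w$lambda2 * bd$LS2 + w$lambda3 * bd$LD +
    w$lambda4 * bd$LU + w$lambda5 * bd$Lgan_G1 + w$lambda6 * bd$Lgan_G2 +
    w$lambda7 * bd$Lcyc
  expect_equal(bd$total, recomputed, tolerance = 1e-6)
  # all terms zero => total zero
  x0 <- matrix(0.1, 4, 4)
  bd0 <- total_loss(x0, nearest_upsample(x0, 2), nearest_upsample(x0, 2), x0,
                    x0, nearest_upsample(x0, 2), matrix(1), matrix(1), w)
  expect_equal(bd0$total, 0)
  # doubling lambda7 adds exactly lambda7 * Lcyc
  w2 <- loss_weights(lambda7 = 2)
  bd2 <- total_loss(x, xsr, y, ylr, xrec, yrec, d1, d2, w2)
  expect_equal(bd2$total - bd$total, bd$Lcyc, tolerance = 1e-12)
  # linearity in lambda3
  w3 <- loss_weights(lambda3 = 1.4)
  bd3 <- total_loss(x, xsr, y, ylr, xrec, yrec, d1, d2, w3)
  expect_equal(bd3$total - bd$total, 0.7 * bd$LD, tolerance = 1e-12)
})

test_that("losses seeing only pooled SR are invariant to sub-pixel permutations", {
  # for s = 2, permuting the 4 sub-pixels inside each 2x2 block of x_sr
  # leaves f_down(x_sr) unchanged, hence the SSIM and downsample losses too
  set.seed(14)
  x <- matrix(runif(4, -1, 1), 2, 2)
  xsr <- matrix(runif(16, -1, 1), 4, 4)
  perms <- list(c(1, 2, 3, 4), c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))
  base_s <- ssim_loss(x, xsr); base_d <- downsample_loss(x, xsr)
  for (pm in perms) {
    xp <- xsr
    for (by in c(0, 2)) for (bx in c(0, 2)) {
      blk <- as.vector(xsr[by + 1:2, bx + 1:2])
      xp[by + 1:2, bx + 1:2] <- matrix(blk[pm], 2, 2)
    }
    expect_equal(ssim_loss(x, xp), base_s, tolerance = 1e-12)
    expect_equal(downsample_loss(x, xp), base_d, tolerance = 1e-12)
  }
})

test_that("loss gradients are finite and match finite differences", {
  eng <- asNamespace("srcycle")
  set.seed(15)
  x <- matrix(runif(16, -1, 1), 4, 4)
  xsr <- matrix(runif(64, -1, 1), 8, 8)
  eps <- 1e-6
  for (fn in list(list(v = ssim_loss, g = eng$ssim_loss_grad),
                  list(v = downsample_loss, g = eng$downsample_loss_grad))) {
    g <- fn$g(x, xsr)
    expect_true(all(is.finite(g)))
    for (i in c(1, 17, 40, 64)) {
      p <- xsr; p[i] <- p[i] + eps
      q <- xsr; q[i] <- q[i] - eps
      expect_equal(g[i], (fn$v(x, p) - fn$v(x, q)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})
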