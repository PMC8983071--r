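#' Loss weights of the total objective
#'
#' The seven weights of the total training objective: `lambda1`, `lambda2`
#' weight the two SSIM losses (G1 and G2 side), `lambda3` the downsample
#' loss, `lambda4` the upsample loss, `lambda5`, `lambda6` the adversarial
#' losses, `lambda7` the cycle-consistency loss. Defaults are
#' (1.0, 1.0, 0.7, 0.3, 1.0, 1.0, 1.0).
#'
#' @param lambda1,lambda2,lambda3,lambda4,lambda5,lambda6,lambda7
#'   Nonnegative reals.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1.0, lambda2 = 1.0, lambda3 = 0.7,
                         lambda4 = 0.3, lambda5 = 1.0, lambda6 = 1.0,
                         lambda7 = 1.0) {
  w <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         lambda4 = lambda4, lambda5 = lambda5, lambda6 = lambda6,
         lambda7 = lambda7)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss_weights: all weights must be finite and >= 0")
  structure(as.list(w), class = "loss_weights")
}

#' SSIM stabilizing constants
#'
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with the conventional `K1 = 0.01`,
#' `K2 = 0.03` and data range `L` (2.0 for images normalized to `[-1, 1]`).
#'
#' @param data_range Dynamic range `L` of the images (default 2).
#' @param K1,K2 Small constants.
#' @return List with `C1`, `C2`, `data_range`.
#' @export
ssim_constants <- function(data_range = 2, K1 = 0.01, K2 = 0.03) {
  stopifnot(data_range > 0, K1 > 0, K2 > 0)
  list(C1 = (K1 * data_range)^2, C2 = (K2 * data_range)^2,
       data_range = data_range)
}

#' Global (single-window) structural similarity
#'
#' SSIM computed from whole-image moments: with means `mu_a`, `mu_b`,
#' population variances `sigma_a^2`, `sigma_b^2` and covariance `sigma_ab`,
#' \deqn{SSIM = \frac{(2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)}
#'                   {(\mu_a^2+\mu_b^2+C_1)(\sigma_a^2+\sigma_b^2+C_2)}.}
#' Symmetric, at most 1, and exactly 1 for identical images. This is the
#' form used inside the SSIM training loss; the evaluation metric
#' [ssim_windowed()] uses local Gaussian windows instead.
#'
#' @param a,b Numeric matrices of equal shape.
#' @param consts Constants from [ssim_constants()].
#' @return Scalar SSIM value.
#' @export
#' @examples
#' ssim_global(matrix(1:4, 2), matrix(1:4, 2))  # 1
ssim_global <- function(a, b, consts = ssim_constants()) {
  a <- as_image_array(a); b <- as_image_array(b)
  if (!all(dim(a) == dim(b))) stop("ssim_global: shape mismatch")
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean(a^2) - mu_a^2
  vb <- mean(b^2) - mu_b^2
  vab <- mean(a * b) - mu_a * mu_b
  ((2 * mu_a * mu_b + consts$C1) * (2 * vab + consts$C2)) /
    ((mu_a^2 + mu_b^2 + consts$C1) * (va + vb + consts$C2))
}

# d SSIM(a, b) / d b with a held fixed (global moments).
ssim_global_grad_b <- function(a, b, consts = ssim_constants()) {
  n <- length(b)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean(a^2) - mu_a^2
  vb <- mean(b^2) - mu_b^2
  vab <- mean(a * b) - mu_a * mu_b
  A1 <- 2 * mu_a * mu_b + consts$C1
  A2 <- 2 * vab + consts$C2
  B1 <- mu_a^2 + mu_b^2 + consts$C1
  B2 <- va + vb + consts$C2
  S <- (A1 * A2) / (B1 * B2)
  dnum <- (2 * mu_a * A2 / n + A1 * 2 * (a - mu_a) / n) / (B1 * B2)
  dden <- S * (2 * mu_b / (n * B1) + 2 * (b - mu_b) / (n * B2))
  dnum - dden
}

# resolve the integer scale between a small and a large image
infer_scale <- function(small, large, what) {
  s <- nrow(large) / nrow(small)
  if (s != round(s) || ncol(large) / ncol(small) != s || s < 1)
    stop(sprintf("%s: sizes %dx%d and %dx%d are not related by an integer scale",
                 what, nrow(small), ncol(small), nrow(large), ncol(large)))
  as.integer(s)
}

#' SSIM loss across resolutions
#'
#' `1 - SSIM(ref, other)` after bringing `other` to the size of `ref`: if
#' `other` is larger by an integer factor it is average-pooled down
#' (the G1-side form, `1 - SSIM(x, f_down(x_sr))`); if smaller it is
#' nearest-upsampled (the G2-side form, `1 - SSIM(y, f_up(y_lr))`). Lies in
#' `[0, 2]` and is 0 iff the resized image equals `ref` in the SSIM sense.
#'
#' @param ref Reference patch (matrix or [image_patch()]).
#' @param other Compared image at the same or an integer-related size.
#' @param consts Constants from [ssim_constants()].
#' @return Scalar loss.
#' @export
ssim_loss <- function(ref, other, consts = ssim_constants()) {
  ref <- as_image_array(ref); other <- as_image_array(other)
  if (nrow(other) >= nrow(ref)) {
    s <- infer_scale(ref, other, "ssim_loss")
    1 - ssim_global(ref, average_pool_downsample(other, s), consts)
  } else {
    s <- infer_scale(other, ref, "ssim_loss")
    1 - ssim_global(ref, nearest_upsample(other, s), consts)
  }
}

# gradient of ssim_loss wrt `other` (either orientation)
ssim_loss_grad <- function(ref, other, consts = ssim_constants()) {
  if (nrow(other) >= nrow(ref)) {
    s <- infer_scale(ref, other, "ssim_loss")
    g <- -ssim_global_grad_b(ref, average_pool_downsample(other, s), consts)
    nearest_upsample(g, s) / s^2                 # adjoint of average pooling
  } else {
    s <- infer_scale(other, ref, "ssim_loss")
    g <- -ssim_global_grad_b(ref, nearest_upsample(other, s), consts)
    block_sum(g, s)                              # adjoint of nearest upsample
  }
}

#' Downsample consistency loss
#'
#' `mean((x - f_down(x_sr))^2)`: the super-resolved image, average-pooled
#' back to the input size, must match the low-resolution input pixel-wise.
#' Prevents the super-resolution generator from shifting intensities or
#' deforming structures relative to its input.
#'
#' @param x Low-resolution patch `n x n`.
#' @param x_sr Super-resolved image `sn x sn`.
#' @return Scalar loss (>= 0; 0 iff `f_down(x_sr) = x` exactly).
#' @export
downsample_loss <- function(x, x_sr) {
  x <- as_image_array(x); x_sr <- as_image_array(x_sr)
  s <- infer_scale(x, x_sr, "downsample_loss")
  mean((x - average_pool_downsample(x_sr, s))^2)
}

downsample_loss_grad <- function(x, x_sr) {
  s <- infer_scale(x, x_sr, "downsample_loss")
  d <- average_pool_downsample(x_sr, s) - x
  nearest_upsample(2 * d / length(x), s) / s^2
}

#' Upsample consistency loss
#'
#' `mean((y - f_up(y_lr))^2)`: the generated low-resolution image,
#' nearest-upsampled back to the high-resolution size, must match the
#' micro-CT input pixel-wise. The G2-side counterpart of
#' [downsample_loss()].
#'
#' @param y High-resolution patch `sn x sn`.
#' @param y_lr Generated low-resolution image `n x n`.
#' @return Scalar loss (>= 0).
#' @export
upsample_loss <- function(y, y_lr) {
  y <- as_image_array(y); y_lr <- as_image_array(y_lr)
  s <- infer_scale(y_lr, y, "upsample_loss")
  mean((y - nearest_upsample(y_lr, s))^2)
}

upsample_loss_grad <- function(y, y_lr) {
  s <- infer_scale(y_lr, y, "upsample_loss")
  d <- nearest_upsample(y_lr, s) - y
  block_sum(2 * d / length(y), s)
}

#' Least-squares adversarial losses
#'
#' The least-squares GAN objective on patch-discriminator score maps: the
#' discriminator loss is `0.5 mean((D(real) - 1)^2) + 0.5 mean(D(fake)^2)`;
#' the generator loss is `mean((D(fake) - 1)^2)`. A binary cross-entropy
#' variant (`kind = "bce"`, scores passed through a sigmoid) is available.
#'
#' @param d_real Discriminator scores on real images (any numeric array);
#'   ignored for `role = "generator"`.
#' @param d_fake Discriminator scores on generated images.
#' @param role `"generator"` or `"discriminator"`.
#' @param kind `"lsgan"` (default) or `"bce"`.
#' @return Scalar loss.
#' @export
adversarial_loss <- function(d_real, d_fake,
                             role = c("generator", "discriminator"),
                             kind = c("lsgan", "bce")) {
  role <- match.arg(role); kind <- match.arg(kind)
  if ((!is.null(d_real) && any(!is.finite(d_real))) || any(!is.finite(d_fake)))
    stop("adversarial_loss: non-finite scores")
  if (kind == "lsgan") {
    if (role == "generator") mean((d_fake - 1)^2)
    else 0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2)
  } else {
    p_fake <- 1 / (1 + exp(-d_fake))
    if (role == "generator") -mean(log(pmax(p_fake, 1e-12)))
    else {
      p_real <- 1 / (1 + exp(-d_real))
      -0.5 * mean(log(pmax(p_real, 1e-12))) -
        0.5 * mean(log(pmax(1 - p_fake, 1e-12)))
    }
  }
}

# gradients of the lsgan forms wrt the score maps
adv_grad_gen <- function(d_fake) 2 * (d_fake - 1) / length(d_fake)
adv_grad_disc_real <- function(d_real) (d_real - 1) / length(d_real)
adv_grad_disc_fake <- function(d_fake) d_fake / length(d_fake)

#' Cycle-consistency loss
#'
#' `mean((x - x_rec)^2) + mean((y - y_rec)^2)` where `x_rec = G2(G1(x))`
#' and `y_rec = G1(G2(y))`: both round trips through the two generators
#' must reproduce their input (squared L2, averaged per pixel so the
#' weights are resolution-independent).
#'
#' @param x,x_rec Low-resolution input and its reconstruction.
#' @param y,y_rec High-resolution input and its reconstruction.
#' @return Scalar loss (0 iff both reconstructions are exact).
#' @export
cycle_loss <- function(x, x_rec, y, y_rec) {
  x <- as_image_array(x); x_rec <- as_image_array(x_rec)
  y <- as_image_array(y); y_rec <- as_image_array(y_rec)
  if (!all(dim(x) == dim(x_rec)) || !all(dim(y) == dim(y_rec)))
    stop("cycle_loss: shape mismatch")
  mean((x - x_rec)^2) + mean((y - y_rec)^2)
}

#' Multi-modality super-resolution (MMSR) loss
#'
#' The cross-resolution consistency objective:
#' `lambda1 * (1 - SSIM(x, f_down(x_sr))) + lambda2 * (1 - SSIM(y, f_up(y_lr)))
#'  + lambda3 * L_D(x, x_sr) + lambda4 * L_U(y, y_lr)`.
#' The SSIM terms tie anatomical structure across resolutions; the
#' downsample/upsample terms tie pixel-wise intensity. This is the loss that
#' makes unpaired super-resolution feasible when the two domains have very
#' different intensity distributions.
#'
#' @param x Clinical low-resolution patch; `x_sr` its super-resolved output.
#' @param x_sr Super-resolved image, `s` times larger than `x`.
#' @param y Micro-CT high-resolution patch; `y_lr` its downscaled output.
#' @param y_lr Generated low-resolution image, `s` times smaller than `y`.
#' @param w A [loss_weights()].
#' @param consts SSIM constants.
#' @return Scalar loss.
#' @export
mmsr_loss <- function(x, x_sr, y, y_lr, w = loss_weights(),
                      consts = ssim_constants()) {
  w$lambda1 * ssim_loss(x, x_sr, consts) +
    w$lambda2 * ssim_loss(y, y_lr, consts) +
    w$lambda3 * downsample_loss(x, x_sr) +
    w$lambda4 * upsample_loss(y, y_lr)
}

#' Total training objective with per-term breakdown
#'
#' MMSR loss plus the two adversarial generator losses and the
#' cycle-consistency loss:
#' `L = MMSR + lambda5 * Lgan(x_sr) + lambda6 * Lgan(y_lr) + lambda7 * Lcyc`.
#' Returns every term so the weighted sum can be recomputed from the
#' breakdown.
#'
#' @inheritParams mmsr_loss
#' @param x_rec Reconstruction `G2(G1(x))`; `y_rec` is `G1(G2(y))`.
#' @param y_rec See `x_rec`.
#' @param d1_fake Discriminator scores of `x_sr` on the micro domain.
#' @param d2_fake Discriminator scores of `y_lr` on the clinical domain.
#' @return A `loss_breakdown` list: `LS1`, `LS2`, `LD`, `LU`, `Lgan_G1`,
#'   `Lgan_G2`, `Lcyc`, `total`.
#' @export
total_loss <- function(x, x_sr, y, y_lr, x_rec, y_rec, d1_fake, d2_fake,
                       w = loss_weights(), consts = ssim_constants()) {
  terms <- list(
    LS1 = ssim_loss(x, x_sr, consts),
    LS2 = ssim_loss(y, y_lr, consts),
    LD = downsample_loss(x, x_sr),
    LU = upsample_loss(y, y_lr),
    Lgan_G1 = adversarial_loss(NULL, d1_fake, "generator"),
    Lgan_G2 = adversarial_loss(NULL, d2_fake, "generator"),
    Lcyc = cycle_loss(x, x_rec, y, y_rec))
  terms$total <- w$lambda1 * terms$LS1 + w$lambda2 * terms$LS2 +
    w$lambda3 * terms$LD + w$lambda4 * terms$LU +
    w$lambda5 * terms$Lgan_G1 + w$lambda6 * terms$Lgan_G2 +
    w$lambda7 * terms$Lcyc
  structure(terms, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total %.4g (LS1 %.3g LS2 %.3g LD %.3g LU %.3g gan %.3g/%.3g cyc %.3g)\n",
    x$total, x$LS1, x$LS2, x$LD, x$LU, x$Lgan_G1, x$Lgan_G2, x$Lcyc))
  invisible(x)
}
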