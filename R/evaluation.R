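#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` in dB. Identical images (zero MSE) are
#' reported as a defined cap of 100 dB so that set means stay finite.
#'
#' @param a,b Numeric matrices of equal shape.
#' @param data_range Dynamic range (default 2 for `[-1, 1]` images).
#' @param cap Value returned for zero MSE (default 100).
#' @return PSNR in dB.
#' @export
#' @examples
#' psnr(matrix(0, 4, 4), matrix(0.2, 4, 4))
psnr <- function(a, b, data_range = 2, cap = 100) {
  a <- as_image_array(a); b <- as_image_array(b)
  if (!all(dim(a) == dim(b))) stop("psnr: shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(data_range^2 / mse))
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  t <- seq_len(size) - (size + 1) / 2
  k <- exp(-t^2 / (2 * sigma^2))
  w <- outer(k, k)
  w / sum(w)
}

#' Windowed structural similarity (reference metric)
#'
#' Mean of the local SSIM map computed over an 11x11 Gaussian window
#' (sigma 1.5) with the standard constants `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`. This is the conventional reporting form of SSIM; the
#' training loss uses the global single-window form [ssim_global()].
#'
#' @param a,b Numeric matrices of equal shape, at least 11x11.
#' @param data_range Dynamic range `L` (default 2).
#' @return Scalar mean SSIM (1 for identical images).
#' @export
ssim_windowed <- function(a, b, data_range = 2) {
  a <- as_image_array(a); b <- as_image_array(b)
  if (!all(dim(a) == dim(b))) stop("ssim_windowed: shape mismatch")
  if (any(dim(a) < 11L)) stop("ssim_windowed: images must be at least 11x11")
  consts <- ssim_constants(data_range)
  win <- gaussian_window()
  w4 <- array(win, c(11L, 11L, 1L, 1L))
  filt <- function(m) {
    y <- .conv2d_fwd(array(m, c(dim(m), 1L, 1L)), w4, 0, 1L, 0L, TRUE)
    matrix(y, dim(y)[1], dim(y)[2])
  }
  mu_a <- filt(a); mu_b <- filt(b)
  va <- filt(a * a) - mu_a^2
  vb <- filt(b * b) - mu_b^2
  vab <- filt(a * b) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + consts$C1) * (2 * vab + consts$C2)) /
    ((mu_a^2 + mu_b^2 + consts$C1) * (va + vb + consts$C2))
  mean(smap)
}

#' Bicubic-degradation evaluation protocol
#'
#' The quantitative protocol for unpaired super-resolution: each
#' high-resolution micro-domain image is bicubic-downsampled by the scale
#' factor to simulate a clinical-resolution input, super-resolved with G1,
#' and the result is compared with the original via [psnr()] and
#' [ssim_windowed()] (the global SSIM is logged as well). Pass
#' `sr_fun` to evaluate a baseline upscaler instead of a trained generator.
#'
#' @param hr_images List of micro-domain HR matrices (sides divisible by
#'   `scale`).
#' @param model An [srcycle_model()] or G1 network; ignored when `sr_fun`
#'   is given.
#' @param scale Integer upscaling factor `s`.
#' @param sr_fun Optional `function(lr_matrix) -> sr_matrix` overriding the
#'   generator (e.g. `function(m) bicubic_resample(m, dim(m) * s)`).
#' @param data_range PSNR/SSIM dynamic range (default 2).
#' @return An `eval_report`: data frame of per-image PSNR/SSIM (windowed and
#'   global), the two means, counts and settings.
#' @export
evaluate_protocol <- function(hr_images, model = NULL, scale,
                              sr_fun = NULL, data_range = 2) {
  scale <- as.integer(scale)
  stopifnot(length(hr_images) >= 1L, scale >= 2L)
  if (is.null(sr_fun)) {
    G1 <- if (inherits(model, "srcycle_model")) model$nets$G1 else model
    sr_fun <- function(m) {
      y <- net_predict(G1, m)
      matrix(y, dim(y)[1], dim(y)[2])
    }
  }
  rows <- lapply(seq_along(hr_images), function(i) {
    hr <- as_image_array(hr_images[[i]])
    if (any(dim(hr) %% scale != 0L))
      stop("evaluate_protocol: HR sides must be divisible by the scale")
    if (any(dim(hr) %/% scale < 4L))
      stop("evaluate_protocol: HR image too small for this scale")
    lr <- bicubic_resample(hr, dim(hr) %/% scale)
    lr <- pmin(pmax(lr, -1), 1)
    sr <- sr_fun(lr)
    if (!all(dim(sr) == dim(hr)))
      stop("evaluate_protocol: SR output does not match HR size")
    data.frame(image = i,
               psnr = psnr(sr, hr, data_range),
               ssim = ssim_windowed(sr, hr, data_range),
               ssim_global = ssim_global(sr, hr,
                                         ssim_constants(data_range)))
  })
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 mean_psnr = mean(per_image$psnr),
                 mean_ssim = mean(per_image$ssim),
                 n = nrow(per_image),
                 scale = scale, data_range = data_range),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d, scale %dx: mean PSNR %.2f dB, mean SSIM %.4f\n",
              x$n, x$scale, x$mean_psnr, x$mean_ssim))
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report An `eval_report` from [evaluate_protocol()].
#' @param path_prefix Files `<prefix>.json` and `<prefix>.csv` are written.
#' @return The two paths, invisibly.
#' @export
write_eval_report <- function(report, path_prefix) {
  jp <- paste0(path_prefix, ".json")
  cp <- paste0(path_prefix, ".csv")
  jsonlite::write_json(list(mean_psnr = report$mean_psnr,
                            mean_ssim = report$mean_ssim, n = report$n,
                            scale = report$scale,
                            data_range = report$data_range),
                       jp, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_image, cp, row.names = FALSE)
  invisible(c(jp, cp))
}
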