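#' Average-pooling downsampling (f-down)
#'
#' Non-overlapping average pooling with stride equal to the pooling factor:
#' each output pixel is the arithmetic mean of its `factor x factor` block.
#' This is the downscaling operator used inside the SSIM and downsample
#' consistency losses.
#'
#' @param img 2-D numeric matrix; both dimensions divisible by `factor`.
#' @param factor Integer >= 1.
#' @return Matrix of dims `dim(img) / factor`.
#' @export
#' @examples
#' average_pool_downsample(matrix(c(0, 1, 1, 0), 2, 2), 2)  # 0.5
average_pool_downsample <- function(img, factor) {
  stopifnot(is.matrix(img), is.numeric(img))
  factor <- as.integer(factor)
  if (factor < 1L) stop("average_pool_downsample: factor must be >= 1")
  if (factor == 1L) return(img)
  h <- nrow(img); w <- ncol(img)
  if (h %% factor != 0L || w %% factor != 0L)
    stop(sprintf(
      "average_pool_downsample: dims %dx%d not divisible by factor %d",
      h, w, factor))
  ho <- h %/% factor; wo <- w %/% factor
  # pool rows, then columns (separable means)
  m <- colMeans(array(img, c(factor, ho, w)), dims = 1)        # ho x w
  t(colMeans(array(t(m), c(factor, wo, ho)), dims = 1))        # ho x wo
}

#' Nearest-neighbour upsampling (f-up)
#'
#' Replicates each input pixel over a `factor x factor` block. Exact left
#' inverse of [average_pool_downsample()]: pooling a nearest-upsampled image
#' by the same factor recovers the original.
#'
#' @param img 2-D numeric matrix.
#' @param factor Integer >= 1.
#' @return Matrix of dims `dim(img) * factor`.
#' @export
#' @examples
#' nearest_upsample(matrix(3), 2)
nearest_upsample <- function(img, factor) {
  stopifnot(is.matrix(img), is.numeric(img))
  factor <- as.integer(factor)
  if (factor < 1L) stop("nearest_upsample: factor must be >= 1")
  if (factor == 1L) return(img)
  img[rep(seq_len(nrow(img)), each = factor),
      rep(seq_len(ncol(img)), each = factor), drop = FALSE]
}

# Adjoint of nearest_upsample: sums each factor x factor block.
block_sum <- function(img, factor) {
  average_pool_downsample(img, factor) * factor^2
}

# Keys cubic convolution kernel, a = -0.5 (the classic bicubic kernel with
# 4-sample support).
keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# 1-D bicubic resampling weights from n_in samples to n_out, half-pixel
# centre alignment, reflect boundary. Returns n_out x n_in sparse-ish matrix.
bicubic_weights_1d <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    base <- floor(src)
    for (k in -1:2) {
      j <- base + k                          # 0-based tap
      wt <- keys_kernel(src - j)
      if (wt == 0) next
      # reflect (symmetric, no edge repetition) onto [0, n_in - 1]
      if (n_in == 1) j <- 0
      else {
        while (j < 0 || j > n_in - 1) {
          if (j < 0) j <- -j
          if (j > n_in - 1) j <- 2 * (n_in - 1) - j
        }
      }
      W[i, j + 1] <- W[i, j + 1] + wt
    }
  }
  # normalize so constants are preserved exactly
  sweep(W, 1, rowSums(W), "/")
}

#' Bicubic resampling
#'
#' Separable cubic-convolution (Keys, a = -0.5) resampling to an arbitrary
#' output shape, with half-pixel centre alignment and reflective boundary
#' handling. Every interior output sample is a weighted sum of a 4x4
#' neighbourhood of source pixels; constant images are preserved exactly.
#' Used by the evaluation protocol to degrade micro-CT images to simulated
#' clinical-resolution inputs.
#'
#' @param img 2-D numeric matrix.
#' @param out_shape Integer length-2 `(rows, cols)`, both >= 1.
#' @return Matrix with dims `out_shape`.
#' @export
#' @examples
#' bicubic_resample(matrix(1:16, 4, 4), c(2, 2))
bicubic_resample <- function(img, out_shape) {
  stopifnot(is.matrix(img), is.numeric(img), length(out_shape) == 2)
  out_shape <- as.integer(out_shape)
  if (any(out_shape < 1L)) stop("bicubic_resample: output shape must be >= 1")
  Wr <- bicubic_weights_1d(nrow(img), out_shape[1])
  Wc <- bicubic_weights_1d(ncol(img), out_shape[2])
  Wr %*% img %*% t(Wc)
}
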