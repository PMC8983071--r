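# shared tiny fixtures; everything is generated in code

tiny_net_cfg <- function(k = 1L, ch = 4L, res = 1L)
  network_config(scale_k = k, n_resblocks = res, base_channels = ch)

tiny_phantom_spec <- function(seed = 1L)
  phantom_spec(hr_size = 32L, scale = 4L, seed = seed)

rand_mat <- function(n, m = n, seed = 1L, lo = -1, hi = 1) {
  set.seed(seed)
  matrix(runif(n * m, lo, hi), n, m)
}

# independent Keys a=-0.5 kernel for bicubic oracles
keys_ref <- function(t, a = -0.5) {
  t <- abs(t)
  if (t <= 1) (a + 2) * t^3 - (a + 3) * t^2 + 1
  else if (t < 2) a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a
  else 0
}

# direct 4x4 weighted-sum bicubic oracle for interior output pixels
# (half-pixel centre alignment; valid only where all taps are interior)
bicubic_oracle_pixel <- function(img, i, j, out_shape) {
  sy <- (i - 0.5) * nrow(img) / out_shape[1] - 0.5
  sx <- (j - 0.5) * ncol(img) / out_shape[2] - 0.5
  by <- floor(sy); bx <- floor(sx)
  acc <- 0
  for (ky in -1:2) for (kx in -1:2) {
    wy <- keys_ref(sy - (by + ky)); wx <- keys_ref(sx - (bx + kx))
    acc <- acc + wy * wx * img[by + ky + 1, bx + kx + 1]
  }
  acc
}
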