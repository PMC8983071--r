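#' Network architecture configuration
#'
#' Hyperparameters of the generator/discriminator family. The scale factor is
#' `2^scale_k`; the main configuration uses `scale_k = 3` (8x: 32x32 clinical
#' patches to 256x256 micro-CT-scale patches) and the 4x configuration uses
#' `scale_k = 2` (48x48 to 192x192). The generator head uses a 3x3 then a 7x7
#' convolution and 9 residual blocks by default.
#'
#' @param scale_k Integer >= 1; scale factor is `2^scale_k`.
#' @param n_resblocks Number of residual blocks (default 9).
#' @param head_kernels Kernel sizes of the two head convolutions (odd).
#' @param base_channels Feature width (default 64; not printed in any
#'   reference, pinned to the CycleGAN convention).
#' @param norm `"batch"` (default) or `"instance"`.
#' @param variant `"sr_no_downblocks"` (the method), `"sr_with_downblocks"`
#'   or `"upblocks_baseline"` (ablation architectures).
#' @return An object of class `network_config`.
#' @export
network_config <- function(scale_k = 3L, n_resblocks = 9L,
                           head_kernels = c(3L, 7L), base_channels = 64L,
                           norm = c("batch", "instance"),
                           variant = c("sr_no_downblocks",
                                       "sr_with_downblocks",
                                       "upblocks_baseline")) {
  norm <- match.arg(norm)
  variant <- match.arg(variant)
  scale_k <- as.integer(scale_k)
  n_resblocks <- as.integer(n_resblocks)
  head_kernels <- as.integer(head_kernels)
  stopifnot(scale_k >= 1L, n_resblocks >= 1L, length(head_kernels) == 2L,
            base_channels >= 1L)
  if (any(head_kernels %% 2L == 0L))
    stop("network_config: head kernel sizes must be odd")
  structure(list(scale_k = scale_k, scale = as.integer(2^scale_k),
                 n_resblocks = n_resblocks, head_kernels = head_kernels,
                 base_channels = as.integer(base_channels), norm = norm,
                 variant = variant),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> %dx (k=%d), %d resblocks, head %dx%d/%dx%d, %d ch, %s norm, %s\n",
    x$scale, x$scale_k, x$n_resblocks, x$head_kernels[1], x$head_kernels[1],
    x$head_kernels[2], x$head_kernels[2], x$base_channels, x$norm, x$variant))
  invisible(x)
}

head_layers <- function(cfg, cin = 1L) {
  C <- cfg$base_channels
  list(layer_conv(cfg$head_kernels[1], cfg$head_kernels[1], cin, C),
       layer_norm(C, cfg$norm),
       layer_act("relu"),
       layer_conv(cfg$head_kernels[2], cfg$head_kernels[2], C, C),
       layer_norm(C, cfg$norm),
       layer_act("relu"))
}

resblock_layers <- function(cfg) {
  lapply(seq_len(cfg$n_resblocks),
         function(i) layer_resblock(cfg$base_channels, cfg$norm))
}

upsample_stage <- function(cfg) {
  C <- cfg$base_channels
  list(layer_conv(3L, 3L, C, 4L * C),
       layer_pixel_shuffle(2L),
       layer_act("relu"))
}

downblock <- function(cfg) {
  C <- cfg$base_channels
  list(layer_conv(3L, 3L, C, C, stride = 2L),
       layer_norm(C, cfg$norm),
       layer_act("relu"))
}

upblock_resize <- function(cfg) {
  # deconvolution upblock realized as nearest-upsample + conv (resize-conv)
  C <- cfg$base_channels
  list(layer_nearest_up(2L),
       layer_conv(3L, 3L, C, C),
       layer_norm(cfg$base_channels, cfg$norm),
       layer_act("relu"))
}

tail_layers <- function(cfg) {
  list(layer_conv(cfg$head_kernels[2], cfg$head_kernels[2],
                  cfg$base_channels, 1L),
       layer_act("tanh"))
}

new_net <- function(cfg, layers, role, scale_exp) {
  structure(list(cfg = cfg, layers = layers, role = role,
                 scale_exp = scale_exp),
            class = "srcycle_net")
}

#' @export
print.srcycle_net <- function(x, ...) {
  cat(sprintf("<srcycle_net> role %s, output scale 2^%d, %d parameters\n",
              x$role, x$scale_exp, net_param_count(x)))
  invisible(x)
}

#' Build the super-resolution generator G1
#'
#' The upscaling generator: no downblocks (feature maps stay at the input
#' resolution, so spatial detail of the small input is never collapsed to a
#' tiny bottleneck), a 3x3 then 7x7 convolutional head, `n_resblocks`
#' residual blocks, then `scale_k` sub-pixel shuffling stages (conv to 4x
#' channels + shuffle r=2 + ReLU) and a 7x7 output convolution with tanh.
#' Maps an `n x n` input to `2^k n x 2^k n`, values in `(-1, 1)`.
#'
#' @param cfg A [network_config()] with `variant = "sr_no_downblocks"`.
#' @param seed Optional integer seed for weight initialization
#'   (zero-mean Gaussian, sd 0.02).
#' @return A generator network object.
#' @export
build_generator_sr <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$variant != "sr_no_downblocks")
    stop("build_generator_sr: cfg$variant must be sr_no_downblocks; ",
         "use build_variant() for ablation architectures")
  if (!is.null(seed)) set.seed(seed)
  layers <- c(head_layers(cfg), resblock_layers(cfg),
              unlist(lapply(seq_len(cfg$scale_k), function(i)
                upsample_stage(cfg)), recursive = FALSE),
              tail_layers(cfg))
  new_net(cfg, layers, "G1", cfg$scale_k)
}

#' Build the downscaling generator G2
#'
#' The inverse-direction generator: same head as G1, then `scale_k`
#' stride-2 downblocks halving the resolution, residual blocks, and a 7x7
#' output convolution with tanh. Maps `2^k n x 2^k n` micro-CT-scale input
#' to an `n x n` clinical-scale image.
#'
#' @inheritParams build_generator_sr
#' @return A generator network object.
#' @export
build_generator_down <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  layers <- c(head_layers(cfg),
              unlist(lapply(seq_len(cfg$scale_k), function(i) downblock(cfg)),
                     recursive = FALSE),
              resblock_layers(cfg),
              tail_layers(cfg))
  new_net(cfg, layers, "G2", -cfg$scale_k)
}

#' Build a patch discriminator
#'
#' A PatchGAN-style discriminator: stride-2 convolution stages (kernel 4,
#' LeakyReLU 0.2, channel width doubling from `base_channels`), a stride-1
#' stage, and a final 1-channel convolution emitting a 2-D map of real/fake
#' scores over overlapping receptive fields. The number of stride-2 stages
#' adapts to the input size (4 at 256 pixels, fewer for small inputs) so the
#' score map always has spatial extent.
#'
#' @param domain_size Side length in pixels of the images this discriminator
#'   judges (>= 16).
#' @param base_channels First-stage width (default 64).
#' @param norm `"batch"` or `"instance"`.
#' @param seed Optional integer seed for weight initialization.
#' @return A discriminator network object.
#' @export
build_discriminator <- function(domain_size, base_channels = 64L,
                                norm = c("batch", "instance"), seed = NULL) {
  norm <- match.arg(norm)
  domain_size <- as.integer(domain_size)
  if (domain_size < 16L)
    stop("build_discriminator: domain_size must be >= 16")
  if (!is.null(seed)) set.seed(seed)
  # 4 stride-2 stages at 256 px (70x70 receptive field, ~30x30 score map);
  # smaller domains keep the same relative locality so the score map stays
  # dense and per-element adversarial gradients keep their full-scale
  # balance against the pixel losses
  n_down <- max(0L, min(4L, as.integer(floor(log2(domain_size / 16)))))
  C <- as.integer(base_channels)
  layers <- list(layer_conv(4L, 4L, 1L, C,
                            stride = if (n_down > 0L) 2L else 1L, pad = 1L,
                            pad_type = "zero"),
                 layer_act("lrelu"))
  cin <- C
  for (i in seq_len(max(0L, n_down - 1L))) {
    cout <- min(cin * 2L, 8L * C)
    layers <- c(layers, list(
      layer_conv(4L, 4L, cin, cout, stride = 2L, pad = 1L, pad_type = "zero"),
      layer_norm(cout, norm),
      layer_act("lrelu")))
    cin <- cout
  }
  cout <- min(cin * 2L, 8L * C)
  layers <- c(layers, list(
    layer_conv(4L, 4L, cin, cout, stride = 1L, pad = 1L, pad_type = "zero"),
    layer_norm(cout, norm),
    layer_act("lrelu"),
    layer_conv(4L, 4L, cout, 1L, stride = 1L, pad = 1L, pad_type = "zero")))
  net <- new_net(NULL, layers, "D", 0L)
  net$domain_size <- domain_size
  net
}

#' Build an ablation generator variant
#'
#' `"sr_with_downblocks"`: head convolutions, `k` stride-2 downblocks (a
#' 32x32 input at k=3 is collapsed to a 4x4 bottleneck), residual blocks,
#' then `2k` sub-pixel shuffling stages, so the output is still `2^k` times
#' the input. `"upblocks_baseline"`: the conventional cycle-consistent
#' translation generator (head, `k` downblocks, resblocks, `k` upblocks)
#' with `k` additional upblocks appended so the output is `2^k` times the
#' input; upblocks are realized as nearest-upsample + convolution.
#'
#' @inheritParams build_generator_sr
#' @param cfg A [network_config()] with an ablation `variant`.
#' @return A generator network object.
#' @export
build_variant <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$scale_k
  if (cfg$variant == "sr_with_downblocks") {
    layers <- c(head_layers(cfg),
                unlist(lapply(seq_len(k), function(i) downblock(cfg)),
                       recursive = FALSE),
                resblock_layers(cfg),
                unlist(lapply(seq_len(2L * k), function(i)
                  upsample_stage(cfg)), recursive = FALSE),
                tail_layers(cfg))
  } else if (cfg$variant == "upblocks_baseline") {
    layers <- c(head_layers(cfg),
                unlist(lapply(seq_len(k), function(i) downblock(cfg)),
                       recursive = FALSE),
                resblock_layers(cfg),
                unlist(lapply(seq_len(2L * k), function(i)
                  upblock_resize(cfg)), recursive = FALSE),
                tail_layers(cfg))
  } else {
    stop("build_variant: cfg$variant must be an ablation variant")
  }
  new_net(cfg, layers, "G1", k)
}

#' Build the full four-network bundle
#'
#' Constructs G1 (super-resolution), G2 (downscaling), D1 (discriminator on
#' the micro/high-resolution domain) and D2 (discriminator on the
#' clinical/low-resolution domain), with seeded weight initialization.
#'
#' @param cfg A [network_config()].
#' @param lr_size Side length of the low-resolution training patches.
#' @param d_channels Discriminator base width (defaults to
#'   `cfg$base_channels`).
#' @param seed Integer seed for weight initialization.
#' @return A list with elements `G1`, `G2`, `D1`, `D2`.
#' @export
build_networks <- function(cfg, lr_size = 32L, d_channels = NULL,
                           seed = 1L) {
  if (is.null(d_channels)) d_channels <- cfg$base_channels
  set.seed(seed)
  G1 <- if (cfg$variant == "sr_no_downblocks") build_generator_sr(cfg)
        else build_variant(cfg)
  G2 <- build_generator_down(cfg)
  D1 <- build_discriminator(max(16L, lr_size * cfg$scale), d_channels,
                            cfg$norm)
  D2 <- build_discriminator(max(16L, lr_size), d_channels, cfg$norm)
  list(G1 = G1, G2 = G2, D1 = D1, D2 = D2)
}

#' Run a network forward in inference mode
#'
#' Normalization layers use their running statistics; no caches are kept.
#'
#' @param net A network object.
#' @param x Matrix, 3-D or 4-D array input.
#' @return Output array of dim `(H', W', C', N)`.
#' @export
net_predict <- function(net, x) {
  net_forward(net, x, train = FALSE)$y
}
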