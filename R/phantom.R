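# Synthetic lung phantoms for the two CT domains.
#
# The micro-domain phantom emulates what micro-CT of fixed lung shows at
# ~50 um: bright vessel cross-sections (disks), bronchi (annular walls with
# dark air lumina) and granular alveolar texture, with a two-mode intensity
# histogram concentrated in the upper part of the normalized range. The
# clinical-domain counterpart is produced by a forward model (blur ->
# average-pool -> monotone intensity remap -> noise) whose broad output
# histogram emulates the clinical H.U. distribution. No CT reconstruction
# physics is simulated.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Phantom generation settings
#'
#' Defaults define the study conditions: 256-pixel high-resolution phantoms
#' and 8x scale (matching 32x32 clinical patches), micro-domain intensity
#' modes at 0.55 (tissue/vessel) and -0.15 (air) of the normalized range,
#' a 1.5-pixel Gaussian PSF and 0.02 additive noise for the clinical
#' forward model.
#'
#' @param hr_size High-resolution side in pixels (divisible by `scale`).
#' @param scale Integer downscale factor `s` between the domains.
#' @param n_vessels,n_bronchi Integer ranges `c(min, max)` of structures.
#' @param alveolar_grain Correlation length (pixels) of the alveolar
#'   texture.
#' @param air_fraction Fraction of alveolar background that is air.
#' @param tissue_mode,air_mode Centres of the micro-domain intensity modes.
#' @param psf_sigma Gaussian blur sigma (HR pixels) of the forward model.
#' @param noise_sigma Additive Gaussian noise sd of the forward model.
#' @param seed Default seed used when an operation is not given one.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(hr_size = 256L, scale = 8L,
                         n_vessels = c(2L, 5L), n_bronchi = c(1L, 3L),
                         alveolar_grain = 3, air_fraction = 0.45,
                         tissue_mode = 0.55, air_mode = -0.15,
                         psf_sigma = 1.5, noise_sigma = 0.02, seed = 1L) {
  hr_size <- as.integer(hr_size); scale <- as.integer(scale)
  stopifnot(hr_size >= 16L, scale >= 2L, psf_sigma >= 0, noise_sigma >= 0,
            air_fraction > 0, air_fraction < 1)
  if (hr_size %% scale != 0L)
    stop("phantom_spec: hr_size must be divisible by scale")
  structure(list(hr_size = hr_size, scale = scale,
                 n_vessels = as.integer(n_vessels),
                 n_bronchi = as.integer(n_bronchi),
                 alveolar_grain = alveolar_grain,
                 air_fraction = air_fraction,
                 tissue_mode = tissue_mode, air_mode = air_mode,
                 psf_sigma = psf_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one micro-domain high-resolution phantom
#'
#' A pure function of `(spec, seed)`: granular alveolar background (smoothed
#' noise thresholded into tissue/air at the two micro-domain modes), at
#' least one bright vessel disk and at least one bronchus (annulus with
#' dark lumen). Structure metadata (centres, radii, wall/lumen values) is
#' attached as `attr(, "structures")`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A micro-domain [image_patch()] of side `spec$hr_size`.
#' @export
generate_micro_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  n <- spec$hr_size
  if (n < 16L) stop("generate_micro_phantom: hr_size too small")
  with_seed(seed, {
    ## alveolar background: smoothed white noise thresholded into air pockets
    g <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), spec$alveolar_grain)
    thr <- stats::quantile(g, spec$air_fraction)
    img <- matrix(spec$tissue_mode, n, n)
    img[g < thr] <- spec$air_mode
    img <- img + 0.04 * matrix(stats::rnorm(n * n), n, n)

    cx <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    cy <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    n_v <- sample(spec$n_vessels[1]:spec$n_vessels[2], 1L)
    n_b <- sample(spec$n_bronchi[1]:spec$n_bronchi[2], 1L)
    vessels <- list(); bronchi <- list()
    for (i in seq_len(n_v)) {
      c0 <- stats::runif(2, 0.15 * n, 0.85 * n)
      r <- stats::runif(1, 0.02 * n, 0.06 * n)
      val <- stats::runif(1, 0.72, 0.85)
      img[(cy - c0[1])^2 + (cx - c0[2])^2 <= r^2] <- val
      vessels[[i]] <- list(center = c0, radius = r, value = val)
    }
    for (i in seq_len(n_b)) {
      c0 <- stats::runif(2, 0.2 * n, 0.8 * n)
      r_in <- stats::runif(1, 0.04 * n, 0.10 * n)
      wall <- stats::runif(1, 0.25, 0.5) * r_in
      wall_val <- stats::runif(1, 0.62, 0.75)
      lumen_val <- stats::runif(1, -0.35, -0.2)
      d2 <- (cy - c0[1])^2 + (cx - c0[2])^2
      img[d2 <= (r_in + wall)^2] <- wall_val
      img[d2 <= r_in^2] <- lumen_val
      bronchi[[i]] <- list(center = c0, r_in = r_in, wall = wall,
                           wall_value = wall_val, lumen_value = lumen_val)
    }
    img <- pmin(pmax(img, -1), 1)
    out <- image_patch(img, intensity_domain("micro"))
    attr(out, "structures") <- list(vessels = vessels, bronchi = bronchi)
    out
  })
}

# Monotone piecewise-linear intensity remap micro -> clinical-like. Both
# modalities image the same attenuation, so the map shifts and compresses the
# modes (keeping the domains' pooled histograms clearly separated) while the
# dominant information loss of the forward model stays in resolution.
clinical_remap <- function(v, spec) {
  xs <- c(-1, spec$air_mode, spec$tissue_mode, 1)
  ys <- c(-1, spec$air_mode - 0.30, spec$tissue_mode - 0.30, 0.75)
  stats::approx(xs, ys, xout = v, rule = 2)$y
}

#' Degrade a micro phantom to its clinical-domain counterpart
#'
#' The forward model standing in for clinical acquisition: Gaussian blur
#' (`psf_sigma`), average-pooling by `scale`, a fixed monotone intensity
#' remap onto a broad clinical-like distribution (monotone, so structure
#' ordering is preserved across domains), then seeded additive Gaussian
#' noise, clipped to `[-1, 1]`.
#'
#' @param hr A micro-domain [image_patch()] (normalized).
#' @param spec A [phantom_spec()].
#' @param seed Seed for the noise (defaults to `spec$seed`); ignored when
#'   `noise_sigma = 0`.
#' @return A clinical-domain [image_patch()] of side `hr_size / scale`.
#' @export
degrade_to_clinical <- function(hr, spec = phantom_spec(), seed = spec$seed) {
  m <- as_image_array(hr)
  if (min(m) < -1 - 1e-9 || max(m) > 1 + 1e-9)
    stop("degrade_to_clinical: input must be normalized")
  m <- gaussian_blur(m, spec$psf_sigma)
  m <- average_pool_downsample(m, spec$scale)
  m <- matrix(clinical_remap(m, spec), nrow(m), ncol(m))
  if (spec$noise_sigma > 0)
    m <- m + with_seed(seed,
      matrix(stats::rnorm(length(m), 0, spec$noise_sigma), nrow(m), ncol(m)))
  m <- pmin(pmax(m, -1), 1)
  image_patch(m, intensity_domain("clinical"))
}

#' Build unpaired training sets for the two domains
#'
#' Micro-domain patches come from one pool of phantom seeds and
#' clinical-domain patches from a disjoint pool (each generated as an
#' independent phantom and pushed through the forward model), so there is
#' no hidden pairing between the two sets — the unpaired condition the
#' method is designed for. Manifests record the provenance seeds.
#'
#' @param spec A [phantom_spec()].
#' @param n_clinical,n_micro Patch counts (>= 1).
#' @param seed Master seed; the two seed pools are derived from it.
#' @return List `clinical` (LR [image_patch()]s), `micro` (HR patches),
#'   `manifest` (data frame: kind, index, seed).
#' @export
make_unpaired_sets <- function(spec = phantom_spec(), n_clinical, n_micro,
                               seed = spec$seed) {
  stopifnot(n_clinical >= 1L, n_micro >= 1L)
  seeds_c <- seed + seq_len(n_clinical)
  seeds_m <- seed + 100000L + seq_len(n_micro)
  if (length(intersect(seeds_c, seeds_m)))
    stop("make_unpaired_sets: seed pools overlap; reduce counts")
  clinical <- lapply(seeds_c, function(s)
    degrade_to_clinical(generate_micro_phantom(spec, s), spec, seed = s))
  micro <- lapply(seeds_m, function(s) generate_micro_phantom(spec, s))
  manifest <- data.frame(
    kind = rep(c("clinical", "micro"), c(n_clinical, n_micro)),
    index = c(seq_len(n_clinical), seq_len(n_micro)),
    seed = c(seeds_c, seeds_m))
  list(clinical = clinical, micro = micro, manifest = manifest)
}

#' Build a paired evaluation set
#'
#' `n` phantom pairs `(hr, lr = degrade_to_clinical(hr))` from a seed pool
#' disjoint from the training pools. Used only for evaluation and oracle
#' checks — never for training the unpaired objective.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of pairs.
#' @param seed Master seed.
#' @return List of `phantom_pair` objects (`hr`, `lr`, `seed`).
#' @export
make_paired_eval_set <- function(spec = phantom_spec(), n, seed = spec$seed) {
  stopifnot(n >= 1L)
  seeds <- seed + 200000L + seq_len(n)
  lapply(seeds, function(s) {
    hr <- generate_micro_phantom(spec, s)
    structure(list(hr = hr, lr = degrade_to_clinical(hr, spec, seed = s),
                   seed = s), class = "phantom_pair")
  })
}
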