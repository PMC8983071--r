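#' Intensity domain of a CT image
#'
#' A CT intensity domain couples a domain name with the clipping window used
#' before normalization. The clinical domain is on the Hounsfield scale and
#' defaults to the window \eqn{[-1000, 2500]} H.U. (air to bone); the micro-CT
#' domain is on a scanner-specific scale and defaults to \eqn{[0, 15000]}
#' (air to dense tumour tissue). Intensities are clipped to the window and
#' mapped affinely onto \eqn{[-1, 1]}.
#'
#' @param name `"clinical"` or `"micro"`.
#' @param clip_low,clip_high Clipping window in native units; defaults depend
#'   on `name`.
#' @return An object of class `intensity_domain`.
#' @export
#' @examples
#' intensity_domain("clinical")
#' intensity_domain("micro", clip_high = 12000)
intensity_domain <- function(name = c("clinical", "micro"),
                             clip_low = NULL, clip_high = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    clinical = c(-1000, 2500),
    micro    = c(0, 15000))
  if (is.null(clip_low))  clip_low  <- defaults[1]
  if (is.null(clip_high)) clip_high <- defaults[2]
  stopifnot(is.numeric(clip_low), is.numeric(clip_high), length(clip_low) == 1,
            length(clip_high) == 1, is.finite(clip_low), is.finite(clip_high))
  if (clip_low >= clip_high)
    stop("intensity_domain: clip_low must be < clip_high")
  structure(list(name = name, clip_low = clip_low, clip_high = clip_high),
            class = "intensity_domain")
}

#' @export
print.intensity_domain <- function(x, ...) {
  cat(sprintf("<intensity_domain> %s, clip [%g, %g]\n",
              x$name, x$clip_low, x$clip_high))
  invisible(x)
}

#' A 3-D CT volume with voxel spacing and domain
#'
#' Volumes are indexed `(z, y, x)`, 0.6 mm-scale for the clinical domain and
#' ~50 um-scale for micro-CT; intensities are native (unnormalized).
#'
#' @param data 3-D numeric array, dims `(z, y, x)`.
#' @param spacing Numeric length-3 voxel spacing in mm, `(z, y, x)`.
#' @param domain An [intensity_domain()].
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, domain) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            all(dim(data) >= 1L), is.numeric(spacing), length(spacing) == 3L,
            inherits(domain, "intensity_domain"))
  if (any(spacing <= 0)) stop("ct_volume: spacing components must be > 0")
  structure(list(data = data, spacing = as.numeric(spacing), domain = domain),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s, %s voxels, spacing %s mm\n", x$domain$name,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' A 2-D image patch
#'
#' The unit of training and inference: a square normalized grayscale patch
#' (origin top-left, row-major interpretation of `data[row, col]`) tagged
#' with its intensity domain.
#'
#' @param data 2-D numeric matrix.
#' @param domain An [intensity_domain()].
#' @param normalized Logical; if `TRUE` all values must lie in `[-1, 1]`.
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(data, domain, normalized = TRUE) {
  stopifnot(is.matrix(data), is.numeric(data),
            inherits(domain, "intensity_domain"))
  if (anyNA(data) || any(!is.finite(data)))
    stop("image_patch: non-finite values")
  if (normalized && (min(data) < -1 - 1e-9 || max(data) > 1 + 1e-9))
    stop("image_patch: normalized patch has values outside [-1, 1]")
  structure(list(data = data, domain = domain, normalized = normalized),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch> %s, %dx%d, %s\n", x$domain$name,
              nrow(x$data), ncol(x$data),
              if (x$normalized) "normalized" else "native"))
  invisible(x)
}

#' A binary mask aligned to an image or volume
#'
#' @param data Logical array (2-D or 3-D).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data) {
  stopifnot(is.array(data) || is.matrix(data), is.logical(data))
  structure(list(data = data), class = "binary_mask")
}

as_image_array <- function(x) {
  if (inherits(x, "ct_volume")) x$data
  else if (inherits(x, "image_patch")) x$data
  else x
}

#' Normalize CT intensities to [-1, 1]
#'
#' Clips intensities to the domain window and maps them affinely so that
#' `clip_low` becomes -1 and `clip_high` becomes +1. For the clinical
#' defaults, -1000 H.U. (air) maps to -1 and 2500 H.U. (bone) to +1; the map
#' is monotone and exactly invertible on the clipped range via
#' [denormalize_intensity()].
#'
#' @param x Numeric array/matrix, [ct_volume()] or [image_patch()] in native
#'   units.
#' @param domain An [intensity_domain()]; taken from `x` when `x` carries one.
#' @return Numeric array of the same shape with values in `[-1, 1]`.
#' @export
#' @examples
#' d <- intensity_domain("clinical")
#' normalize_intensity(c(-1500, -1000, 750, 2500), d)  # -1 -1 0 1
normalize_intensity <- function(x, domain = NULL) {
  if (is.null(domain)) {
    if (inherits(x, "ct_volume") || inherits(x, "image_patch")) domain <- x$domain
    else stop("normalize_intensity: domain required for raw arrays")
  }
  stopifnot(inherits(domain, "intensity_domain"))
  a <- as_image_array(x)
  bad <- which(!is.finite(a))
  if (length(bad))
    stop(sprintf("normalize_intensity: non-finite value at index %d", bad[1]))
  a <- pmin(pmax(a, domain$clip_low), domain$clip_high)
  2 * (a - domain$clip_low) / (domain$clip_high - domain$clip_low) - 1
}

#' Invert intensity normalization
#'
#' Exact inverse of [normalize_intensity()] on the clipped range: -1 maps
#' back to `clip_low` and +1 to `clip_high`.
#'
#' @param a Numeric array with values in `[-1, 1]` (tolerance 1e-6).
#' @param domain An [intensity_domain()].
#' @return Array of native-unit intensities.
#' @export
denormalize_intensity <- function(a, domain) {
  stopifnot(inherits(domain, "intensity_domain"))
  a <- as_image_array(a)
  if (min(a) < -1 - 1e-6 || max(a) > 1 + 1e-6)
    stop("denormalize_intensity: values outside [-1, 1]")
  a <- pmin(pmax(a, -1), 1)
  domain$clip_low + (a + 1) / 2 * (domain$clip_high - domain$clip_low)
}
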