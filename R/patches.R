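#' Randomly extract normalized training patches
#'
#' Samples `n` square patches uniformly over all valid top-left positions
#' across the axial slices of a volume (or slice stack). With a mask, a
#' position is accepted only when at least half of the patch pixels lie
#' inside the mask, which keeps all-background patches out of the training
#' set. Patches are returned intensity-normalized to `[-1, 1]`; sampling is
#' a pure function of the seed.
#'
#' @param v A [ct_volume()] (native intensities) or a 3-D array of
#'   already-normalized slices `(z, y, x)` with `domain` given.
#' @param size Patch side in pixels (default 32).
#' @param n Number of patches (default 2000, the per-case count of the main
#'   configuration).
#' @param seed Integer seed.
#' @param mask Optional [binary_mask()] aligned to the volume.
#' @param domain Required when `v` is a raw normalized array.
#' @return List of `n` [image_patch()]es; positions in
#'   `attr(, "manifest")` (data frame: z, y, x, 1-based top-left).
#' @export
extract_patches <- function(v, size = 32L, n = 2000L, seed = 1L,
                            mask = NULL, domain = NULL) {
  size <- as.integer(size); n <- as.integer(n)
  stopifnot(n >= 1L, size >= 2L)
  if (inherits(v, "ct_volume")) {
    domain <- v$domain
    vol <- normalize_intensity(v$data, domain)
  } else {
    stopifnot(length(dim(v)) == 3L, inherits(domain, "intensity_domain"))
    vol <- v
  }
  d <- dim(vol)
  if (size > d[2] || size > d[3])
    stop("extract_patches: patch size does not fit inside the slices")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "binary_mask"), all(dim(mask$data) == d))
  }
  max_y <- d[2] - size + 1L; max_x <- d[3] - size + 1L
  with_seed(seed, {
    out <- vector("list", n)
    man <- matrix(0L, n, 3L)
    got <- 0L; tries <- 0L; cap <- 1000L * n
    while (got < n) {
      tries <- tries + 1L
      if (tries > cap)
        stop(sprintf(
          "extract_patches: no valid position after %d rejections (acceptance rate %.2g)",
          tries, got / tries))
      z <- sample.int(d[1], 1L)
      y <- sample.int(max_y, 1L)
      x <- sample.int(max_x, 1L)
      if (!is.null(mask)) {
        cov <- mean(mask$data[z, y:(y + size - 1L), x:(x + size - 1L)])
        if (cov < 0.5) next
      }
      got <- got + 1L
      out[[got]] <- image_patch(
        matrix(vol[z, y:(y + size - 1L), x:(x + size - 1L)], size, size),
        domain)
      man[got, ] <- c(z, y, x)
    }
    attr(out, "manifest") <- data.frame(z = man[, 1], y = man[, 2],
                                        x = man[, 3])
    out
  })
}

#' Write / read a patch set as TIFFs with a manifest
#'
#' Each normalized patch is stored as a 16-bit grayscale TIFF (values
#' linearly mapped from `[-1, 1]` to `[0, 65535]`) next to a CSV manifest
#' (filename, domain, source position if known, seed).
#'
#' @param patches List of [image_patch()]es (e.g. from
#'   [extract_patches()]).
#' @param dir Output directory (created).
#' @param prefix Filename prefix.
#' @param seed Seed recorded in the manifest.
#' @param source Source volume label recorded in the manifest.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_patch_set <- function(patches, dir, prefix = "patch", seed = NA,
                            source = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- attr(patches, "manifest")
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    fn <- sprintf("%s_%05d.tif", prefix, i)
    tiff::writeTIFF((as_image_array(p) + 1) / 2,
                    file.path(dir, fn), bits.per.sample = 16L)
    data.frame(filename = fn, domain = p$domain$name, source = source,
               z = if (is.null(man)) NA_integer_ else man$z[i],
               y = if (is.null(man)) NA_integer_ else man$y[i],
               x = if (is.null(man)) NA_integer_ else man$x[i],
               seed = seed)
  })
  mp <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(do.call(rbind, rows), mp, row.names = FALSE)
  invisible(mp)
}

#' @rdname write_patch_set
#' @param manifest Path to a manifest CSV written by [write_patch_set()].
#' @export
read_patch_set <- function(manifest) {
  man <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    m <- tiff::readTIFF(file.path(dir, man$filename[i]))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    image_patch(m * 2 - 1, intensity_domain(man$domain[i]))
  })
}
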