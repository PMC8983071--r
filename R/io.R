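# Volume readers/writers. NIfTI goes through RNifti; MetaImage (.mhd/.mha)
# is parsed directly (plain key = value header + raw voxel block), since no
# installed package reads it. Volumes are reoriented to (z, y, x) indexing.

#' Read a CT volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or MetaImage (`.mhd` with sidecar raw,
#' or self-contained `.mha`) into a [ct_volume()] with `(z, y, x)` indexing
#' and native intensities.
#'
#' @param path File path.
#' @param domain An [intensity_domain()] tag for the volume.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path, domain) {
  stopifnot(inherits(domain, "intensity_domain"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)            # (x, y, z)
    arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
    ct_volume(arr, rev(sp[1:3]), domain)
  } else if (grepl("\\.(mhd|mha)$", lower)) {
    read_metaimage(path, domain)
  } else {
    stop("read_ct_volume: unsupported format (use .nii/.nii.gz/.mhd/.mha)")
  }
}

meta_type <- function(t) {
  switch(t,
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
    MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
    MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE),
    stop("read_metaimage: unsupported ElementType ", t))
}

read_metaimage <- function(path, domain) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("read_metaimage: no ElementDataFile in header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])     # (x, y, z)
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, 3)
  ty <- meta_type(hdr$ElementType)
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    raw <- readBin(con, ty$what, n = n, size = ty$size, signed = ty$signed,
                   endian = "little")
  } else {
    rp <- file.path(dirname(path), data_file)
    raw <- readBin(rp, ty$what, n = n, size = ty$size, signed = ty$signed,
                   endian = "little")
  }
  if (length(raw) < n) stop("read_metaimage: truncated voxel data")
  arr <- aperm(array(as.numeric(raw), dims), c(3, 2, 1))      # -> (z, y, x)
  ct_volume(arr, rev(sp), domain)
}

#' Write a CT volume as NIfTI
#'
#' @param v A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  arr <- aperm(v$data, c(3, 2, 1))                            # -> (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(v$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a normalized 2-D image as 16-bit TIFF
#'
#' Values in `[-1, 1]` are mapped linearly to `[0, 65535]`.
#'
#' @param img Matrix or [image_patch()] with values in `[-1, 1]`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  m <- as_image_array(img)
  if (min(m) < -1 - 1e-9 || max(m) > 1 + 1e-9)
    stop("write_image_tiff: values outside [-1, 1]")
  tiff::writeTIFF(pmin(pmax((m + 1) / 2, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}
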