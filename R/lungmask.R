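#' Coarse lung segmentation by region growing
#'
#' Segments the lungs from a clinical chest CT volume in native Hounsfield
#' units: voxels below the air/parenchyma threshold (-400 H.U.) are grown
#' into 6-connected components; components touching the volume border
#' (outside-body air) are discarded; the remainder is the coarse lung mask,
#' closed by per-slice morphological hole filling so vessels inside the
#' lung are included. Idempotent under a second hole-filling pass.
#'
#' @param v A clinical-domain [ct_volume()] in native H.U.
#' @param threshold Growing threshold in H.U. (default -400).
#' @param min_voxels Minimum component size kept (default 50).
#' @return A [binary_mask()] with the shape of the volume.
#' @export
lung_mask <- function(v, threshold = -400, min_voxels = 50L) {
  stopifnot(inherits(v, "ct_volume"))
  if (v$domain$name != "clinical")
    stop("lung_mask: expects a clinical-domain volume in H.U.")
  low <- v$data < threshold
  if (!any(low)) stop("no lung region")
  lab <- .label_components_3d(low)
  d <- dim(lab)
  # exclude outside-body air: components touching an in-plane (y/x) border;
  # axial (z) faces are not used, since lungs usually span the cropped extent
  border <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border <- setdiff(border, 0L)
  sizes <- tabulate(lab)
  keep <- setdiff(which(sizes >= min_voxels), border)
  if (!length(keep)) stop("no lung region")
  mask <- array(lab %in% keep, d)
  for (z in seq_len(d[1]))
    mask[z, , ] <- fill_holes_slice(mask[z, , , drop = TRUE])
  binary_mask(mask)
}

fill_holes_slice <- function(m) {
  f <- EBImage::fillHull(matrix(as.integer(m), nrow(m), ncol(m)))
  matrix(as.logical(f), nrow(m), ncol(m))
}
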