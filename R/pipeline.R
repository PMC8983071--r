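#' Tiling grid for whole-slice inference
#'
#' @param tile Tile side in LR pixels (default 32).
#' @param overlap Overlap between neighbouring tiles in LR pixels
#'   (default 8, must be < `tile`).
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(tile = 32L, overlap = 8L) {
  tile <- as.integer(tile); overlap <- as.integer(overlap)
  stopifnot(tile >= 4L, overlap >= 0L)
  if (overlap >= tile) stop("tile_grid: overlap must be < tile size")
  structure(list(tile = tile, overlap = overlap), class = "tile_grid")
}

tile_starts <- function(n, tile, overlap) {
  if (n < tile) stop("infer_slice: slice smaller than one tile")
  stride <- tile - overlap
  unique(c(seq(1L, n - tile + 1L, by = stride), n - tile + 1L))
}

# 1-D feather profile in SR pixels: linear ramps of length `ramp` at both
# ends, never zero so normalization is well defined everywhere.
feather_1d <- function(len, ramp) {
  w <- rep(1, len)
  if (ramp > 0) {
    r <- seq_len(min(ramp, len)) / (ramp + 1)
    w[seq_along(r)] <- r
    w[len + 1 - seq_along(r)] <- pmin(w[len + 1 - seq_along(r)], r)
  }
  w
}

#' Tiled whole-slice super-resolution
#'
#' Super-resolves a full clinical slice by running G1 on overlapping tiles
#' and blending them with linear feathering in the overlaps; accumulated
#' blend weights are normalized so they sum to 1 at every output pixel,
#' which makes the stitching exact wherever overlapping tiles agree (and
#' seam-free on constant inputs for any constant-preserving generator).
#'
#' @param slice Normalized 2-D clinical image (matrix or [image_patch()]).
#' @param model An [srcycle_model()] or G1 network object.
#' @param grid A [tile_grid()].
#' @param scale Output scale `2^k`; inferred from the model when possible.
#' @return Super-resolved matrix of size `dim(slice) * scale`.
#' @export
infer_slice <- function(slice, model, grid = tile_grid(), scale = NULL) {
  m <- as_image_array(slice)
  if (min(m) < -1 - 1e-9 || max(m) > 1 + 1e-9)
    stop("infer_slice: slice must be normalized to [-1, 1]")
  G1 <- if (inherits(model, "srcycle_model")) model$nets$G1 else model
  if (is.null(scale)) {
    if (is.function(G1)) stop("infer_slice: scale required for a stub function")
    scale <- 2L^G1$scale_exp
  }
  sr_fun <- if (is.function(G1)) G1 else function(t) {
    y <- net_predict(G1, t)
    matrix(y, dim(y)[1], dim(y)[2])
  }
  t <- grid$tile; o <- grid$overlap
  ys <- tile_starts(nrow(m), t, o)
  xs <- tile_starts(ncol(m), t, o)
  ts <- t * scale; ro <- o * scale
  w1 <- feather_1d(ts, ro)
  wt <- outer(w1, w1)
  num <- matrix(0, nrow(m) * scale, ncol(m) * scale)
  den <- matrix(0, nrow(m) * scale, ncol(m) * scale)
  for (y0 in ys) for (x0 in xs) {
    tl <- m[y0:(y0 + t - 1L), x0:(x0 + t - 1L)]
    sr <- sr_fun(tl)
    if (!all(dim(sr) == ts))
      stop("infer_slice: generator output does not match tile * scale")
    ry <- ((y0 - 1L) * scale + 1L):((y0 - 1L) * scale + ts)
    rx <- ((x0 - 1L) * scale + 1L):((x0 - 1L) * scale + ts)
    num[ry, rx] <- num[ry, rx] + wt * sr
    den[ry, rx] <- den[ry, rx] + wt
  }
  num / den
}

## ---- run configuration -----------------------------------------------------

rc_known <- c("network", "training", "loss_weights", "phantom", "paths",
              "tile", "seed")

#' Load and validate a run configuration
#'
#' A single YAML file with sections `network`, `training`, `loss_weights`,
#' `phantom`, `tile`, `paths` and a top-level `seed`; every key is validated
#' against the corresponding constructor and unknown keys are rejected
#' before any computation. CLI-style overrides (a named list) are merged on
#' top.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides Named list of `section$key` overrides, e.g.
#'   `list(network = list(scale_k = 2))`.
#' @return A `run_config` list with instantiated configuration objects.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), rc_known)
  if (length(unknown))
    stop("run_config: unknown keys: ", paste(unknown, collapse = ", "))
  for (sec in names(overrides))
    raw[[sec]] <- utils::modifyList(raw[[sec]] %||% list(), overrides[[sec]])
  check_args <- function(args, fn, what) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop(sprintf("run_config: unknown %s keys: %s", what,
                   paste(bad, collapse = ", ")))
    args
  }
  net <- do.call(network_config,
                 check_args(raw$network %||% list(), network_config,
                            "network"))
  trn <- do.call(train_config,
                 check_args(raw$training %||% list(), train_config,
                            "training"))
  w <- do.call(loss_weights,
               check_args(raw$loss_weights %||% list(), loss_weights,
                          "loss_weights"))
  ph <- do.call(phantom_spec,
                check_args(raw$phantom %||% list(), phantom_spec, "phantom"))
  tg <- do.call(tile_grid,
                check_args(raw$tile %||% list(), tile_grid, "tile"))
  structure(list(network = net, training = trn, loss_weights = w,
                 phantom = ph, tile = tg,
                 seed = raw$seed %||% trn$seed,
                 paths = raw$paths %||% list()),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolved_config_yaml <- function(rc) {
  yaml::as.yaml(list(network = unclass(rc$network),
                     training = unclass(rc$training),
                     loss_weights = unclass(rc$loss_weights),
                     phantom = unclass(rc$phantom),
                     tile = unclass(rc$tile), seed = rc$seed))
}

## ---- pipeline commands -----------------------------------------------------

log_config <- function(rc, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(resolved_config_yaml(rc),
             file.path(out_dir, "resolved_config.yaml"))
}

#' Pipeline commands
#'
#' Idempotent orchestration entry points behind the command-line script:
#' each logs its fully resolved configuration into the output directory,
#' derives all randomness from the configured seed, and never mutates its
#' inputs.
#'
#' `run_make_phantoms` writes unpaired clinical/micro phantom patch sets
#' (16-bit TIFFs + CSV manifests). `run_train` trains on TIFF patch sets
#' (or freshly generated phantoms when `clinical_dir` is `NULL`) and writes
#' checkpoints plus a loss log. `run_infer` super-resolves every TIFF in a
#' directory with a trained checkpoint. `run_evaluate` runs the
#' bicubic-degradation protocol on a directory of HR TIFFs (or generated
#' phantoms) and writes the report as JSON/CSV.
#'
#' @param rc A [run_config()].
#' @param out_dir Output directory.
#' @param n_clinical,n_micro Patch counts for phantom generation.
#' @return The primary artifact of each command (invisibly): manifest
#'   paths, the trained model, output paths, or an `eval_report`.
#' @export
run_make_phantoms <- function(rc, out_dir, n_clinical = 100L,
                              n_micro = 100L) {
  log_config(rc, out_dir)
  sets <- make_unpaired_sets(rc$phantom, n_clinical, n_micro, seed = rc$seed)
  mc <- write_patch_set(sets$clinical, file.path(out_dir, "clinical"),
                        "clinical", seed = rc$seed, source = "phantom")
  mm <- write_patch_set(sets$micro, file.path(out_dir, "micro"),
                        "micro", seed = rc$seed, source = "phantom")
  utils::write.csv(sets$manifest, file.path(out_dir, "provenance.csv"),
                   row.names = FALSE)
  invisible(c(mc, mm))
}

#' @rdname run_make_phantoms
#' @param clinical_dir,micro_dir Manifest CSVs of training patch sets;
#'   `NULL` generates phantom sets on the fly.
#' @param d_channels Discriminator width override.
#' @export
run_train <- function(rc, out_dir, clinical_dir = NULL, micro_dir = NULL,
                      n_clinical = 64L, n_micro = 64L, d_channels = NULL) {
  log_config(rc, out_dir)
  if (is.null(clinical_dir)) {
    sets <- make_unpaired_sets(rc$phantom, n_clinical, n_micro,
                               seed = rc$seed)
    clinical <- sets$clinical; micro <- sets$micro
  } else {
    clinical <- read_patch_set(clinical_dir)
    micro <- read_patch_set(micro_dir)
  }
  model <- fit(clinical, micro, rc$training, rc$network, rc$loss_weights,
               out_dir = out_dir, d_channels = d_channels)
  invisible(model)
}

#' @rdname run_make_phantoms
#' @param checkpoint Path to a checkpoint written by [fit()].
#' @param in_dir Directory of input TIFFs.
#' @export
run_infer <- function(rc, out_dir, checkpoint, in_dir) {
  log_config(rc, out_dir)
  model <- load_checkpoint(checkpoint)
  files <- list.files(in_dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (!length(files)) stop("run_infer: no TIFF inputs in ", in_dir)
  outs <- vapply(files, function(f) {
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    sr <- infer_slice(m * 2 - 1, model, rc$tile)
    op <- file.path(out_dir, paste0("sr_", basename(f)))
    write_image_tiff(sr, op)
    op
  }, "")
  invisible(outs)
}

#' @rdname run_make_phantoms
#' @param hr_dir Directory of HR TIFFs for evaluation; `NULL` generates a
#'   paired phantom evaluation set.
#' @param n_eval Number of generated evaluation images when `hr_dir` is
#'   `NULL`.
#' @export
run_evaluate <- function(rc, out_dir, checkpoint, hr_dir = NULL,
                         n_eval = 20L) {
  log_config(rc, out_dir)
  model <- load_checkpoint(checkpoint)
  if (is.null(hr_dir)) {
    pairs <- make_paired_eval_set(rc$phantom, n_eval, seed = rc$seed)
    hr <- lapply(pairs, function(p) as_image_array(p$hr))
  } else {
    files <- list.files(hr_dir, pattern = "\\.tiff?$", full.names = TRUE)
    hr <- lapply(files, function(f) {
      m <- tiff::readTIFF(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m * 2 - 1
    })
  }
  rep <- evaluate_protocol(hr, model, scale = rc$network$scale)
  write_eval_report(rep, file.path(out_dir, "eval_report"))
  message(sprintf("mean PSNR %.2f dB  mean SSIM %.4f", rep$mean_psnr,
                  rep$mean_ssim))
  invisible(rep)
}
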