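#' Training configuration
#'
#' Optimization schedule of the full-scale configuration: Adam (betas 0.5/0.999),
#' learning rate 1e-5 held flat for 100 epochs then decayed linearly to 0 at
#' epoch 200, mini-batch 4. `patches_per_epoch` defaults to the full patch
#' set (one epoch = one pass).
#'
#' @param epochs Total epochs (default 200).
#' @param batch_size Mini-batch size (default 4).
#' @param lr0 Initial learning rate (default 1e-5).
#' @param decay_start_epoch Last epoch of the flat segment (default 100).
#' @param beta1,beta2 Adam moment coefficients (default 0.5, 0.999).
#' @param pool_size Fake-image history pool capacity (default 50; 0 disables).
#' @param seed Integer seed controlling all training randomness.
#' @param patches_per_epoch Patches consumed per epoch (`NULL` = all).
#' @param checkpoint_every Save a checkpoint every this many epochs.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 4L, lr0 = 1e-5,
                         decay_start_epoch = 100L, beta1 = 0.5,
                         beta2 = 0.999, pool_size = 50L, seed = 1L,
                         patches_per_epoch = NULL, checkpoint_every = 1L) {
  epochs <- as.integer(epochs)
  decay_start_epoch <- as.integer(decay_start_epoch)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr0 > 0,
            decay_start_epoch < epochs, pool_size >= 0L)
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 lr0 = lr0, decay_start_epoch = decay_start_epoch,
                 beta1 = beta1, beta2 = beta2,
                 pool_size = as.integer(pool_size), seed = as.integer(seed),
                 patches_per_epoch = patches_per_epoch,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr0` for epochs up to `decay_start_epoch`, then linear decay reaching 0
#' at the final epoch: with the defaults, 1e-5 from epoch 1 to 100, 5e-6 at
#' epoch 150, 0 at epoch 200.
#'
#' @param epoch 1-based epoch index within `[1, cfg$epochs]`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
#' @examples
#' lr_schedule(150, train_config())  # 5e-6
lr_schedule <- function(epoch, cfg = train_config()) {
  epoch <- as.numeric(epoch)
  if (any(epoch < 1 | epoch > cfg$epochs))
    stop(sprintf("lr_schedule: epoch out of range [1, %d]", cfg$epochs))
  ifelse(epoch <= cfg$decay_start_epoch, cfg$lr0,
         cfg$lr0 * (cfg$epochs - epoch) / (cfg$epochs - cfg$decay_start_epoch))
}

## ---- image pool ------------------------------------------------------------

image_pool <- function(capacity) {
  list(capacity = as.integer(capacity), images = list())
}

# Returns list(pool, images): for each fresh fake, either passes it through
# or (with prob 0.5 once the pool is full) swaps it against a stored one.
# Uses the ambient R RNG so training remains seed-deterministic.
pool_query <- function(pool, fakes) {
  if (pool$capacity == 0L) return(list(pool = pool, images = fakes))
  out <- vector("list", length(fakes))
  for (i in seq_along(fakes)) {
    img <- fakes[[i]]
    if (length(pool$images) < pool$capacity) {
      pool$images[[length(pool$images) + 1L]] <- img
      out[[i]] <- img
    } else if (stats::runif(1) > 0.5) {
      j <- sample.int(pool$capacity, 1L)
      out[[i]] <- pool$images[[j]]
      pool$images[[j]] <- img
    } else {
      out[[i]] <- img
    }
  }
  list(pool = pool, images = out)
}

## ---- model bundle ----------------------------------------------------------

#' Assemble a trainable model
#'
#' Bundles the four networks with their Adam states, fake-image pools, loss
#' weights and configurations into a single state object consumed by
#' [train_step()] and [fit()].
#'
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param w A [loss_weights()].
#' @param lr_size Low-resolution training patch side (default 32).
#' @param d_channels Discriminator base width (defaults to generator width).
#' @return An object of class `srcycle_model`.
#' @export
srcycle_model <- function(net_cfg, train_cfg = train_config(),
                          w = loss_weights(), lr_size = 32L,
                          d_channels = NULL) {
  nets <- build_networks(net_cfg, lr_size = lr_size, d_channels = d_channels,
                         seed = train_cfg$seed)
  structure(list(
    nets = nets, net_cfg = net_cfg, train_cfg = train_cfg, w = w,
    consts = ssim_constants(),
    opt = list(G1 = adam_init(), G2 = adam_init(),
               D1 = adam_init(), D2 = adam_init()),
    pools = list(hr = image_pool(train_cfg$pool_size),
                 lr = image_pool(train_cfg$pool_size)),
    lr_size = as.integer(lr_size), step = 0L, epoch = 0L),
    class = "srcycle_model")
}

#' @export
print.srcycle_model <- function(x, ...) {
  cat(sprintf("<srcycle_model> %dx scale, step %d, epoch %d\n",
              x$net_cfg$scale, x$step, x$epoch))
  invisible(x)
}

batch_tensor <- function(patches, idx = seq_along(patches)) {
  mats_to_tensor(lapply(patches[idx], as_image_array))
}

## ---- one optimization step -------------------------------------------------

#' One alternating training step
#'
#' Runs one joint generator update (G1 and G2, on the total objective) then
#' one update per discriminator using history-pooled fakes. Gradients are
#' exact: the SSIM/downsample/upsample/cycle/adversarial terms are
#' differentiated analytically and backpropagated through the generators,
#' and the adversarial generator term through the frozen discriminators.
#' Returns the pre-update loss breakdown.
#'
#' @param model An [srcycle_model()].
#' @param batch_x Clinical low-resolution batch, dim `(n, n, 1, B)`.
#' @param batch_y Micro high-resolution batch, dim `(sn, sn, 1, B)`.
#' @param lr Learning rate for this step.
#' @return List `model` (updated) and `losses` (a `loss_breakdown`).
#' @export
train_step <- function(model, batch_x, batch_y, lr) {
  s <- model$net_cfg$scale
  dx_ <- dim(batch_x); dy_ <- dim(batch_y)
  if (is.null(dx_) || length(dx_) != 4L || is.null(dy_) || length(dy_) != 4L)
    stop("train_step: batches must be (H, W, 1, B) arrays")
  if (dy_[1] != s * dx_[1] || dy_[2] != s * dx_[2])
    stop(sprintf("train_step: size mismatch, expected HR = %dx LR", s))
  B <- dx_[4]
  w <- model$w; consts <- model$consts
  G1 <- model$nets$G1; G2 <- model$nets$G2
  D1 <- model$nets$D1; D2 <- model$nets$D2

  ## ---- generator forward ----
  f1 <- net_forward(G1, batch_x, TRUE); G1 <- f1$net; x_sr <- f1$y
  f2 <- net_forward(G2, batch_y, TRUE); G2 <- f2$net; y_lr <- f2$y
  f3 <- net_forward(G2, x_sr, TRUE);    G2 <- f3$net; x_rec <- f3$y
  f4 <- net_forward(G1, y_lr, TRUE);    G1 <- f4$net; y_rec <- f4$y
  fd1 <- net_forward(D1, x_sr, TRUE); d1_fake <- fd1$y
  fd2 <- net_forward(D2, y_lr, TRUE); d2_fake <- fd2$y

  ## ---- losses (pre-update) ----
  xs <- tensor_to_mats(batch_x); ys <- tensor_to_mats(batch_y)
  xsrs <- tensor_to_mats(x_sr); ylrs <- tensor_to_mats(y_lr)
  LS1 <- mean(vapply(seq_len(B), function(i)
    ssim_loss(xs[[i]], xsrs[[i]], consts), 0))
  LS2 <- mean(vapply(seq_len(B), function(i)
    ssim_loss(ys[[i]], ylrs[[i]], consts), 0))
  LD <- mean(vapply(seq_len(B), function(i)
    downsample_loss(xs[[i]], xsrs[[i]]), 0))
  LU <- mean(vapply(seq_len(B), function(i)
    upsample_loss(ys[[i]], ylrs[[i]]), 0))
  Lgan_G1 <- adversarial_loss(NULL, d1_fake, "generator")
  Lgan_G2 <- adversarial_loss(NULL, d2_fake, "generator")
  Lcyc <- mean((batch_x - x_rec)^2) + mean((batch_y - y_rec)^2)
  losses <- structure(list(
    LS1 = LS1, LS2 = LS2, LD = LD, LU = LU, Lgan_G1 = Lgan_G1,
    Lgan_G2 = Lgan_G2, Lcyc = Lcyc,
    total = w$lambda1 * LS1 + w$lambda2 * LS2 + w$lambda3 * LD +
      w$lambda4 * LU + w$lambda5 * Lgan_G1 + w$lambda6 * Lgan_G2 +
      w$lambda7 * Lcyc), class = "loss_breakdown")

  ## ---- generator gradients ----
  # pixel-level terms on x_sr and y_lr
  g_xsr <- array(0, dim(x_sr)); g_ylr <- array(0, dim(y_lr))
  for (i in seq_len(B)) {
    gi <- matrix(0, dim(x_sr)[1], dim(x_sr)[2])
    if (w$lambda1 > 0) gi <- gi + w$lambda1 * ssim_loss_grad(xs[[i]], xsrs[[i]], consts)
    if (w$lambda3 > 0) gi <- gi + w$lambda3 * downsample_loss_grad(xs[[i]], xsrs[[i]])
    g_xsr[, , 1, i] <- gi / B
    hi <- matrix(0, dim(y_lr)[1], dim(y_lr)[2])
    if (w$lambda2 > 0) hi <- hi + w$lambda2 * ssim_loss_grad(ys[[i]], ylrs[[i]], consts)
    if (w$lambda4 > 0) hi <- hi + w$lambda4 * upsample_loss_grad(ys[[i]], ylrs[[i]])
    g_ylr[, , 1, i] <- hi / B
  }
  # cycle terms
  d_xrec <- w$lambda7 * 2 * (x_rec - batch_x) / length(batch_x)
  d_yrec <- w$lambda7 * 2 * (y_rec - batch_y) / length(batch_y)
  # adversarial terms, through frozen discriminators
  if (w$lambda5 > 0) {
    bd1 <- net_backward(D1, fd1$caches, w$lambda5 * adv_grad_gen(d1_fake))
    g_xsr <- g_xsr + bd1$dx
  }
  if (w$lambda6 > 0) {
    bd2 <- net_backward(D2, fd2$caches, w$lambda6 * adv_grad_gen(d2_fake))
    g_ylr <- g_ylr + bd2$dx
  }
  # back through the cycle passes first (their dx feeds the main passes)
  b3 <- net_backward(G2, f3$caches, d_xrec)   # grads for G2, dx -> x_sr
  b4 <- net_backward(G1, f4$caches, d_yrec)   # grads for G1, dx -> y_lr
  g_xsr <- g_xsr + b3$dx
  g_ylr <- g_ylr + b4$dx
  b1 <- net_backward(G1, f1$caches, g_xsr)
  b2 <- net_backward(G2, f2$caches, g_ylr)
  grads_G1 <- grads_add(b1$grads, b4$grads)
  grads_G2 <- grads_add(b2$grads, b3$grads)

  up <- adam_step(G1, grads_G1, model$opt$G1, lr,
                  model$train_cfg$beta1, model$train_cfg$beta2)
  G1 <- up$net; model$opt$G1 <- up$state
  up <- adam_step(G2, grads_G2, model$opt$G2, lr,
                  model$train_cfg$beta1, model$train_cfg$beta2)
  G2 <- up$net; model$opt$G2 <- up$state

  ## ---- discriminator updates (pooled fakes, generators frozen) ----
  q1 <- pool_query(model$pools$hr, xsrs); model$pools$hr <- q1$pool
  q2 <- pool_query(model$pools$lr, ylrs); model$pools$lr <- q2$pool
  fake_hr <- mats_to_tensor(q1$images)
  fake_lr <- mats_to_tensor(q2$images)

  fr <- net_forward(D1, batch_y, TRUE); D1 <- fr$net
  br <- net_backward(D1, fr$caches, adv_grad_disc_real(fr$y))
  ff <- net_forward(D1, fake_hr, TRUE); D1 <- ff$net
  bf <- net_backward(D1, ff$caches, adv_grad_disc_fake(ff$y))
  up <- adam_step(D1, grads_add(br$grads, bf$grads), model$opt$D1, lr,
                  model$train_cfg$beta1, model$train_cfg$beta2)
  D1 <- up$net; model$opt$D1 <- up$state

  fr <- net_forward(D2, batch_x, TRUE); D2 <- fr$net
  br <- net_backward(D2, fr$caches, adv_grad_disc_real(fr$y))
  ff <- net_forward(D2, fake_lr, TRUE); D2 <- ff$net
  bf <- net_backward(D2, ff$caches, adv_grad_disc_fake(ff$y))
  up <- adam_step(D2, grads_add(br$grads, bf$grads), model$opt$D2, lr,
                  model$train_cfg$beta1, model$train_cfg$beta2)
  D2 <- up$net; model$opt$D2 <- up$state

  model$nets <- list(G1 = G1, G2 = G2, D1 = D1, D2 = D2)
  model$step <- model$step + 1L
  list(model = model, losses = losses)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load a training checkpoint
#'
#' A checkpoint is a single archive holding all four networks' weights and
#' optimizer states, the image pools, the full network/training/loss
#' configuration (also embedded as YAML text), the epoch counter and the RNG
#' state, under a versioned schema. Restoring it and continuing reproduces
#' the uninterrupted run exactly.
#'
#' @param model An [srcycle_model()].
#' @param path File path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(schema = "srcycle-checkpoint-1", model = model,
             rng = if (exists(".Random.seed", envir = globalenv()))
               get(".Random.seed", envir = globalenv()) else NULL,
             config_text = yaml::as.yaml(list(
               network = unclass(model$net_cfg),
               training = unclass(model$train_cfg),
               loss_weights = unclass(model$w))))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "srcycle-checkpoint-1"))
    stop("load_checkpoint: unrecognized checkpoint schema")
  if (!is.null(ck$rng))
    assign(".Random.seed", ck$rng, envir = globalenv())
  ck$model
}

## ---- fit -------------------------------------------------------------------

#' Train on unpaired patch sets
#'
#' Iterates `epochs x ceil(patches_per_epoch / batch_size)` steps, shuffling
#' the clinical and micro patch sets independently every epoch (unpaired
#' sampling), calling [train_step()] with the scheduled learning rate,
#' appending a per-step loss log (CSV) and writing periodic checkpoints.
#' Fully deterministic under a fixed seed; resumable from a checkpoint.
#'
#' @param clinical_patches List of normalized clinical LR patches (matrices
#'   or [image_patch()]s), all `n x n`.
#' @param micro_patches List of normalized micro HR patches, all `sn x sn`.
#' @param train_cfg A [train_config()].
#' @param net_cfg A [network_config()].
#' @param w A [loss_weights()].
#' @param out_dir Directory for checkpoints and the loss log (created).
#' @param resume_from Optional checkpoint path to resume from.
#' @param d_channels Discriminator base width.
#' @param verbose Print per-epoch loss summaries.
#' @return The trained [srcycle_model()] (invisibly also saved as
#'   `checkpoint_final.rds` in `out_dir`).
#' @export
fit <- function(clinical_patches, micro_patches, train_cfg = train_config(),
                net_cfg = network_config(), w = loss_weights(),
                out_dir = tempfile("srcycle_run_"), resume_from = NULL,
                d_channels = NULL, verbose = FALSE) {
  if (length(clinical_patches) == 0L || length(micro_patches) == 0L)
    stop("fit: both patch sets must be non-empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_lr <- nrow(as_image_array(clinical_patches[[1]]))
  if (!is.null(resume_from)) {
    model <- load_checkpoint(resume_from)
  } else {
    model <- srcycle_model(net_cfg, train_cfg, w, lr_size = n_lr,
                           d_channels = d_channels)
    set.seed(train_cfg$seed)
  }
  ppe <- train_cfg$patches_per_epoch
  if (is.null(ppe)) ppe <- length(clinical_patches)
  steps_per_epoch <- ceiling(ppe / train_cfg$batch_size)
  log_path <- file.path(out_dir, "loss_log.csv")
  if (is.null(resume_from) && file.exists(log_path)) unlink(log_path)
  start_epoch <- model$epoch + 1L
  for (epoch in seq(start_epoch, train_cfg$epochs)) {
    lr <- lr_schedule(epoch, train_cfg)
    ix <- sample(rep_len(seq_along(clinical_patches), ppe))
    iy <- sample(rep_len(seq_along(micro_patches), ppe))
    rows <- vector("list", steps_per_epoch)
    for (st in seq_len(steps_per_epoch)) {
      take <- ((st - 1L) * train_cfg$batch_size + 1L):
        min(st * train_cfg$batch_size, ppe)
      bx <- batch_tensor(clinical_patches, ix[take])
      by <- batch_tensor(micro_patches, iy[take])
      res <- train_step(model, bx, by, lr)
      model <- res$model
      rows[[st]] <- data.frame(epoch = epoch, step = st,
                               as.data.frame(unclass(res$losses)), lr = lr)
    }
    log_df <- do.call(rbind, rows)
    utils::write.table(log_df, log_path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(log_path), append =
                         file.exists(log_path))
    model$epoch <- epoch
    if (verbose)
      message(sprintf("epoch %d/%d  lr %.2e  total %.4f", epoch,
                      train_cfg$epochs, lr, mean(log_df$total)))
    if (epoch %% train_cfg$checkpoint_every == 0L || epoch == train_cfg$epochs)
      save_checkpoint(model, file.path(out_dir,
                                       sprintf("checkpoint_epoch%03d.rds",
                                               epoch)))
  }
  save_checkpoint(model, file.path(out_dir, "checkpoint_final.rds"))
  model
}

#' Super-resolve patches with the trained G1
#'
#' Inference uses only the upscaling generator, with normalization layers in
#' evaluation mode (running statistics), so identical inputs give identical
#' outputs. The generator is fully convolutional: any input at least as
#' large as its kernels is accepted.
#'
#' @param patches A single patch (matrix or [image_patch()]) or a list.
#' @param model An [srcycle_model()] (or a bare G1 network object).
#' @return An [image_patch()] in the micro domain (or a list of them),
#'   `2^k` times larger, values in `[-1, 1]`.
#' @export
infer <- function(patches, model) {
  G1 <- if (inherits(model, "srcycle_model")) model$nets$G1 else model
  single <- !is.list(patches) || inherits(patches, "image_patch")
  lst <- if (single) list(patches) else patches
  out <- lapply(lst, function(p) {
    if (inherits(p, "image_patch") && !p$normalized)
      stop("infer: patches must be normalized")
    m <- as_image_array(p)
    if (!p_is_normalized(m))
      stop("infer: patch values outside [-1, 1]; normalize first")
    y <- net_predict(G1, m)
    image_patch(matrix(y, dim(y)[1], dim(y)[2]), intensity_domain("micro"))
  })
  if (single) out[[1]] else out
}

p_is_normalized <- function(m) min(m) >= -1 - 1e-9 && max(m) <= 1 + 1e-9
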