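# Minimal convolutional training engine with exact manual backpropagation.
# Tensors are plain R arrays with dim (H, W, C, N); Rcpp/Armadillo kernels do
# the im2col convolutions, everything else is vectorized R. Only what the
# generators/discriminators need is implemented: conv2d (stride 1/2, reflect
# or zero padding), batch/instance norm, ReLU/LeakyReLU/tanh, sub-pixel
# shuffle, nearest-upsample, residual blocks, and Adam.

as_tensor <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) array(x, c(dim(x), 1L))
  else x
}

tensor_to_mats <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(n) matrix(x[, , 1L, n], d[1], d[2]))
}

mats_to_tensor <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), c(d[1], d[2], 1L, length(lst)))
}

## ---- layers ----------------------------------------------------------------

layer_conv <- function(kh, kw, cin, cout, stride = 1L, pad = NULL,
                       pad_type = c("reflect", "zero")) {
  pad_type <- match.arg(pad_type)
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad),
       reflect = pad_type == "reflect",
       w = array(stats::rnorm(kh * kw * cin * cout, 0, 0.02),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

layer_norm <- function(channels, kind = c("batch", "instance"),
                       momentum = 0.1, eps = 1e-5) {
  kind <- match.arg(kind)
  list(type = "norm", kind = kind, channels = channels,
       gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels),
       momentum = momentum, eps = eps)
}

layer_act <- function(fun = c("relu", "lrelu", "tanh"), alpha = 0.2) {
  list(type = "act", fun = match.arg(fun), alpha = alpha)
}

layer_pixel_shuffle <- function(r) list(type = "pixel_shuffle", r = as.integer(r))

layer_nearest_up <- function(r) list(type = "nearest_up", r = as.integer(r))

layer_resblock <- function(channels, norm_kind, kernel = 3L) {
  list(type = "resblock", layers = list(
    layer_conv(kernel, kernel, channels, channels),
    layer_norm(channels, norm_kind),
    layer_act("relu"),
    layer_conv(kernel, kernel, channels, channels),
    layer_norm(channels, norm_kind)))
}

## ---- pixel shuffle ---------------------------------------------------------

pixel_shuffle_index <- function(H, W, C, r) {
  Co <- C %/% (r * r); Ho <- r * H; Wo <- r * W
  y <- rep.int(0:(Ho - 1L), Wo * Co)
  x <- rep.int(rep(0:(Wo - 1L), each = Ho), Co)
  co <- rep(0:(Co - 1L), each = Ho * Wo)
  cin <- co * r * r + r * (y %% r) + (x %% r)
  1L + (y %/% r) + H * (x %/% r) + H * W * cin
}

#' Sub-pixel shuffle (channel-to-space rearrangement)
#'
#' Rearranges a tensor with `C*r^2` channels of size `H x W` into `C`
#' channels of size `rH x rW`:
#' `out[c, y, x] = in[c*r^2 + r*(y %% r) + (x %% r), y %/% r, x %/% r]`
#' (0-based). A bijection: no value is created or lost. This is the
#' upscaling primitive appended to the super-resolution generator in place
#' of deconvolution upblocks.
#'
#' @param features Array of dim `(H, W, C, N)` (or `(H, W, C)` for a single
#'   sample) with `C` divisible by `r^2`.
#' @param r Integer upscaling factor >= 1.
#' @return Array of dim `(rH, rW, C/r^2, N)`.
#' @export
#' @examples
#' f <- array(c(1, 2, 3, 4), c(1, 1, 4, 1))
#' pixel_shuffle(f, 2)[, , 1, 1]  # 2x2: rows (1,2) and (3,4)
pixel_shuffle <- function(features, r) {
  r <- as.integer(r)
  if (r < 1L) stop("pixel_shuffle: r must be >= 1")
  squeeze <- length(dim(features)) == 3L
  x <- if (squeeze) array(features, c(dim(features), 1L)) else features
  d <- dim(x)
  if (d[3] %% (r * r) != 0L)
    stop(sprintf("pixel_shuffle: %d channels not divisible by r^2 = %d",
                 d[3], r * r))
  if (r == 1L) return(features)
  idx <- pixel_shuffle_index(d[1], d[2], d[3], r)
  per <- prod(d[1:3])
  full <- rep(idx, d[4]) + rep((seq_len(d[4]) - 1L) * per, each = length(idx))
  out <- array(x[full], c(r * d[1], r * d[2], d[3] %/% (r * r), d[4]))
  if (squeeze) array(out, dim(out)[1:3]) else out
}

## ---- forward / backward ----------------------------------------------------

norm_stats_shape <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])   # local binding: no data copy
  x
}

layer_forward <- function(layer, x, train) {
  d <- dim(x)
  switch(layer$type,
    conv = {
      y <- .conv2d_fwd(x, layer$w, layer$b, layer$stride, layer$pad,
                       layer$reflect)
      list(layer = layer, y = y, cache = x)
    },
    norm = {
      m <- d[1] * d[2]
      xr <- norm_stats_shape(x)
      if (layer$kind == "batch") {
        if (train) {
          ch_mean <- colMeans(xr, dims = 1)              # C x N
          mu <- rowMeans(ch_mean)
          ex2 <- rowMeans(colMeans(xr * xr, dims = 1))
          v <- pmax(ex2 - mu^2, 0)
          layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
            layer$momentum * mu
          layer$running_var <- (1 - layer$momentum) * layer$running_var +
            layer$momentum * v
        } else {
          mu <- layer$running_mean; v <- layer$running_var
        }
        invstd <- 1 / sqrt(v + layer$eps)
        mu_b <- rep(rep(mu, each = m), times = d[4])
        is_b <- rep(rep(invstd, each = m), times = d[4])
        g_b <- rep(rep(layer$gamma, each = m), times = d[4])
        b_b <- rep(rep(layer$beta, each = m), times = d[4])
      } else {                                           # instance norm
        mu <- colMeans(xr, dims = 1)                     # C x N
        ex2 <- colMeans(xr * xr, dims = 1)
        v <- pmax(ex2 - mu^2, 0)
        invstd <- 1 / sqrt(v + layer$eps)
        mu_b <- rep(as.vector(mu), each = m)
        is_b <- rep(as.vector(invstd), each = m)
        g_b <- rep(rep(layer$gamma, each = m), times = d[4])
        b_b <- rep(rep(layer$beta, each = m), times = d[4])
      }
      xhat <- array((as.vector(x) - mu_b) * is_b, d)
      y <- array(as.vector(xhat) * g_b + b_b, d)
      list(layer = layer, y = y,
           cache = list(xhat = xhat, invstd = invstd, train = train))
    },
    act = {
      y <- switch(layer$fun,
        relu = pmax(x, 0),
        lrelu = { z <- x; neg <- x < 0; z[neg] <- layer$alpha * z[neg]; z },
        tanh = tanh(x))
      dim(y) <- d
      list(layer = layer, y = y,
           cache = if (layer$fun == "tanh") y else x)
    },
    pixel_shuffle = {
      list(layer = layer, y = pixel_shuffle(x, layer$r), cache = d)
    },
    nearest_up = {
      r <- layer$r
      y <- x[rep(seq_len(d[1]), each = r), rep(seq_len(d[2]), each = r), , ,
             drop = FALSE]
      list(layer = layer, y = y, cache = d)
    },
    resblock = {
      sub <- seq_forward(layer$layers, x, train)
      layer$layers <- sub$layers
      list(layer = layer, y = x + sub$y, cache = sub$caches)
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- .conv2d_bwd(cache, layer$w, dy, layer$stride, layer$pad,
                       layer$reflect)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    norm = {
      d <- dim(dy)
      m <- d[1] * d[2]
      xhat <- cache$xhat
      g_b <- rep(rep(layer$gamma, each = m), times = d[4])
      dxhat <- array(as.vector(dy) * g_b, d)
      dyr <- norm_stats_shape(dy)
      dxr <- norm_stats_shape(dxhat)
      xhr <- norm_stats_shape(xhat)
      dgamma <- rowSums(colSums(dyr * xhr, dims = 1))
      dbeta <- rowSums(colSums(dyr, dims = 1))
      if (layer$kind == "batch" && cache$train) {
        M <- m * d[4]
        s1 <- rowSums(colSums(dxr, dims = 1))            # per channel
        s2 <- rowSums(colSums(dxr * xhr, dims = 1))
        s1_b <- rep(rep(s1, each = m), times = d[4])
        s2_b <- rep(rep(s2, each = m), times = d[4])
        is_b <- rep(rep(cache$invstd, each = m), times = d[4])
        dx <- array(is_b / M *
                      (M * as.vector(dxhat) - s1_b - as.vector(xhat) * s2_b), d)
      } else if (layer$kind == "instance") {
        M <- m
        s1 <- colSums(dxr, dims = 1)                     # C x N
        s2 <- colSums(dxr * xhr, dims = 1)
        s1_b <- rep(as.vector(s1), each = m)
        s2_b <- rep(as.vector(s2), each = m)
        is_b <- rep(as.vector(cache$invstd), each = m)
        dx <- array(is_b / M *
                      (M * as.vector(dxhat) - s1_b - as.vector(xhat) * s2_b), d)
      } else {                                           # eval-mode batch norm
        is_b <- rep(rep(cache$invstd, each = m), times = d[4])
        dx <- array(as.vector(dxhat) * is_b, d)
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      dx <- switch(layer$fun,
        relu = dy * (cache > 0),
        lrelu = { z <- dy; neg <- cache < 0
                  z[neg] <- layer$alpha * z[neg]; z },
        tanh = dy * (1 - cache^2))
      dim(dx) <- dim(dy)
      list(dx = dx, grads = NULL)
    },
    pixel_shuffle = {
      d <- cache
      if (layer$r == 1L) return(list(dx = dy, grads = NULL))
      idx <- pixel_shuffle_index(d[1], d[2], d[3], layer$r)
      per <- prod(d[1:3])
      full <- rep(idx, d[4]) +
        rep((seq_len(d[4]) - 1L) * per, each = length(idx))
      dx <- numeric(prod(d))
      dx[full] <- as.vector(dy)
      list(dx = array(dx, d), grads = NULL)
    },
    nearest_up = {
      d <- cache; r <- layer$r
      dd <- dim(dy)
      # sum over rows within blocks, then over columns
      a <- colSums(array(dy, c(r, d[1], dd[2] * d[3] * d[4])), dims = 1)
      a <- array(a, c(d[1], dd[2], d[3], d[4]))
      a <- aperm(a, c(2, 1, 3, 4))
      b <- colSums(array(a, c(r, d[2], d[1] * d[3] * d[4])), dims = 1)
      b <- array(b, c(d[2], d[1], d[3], d[4]))
      list(dx = aperm(b, c(2, 1, 3, 4)), grads = NULL)
    },
    resblock = {
      sub <- seq_backward(layer$layers, cache, dy)
      list(dx = dy + sub$dx, grads = sub$grads)
    },
    stop("unknown layer type"))
}

seq_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], x, train)
    layers[[i]] <- st$layer
    caches[[i]] <- st$cache
    x <- st$y
  }
  list(y = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    st <- layer_backward(layers[[i]], caches[[i]], dy)
    grads[i] <- list(st$grads)      # [[<- would drop NULL entries
    dy <- st$dx
  }
  list(dx = dy, grads = grads)
}

net_forward <- function(net, x, train = TRUE) {
  st <- seq_forward(net$layers, as_tensor(x), train)
  net$layers <- st$layers
  list(y = st$y, caches = st$caches, net = net)
}

net_backward <- function(net, caches, dy) {
  seq_backward(net$layers, caches, dy)
}

## ---- parameters and Adam ---------------------------------------------------

param_names <- function(layer) {
  switch(layer$type,
    conv = c("w", "b"),
    norm = c("gamma", "beta"),
    character(0))
}

walk_params <- function(layers, fn, path = "") {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "resblock") walk_params(l$layers, fn, paste0(path, i, "."))
    else for (p in param_names(l)) fn(paste0(path, i, ".", p))
  }
}

net_param_count <- function(net) {
  count <- 0L
  rec <- function(layers) {
    for (l in layers) {
      if (l$type == "resblock") rec(l$layers)
      else for (p in param_names(l)) count <<- count + length(l[[p]])
    }
  }
  rec(net$layers)
  count
}

net_param_checksum <- function(net) {
  s <- 0
  rec <- function(layers) {
    for (l in layers) {
      if (l$type == "resblock") rec(l$layers)
      else for (p in param_names(l)) s <<- s + sum(l[[p]])
    }
  }
  rec(net$layers)
  s
}

adam_init <- function() list(t = 0L, m = list(), v = list())

# Applies one Adam step to every parameter of `net` given a parallel grads
# structure from net_backward; scale multiplies the gradient (used to average
# accumulated branches).
adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  upd <- function(layers, grads, path) {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type == "resblock") {
        l$layers <- upd(l$layers, grads[[i]], paste0(path, i, "."))
      } else {
        for (p in param_names(l)) {
          g <- grads[[i]][[p]]
          if (is.null(g)) next
          key <- paste0(path, i, ".", p)
          m <- state$m[[key]]; v <- state$v[[key]]
          if (is.null(m)) { m <- g * 0; v <- g * 0 }
          m <- beta1 * m + (1 - beta1) * g
          v <- beta2 * v + (1 - beta2) * g * g
          state$m[[key]] <<- m
          state$v[[key]] <<- v
          l[[p]] <- l[[p]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
        }
      }
      layers[[i]] <- l
    }
    layers
  }
  net$layers <- upd(net$layers, grads, "")
  list(net = net, state = state)
}

# Element-wise sum of two parallel grads structures (NULL-safe, recursive).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(a)) {
    r <- grads_add(a[[i]], b[[i]])
    if (is.null(r)) out[i] <- list(NULL) else out[[i]] <- r
  }
  out
}

# Gaussian blur with a (2*ceil(3 sigma)+1)^2 kernel, reflect boundaries.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  t <- (-rad):rad
  k1 <- exp(-t^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  x <- array(img, c(dim(img), 1L, 1L))
  w <- array(k2, c(dim(k2), 1L, 1L))
  y <- .conv2d_fwd(x, w, 0, 1L, rad, TRUE)
  matrix(y, nrow(img), ncol(img))
}
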