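# Convolutional encoder-decoder (U-Net) for image-to-image regression,
# implemented directly on BLAS-backed matrix products.
#
# Feature maps are 4-D arrays (H, W, B, C) so a channel-contraction is a
# single GEMM on an (H*W*B) x C matrix. A 3x3 "same" convolution is nine
# shifted GEMMs; a 2x2 stride-2 transposed convolution is four GEMMs with
# interleaved assignment. Training minimises the pixelwise squared
# reconstruction error with Adam; weights are Xavier-initialised Gaussians.

# ---- layer primitives ----------------------------------------------------

conv3_forward <- function(x, K, b) {
  list(out = conv3_fwd_cpp(x, K, b), x = x)
}

conv3_backward <- function(cache, K, dout) {
  conv3_bwd_cpp(cache$x, K, dout)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(cache, dout) dout * cache$mask

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  io <- seq(1, H, 2); ie <- seq(2, H, 2)
  jo <- seq(1, W, 2); je <- seq(2, W, 2)
  s00 <- x[io, jo, , , drop = FALSE]; s10 <- x[ie, jo, , , drop = FALSE]
  s01 <- x[io, je, , , drop = FALSE]; s11 <- x[ie, je, , , drop = FALSE]
  y <- pmax(s00, s10, s01, s11)
  m00 <- s00 == y
  m10 <- (s10 == y) & !m00
  m01 <- (s01 == y) & !m00 & !m10
  m11 <- (s11 == y) & !m00 & !m10 & !m01
  list(out = y, masks = list(m00, m10, m01, m11), dims = d)
}

maxpool2_backward <- function(cache, dout) {
  d <- cache$dims; H <- d[1]; W <- d[2]
  dx <- array(0, d)
  io <- seq(1, H, 2); ie <- seq(2, H, 2)
  jo <- seq(1, W, 2); je <- seq(2, W, 2)
  dx[io, jo, , ] <- dout * cache$masks[[1]]
  dx[ie, jo, , ] <- dout * cache$masks[[2]]
  dx[io, je, , ] <- dout * cache$masks[[3]]
  dx[ie, je, , ] <- dout * cache$masks[[4]]
  dx
}

upconv2_forward <- function(x, K, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[3]; Cin <- d[4]
  Cout <- dim(K)[4]
  xm <- x; dim(xm) <- c(H * W * B, Cin)
  y <- array(0, c(2 * H, 2 * W, B, Cout))
  for (di in 1:2) for (dj in 1:2) {
    sub <- xm %*% matrix(K[di, dj, , ], Cin, Cout)
    dim(sub) <- c(H, W, B, Cout)
    y[seq(di, 2 * H, 2), seq(dj, 2 * W, 2), , ] <- sub
  }
  y <- y + rep(b, each = 4 * H * W * B)
  list(out = y, xm = xm, dims = d)
}

upconv2_backward <- function(cache, K, dout) {
  d <- cache$dims; H <- d[1]; W <- d[2]; B <- d[3]; Cin <- d[4]
  Cout <- dim(K)[4]
  dK <- array(0, dim(K))
  dxm <- matrix(0, H * W * B, Cin)
  db <- 0
  for (di in 1:2) for (dj in 1:2) {
    sub <- dout[seq(di, 2 * H, 2), seq(dj, 2 * W, 2), , , drop = FALSE]
    dim(sub) <- c(H * W * B, Cout)
    dK[di, dj, , ] <- crossprod(cache$xm, sub)
    dxm <- dxm + sub %*% t(matrix(K[di, dj, , ], Cin, Cout))
    db <- db + colSums(sub)
  }
  dx <- dxm; dim(dx) <- d
  list(dx = dx, dK = dK, db = db)
}

conv1_forward <- function(x, K, b) {
  d <- dim(x); Cin <- d[4]; Cout <- ncol(K)
  xm <- x; dim(xm) <- c(prod(d[1:3]), Cin)
  out <- xm %*% K + rep(b, each = prod(d[1:3]))
  dim(out) <- c(d[1:3], Cout)
  list(out = out, xm = xm, dims = d)
}

conv1_backward <- function(cache, K, dout) {
  d <- cache$dims; Cout <- ncol(K)
  dm <- dout; dim(dm) <- c(prod(d[1:3]), Cout)
  list(dx = array(dm %*% t(K), d), dK = crossprod(cache$xm, dm),
       db = colSums(dm))
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# ---- network construction ------------------------------------------------

xavier <- function(dims, fan_in, fan_out) {
  array(rnorm(prod(dims), sd = sqrt(2 / (fan_in + fan_out))), dims)
}

#' Build a U-Net model
#'
#' Encoder of `depth` levels (two 3x3 convolutions + ReLU, then 2x2 max
#' pooling), a two-convolution bottleneck, and a mirrored decoder with 2x2
#' transposed convolutions and skip concatenations; a linear 1x1 convolution
#' head produces the regression output. Weights are Gaussian with Xavier
#' scaling, drawn from `seed`.
#'
#' @param in_channels input channels (3: real, imaginary, magnitude).
#' @param out_channels output channels (1 for architecture 1, 3 for
#'   architecture 2).
#' @param depth number of down/up-sampling levels (>= 2).
#' @param base_filters filters at the first level; doubled per level.
#' @param seed integer seed for the initialisation.
#' @return a `csinet_unet` model object.
#' @export
build_unet <- function(in_channels = 3, out_channels = 1, depth = 4,
                       base_filters = 32, seed = 1) {
  stopifnot(depth >= 2)
  params <- list()
  with_seed(seed, {
    cin <- in_channels
    for (l in seq_len(depth)) {
      f <- base_filters * 2^(l - 1)
      params[[paste0("enc", l, "a")]] <- list(W = xavier(c(3, 3, cin, f), 9 * cin, 9 * f), b = rep(0, f))
      params[[paste0("enc", l, "b")]] <- list(W = xavier(c(3, 3, f, f), 9 * f, 9 * f), b = rep(0, f))
      cin <- f
    }
    fb <- base_filters * 2^depth
    params[["bot_a"]] <- list(W = xavier(c(3, 3, cin, fb), 9 * cin, 9 * fb), b = rep(0, fb))
    params[["bot_b"]] <- list(W = xavier(c(3, 3, fb, fb), 9 * fb, 9 * fb), b = rep(0, fb))
    cup <- fb
    for (l in seq(depth, 1)) {
      f <- base_filters * 2^(l - 1)
      params[[paste0("up", l)]] <- list(W = xavier(c(2, 2, cup, f), 4 * cup, 4 * f), b = rep(0, f))
      params[[paste0("dec", l, "a")]] <- list(W = xavier(c(3, 3, 2 * f, f), 18 * f, 9 * f), b = rep(0, f))
      params[[paste0("dec", l, "b")]] <- list(W = xavier(c(3, 3, f, f), 9 * f, 9 * f), b = rep(0, f))
      cup <- f
    }
    params[["head"]] <- list(W = xavier(c(cup, out_channels), cup, out_channels),
                             b = rep(0, out_channels))
  })
  structure(list(params = params,
                 config = list(in_channels = in_channels,
                               out_channels = out_channels,
                               depth = depth, base_filters = base_filters,
                               seed = seed)),
            class = "csinet_unet")
}

#' @export
print.csinet_unet <- function(x, ...) {
  cat(sprintf("<csinet_unet> depth %d, %d base filters, %d -> %d channels, %d parameters\n",
              x$config$depth, x$config$base_filters, x$config$in_channels,
              x$config$out_channels, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `csinet_unet`.
#' @return integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

unet_forward <- function(params, x, depth, keep_cache = TRUE) {
  cache <- list()
  skips <- list()
  h <- x
  for (l in seq_len(depth)) {
    ca <- conv3_forward(h, params[[paste0("enc", l, "a")]]$W, params[[paste0("enc", l, "a")]]$b)
    ra <- relu_forward(ca$out)
    cb <- conv3_forward(ra$out, params[[paste0("enc", l, "b")]]$W, params[[paste0("enc", l, "b")]]$b)
    rb <- relu_forward(cb$out)
    pl <- maxpool2_forward(rb$out)
    skips[[l]] <- rb$out
    h <- pl$out
    if (keep_cache) cache[[paste0("enc", l)]] <- list(ca = ca, ra = ra, cb = cb, rb = rb, pl = pl)
  }
  ca <- conv3_forward(h, params$bot_a$W, params$bot_a$b)
  ra <- relu_forward(ca$out)
  cb <- conv3_forward(ra$out, params$bot_b$W, params$bot_b$b)
  rb <- relu_forward(cb$out)
  h <- rb$out
  if (keep_cache) cache$bot <- list(ca = ca, ra = ra, cb = cb, rb = rb)
  for (l in seq(depth, 1)) {
    up <- upconv2_forward(h, params[[paste0("up", l)]]$W, params[[paste0("up", l)]]$b)
    cc <- concat4(up$out, skips[[l]])
    ca <- conv3_forward(cc, params[[paste0("dec", l, "a")]]$W, params[[paste0("dec", l, "a")]]$b)
    ra <- relu_forward(ca$out)
    cb <- conv3_forward(ra$out, params[[paste0("dec", l, "b")]]$W, params[[paste0("dec", l, "b")]]$b)
    rb <- relu_forward(cb$out)
    h <- rb$out
    if (keep_cache) cache[[paste0("dec", l)]] <- list(up = up, ca = ca, ra = ra, cb = cb, rb = rb,
                                                      n_up = dim(up$out)[4])
  }
  hd <- conv1_forward(h, params$head$W, params$head$b)
  if (keep_cache) cache$head <- hd
  list(out = hd$out, cache = cache, skips_dims = lapply(skips, dim))
}

unet_backward <- function(params, fwd, dout, depth) {
  grads <- list()
  cache <- fwd$cache
  hb <- conv1_backward(cache$head, params$head$W, dout)
  grads$head <- list(W = hb$dK, b = hb$db)
  dh <- hb$dx
  dskips <- vector("list", depth)
  for (l in seq_len(depth)) {     # decoder levels from finest back up
    cc <- cache[[paste0("dec", l)]]
    drb <- relu_backward(cc$rb, dh)
    bb <- conv3_backward(cc$cb, params[[paste0("dec", l, "b")]]$W, drb)
    grads[[paste0("dec", l, "b")]] <- list(W = bb$dK, b = bb$db)
    dra <- relu_backward(cc$ra, bb$dx)
    ba <- conv3_backward(cc$ca, params[[paste0("dec", l, "a")]]$W, dra)
    grads[[paste0("dec", l, "a")]] <- list(W = ba$dK, b = ba$db)
    ncat <- dim(ba$dx)[4]
    nup <- cc$n_up
    dup_out <- ba$dx[, , , seq_len(nup), drop = FALSE]
    dskips[[l]] <- ba$dx[, , , (nup + 1):ncat, drop = FALSE]
    ub <- upconv2_backward(cc$up, params[[paste0("up", l)]]$W, dup_out)
    grads[[paste0("up", l)]] <- list(W = ub$dK, b = ub$db)
    dh <- ub$dx
  }
  cc <- cache$bot
  drb <- relu_backward(cc$rb, dh)
  bb <- conv3_backward(cc$cb, params$bot_b$W, drb)
  grads$bot_b <- list(W = bb$dK, b = bb$db)
  dra <- relu_backward(cc$ra, bb$dx)
  ba <- conv3_backward(cc$ca, params$bot_a$W, dra)
  grads$bot_a <- list(W = ba$dK, b = ba$db)
  dh <- ba$dx
  for (l in seq(depth, 1)) {      # encoder levels from deepest
    cc <- cache[[paste0("enc", l)]]
    dpool <- maxpool2_backward(cc$pl, dh)
    dtotal <- dpool + dskips[[l]]
    drb <- relu_backward(cc$rb, dtotal)
    bb <- conv3_backward(cc$cb, params[[paste0("enc", l, "b")]]$W, drb)
    grads[[paste0("enc", l, "b")]] <- list(W = bb$dK, b = bb$db)
    dra <- relu_backward(cc$ra, bb$dx)
    ba <- conv3_backward(cc$ca, params[[paste0("enc", l, "a")]]$W, dra)
    grads[[paste0("enc", l, "a")]] <- list(W = ba$dK, b = ba$db)
    dh <- ba$dx
  }
  grads
}

# ---- training ------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(mW = array(0, dim(p$W) %||% length(p$W)),
                                  vW = array(0, dim(p$W) %||% length(p$W)),
                                  mb = rep(0, length(p$b)),
                                  vb = rep(0, length(p$b))))
}

adam_step <- function(params, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Train a U-Net on image pairs
#'
#' Minimises the mean pixelwise squared reconstruction error with Adam.
#' Sample order is reshuffled each epoch from `seed`; training is fully
#' deterministic given the seed.
#'
#' @param model a `csinet_unet` from [build_unet()].
#' @param inputs array `(H, W, N, C_in)` of (already normalised) inputs.
#' @param targets array `(H, W, N, C_out)` of normalised targets.
#' @param epochs,batch_size,lr training hyper-parameters (defaults 75 / 10 /
#'   1e-3).
#' @param seed shuffling seed.
#' @param channel_weights optional per-output-channel loss weights
#'   (default 1).
#' @param verbose print per-epoch losses.
#' @return the model with trained parameters and a `loss_curve` element
#'   (mean training loss per epoch).
#' @export
train_unet <- function(model, inputs, targets, epochs = 75, batch_size = 10,
                       lr = 1e-3, seed = 1, channel_weights = NULL,
                       verbose = FALSE) {
  dI <- dim(inputs); dT <- dim(targets)
  stopifnot(length(dI) == 4, length(dT) == 4, dI[3] == dT[3])
  if (dI[1] %% 2^model$config$depth != 0 || dI[2] %% 2^model$config$depth != 0)
    stop_csinet("input %d x %d not divisible by 2^depth = %d; pad the images to a multiple",
                dI[1], dI[2], 2^model$config$depth)
  n <- dI[3]
  params <- model$params
  st <- adam_init(params)
  tstep <- 0
  wch <- channel_weights %||% rep(1, dT[4])
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        x <- inputs[, , idx, , drop = FALSE]
        y <- targets[, , idx, , drop = FALSE]
        fwd <- unet_forward(params, x, model$config$depth)
        resid <- fwd$out - y
        if (any(!is.finite(resid)))
          stop_csinet("non-finite training loss at epoch %d; lower the learning rate", ep)
        wrs <- sweep(resid, 4, wch, `*`)
        loss <- mean(wrs * resid)
        dout <- 2 * wrs / length(resid)
        grads <- unet_backward(params, fwd, dout, model$config$depth)
        tstep <- tstep + 1
        upd <- adam_step(params, grads, st, tstep, lr)
        params <- upd$params; st <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      losses[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %3d  loss %.6g", ep, losses[ep]))
    }
  })
  model$params <- params
  model$loss_curve <- losses
  model
}

#' Predict with a trained U-Net
#'
#' @param model a trained `csinet_unet`.
#' @param x input array `(H, W, C_in)` for a single image or
#'   `(H, W, N, C_in)` for a batch, already normalised.
#' @return array of predictions with matching leading dimensions.
#' @export
predict_unet <- function(model, x) {
  single <- length(dim(x)) == 3
  if (single) dim(x) <- c(dim(x)[1], dim(x)[2], 1, dim(x)[3])
  out <- unet_forward(model$params, x, model$config$depth, keep_cache = FALSE)$out
  if (single) { d <- dim(out); dim(out) <- c(d[1], d[2], d[4]) }
  out
}

# ---- normalisation and input stacks --------------------------------------

#' Fit a per-channel affine (min-max) normaliser
#'
#' @param x array `(H, W, N, C)` of training-split images.
#' @return a `csinet_normalizer` mapping each channel to `[0, 1]`.
#' @export
fit_normalizer <- function(x) {
  C <- dim(x)[4]
  lo <- hi <- numeric(C)
  for (c in seq_len(C)) {
    lo[c] <- min(x[, , , c]); hi[c] <- max(x[, , , c])
    if (hi[c] == lo[c]) hi[c] <- lo[c] + 1
  }
  structure(list(lo = lo, hi = hi), class = "csinet_normalizer")
}

#' Apply a normaliser channelwise
#' @param nrm a `csinet_normalizer`.
#' @param x array whose last dimension is the channel.
#' @return normalised array.
#' @export
normalize_stack <- function(nrm, x) {
  nd <- length(dim(x))
  sweep(sweep(x, nd, nrm$lo, `-`), nd, nrm$hi - nrm$lo, `/`)
}

#' Invert a normaliser channelwise
#' @param nrm a `csinet_normalizer`.
#' @param x normalised array whose last dimension is the channel.
#' @return denormalised array.
#' @export
denormalize_stack <- function(nrm, x) {
  nd <- length(dim(x))
  sweep(sweep(x, nd, nrm$hi - nrm$lo, `*`), nd, nrm$lo, `+`)
}

#' Build the 3-channel network input from a complex reconstruction
#'
#' Channels are the real part, the imaginary part and the magnitude
#' `sqrt(real^2 + imag^2)` of the reconstructed complex permittivity.
#'
#' @param recon_real,recon_imag real-valued images of identical shape
#'   (eps' and eps'' of the reconstruction).
#' @param normalizer optional `csinet_normalizer` fitted on the training
#'   split; if supplied the stack is returned normalised.
#' @return array `(H, W, 3)`.
#' @export
make_input_stack <- function(recon_real, recon_imag, normalizer = NULL) {
  if (!all(dim(recon_real) == dim(recon_imag)))
    stop_csinet("real and imaginary images must share their shape")
  stack <- array(c(recon_real, recon_imag,
                   sqrt(recon_real^2 + recon_imag^2)),
                 c(dim(recon_real), 3))
  if (!is.null(normalizer)) stack <- normalize_stack(normalizer, stack)
  stack
}
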