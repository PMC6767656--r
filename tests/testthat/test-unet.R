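test_that("analytic gradients match finite differences", {
  model <- build_unet(in_channels = 2, out_channels = 2, depth = 2,
                      base_filters = 2, seed = 3)
  set.seed(1)
  H <- 8; W <- 8; B <- 2
  x <- array(rnorm(H * W * B * 2), c(H, W, B, 2))
  y <- array(rnorm(H * W * B * 2), c(H, W, B, 2))
  lossfn <- function(params)
    mean((csinet:::unet_forward(params, x, 2, keep_cache = FALSE)$out - y)^2)
  fwd <- csinet:::unet_forward(model$params, x, 2)
  grads <- csinet:::unet_backward(model$params, fwd,
                                  2 * (fwd$out - y) / length(y), 2)
  eps <- 1e-5
  for (nm in c("enc1a", "enc2b", "bot_a", "up2", "dec1a", "head")) {
    for (k in 1:3) {
      i <- sample(length(model$params[[nm]]$W), 1)
      p2 <- model$params; p2[[nm]]$W[i] <- p2[[nm]]$W[i] + eps
      p3 <- model$params; p3[[nm]]$W[i] <- p3[[nm]]$W[i] - eps
      gnum <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_lt(abs(gnum - grads[[nm]]$W[i]) / max(abs(gnum), 1e-8), 1e-3)
    }
  }
})

test_that("output shapes, zero weights and parameter counts behave as designed", {
  m <- build_unet(3, 1, depth = 3, base_filters = 4, seed = 1)
  x <- array(rnorm(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  out <- csinet:::unet_forward(m$params, x, 3, keep_cache = FALSE)$out
  expect_equal(dim(out), c(32, 32, 2, 1))
  m3 <- build_unet(3, 3, depth = 2, base_filters = 4, seed = 1)
  out3 <- predict_unet(m3, array(rnorm(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(dim(out3), c(16, 16, 3))
  # zeroed weights and biases give the zero map
  mz <- m
  mz$params <- lapply(mz$params, function(p) list(W = p$W * 0, b = p$b * 0))
  outz <- predict_unet(mz, array(rnorm(32 * 32 * 3), c(32, 32, 3)))
  expect_true(all(outz == 0))
  # capacity grows strictly with width
  expect_gt(n_params(build_unet(3, 1, 3, 8)), n_params(build_unet(3, 1, 3, 4)))
  # indivisible input sizes are rejected with a padding hint
  xs <- array(0, c(20, 20, 4, 3))
  ys <- array(0, c(20, 20, 4, 1))
  expect_error(train_unet(build_unet(3, 1, depth = 3), xs, ys, epochs = 1),
               "pad")
})

test_that("prediction is a deterministic pure function", {
  m <- build_unet(3, 1, depth = 2, base_filters = 4, seed = 9)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict_unet(m, x), predict_unet(m, x))
})

test_that("training is deterministic given the seed and overfits a tiny set", {
  set.seed(10)
  n <- 6
  xs <- array(rnorm(16 * 16 * n * 3), c(16, 16, n, 3))
  ys <- array(0, c(16, 16, n, 1))
  for (i in 1:n) ys[, , i, 1] <- 0.5 * xs[, , i, 1] - 0.2 * xs[, , i, 3]
  m1 <- train_unet(build_unet(3, 1, 2, 6, seed = 4), xs, ys,
                   epochs = 5, batch_size = 3, lr = 1e-3, seed = 11)
  m2 <- train_unet(build_unet(3, 1, 2, 6, seed = 4), xs, ys,
                   epochs = 5, batch_size = 3, lr = 1e-3, seed = 11)
  expect_equal(m1$loss_curve, m2$loss_curve, tolerance = 1e-12)
  m3 <- train_unet(build_unet(3, 1, 2, 6, seed = 4), xs, ys,
                   epochs = 200, batch_size = 3, lr = 2e-3, seed = 11)
  expect_lt(tail(m3$loss_curve, 1), 0.1 * m3$loss_curve[1])
})

test_that("input stacks carry the magnitude channel and normalisers invert", {
  r <- matrix(3, 8, 8); im <- matrix(4, 8, 8)
  s <- make_input_stack(r, im)
  expect_equal(s[, , 3], matrix(5, 8, 8))
  s2 <- make_input_stack(r, matrix(0, 8, 8))
  expect_equal(s2[, , 3], abs(r))
  expect_error(make_input_stack(r, matrix(0, 4, 4)), "shape")
  set.seed(2)
  x <- array(rnorm(8 * 8 * 5 * 3, sd = 10), c(8, 8, 5, 3))
  nrm <- fit_normalizer(x)
  expect_equal(denormalize_stack(nrm, normalize_stack(nrm, x)), x,
               tolerance = 1e-6)
  xn <- normalize_stack(nrm, x)
  expect_gte(min(xn), 0); expect_lte(max(xn), 1)
})

test_that("architecture 1 trains two networks and architecture 2 one", {
  set.seed(3)
  n <- 4
  recons <- truths <- list()
  for (i in 1:n) {
    recons[[i]] <- list(real = matrix(rnorm(256, 20, 5), 16, 16),
                        imag = matrix(rnorm(256, 3, 1), 16, 16))
    truths[[i]] <- list(real = recons[[i]]$real + 1,
                        imag = recons[[i]]$imag * 0.9)
  }
  cfgt <- list(depth = 2, base_filters = 2, epochs = 1, batch_size = 2, seed = 5)
  e1 <- train_enhancer(recons, truths, arch = 1, config = cfgt)
  expect_named(e1$models, c("real", "imag"))
  e2 <- train_enhancer(recons, truths, arch = 2, config = cfgt)
  expect_named(e2$models, "joint")
  p1 <- enhance(e1, recons[[1]])
  expect_equal(dim(p1$real), c(16, 16))
  p2 <- enhance(e2, recons[[1]])
  expect_named(p2, c("real", "imag", "magnitude"))
})
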