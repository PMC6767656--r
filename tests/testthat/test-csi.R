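test_that("condensed operators are linear with exact adjoints", {
  geo <- toy_geometry(8)
  mesh <- disk_mesh(geo$omega_radius, 0.35)
  pr <- homogeneous_prior(32, 0.2)
  ops <- build_operators(mesh, pr, geo)
  m <- ncol(ops$G_D)
  expect_lt(max(Mod(ops$G_S %*% rep(0 + 0i, m))), 1e-15)  # L[0] = 0
  set.seed(4)
  w1 <- complex(real = rnorm(m), imaginary = rnorm(m))
  w2 <- complex(real = rnorm(m), imaginary = rnorm(m))
  a <- 0.3 - 1.2i; b <- -0.8 + 0.4i
  lin <- ops$G_D %*% (a * w1 + b * w2) - a * (ops$G_D %*% w1) - b * (ops$G_D %*% w2)
  expect_lt(max(Mod(lin)) / max(Mod(ops$G_D %*% w1)), 1e-10)
  # adjoint identity <G w, f> = <w, G^H f>
  f <- complex(real = rnorm(nrow(ops$G_S)), imaginary = rnorm(nrow(ops$G_S)))
  lhs <- sum(Conj(ops$G_S %*% w1) * f)
  rhs <- sum(Conj(w1) * (Conj(t(ops$G_S)) %*% f))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  # the domain Green function decays away from a point-like source
  src <- which.min(rowSums((mesh$nodes[ops$d_idx, ] -
                              matrix(c(2, 2), m, 2, byrow = TRUE))^2))
  w <- rep(0 + 0i, m); w[src] <- 1
  resp <- Mod(ops$G_D %*% w)
  d <- sqrt(rowSums((mesh$nodes[ops$d_idx, ] -
                       matrix(mesh$nodes[ops$d_idx, ][src, ], m, 2, byrow = TRUE))^2))
  near <- mean(resp[d > 0.1 & d < 1]); far <- mean(resp[d > 2.5])
  expect_gt(near, 2 * far)
})

test_that("the cost functional matches direct arithmetic on the hand-built toy", {
  ops <- toy_operators()
  toy <- fx$toy_csi
  # consistent pair: both residuals vanish
  cc <- compute_cost(toy$chi_true, toy$W_true, toy$f, ops)
  expect_lt(cc$F_CSI, 1e-10)
  # w = 0 with nonzero data: F_S = 1 exactly
  W0 <- matrix(0 + 0i, 2, 2)
  cc0 <- compute_cost(toy$chi_true, W0, toy$f, ops)
  expect_equal(cc0$F_S, 1)
  # brute-force evaluation with explicit per-transmitter sums
  set.seed(1)
  W <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  chi <- c(0.2 + 0.1i, -0.1 + 0.3i)
  cc2 <- compute_cost(chi, W, toy$f, ops)
  FS <- FD <- num_eta <- 0
  for (t in 1:2) {
    rho <- toy$f[, t] - ops$G_S %*% W[, t]
    FS <- FS + sum(Mod(rho)^2)
    d <- chi * ops$einc[, t] - W[, t] + chi * (ops$G_D %*% W[, t])
    FD <- FD + sum(Mod(d)^2)
    num_eta <- num_eta + sum(Mod(chi * ops$einc[, t])^2)
  }
  expect_equal(cc2$F_S, FS / sum(Mod(toy$f)^2), tolerance = 1e-12)
  expect_equal(cc2$F_D, FD / num_eta, tolerance = 1e-12)
  expect_error(compute_cost(c(0 + 0i, 0 + 0i), W, toy$f, ops), "zero contrast")
})

test_that("back-propagation initialisation is deterministic and never worse than zero sources", {
  ops <- toy_operators()
  st0 <- init_state(matrix(0 + 0i, 2, 2), ops)
  expect_lt(max(Mod(st0$W)), 1e-15)
  st1 <- init_state(fx$toy_csi$f, ops)
  st2 <- init_state(fx$toy_csi$f, ops)
  expect_identical(st1$W, st2$W)
  cc <- compute_cost(st1$chi, st1$W, fx$toy_csi$f, ops)
  expect_lte(cc$F_S, 1)
})

test_that("the contrast update solves the nodewise least-squares problem", {
  ops <- toy_operators()
  set.seed(2)
  W <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  st <- structure(list(W = W, chi = NULL, eta_D = NULL, g_prev = NULL,
                       v_prev = NULL, n_dead_nodes = 0L), class = "csi_state")
  st <- update_contrast(st, ops)
  E <- ops$einc + ops$G_D %*% W
  for (node in 1:2) {
    # brute-force normal equation for chi at one node
    num <- sum(W[node, ] * Conj(E[node, ]))
    den <- sum(Mod(E[node, ])^2)
    expect_equal(st$chi[node], num / den, tolerance = 1e-12)
  }
  # w proportional to the total field recovers the exact scalar contrast
  cval <- 0.37 - 0.21i
  Efix <- solve(diag(2) - cval * ops$G_D, ops$einc)
  stc <- structure(list(W = cval * Efix, chi = NULL, eta_D = NULL,
                        g_prev = NULL, v_prev = NULL, n_dead_nodes = 0L),
                   class = "csi_state")
  stc <- update_contrast(stc, ops)
  expect_equal(stc$chi, rep(cval, 2), tolerance = 1e-10)
})

test_that("source updates never increase the cost and fixed points stay fixed", {
  ops <- toy_operators()
  toy <- fx$toy_csi
  # stationary at the consistent solution
  st <- structure(list(W = toy$W_true, chi = toy$chi_true,
                       eta_D = csinet:::cnorm2(toy$chi_true * ops$einc),
                       g_prev = NULL, v_prev = NULL, n_dead_nodes = 0L),
                  class = "csi_state")
  st2 <- update_sources(st, toy$f, ops)
  expect_lt(max(Mod(st2$W - toy$W_true)), 1e-10)
  # monotone cost over 50 iterations on noisy (inconsistent) data
  set.seed(3)
  fn <- toy$f + 0.05 * matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  res <- run_csi(fn, operators = ops, n_iters = 50)
  h <- res$cost_history$F_CSI
  expect_true(all(diff(h) <= 1e-10 * h[-length(h)] + 1e-14))
})

test_that("the hand-built toy problem is solved to numerical consistency", {
  ops <- toy_operators()
  res <- run_csi(fx$toy_csi$f, operators = ops, n_iters = 200,
                 snapshot_iters = c(10, 200))
  expect_lt(tail(res$cost_history$F_CSI, 1), 1e-8)
  expect_lt(max(Mod(res$chi - fx$toy_csi$chi_true)), 1e-3)
  expect_named(res$snapshots, c("10", "200"))
  expect_error(run_csi(fx$toy_csi$f, operators = ops, n_iters = 5,
                       snapshot_iters = 9), "snapshot")
})

test_that("total permittivity inverts the contrast definition", {
  geo <- toy_geometry(4)
  mesh <- disk_mesh(geo$omega_radius, 0.4)
  pr <- homogeneous_prior(32, 0.2)
  ops <- build_operators(mesh, pr, geo)
  m <- ncol(ops$G_D)
  expect_equal(total_permittivity(rep(0 + 0i, m), ops), ops$eps_n_nodes)
  chi1 <- rep(1 + 0i, m)
  eps1 <- total_permittivity(chi1, ops)
  expect_equal(eps1[ops$d_idx], 2 * ops$eps_n_nodes[ops$d_idx], tolerance = 1e-14)
  set.seed(8)
  chi <- complex(real = rnorm(m), imaginary = rnorm(m))
  eps <- total_permittivity(chi, ops)
  back <- contrast_of(eps[ops$d_idx], ops$eps_n_nodes[ops$d_idx])
  expect_equal(back, chi, tolerance = 1e-12)
  # constant nodal field rasterises to a constant image
  img <- rasterize(rep(3.5, mesh$n_nodes), mesh, c(32, 32), 0.2)
  expect_equal(img, matrix(3.5, 32, 32), tolerance = 1e-12)
})
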