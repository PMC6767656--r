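test_that("mesh refinement scales triangle count quadratically and stays valid", {
  m1 <- disk_mesh(8, 0.8)
  m2 <- disk_mesh(8, 0.4)
  expect_gt(m2$n_tri / m1$n_tri, 3.5)
  expect_lt(m2$n_tri / m1$n_tri, 4.6)
  expect_true(all(m1$elem$area > 0))
  expect_true(all(m2$elem$area > 0))
  # boundary nodes lie on the rim circle
  r <- sqrt(rowSums(m2$nodes[m2$boundary_nodes, ]^2))
  expect_lt(max(abs(r - 8)), 1e-9)
  expect_error(disk_mesh(8, 5), "too coarse")
})

test_that("every pixel centre receives convex interpolation weights", {
  mesh <- disk_mesh(7.5, 0.35)
  P <- raster_matrix(mesh, c(32, 32), 0.2)
  expect_equal(unname(Matrix::rowSums(P)), rep(1, 32 * 32), tolerance = 1e-12)
  expect_gte(min(P@x), 0)
  expect_lte(max(P@x), 1 + 1e-12)
  # linear fields are reproduced exactly by the P1 basis
  v <- 1.5 * mesh$nodes[, 1] - 0.7 * mesh$nodes[, 2] + 2
  img <- rasterize(v, mesh, c(32, 32), 0.2, P = P)
  x <- (seq_len(32) - 0.5) * 0.2 - 3.2
  ref <- outer(x, x, function(a, b) 1.5 * a - 0.7 * b + 2)
  expect_equal(img, ref, tolerance = 1e-12)
})

test_that("mesh refinement reduces rasterisation error of a smooth field", {
  f <- function(p) sin(p[, 1]) * cos(0.8 * p[, 2])
  x <- (seq_len(32) - 0.5) * 0.2 - 3.2
  ref <- outer(x, x, function(a, b) sin(a) * cos(0.8 * b))
  err <- vapply(c(0.7, 0.35), function(h) {
    mesh <- disk_mesh(7.5, h)
    img <- rasterize(f(mesh$nodes), mesh, c(32, 32), 0.2)
    sqrt(mean((img - ref)^2))
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
})

test_that("FEM point-source fields match the closed-form line source in a homogeneous medium", {
  # lossless medium: the absorbing rim sits farther out so its residual
  # reflection stays below the discretisation error
  geo <- acquisition_geometry(n_antennas = 4, s_radius = 5, d_halfwidth = 3.2,
                              background_eps = 23 + 0i, omega_radius = 16)
  mesh <- disk_mesh(geo$omega_radius, 0.16)
  fields <- solve_incident(geo, mesh, rep(23 + 0i, mesh$n_nodes), method = "point")
  d_idx <- which(abs(mesh$nodes[, 1]) <= 3.2 & abs(mesh$nodes[, 2]) <= 3.2)
  ref <- csinet:::incident_analytic(geo, mesh$nodes[d_idx, ])
  err <- sqrt(sum(Mod(fields[d_idx, ] - ref)^2) / sum(Mod(ref)^2))
  expect_lt(err, 0.02)
})

test_that("hybrid incident fields reduce to the analytic field on a homogeneous background", {
  geo <- toy_geometry(4)
  mesh <- disk_mesh(geo$omega_radius, 0.3)
  f1 <- solve_incident(geo, mesh)
  f2 <- csinet:::incident_analytic(geo, mesh$nodes)
  expect_identical(f1, f2)
})

test_that("point-source fields are reciprocal", {
  geo <- toy_geometry(6)
  mesh <- disk_mesh(geo$omega_radius, 0.3)
  eps <- rep(as.complex(geo$background_eps), mesh$n_nodes)
  eps[sqrt(rowSums(mesh$nodes^2)) < 2] <- 30 - 3i  # off-centre of antennas
  fields <- solve_point_source(geo, mesh, eps)
  R <- csinet:::interp_matrix(mesh, geo$tx_positions)
  at_rx <- csinet:::sp_cmult(R, fields)   # [receiver, transmitter]
  offdiag <- at_rx[upper.tri(at_rx)]
  expect_lt(max(Mod(at_rx - t(at_rx))) / max(Mod(offdiag)), 0.01)
})

test_that("a phantom equal to the background scatters nothing", {
  geo <- toy_geometry(8)
  ph <- cylinder_phantom(1.5, geo$background_eps, 32, 0.2)
  mesh <- disk_mesh(geo$omega_radius, 0.3)
  ds <- forward_scatter(ph, geo, mesh)
  expect_lt(max(Mod(ds$f)), 1e-12)
})

test_that("noise injection is calibrated, seeded and unbiased", {
  geo <- toy_geometry(24)
  ph <- cylinder_phantom(1.5, 30 - 3i, 32, 0.2)
  ds <- forward_scatter(ph, geo, disk_mesh(geo$omega_radius, 0.3))
  expect_identical(add_noise(ds, 0), ds)
  n1 <- add_noise(ds, 0.05, seed = 5)
  n2 <- add_noise(ds, 0.05, seed = 5)
  expect_identical(n1$f, n2$f)
  realized <- sqrt(sum(Mod(n1$f - ds$f)^2) / sum(Mod(ds$f)^2))
  expect_gte(realized, 0.045)
  expect_lte(realized, 0.055)
  expect_equal(n1$noise_level, 0.05)
  # empirical mean of the injected noise is zero within 3 standard errors
  big <- ds; big$f <- matrix(rep(ds$f, 20), nrow = nrow(ds$f))
  nb <- add_noise(big, 0.05, seed = 9)
  noise <- nb$f - big$f
  sigma <- 0.05 * sqrt(mean(Mod(big$f)^2))
  se <- sigma / sqrt(2 * length(noise))
  expect_lt(abs(mean(Re(noise))), 3 * se)
  expect_lt(abs(mean(Im(noise))), 3 * se)
})
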