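# Transverse-magnetic scattered-field simulation.
#
# The out-of-plane electric field of a 2D TM setup satisfies the scalar
# Helmholtz equation. Synthetic receiver data is produced by a P1 FEM solve
# of the scattered-field form A u = (M_{k^2(eps)} - M_{k^2(eps_b)}) e_inc,
# with the analytic line-source incident field e_inc in the right-hand side,
# on a mesh finer than (and independent of) the inversion mesh.

SPEED_OF_LIGHT_CM <- 2.99792458e10  # cm/s

#' Acquisition geometry for a circular microwave tomography setup
#'
#' Transmitters and receivers are colocated, equally spaced on a measurement
#' circle S that encloses the square imaging domain D.
#'
#' @param frequency operating frequency in Hz.
#' @param n_antennas number of transmitters (= receivers) on S.
#' @param s_radius radius of S in cm; must exceed half the diagonal of D.
#' @param background_eps complex relative permittivity of the immersion
#'   medium, written eps' - 1i * eps'' (loss as a negative imaginary part).
#' @param d_halfwidth half the side length of the square imaging domain D (cm).
#' @param omega_radius radius of the outer problem-domain boundary (cm);
#'   defaults to 1.5 x `s_radius`.
#' @return an `acquisition_geometry` object.
#' @export
acquisition_geometry <- function(frequency = 1e9, n_antennas = 24,
                                 s_radius = 9.5,
                                 background_eps = 23 - 1i,
                                 d_halfwidth = 6.4,
                                 omega_radius = 1.5 * s_radius) {
  if (s_radius <= d_halfwidth * sqrt(2))
    stop_csinet("S radius %g cm places antennas inside the imaging square D (needs > %g cm)",
                s_radius, d_halfwidth * sqrt(2))
  if (omega_radius <= s_radius)
    stop_csinet("outer boundary must lie beyond the measurement circle")
  ang <- 2 * pi * (seq_len(n_antennas) - 1) / n_antennas
  pos <- cbind(x = s_radius * cos(ang), y = s_radius * sin(ang))
  k0 <- 2 * pi * frequency / SPEED_OF_LIGHT_CM
  structure(list(
    frequency = frequency, n_antennas = as.integer(n_antennas),
    s_radius = s_radius, background_eps = background_eps,
    d_halfwidth = d_halfwidth, omega_radius = omega_radius,
    tx_positions = pos, rx_positions = pos,
    k0 = k0, k_bg = k0 * sqrt(background_eps)
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry> %.3g GHz, %d tx/rx on S (r = %.3g cm), D = [%.3g]^2 cm, eps_bg = %s\n",
              x$frequency / 1e9, x$n_antennas, x$s_radius, 2 * x$d_halfwidth,
              format(x$background_eps)))
  invisible(x)
}

#' Default mesh for a geometry
#'
#' Edge length is a fraction of the shortest wavelength present, i.e. the
#' wavelength in the highest-permittivity tissue expected in the domain.
#'
#' @param geometry an `acquisition_geometry`.
#' @param max_edge_frac maximum edge length as a fraction of the shortest
#'   wavelength (default 1/10).
#' @param max_eps largest relative permittivity magnitude expected (sets the
#'   shortest wavelength; default 50, the tumor value).
#' @return a `csinet_mesh` covering the problem domain Omega.
#' @export
build_mesh <- function(geometry, max_edge_frac = 0.1, max_eps = 50) {
  lam_min <- 2 * pi / (geometry$k0 * sqrt(max_eps))
  disk_mesh(geometry$omega_radius, max_edge_frac * lam_min)
}

# complex permittivity per mesh node given a phantom pixel map (nearest pixel,
# background outside the pixel grid)
eps_on_mesh <- function(mesh, eps_grid, pixel_size, background_eps) {
  M <- nrow(eps_grid); N <- ncol(eps_grid)
  w <- M * pixel_size; h <- N * pixel_size
  i <- floor((mesh$nodes[, 1] + w / 2) / pixel_size) + 1
  j <- floor((mesh$nodes[, 2] + h / 2) / pixel_size) + 1
  inside <- i >= 1 & i <= M & j >= 1 & j <= N
  out <- rep(as.complex(background_eps), mesh$n_nodes)
  out[inside] <- eps_grid[cbind(i[inside], j[inside])]
  out
}

# assemble the complex Helmholtz FEM system A = K - M_{k^2} + (1i k_b + 1/(2R)) B
#
# The mass matrix blends the consistent and row-lumped P1 forms,
# M = theta M_cons + (1 - theta) M_lump. On this structured triangulation the
# two have numerical-dispersion errors of opposite sign; theta = 0.3
# (calibrated once against the analytic cylinder series) roughly cancels the
# leading phase error and cuts receiver-field error by ~4x at fixed h.
helmholtz_system <- function(mesh, eps_nodes, geometry, cache = NULL,
                             mass_blend = 0.3) {
  K <- cache$K %||% assemble_stiffness(mesh)
  B <- cache$B %||% assemble_boundary_mass(mesh)
  k2 <- geometry$k0^2 * eps_nodes
  tp <- cache$tp %||% tri_triplets(mesh)
  e <- mesh$elem
  wel <- (k2[mesh$tri[, 1]] + k2[mesh$tri[, 2]] + k2[mesh$tri[, 3]]) / 3
  base <- mass_blend * c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12 +
    (1 - mass_blend) * c(4, 0, 0, 0, 4, 0, 0, 0, 4) / 12
  Mre <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = as.vector(outer(e$area * Re(wel), base)),
                              dims = c(mesh$n_nodes, mesh$n_nodes))
  Mim <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = as.vector(outer(e$area * Im(wel), base)),
                              dims = c(mesh$n_nodes, mesh$n_nodes))
  bf <- 1i * geometry$k_bg + 1 / (2 * mesh$radius)
  list(A_re = K - Mre + Re(bf) * B, A_im = -Mim + Im(bf) * B,
       M_re = Mre, M_im = Mim, K = K, B = B, tp = tp)
}

sp_cmult <- function(S, Z) {
  as.matrix(S %*% Re(Z)) + 1i * as.matrix(S %*% Im(Z))
}

#' Precompute mesh-constant quantities for repeated forward/inverse solves
#'
#' Stiffness, boundary mass, assembly indices, analytic incident fields at
#' the nodes, the background-medium mass matrices and the receiver
#' interpolation matrix depend only on (geometry, mesh); batch pipelines
#' reuse them across phantoms.
#'
#' @param geometry an `acquisition_geometry`.
#' @param mesh a `csinet_mesh`.
#' @return a `fem_context` list.
#' @export
fem_context <- function(geometry, mesh) {
  sysb <- helmholtz_system(mesh, rep(as.complex(geometry$background_eps), mesh$n_nodes),
                           geometry)
  structure(list(geometry = geometry, mesh = mesh,
                 K = sysb$K, B = sysb$B, tp = sysb$tp, sysb = sysb,
                 einc_nodes = incident_analytic(geometry, mesh$nodes),
                 Rrx = interp_matrix(mesh, geometry$rx_positions)),
            class = "fem_context")
}

# analytic incident fields of all transmitters at given points (homogeneous
# background)
incident_analytic <- function(geometry, pts) {
  tx <- geometry$tx_positions
  out <- matrix(0i, nrow(pts), nrow(tx))
  for (t in seq_len(nrow(tx))) {
    d <- sqrt((pts[, 1] - tx[t, 1])^2 + (pts[, 2] - tx[t, 2])^2)
    out[, t] <- line_source_field(geometry$k_bg, d)
  }
  out
}

#' Incident fields on the mesh for a (possibly inhomogeneous) numerical background
#'
#' For a homogeneous background equal to the immersion medium this returns the
#' closed-form outgoing line-source field sampled at the nodes. For an
#' inhomogeneous numerical background the FEM correction
#' `A_n u = (M_{k_n^2} - M_{k_b^2}) e_inc` is added. `method = "point"`
#' instead discretises the line source itself as a FEM load (used to validate
#' the solver against the closed form).
#'
#' @param geometry an `acquisition_geometry`.
#' @param mesh a `csinet_mesh`.
#' @param eps_n_nodes complex relative permittivity per mesh node (defaults
#'   to the homogeneous immersion medium).
#' @param method `"hybrid"` (analytic + FEM correction) or `"point"`
#'   (pure FEM with a point-source load).
#' @return complex matrix `n_nodes x n_tx` of incident fields.
#' @export
solve_incident <- function(geometry, mesh, eps_n_nodes = NULL,
                           method = c("hybrid", "point")) {
  method <- match.arg(method)
  if (is.null(eps_n_nodes))
    eps_n_nodes <- rep(as.complex(geometry$background_eps), mesh$n_nodes)
  if (length(eps_n_nodes) != mesh$n_nodes)
    stop_csinet("eps_n_nodes must have one value per mesh node")
  einc <- incident_analytic(geometry, mesh$nodes)
  if (method == "hybrid") {
    depsk2 <- geometry$k0^2 * (eps_n_nodes - geometry$background_eps)
    if (max(Mod(depsk2)) < 1e-14) return(einc)
    sys <- helmholtz_system(mesh, eps_n_nodes, geometry)
    sysb <- helmholtz_system(mesh, rep(as.complex(geometry$background_eps), mesh$n_nodes),
                             geometry, cache = sys)
    dM_re <- sys$M_re - sysb$M_re
    dM_im <- sys$M_im - sysb$M_im
    rhs <- sp_cmult(dM_re, einc) + 1i * sp_cmult(dM_im, einc)
    fac <- cfactor(sys$A_re, sys$A_im)
    einc + csolve(fac, rhs)
  } else {
    sys <- helmholtz_system(mesh, eps_n_nodes, geometry)
    fac <- cfactor(sys$A_re, sys$A_im)
    load <- Matrix::t(interp_matrix(mesh, geometry$tx_positions))
    csolve(fac, as.matrix(load))
  }
}

#' Point-source FEM fields (total-field solve for a given permittivity map)
#' @keywords internal
solve_point_source <- function(geometry, mesh, eps_nodes) {
  solve_incident(geometry, mesh, eps_nodes, method = "point")
}

#' Simulate noise-free scattered-field data for a phantom
#'
#' @param phantom a `csinet_phantom`.
#' @param geometry an `acquisition_geometry`.
#' @param mesh forward `csinet_mesh`; defaults to `build_mesh(geometry,
#'   max_edge_frac = 1/15)` refined relative to the inversion default.
#' @return a `scatter_dataset`: complex receiver matrix `f` (`n_rx x n_tx`,
#'   scattered field relative to the homogeneous immersion medium), analytic
#'   incident fields at the receivers, the geometry, and `noise_level = 0`.
#' @export
forward_scatter <- function(phantom, geometry, mesh = NULL, context = NULL) {
  if (is.null(mesh)) mesh <- context$mesh %||% build_mesh(geometry, max_edge_frac = 1 / 15)
  if (is.null(context)) context <- fem_context(geometry, mesh)
  eps <- phantom_eps_complex(phantom)
  px <- attr(phantom$labels, "pixel_size")
  eps_nodes <- eps_on_mesh(mesh, eps, px, geometry$background_eps)
  sys <- helmholtz_system(mesh, eps_nodes, geometry, cache = context)
  sysb <- context$sysb
  einc <- context$einc_nodes
  dM_re <- sys$M_re - sysb$M_re
  dM_im <- sys$M_im - sysb$M_im
  rhs <- sp_cmult(dM_re, einc) + 1i * sp_cmult(dM_im, einc)
  fac <- cfactor(sys$A_re, sys$A_im)
  u <- csolve(fac, rhs)
  f <- sp_cmult(context$Rrx, u)
  inc_rx <- incident_analytic(geometry, geometry$rx_positions)
  structure(list(f = f, inc_rx = inc_rx, geometry = geometry,
                 noise_level = 0, forward_h = mesh$h),
            class = "scatter_dataset")
}

#' @export
print.scatter_dataset <- function(x, ...) {
  cat(sprintf("<scatter_dataset> %d rx x %d tx, noise %.1f%%, |f|_rms = %.3g\n",
              nrow(x$f), ncol(x$f), 100 * x$noise_level,
              sqrt(mean(Mod(x$f)^2))))
  invisible(x)
}

#' Add complex Gaussian measurement noise
#'
#' Independent zero-mean circular complex Gaussian noise per datum, scaled so
#' the expected noise RMS equals `level` times the RMS of the noise-free data
#' over the whole measurement set.
#'
#' @param dataset a `scatter_dataset`.
#' @param level relative noise level (e.g. 0.05 for 5\%).
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @return the dataset with noisy `f` and `noise_level` recorded.
#' @export
add_noise <- function(dataset, level, seed = NULL) {
  stopifnot(level >= 0)
  if (level == 0) return(dataset)
  f <- dataset$f
  sigma <- level * sqrt(mean(Mod(f)^2))
  noise <- with_seed(seed, {
    (matrix(rnorm(length(f)), nrow(f)) +
       1i * matrix(rnorm(length(f)), nrow(f))) * (sigma / sqrt(2))
  })
  dataset$f <- f + noise
  dataset$noise_level <- level
  dataset
}
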