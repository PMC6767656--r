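# Finite-element contrast source inversion.
#
# State variables live on the mesh nodes inside the imaging domain D. The
# FEM solve that maps contrast sources to fields is factorised once per
# prior and condensed into two dense Green matrices:
#   G_S : D sources -> receiver values      (M_S L)
#   G_D : D sources -> fields on D nodes    (M_D L)
# so that every CSI iteration is dense BLAS work and operator adjoints are
# exact conjugate transposes. The cost functional is the sum of the
# normalised data error F_S and normalised domain error F_D; contrast
# sources are updated by one Polak-Ribiere conjugate-gradient step with an
# exact (quadratic) line search per transmitter, then the contrast by its
# closed-form nodewise least-squares minimiser.

#' Build the CSI operator bundle for a prior background
#'
#' Assembles the FEM system with the prior as numerical background,
#' factorises it, and condenses the contrast-source-to-field map into dense
#' receiver and domain Green matrices. Incident fields (with respect to the
#' prior) are computed on the D nodes and at the receivers.
#'
#' @param mesh inversion `csinet_mesh`.
#' @param prior a `csinet_prior` (or a phantom-shaped list with
#'   `eps_n_real`/`eps_n_imag` grids).
#' @param geometry an `acquisition_geometry`.
#' @return an `operator_bundle`.
#' @export
build_operators <- function(mesh, prior, geometry, context = NULL) {
  if (is.null(context)) context <- fem_context(geometry, mesh)
  px <- attr(prior$region_labels, "pixel_size")
  eps_n_nodes <- eps_on_mesh(mesh, prior_eps_complex(prior), px,
                             geometry$background_eps)
  d_idx <- which(abs(mesh$nodes[, 1]) <= geometry$d_halfwidth + 1e-9 &
                 abs(mesh$nodes[, 2]) <= geometry$d_halfwidth + 1e-9)
  sys <- helmholtz_system(mesh, eps_n_nodes, geometry, cache = context)
  fac <- cfactor(sys$A_re, sys$A_im)

  # L[w] = A^{-1} M_{k_n^2}|_D w ; condense through the factorisation
  C <- as.matrix(sys$M_re[, d_idx]) + 1i * as.matrix(sys$M_im[, d_idx])
  X <- csolve(fac, C)
  Rrx <- context$Rrx
  G_S <- sp_cmult(Rrx, X)
  G_D <- X[d_idx, , drop = FALSE]

  # incident fields for the prior background: analytic + FEM correction
  einc_an <- context$einc_nodes
  sysb <- context$sysb
  dM_re <- sys$M_re - sysb$M_re
  dM_im <- sys$M_im - sysb$M_im
  corr_rhs <- sp_cmult(dM_re, einc_an) + 1i * sp_cmult(dM_im, einc_an)
  corr <- csolve(fac, corr_rhs)
  einc_full <- einc_an + corr
  # receiver-side incident difference field (prior minus immersion medium):
  # smooth at the colocated transmitter/receiver positions because its
  # sources live inside the breast, unlike the two singular incident fields
  # individually
  operator_bundle(G_S, G_D, einc_full[d_idx, , drop = FALSE],
                  inc_delta_rx = sp_cmult(Rrx, corr),
                  d_idx = d_idx, mesh = mesh, geometry = geometry,
                  eps_n_nodes = eps_n_nodes)
}

#' Assemble an operator bundle from explicit matrices
#'
#' Exposed so that tiny hand-built problems (e.g. a 3-node toy with 2x2
#' operators) exercise the same inversion code paths.
#'
#' @param G_S complex `n_rx x m` receiver Green matrix.
#' @param G_D complex `m x m` domain Green matrix.
#' @param einc complex `m x n_tx` incident fields on D nodes.
#' @param ... further fields stored on the bundle.
#' @return an `operator_bundle`.
#' @export
operator_bundle <- function(G_S, G_D, einc, ...) {
  stopifnot(ncol(G_S) == nrow(G_D), nrow(G_D) == ncol(G_D),
            nrow(einc) == nrow(G_D))
  structure(list(G_S = G_S, G_D = G_D, einc = einc, ...),
            class = "operator_bundle")
}

#' @export
print.operator_bundle <- function(x, ...) {
  cat(sprintf("<operator_bundle> %d receivers, %d D nodes, %d transmitters\n",
              nrow(x$G_S), nrow(x$G_D), ncol(x$einc)))
  invisible(x)
}

# prior-referenced data: the measured scattered field (relative to the
# homogeneous immersion medium) minus the incident difference field of the
# prior, i.e. E_tot - E_inc(prior) without ever evaluating a singular
# incident field at a colocated transmitter/receiver
calibrate_data <- function(dataset, operators) {
  dataset$f - operators$inc_delta_rx
}

#' Evaluate the CSI cost functional
#'
#' `F_S` is the data error normalised by the data norm; `F_D` is the domain
#' error normalised by `sum_t ||chi . e_t^inc||^2` evaluated at the supplied
#' contrast. Hadamard products are taken nodewise on D.
#'
#' @param chi complex contrast on D nodes.
#' @param sources complex `m x n_tx` contrast sources.
#' @param fdata complex `n_rx x n_tx` prior-referenced scattered-field data.
#' @param operators an `operator_bundle`.
#' @param eta_D optional fixed domain normaliser (defaults to the value at
#'   `chi`).
#' @return list with `F_S`, `F_D`, `F_CSI`.
#' @export
compute_cost <- function(chi, sources, fdata, operators, eta_D = NULL) {
  if (all(Mod(chi) == 0))
    stop_csinet("F_D is undefined for an identically zero contrast (its normaliser vanishes)")
  rho <- fdata - operators$G_S %*% sources
  F_S <- cnorm2(rho) / cnorm2(fdata)
  d <- chi * operators$einc - sources + chi * (operators$G_D %*% sources)
  if (is.null(eta_D)) eta_D <- cnorm2(chi * operators$einc)
  F_D <- cnorm2(d) / eta_D
  list(F_S = F_S, F_D = F_D, F_CSI = F_S + F_D)
}

#' Initialise the CSI state by back-propagation
#'
#' Contrast sources start at `w_t = s_t (M_S L)^H f_t` with the
#' per-transmitter complex scalar `s_t` minimising the data error; the
#' contrast is then the closed-form update from these sources. Deterministic.
#'
#' @param fdata prior-referenced data matrix (`n_rx x n_tx`).
#' @param operators an `operator_bundle`.
#' @return a `csi_state`.
#' @export
init_state <- function(fdata, operators) {
  g <- Conj(t(operators$G_S)) %*% fdata         # (M_S L)^H f
  Gg <- operators$G_S %*% g
  den <- colSums(Mod(Gg)^2)
  s <- ifelse(den > 0, colSums(Conj(Gg) * fdata) / den, 0 + 0i)
  W <- sweep(g, 2, s, `*`)
  st <- structure(list(W = W, chi = NULL, eta_D = NULL,
                       g_prev = NULL, v_prev = NULL,
                       n_dead_nodes = 0L,
                       cost_history = NULL, snapshots = list()),
                  class = "csi_state")
  update_contrast(st, operators)
}

#' One contrast-source update (Polak-Ribiere CG step, exact line search)
#'
#' The contrast and the domain normaliser `eta_D` stay fixed; the cost is
#' quadratic in the step length, so the exact minimiser is used and the cost
#' cannot increase.
#'
#' @param state a `csi_state` with non-null `chi` and `eta_D`.
#' @param fdata prior-referenced data matrix.
#' @param operators an `operator_bundle`.
#' @return updated `csi_state`.
#' @export
update_sources <- function(state, fdata, operators) {
  chi <- state$chi; W <- state$W
  eta_S <- 1 / cnorm2(fdata)
  eta_D <- 1 / state$eta_D
  GS <- operators$G_S; GD <- operators$G_D
  rho <- fdata - GS %*% W
  d <- chi * operators$einc - W + chi * (GD %*% W)
  g <- -(Conj(t(GS)) %*% rho) * eta_S + (-d + Conj(t(GD)) %*% (Conj(chi) * d)) * eta_D
  if (any(!is.finite(Re(g))) || any(!is.finite(Im(g))))
    stop_csinet("non-finite gradient in contrast-source update")
  if (is.null(state$g_prev)) {
    v <- -g
  } else {
    gp <- state$g_prev
    den <- colSums(Mod(gp)^2)
    beta <- Re(colSums(Conj(g - gp) * g))
    beta <- ifelse(den > 0, pmax(beta / den, 0), 0)
    v <- -g + sweep(state$v_prev, 2, beta, `*`)
  }
  Gv <- GS %*% v
  q <- -v + chi * (GD %*% v)
  num <- Re(colSums(Conj(Gv) * rho)) * eta_S - Re(colSums(Conj(q) * d)) * eta_D
  den <- colSums(Mod(Gv)^2) * eta_S + colSums(Mod(q)^2) * eta_D
  alpha <- ifelse(den > 0, num / den, 0)
  state$W <- W + sweep(v, 2, alpha, `*`)
  state$g_prev <- g
  state$v_prev <- v
  state
}

#' Closed-form contrast update
#'
#' With sources fixed, the minimiser of the (unnormalised) domain error is
#' `chi = sum_t w_t conj(E_t) / sum_t |E_t|^2` nodewise, with total fields
#' `E_t = e_t^inc + M_D L[w_t]`. Nodes where the field energy vanishes get
#' `chi = 0` and are counted in `n_dead_nodes`.
#'
#' @param state a `csi_state`.
#' @param operators an `operator_bundle`.
#' @return updated `csi_state`.
#' @export
update_contrast <- function(state, operators) {
  E <- operators$einc + operators$G_D %*% state$W
  den <- rowSums(Mod(E)^2)
  num <- rowSums(state$W * Conj(E))
  dead <- den == 0
  chi <- ifelse(dead, 0 + 0i, num / pmax(den, .Machine$double.xmin))
  state$chi <- chi
  state$n_dead_nodes <- sum(dead)
  if (is.null(state$eta_D)) state$eta_D <- max(cnorm2(chi * operators$einc),
                                               .Machine$double.xmin)
  state
}

#' Run contrast source inversion
#'
#' Alternates contrast-source and contrast updates for `n_iters` iterations.
#' The domain normaliser is recomputed once per outer iteration from the
#' previous contrast. Contrast snapshots are stored at the requested
#' iterations.
#'
#' @param dataset a `scatter_dataset` (or a prior-referenced data matrix when
#'   `operators` is supplied directly).
#' @param prior a `csinet_prior`; ignored when `operators` is given.
#' @param n_iters number of outer iterations (>= 1).
#' @param snapshot_iters integer vector of iterations at which to store the
#'   contrast (subset of `1:n_iters`).
#' @param geometry an `acquisition_geometry` (required with `prior`).
#' @param mesh inversion mesh; defaults to `build_mesh(geometry)`.
#' @param operators optionally a prebuilt `operator_bundle`.
#' @param cost_increase_tol relative per-step cost-increase tolerance before
#'   aborting (default 1e-10).
#' @return a `csi_result`: final contrast, snapshots, cost history, operator
#'   bundle.
#' @export
run_csi <- function(dataset, prior = NULL, n_iters = 250,
                    snapshot_iters = integer(0), geometry = NULL, mesh = NULL,
                    operators = NULL, cost_increase_tol = 1e-10) {
  stopifnot(n_iters >= 1)
  if (length(snapshot_iters) && (min(snapshot_iters) < 1 || max(snapshot_iters) > n_iters))
    stop_csinet("snapshot_iters must lie in [1, n_iters]")
  if (is.null(operators)) {
    if (is.null(prior) || is.null(geometry))
      stop_csinet("either operators or (prior, geometry) must be supplied")
    if (is.null(mesh)) mesh <- build_mesh(geometry)
    operators <- build_operators(mesh, prior, geometry)
  }
  fdata <- if (inherits(dataset, "scatter_dataset"))
    calibrate_data(dataset, operators) else dataset

  state <- init_state(fdata, operators)
  hist <- matrix(NA_real_, n_iters, 4,
                 dimnames = list(NULL, c("iter", "F_S", "F_D", "F_CSI")))
  snapshots <- list()
  prev_cost <- Inf
  for (it in seq_len(n_iters)) {
    state$eta_D <- max(cnorm2(state$chi * operators$einc), .Machine$double.xmin)
    state <- update_sources(state, fdata, operators)
    state <- update_contrast(state, operators)
    cost <- compute_cost(state$chi, state$W, fdata, operators, eta_D = state$eta_D)
    hist[it, ] <- c(it, cost$F_S, cost$F_D, cost$F_CSI)
    if (cost$F_CSI > prev_cost * (1 + cost_increase_tol) + 1e-14)
      warning(sprintf("CSI cost increased at iteration %d (%.3e -> %.3e)",
                      it, prev_cost, cost$F_CSI))
    prev_cost <- cost$F_CSI
    if (it %in% snapshot_iters) snapshots[[as.character(it)]] <- state$chi
  }
  structure(list(chi = state$chi, snapshots = snapshots,
                 cost_history = as.data.frame(hist),
                 operators = operators, state = state),
            class = "csi_result")
}

#' @export
print.csi_result <- function(x, ...) {
  n <- nrow(x$cost_history)
  cat(sprintf("<csi_result> %d iterations, final F_CSI = %.4g (F_S = %.4g, F_D = %.4g)\n",
              n, x$cost_history$F_CSI[n], x$cost_history$F_S[n], x$cost_history$F_D[n]))
  invisible(x)
}

#' Total permittivity from a contrast
#'
#' Inverts the contrast definition: `eps_r = eps_n (1 + chi)` on the D
#' nodes; outside D the numerical background is returned unchanged.
#'
#' @param chi complex contrast on D nodes.
#' @param operators the `operator_bundle` the contrast was computed with.
#' @return complex vector over all mesh nodes.
#' @export
total_permittivity <- function(chi, operators) {
  out <- operators$eps_n_nodes
  out[operators$d_idx] <- out[operators$d_idx] * (1 + chi)
  out
}

#' Contrast of a permittivity map against a numerical background
#' @param eps_r,eps_n complex arrays of identical shape.
#' @return `(eps_r - eps_n) / eps_n`.
#' @export
contrast_of <- function(eps_r, eps_n) (eps_r - eps_n) / eps_n

#' Rasterise nodal values to a pixel grid
#'
#' Barycentric (linear basis) interpolation of mesh-node values to pixel
#' centres of an `M x N` grid centred on the mesh origin.
#'
#' @param node_values complex or numeric vector over all mesh nodes.
#' @param mesh the `csinet_mesh`.
#' @param grid_shape `c(M, N)` pixels.
#' @param pixel_size pixel edge (cm).
#' @param P optional precomputed interpolation matrix from
#'   [raster_matrix()].
#' @return an `M x N` matrix.
#' @export
rasterize <- function(node_values, mesh, grid_shape, pixel_size, P = NULL) {
  if (is.null(P)) P <- raster_matrix(mesh, grid_shape, pixel_size)
  v <- if (is.complex(node_values))
    as.vector(P %*% Re(node_values)) + 1i * as.vector(P %*% Im(node_values))
  else as.vector(P %*% node_values)
  matrix(v, grid_shape[1], grid_shape[2])
}

#' Interpolation matrix from mesh nodes to pixel centres
#' @param mesh a `csinet_mesh`.
#' @param grid_shape `c(M, N)` pixels.
#' @param pixel_size pixel edge (cm).
#' @return sparse `(M*N) x n_nodes` matrix.
#' @export
raster_matrix <- function(mesh, grid_shape, pixel_size) {
  M <- grid_shape[1]; N <- grid_shape[2]
  x <- (seq_len(M) - 0.5) * pixel_size - M * pixel_size / 2
  y <- (seq_len(N) - 0.5) * pixel_size - N * pixel_size / 2
  # column-major pixel order: row index fastest
  pts <- cbind(rep(x, times = N), rep(y, each = N))
  interp_matrix(mesh, pts)
}
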