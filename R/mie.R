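# Analytic validation oracle: scattering of a TM line source by a
# homogeneous circular cylinder centred in the imaging domain, via the
# cylindrical-harmonic series. Fields and data are referenced to the
# homogeneous immersion medium, matching `forward_scatter`.

#' Analytic scattered field of a homogeneous dielectric cylinder
#'
#' Series solution for a circular cylinder of radius `radius` (cm) and
#' complex relative permittivity `eps_cyl` centred at the origin, illuminated
#' by the unit line sources of `geometry`. Harmonics are accumulated until
#' the magnitude of the next term falls below `tol` relative to the running
#' field amplitude.
#'
#' @param radius cylinder radius (cm); must be smaller than the measurement
#'   circle radius.
#' @param eps_cyl complex relative permittivity of the cylinder
#'   (`eps' - 1i eps''`).
#' @param geometry an `acquisition_geometry`.
#' @param points optional matrix of evaluation points (cm) outside the
#'   cylinder; defaults to the receiver positions.
#' @param tol series truncation tolerance (default 1e-12).
#' @return complex matrix `n_points x n_tx` of scattered fields.
#' @export
mie_cylinder_reference <- function(radius, eps_cyl, geometry, points = NULL,
                                   tol = 1e-12) {
  if (radius >= geometry$s_radius)
    stop_csinet("cylinder radius must be smaller than the measurement circle")
  if (is.null(points)) points <- geometry$rx_positions
  points <- as.matrix(points)
  kb <- geometry$k_bg
  kc <- geometry$k0 * sqrt(as.complex(eps_cyl))
  xb <- kb * radius
  xc <- kc * radius
  nmax <- as.integer(ceiling(Mod(xb)) + 40L)

  Jb <- besselj_complex(nmax + 1L, xb)
  Jc <- besselj_complex(nmax + 1L, xc)
  Hb <- hankel2_complex(nmax + 1L, xb)
  dJb <- bessel_deriv(Jb, xb)
  dJc <- bessel_deriv(Jc, xc)
  dHb <- bessel_deriv(Hb, xb)
  n_ord <- seq(0L, nmax)
  i1 <- n_ord + 1L
  ratio <- (kc * dJc[i1] * Jb[i1] - kb * dJb[i1] * Jc[i1]) /
           (kb * dHb[i1] * Jc[i1] - kc * dJc[i1] * Hb[i1])

  tx <- geometry$tx_positions
  rho_s <- sqrt(rowSums(tx^2)); phi_s <- atan2(tx[, 2], tx[, 1])
  rho_p <- sqrt(rowSums(points^2)); phi_p <- atan2(points[, 2], points[, 1])
  if (any(rho_p < radius - 1e-9))
    stop_csinet("evaluation points must lie outside the cylinder")

  H_s <- t(vapply(rho_s, function(r) hankel2_complex(nmax, kb * r), complex(nmax + 1L)))
  H_p <- t(vapply(rho_p, function(r) hankel2_complex(nmax, kb * r), complex(nmax + 1L)))

  out <- matrix(0i, nrow(points), nrow(tx))
  for (t in seq_len(nrow(tx))) {
    dphi <- phi_p - phi_s[t]
    acc <- rep(0i, nrow(points))
    converged <- FALSE
    for (n in 0:nmax) {
      coef <- -0.25i * ratio[n + 1L] * H_s[t, n + 1L]
      term <- coef * H_p[, n + 1L] * cos(n * dphi)
      if (n > 0) term <- 2 * term
      acc <- acc + term
      scale_now <- max(Mod(acc))
      if (n > Mod(xb) + 2 && max(Mod(term)) < tol * max(scale_now, 1e-300)) {
        converged <- TRUE
        break
      }
    }
    if (!converged && max(Mod(coef * H_p[, nmax + 1L])) > 1e-6 * max(Mod(acc)))
      stop_csinet("cylinder series did not converge within %d harmonics", nmax)
    out[, t] <- acc
  }
  out
}

# derivative via C'_n = C_{n-1} - (n/z) C_n given orders 0..(nmax+1)
bessel_deriv <- function(C, z) {
  n <- seq_along(C) - 1L
  d <- complex(length(C) - 1L)
  d[1] <- -C[2]
  idx <- seq(2L, length(C) - 1L)
  d[idx] <- C[idx - 1L] - ((idx - 1L) / z) * C[idx]
  d
}
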