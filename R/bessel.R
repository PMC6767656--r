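# Cylinder functions of integer order for complex argument.
#
# Base R's besselJ/besselY only accept real arguments; scattering in a lossy
# immersion medium needs J_n, Y_n and H_n^(2) at complex wavenumber times
# radius. Orders stay modest (<= ~60) and |z| stays below a few tens here,
# which permits a classical scheme:
#   * J_n by Miller's backward recurrence with the J_0 + 2*sum J_2k = 1
#     normalisation (valid for complex z),
#   * Y_0, Y_1 by the ascending series for |z| < 10, by the Hankel asymptotic
#     expansion beyond,
#   * H_n^(2) = J_n - i Y_n propagated upward (stable: |H_n| grows with n).
# Accuracy is limited by series cancellation to ~1e-10 relative near the
# series/asymptotic cut-over, ample for the 1e-6..1e-2 tolerances used here.

EULER_GAMMA <- 0.57721566490153286060651209

#' Bessel J of integer orders 0..nmax for complex argument
#'
#' @param nmax highest order.
#' @param z complex scalar argument.
#' @return complex vector of length `nmax + 1`, orders `0:nmax`.
#' @keywords internal
besselj_complex <- function(nmax, z) {
  z <- as.complex(z)
  if (Mod(z) < 1e-30) return(c(1 + 0i, rep(0 + 0i, nmax)))
  m <- as.integer(nmax + ceiling(1.2 * Mod(z)) + 25L)
  if (m %% 2L == 1L) m <- m + 1L
  f <- complex(m + 2L)            # f[k + 1] holds order k, k = 0..m+1
  f[m + 1L] <- 1e-280 + 0i        # order m
  for (k in seq(m, 1L)) {
    f[k] <- (2 * k / z) * f[k + 1L] - f[k + 2L]
    if (Mod(f[k]) > 1e200) f <- f * 1e-200
  }
  norm <- f[1L] + 2 * sum(f[seq(3L, m + 1L, by = 2L)])  # J0 + 2*sum J_{2k}
  f[seq_len(nmax + 1L)] / norm
}

# Hankel asymptotic expansion for H_nu^(2), nu = 0 or 1, |z| >= ~10.
hankel2_asym <- function(nu, z) {
  zi <- 1 / z
  mu <- 4 * nu^2
  a <- 1 + 0i
  s <- a
  term_ok <- TRUE
  for (k in 1:30) {
    a <- a * (mu - (2 * k - 1)^2) / (8i * k) * zi  # (-i)^k folded into sign
    # note: a_k(nu)/(-i)^k ... derived below; keep magnitudes monitored
    if (Mod(a) > Mod(s) * 10) { term_ok <- FALSE; break }
    s <- s + a
    if (Mod(a) < 1e-17 * Mod(s)) break
  }
  if (!term_ok && Mod(a) > 1e-8 * Mod(s))
    stop_csinet("hankel2_asym: divergent asymptotic series at |z| = %g", Mod(z))
  sqrt(2 / (pi * z)) * exp(-1i * (z - nu * pi / 2 - pi / 4)) * s
}

# Y0, Y1 by ascending series (complex z, |z| < ~12)
bessely01_series <- function(z) {
  j <- besselj_complex(1L, z)
  lg <- log(z / 2) + EULER_GAMMA
  # Y0 = (2/pi) [ (ln(z/2)+gamma) J0 + sum_{k>=1} (-1)^{k+1} H_k (z^2/4)^k/(k!)^2 ]
  q <- z^2 / 4
  term <- q; hk <- 1; s0 <- term * hk; sgn <- -1
  for (k in 2:80) {
    term <- term * q / k^2
    hk <- hk + 1 / k
    add <- sgn * term * hk
    s0 <- s0 + add
    sgn <- -sgn
    if (Mod(add) < 1e-18 * (Mod(s0) + 1e-30)) break
  }
  y0 <- (2 / pi) * (lg * j[1] + s0)
  # Y1 (Abramowitz & Stegun 9.1.11 rearranged)
  # Y1 = (2/pi) ln(z/2) J1 - (2/(pi z)) - (1/pi) * (z/2) * sum_{k>=0}
  #      (-1)^k [psi(k+1) + psi(k+2)] (z^2/4)^k / (k! (k+1)!)
  psum <- 0 + 0i
  term <- 1 + 0i  # (z^2/4)^k / (k!(k+1)!) at k = 0
  pk <- -EULER_GAMMA             # psi(1)
  pk1 <- -EULER_GAMMA + 1        # psi(2)
  sgn <- 1
  for (k in 0:80) {
    add <- sgn * (pk + pk1) * term
    psum <- psum + add
    if (k > 2 && Mod(add) < 1e-18 * (Mod(psum) + 1e-30)) break
    term <- term * q / ((k + 1) * (k + 2))
    pk <- pk + 1 / (k + 1)
    pk1 <- pk1 + 1 / (k + 2)
    sgn <- -sgn
  }
  y1 <- (2 / pi) * log(z / 2) * j[2] - 2 / (pi * z) - (z / (2 * pi)) * psum
  c(y0, y1)
}

#' Hankel functions of the second kind, orders 0..nmax, complex argument
#'
#' Used for outgoing cylindrical waves under the e^{+j omega t} convention.
#'
#' @param nmax highest order.
#' @param z complex scalar argument (Im(z) <= 0 for physical lossy media).
#' @return complex vector of length `nmax + 1`.
#' @keywords internal
hankel2_complex <- function(nmax, z) {
  z <- as.complex(z)
  if (Mod(z) >= 10) {
    h0 <- hankel2_asym(0, z)
    h1 <- hankel2_asym(1, z)
  } else {
    j <- besselj_complex(1L, z)
    y <- bessely01_series(z)
    h0 <- j[1] - 1i * y[1]
    h1 <- j[2] - 1i * y[2]
  }
  out <- complex(nmax + 1L)
  out[1] <- h0
  if (nmax >= 1) out[2] <- h1
  if (nmax >= 2) {
    for (n in 1:(nmax - 1L)) out[n + 2L] <- (2 * n / z) * out[n + 1L] - out[n]
  }
  out
}

#' Outgoing 2D line-source field (free-space Green function)
#'
#' Field of a unit line source in a homogeneous medium with wavenumber `k`
#' under the e^{+j omega t} convention: E(r) = -(j/4) H_0^(2)(k r), the
#' solution of (Laplacian + k^2) E = -delta.
#'
#' @param k complex wavenumber (rad/cm), `Im(k) <= 0` for a lossy medium.
#' @param dist vector of distances (cm) from the source; entries below
#'   `1e-9` are clamped to the mesh-scale value `1e-3`.
#' @return complex vector of field values.
#' @export
line_source_field <- function(k, dist) {
  d <- pmax(dist, 1e-3)
  z <- k * d
  # vectorised H0^(2): split by regime
  out <- complex(length(z))
  big <- Mod(z) >= 10
  if (any(big)) {
    zb <- z[big]
    s <- rep(1 + 0i, length(zb))
    a <- rep(1 + 0i, length(zb))
    for (kk in 1:30) {
      a <- a * (-(2 * kk - 1)^2) / (8i * kk) / zb
      s <- s + a
      if (max(Mod(a)) < 1e-16) break
    }
    out[big] <- sqrt(2 / (pi * zb)) * exp(-1i * (zb - pi / 4)) * s
  }
  if (any(!big)) {
    zs <- z[!big]
    q <- zs^2 / 4
    # J0 and the Y0 ascending series, term-recursive and vectorised over z
    j0 <- rep(1 + 0i, length(zs)); term <- rep(1 + 0i, length(zs))
    for (k in 1:45) { term <- term * (-q) / k^2; j0 <- j0 + term }
    s0 <- q; term <- q; hk <- 1; sgn <- -1
    for (k in 2:45) {
      term <- term * q / k^2
      hk <- hk + 1 / k
      s0 <- s0 + sgn * term * hk
      sgn <- -sgn
    }
    y0 <- (2 / pi) * ((log(zs / 2) + EULER_GAMMA) * j0 + s0)
    out[!big] <- j0 - 1i * y0
  }
  -0.25i * out
}
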