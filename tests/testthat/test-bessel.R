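test_that("complex Bessel J matches base R on the real axis", {
  for (z in c(0.4, 2.7, 9.1, 14.5, 33)) {
    J <- csinet:::besselj_complex(12L, z + 0i)
    expect_equal(Re(J), besselJ(z, 0:12), tolerance = 1e-9)
    expect_lt(max(abs(Im(J))), 1e-12)
  }
})

test_that("Hankel functions satisfy the cross-product (Wronskian) identity at complex argument", {
  for (z in c(0.7 - 0.2i, 3 - 1i, 8 - 0.5i, 9.9 - 0.1i, 15 - 2i, 40 - 1i)) {
    n <- 12L
    J <- csinet:::besselj_complex(n + 1L, z)
    H <- csinet:::hankel2_complex(n + 1L, z)
    Y <- (J - H) / 1i
    w <- J[2:(n + 2)] * Y[1:(n + 1)] - J[1:(n + 1)] * Y[2:(n + 2)]
    expect_lt(max(Mod(w - 2 / (pi * z))), 1e-9 * Mod(2 / (pi * z)))
  }
})

test_that("series and asymptotic Hankel branches agree where both are valid", {
  for (z in c(10.5 + 0i, 11 - 0.5i, 10.2 - 2i)) {
    j <- csinet:::besselj_complex(1L, z)
    y <- csinet:::bessely01_series(z)
    h_series <- j - 1i * y
    h_asym <- c(csinet:::hankel2_asym(0, z), csinet:::hankel2_asym(1, z))
    expect_lt(max(Mod(h_series - h_asym)) / max(Mod(h_asym)), 1e-8)
  }
})

test_that("vectorised line-source field equals the scalar Hankel evaluation", {
  k <- 1.0043 - 0.0218i
  d <- c(0.2, 1.7, 8.3, 9.99, 10.01, 25)
  f <- line_source_field(k, d)
  ref <- vapply(k * pmax(d, 1e-3),
                function(z) -0.25i * csinet:::hankel2_complex(0L, z)[1],
                complex(1))
  expect_equal(f, ref, tolerance = 1e-9)
})
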