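# Shared miniature fixtures, built once per test run.

fx <- fixture_suite()

toy_operators <- function() {
  operator_bundle(fx$toy_csi$G_S, fx$toy_csi$G_D, fx$toy_csi$einc)
}

# geometry of the 32 x 32 toy problem (half-scale breast in a 6.4 cm domain)
toy_geometry <- function(n_antennas = 24) {
  acquisition_geometry(n_antennas = n_antennas, s_radius = 5, d_halfwidth = 3.2)
}

# small homogeneous-background prior on an M x M pixel grid
homogeneous_prior <- function(M, pixel_size, background_eps = 23 - 1i) {
  labels <- structure(matrix(0L, M, M), pixel_size = pixel_size, model_id = "I")
  structure(list(eps_n_real = matrix(Re(background_eps), M, M),
                 eps_n_imag = matrix(-Im(background_eps), M, M),
                 region_labels = labels, boundary_jitter = 0, value_error = 0),
            class = "csinet_prior")
}

# cylinder phantom on a pixel grid (exterior = immersion medium)
cylinder_phantom <- function(radius, eps_cyl, M, pixel_size,
                             background_eps = 23 - 1i) {
  grid <- matrix(as.complex(background_eps), M, M)
  x <- (seq_len(M) - 0.5) * pixel_size - M * pixel_size / 2
  X <- matrix(x, M, M); Y <- t(X)
  grid[X^2 + Y^2 <= radius^2] <- as.complex(eps_cyl)
  structure(list(eps_real = Re(grid), eps_imag = -Im(grid),
                 labels = structure(matrix(0L, M, M), pixel_size = pixel_size),
                 tumor_mask = matrix(FALSE, M, M), n_tumors = 0L),
            class = "csinet_phantom")
}

# brute-force pairwise AUC oracle (ties count half)
pairwise_auc <- function(features, tumor) {
  pos <- features[tumor]; neg <- features[!tumor]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
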