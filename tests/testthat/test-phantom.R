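test_that("base models have the stated physical extents", {
  lab <- make_base_model("II", c(128, 128), 0.1, seed = 7)
  rows <- range(which(rowSums(lab > 0) > 0))
  cols <- range(which(colSums(lab > 0) > 0))
  # fatty breast is 11.2 x 9.6 cm -> about 112 x 96 px at 0.1 cm/px
  expect_lt(abs(diff(rows) + 1 - 112), 6)
  expect_lt(abs(diff(cols) + 1 - 96), 6)
  expect_error(make_base_model("IV", c(64, 64), 0.2), "valid ids")
})

test_that("fibroglandular fraction orders with density class over seeds", {
  frac <- function(model, seed) {
    lab <- make_base_model(model, c(64, 64), 0.2, seed = seed)
    sum(lab == 3L) / sum(lab > 0L)
  }
  seeds <- 1:20
  f2 <- vapply(seeds, function(s) frac("II", s), numeric(1))
  f1 <- vapply(seeds, function(s) frac("I", s), numeric(1))
  f3 <- vapply(seeds, function(s) frac("III", s), numeric(1))
  expect_gt(mean(f3), mean(f1))
  expect_gt(mean(f1), mean(f2))
})

test_that("label maps are deterministic given the seed and skin rings are closed", {
  a <- make_base_model("I", c(64, 64), 0.2, seed = 5)
  b <- make_base_model("I", c(64, 64), 0.2, seed = 5)
  expect_identical(a, b)
  for (m in c("I", "II", "III")) for (s in c(1, 9, 33)) {
    lab <- make_base_model(m, c(64, 64), 0.2, seed = s)
    expect_true(csinet:::skin_ring_closed(lab))
  }
})

test_that("tumor growth halts at one pixel when the diameter equals the pixel size", {
  lab <- make_base_model("I", c(64, 64), 0.2, seed = 3)
  m <- grow_tumor(lab, 0.2, seed = 11)
  expect_equal(sum(m), 1L)
})

test_that("grown tumors stay inside fibroglandular tissue and under the diameter bound", {
  lab <- make_base_model("I", c(64, 64), 0.2, seed = 3)
  px <- attr(lab, "pixel_size")
  centroids <- matrix(0, 10, 2)
  for (draw in 1:200) {
    dmax <- runif(1, 1.1, 1.5)
    m <- grow_tumor(lab, dmax, seed = draw)
    expect_true(all(lab[m] == 3L))
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) > 1) {
      d2 <- max(dist(idx * px))
      expect_lte(d2, dmax)
    }
    if (draw <= 10) centroids[draw, ] <- colMeans(idx)
  }
  expect_gte(nrow(unique(round(centroids))), 2)
})

test_that("tumor growth is rejected without fibroglandular pixels", {
  lab <- make_base_model("I", c(64, 64), 0.2, seed = 3)
  lab[lab == 3L] <- 2L
  expect_error(grow_tumor(lab, 1.2), "eligible seed")
})

test_that("two-tumor phantoms hold two disjoint non-touching components", {
  lab <- make_base_model("III", c(64, 64), 0.2, seed = 2)
  for (s in 1:5) {
    lab2 <- csinet:::add_tumors(lab, 2, c(1.1, 1.5), seed = s)
    expect_equal(csinet:::count_components(lab2 == 4L), 2L)
  }
})

test_that("permittivity assignment honours the tissue table", {
  lab <- make_base_model("I", c(64, 64), 0.2, seed = 3)
  lab <- csinet:::add_tumors(lab, 1, c(1.1, 1.5), seed = 4)
  ph0 <- assign_permittivity(lab, texture_level = 0, seed = 1)
  tt <- default_tissue_table()
  expect_true(all(ph0$eps_real[lab == 4L] == tt["4", 1]))
  expect_true(all(ph0$eps_imag[lab == 4L] == tt["4", 2]))
  expect_true(all(ph0$eps_real[lab == 0L] == tt["0", 1]))  # exterior exact
  ph <- assign_permittivity(lab, texture_level = 0.1, seed = 1)
  for (code in 1:4) {
    sel <- lab == code
    expect_lt(abs(mean(ph$eps_real[sel]) / tt[as.character(code), 1] - 1), 0.03)
  }
  expect_true(all(ph$eps_real[lab == 0L] == tt["0", 1]))
  bad <- tt[-1, , drop = FALSE]
  expect_error(assign_permittivity(lab, bad), "missing label")
})

test_that("the exact prior is the tumor-free phantom and never holds a tumor label", {
  lab <- make_base_model("II", c(64, 64), 0.2, seed = 6)
  lab <- csinet:::add_tumors(lab, 1, c(1.1, 1.5), seed = 7)
  ph <- assign_permittivity(lab, texture_level = 0, seed = 1)
  pr <- make_prior(ph, 0, 0, seed = 2)
  tm <- ph$tumor_mask
  expect_equal(pr$eps_n_real[!tm], ph$eps_real[!tm])
  expect_equal(pr$eps_n_imag[!tm], ph$eps_imag[!tm])
  tt <- default_tissue_table()
  expect_true(all(pr$eps_n_real[tm] == tt["3", 1]))
  expect_false(any(pr$region_labels == 4L))
  # zero contrast everywhere except tumor pixels
  chi <- contrast_of(csinet:::phantom_eps_complex(ph),
                     csinet:::prior_eps_complex(pr))
  expect_lt(max(Mod(chi[!tm])), 1e-12)
  expect_gt(min(Mod(chi[tm])), 0.1)
})

test_that("a degraded prior keeps most pixel labels", {
  lab <- make_base_model("I", c(128, 128), 0.1, seed = 8)
  lab <- csinet:::add_tumors(lab, 1, c(1.1, 1.5), seed = 9)
  ph <- assign_permittivity(lab, texture_level = 0, seed = 1)
  pr <- make_prior(ph, 2, 0.05, seed = 3)
  clean <- lab; clean[clean == 4L] <- 3L
  expect_gte(mean(pr$region_labels == clean), 0.95)
  expect_false(any(pr$region_labels == 4L))
})

test_that("dataset generation writes balanced, reproducible manifests", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  man <- generate_dataset(1, 0, 99, d1, grid_shape = c(32, 32),
                          pixel_size = 0.2, scale = 0.5,
                          tumor_diameter_range = c(0.55, 0.75))
  expect_equal(nrow(man$entries), 3L)
  expect_setequal(man$entries$model_id, c("I", "II", "III"))

  man2 <- generate_dataset(8, 8, 42, d2, grid_shape = c(32, 32),
                           pixel_size = 0.2, scale = 0.5,
                           tumor_diameter_range = c(0.55, 0.75))
  expect_equal(nrow(man2$entries), 48L)
  expect_equal(sum(man2$entries$n_tumors == 1), 24L)
  tab <- table(man2$entries$fold, man2$entries$model_id)
  expect_true(all(tab == 4L))  # balanced folds per model
  # reproducibility: same master seed -> identical manifest and phantoms
  d3 <- file.path(tempdir(), "ds3")
  man3 <- generate_dataset(8, 8, 42, d3, grid_shape = c(32, 32),
                           pixel_size = 0.2, scale = 0.5,
                           tumor_diameter_range = c(0.55, 0.75))
  expect_identical(man2$entries[, c("path", "model_id", "n_tumors", "fold")],
                   man3$entries[, c("path", "model_id", "n_tumors", "fold")])
  p2 <- csinet:::load_phantom(man2, 5)
  p3 <- csinet:::load_phantom(man3, 5)
  expect_identical(p2$phantom$eps_real, p3$phantom$eps_real)
  # manifest JSON round-trips
  man_r <- read_manifest(file.path(d2, "manifest.json"))
  expect_equal(man_r$entries$fold, man2$entries$fold)
  # every generated tumor respects the invariants
  for (i in seq_len(nrow(man2$entries))) {
    pp <- csinet:::load_phantom(man2, i)
    expect_true(all(pp$phantom$tumor_mask == (pp$phantom$labels == 4L)))
  }
})
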