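test_that("rms_error matches direct arithmetic", {
  a <- matrix(1:25, 5, 5) * 1.0
  expect_equal(rms_error(a, a), 0)
  expect_equal(rms_error(a + 2, a), 2)
  set.seed(6)
  p <- matrix(rnorm(25), 5, 5); q <- matrix(rnorm(25), 5, 5)
  m <- matrix(runif(25) > 0.4, 5, 5)
  expect_equal(rms_error(p, q, m), sqrt(mean((p[m] - q[m])^2)))
  expect_error(rms_error(p, q, m & FALSE), "empty")
  expect_error(rms_error(p, matrix(0, 2, 2)), "shape")
})

test_that("pixel ROC-AUC equals the brute-force pairwise statistic", {
  # degenerate polarities
  expect_equal(pixel_roc_auc(rep(1, 10), c(rep(TRUE, 3), rep(FALSE, 7)))$auc, 0.5)
  expect_equal(pixel_roc_auc(c(1, 2, 3, 9, 8), c(F, F, F, T, T))$auc, 1)
  expect_error(pixel_roc_auc(1:4, rep(TRUE, 4)), "both tumor")
  # 6-pixel worked example, oracle = exhaustive pair comparison
  r6 <- fx$roc6
  oracle <- pairwise_auc(r6$features, r6$tumor)
  got <- pixel_roc_auc(r6$features, r6$tumor)
  expect_equal(got$auc, oracle)
  expect_equal(got$roc$fpr[1], 0); expect_equal(got$roc$tpr[1], 0)
  expect_equal(tail(got$roc$fpr, 1), 1); expect_equal(tail(got$roc$tpr, 1), 1)
  # random inputs with ties, up to 1000 pixels
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(50:1000, 1)
    feat <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
    tum <- runif(n) < 0.2
    if (!any(tum) || all(tum)) next
    expect_equal(pixel_roc_auc(feat, tum)$auc, pairwise_auc(feat, tum),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone feature transforms", {
  set.seed(13)
  feat <- rnorm(400); tum <- runif(400) < 0.25
  a0 <- pixel_roc_auc(feat, tum)$auc
  expect_equal(pixel_roc_auc(exp(feat), tum)$auc, a0)
  expect_equal(pixel_roc_auc(2 * feat - 7, tum)$auc, a0)
  expect_equal(pixel_roc_auc(atan(feat), tum)$auc, a0)
})

test_that("image transforms compose correctly", {
  set.seed(14)
  img <- matrix(rnorm(64), 8, 8)
  r <- img
  for (k in 1:4) r <- csinet:::transform_image(r, "rot90")
  expect_equal(r, img)
  expect_equal(csinet:::transform_image(csinet:::transform_image(img, "flip_h"), "flip_h"), img)
  expect_equal(csinet:::transform_image(csinet:::transform_image(img, "rot90"), "rot270"), img)
  expect_equal(csinet:::transform_image(img, "rot180"),
               csinet:::transform_image(csinet:::transform_image(img, "rot90"), "rot90"))
})

# A tiny cross-validation world: CSI reconstructions are emulated as the
# truth plus smooth artifacts and blur, so the partition/exclusion logic and
# report layout are exercised without the physics stack.
make_cv_world <- function() {
  dir <- file.path(tempdir(), "cvworld")
  man <- generate_dataset(4, 0, 77, dir, grid_shape = c(32, 32),
                          pixel_size = 0.2, scale = 0.5,
                          tumor_diameter_range = c(0.55, 0.75))
  recons <- list()
  set.seed(20)
  for (i in seq_len(nrow(man$entries))) {
    ph <- csinet:::load_phantom(man, i)$phantom
    blur <- function(x) {
      y <- x
      y[2:31, 2:31] <- (x[1:30, 2:31] + x[3:32, 2:31] + x[2:31, 1:30] +
                        x[2:31, 3:32] + 4 * x[2:31, 2:31]) / 8
      y
    }
    recons[[i]] <- list(real = blur(ph$eps_real) + matrix(rnorm(1024, 0, 2), 32),
                        imag = blur(ph$eps_imag) + matrix(rnorm(1024, 0, 0.5), 32))
  }
  list(man = man, recons = recons)
}

test_that("cross-validation partitions folds and honours model exclusions", {
  w <- make_cv_world()
  cfgt <- list(depth = 2, base_filters = 2, epochs = 1, batch_size = 4, seed = 2)
  rep <- run_cross_validation(w$man, w$recons, settings = "A", arch = 1,
                              train_config = cfgt, folds = 0:3)
  # every phantom appears exactly once as a test example across the folds
  a_rows <- rep[rep$technique == "U-Net A" & rep$subset == "I,II,III" &
                rep$part == "real", ]
  expect_equal(sum(a_rows$n_phantoms), nrow(w$man$entries))
  expect_equal(nrow(a_rows), 4)
  # one row per technique x part x subset x fold
  expect_equal(nrow(rep), 4 * 2 * 2 * length(csinet:::MODEL_SUBSETS))
  # settings B-D exclude one model from training but not from testing
  repB <- run_cross_validation(w$man, w$recons, settings = "B", arch = 1,
                               train_config = cfgt, folds = 0)
  expect_true("III" %in% repB$subset)
  expect_true(all(c("CSI", "U-Net B") %in% repB$technique))
})

test_that("the robustness grid covers snapshots x transforms and reports render", {
  w <- make_cv_world()
  idx <- which(w$man$entries$fold == 0)
  truths <- lapply(idx, function(i) {
    ph <- csinet:::load_phantom(w$man, i)$phantom
    list(real = ph$eps_real, imag = ph$eps_imag)
  })
  masks <- lapply(idx, function(i) csinet:::load_phantom(w$man, i)$phantom$labels > 0)
  tmasks <- lapply(idx, function(i) csinet:::load_phantom(w$man, i)$phantom$tumor_mask)
  enh <- train_enhancer(w$recons[idx], truths, arch = 1,
                        config = list(depth = 2, base_filters = 2, epochs = 1,
                                      batch_size = 4, seed = 3))
  rob <- robustness_suite(enh, list("20" = w$recons[idx], "30" = w$recons[idx]),
                          truths, masks, tmasks)
  expect_equal(nrow(rob), 2 * 6 * 2 * 2)  # snapshots x transforms x technique x part
  ident <- rob[rob$transform == "identity" & rob$snapshot == "20", ]
  again <- rob[rob$transform == "identity" & rob$snapshot == "30", ]
  expect_equal(ident$rms, again$rms)  # same inputs reproduce the same numbers
  # render + JSON round trip
  out <- file.path(tempdir(), "repout")
  w2 <- run_cross_validation(w$man, w$recons, settings = "A", arch = 1,
                             train_config = list(depth = 2, base_filters = 2,
                                                 epochs = 1, batch_size = 4,
                                                 seed = 2), folds = 0)
  paths <- render_report(w2, out)
  expect_true(all(file.exists(paths)))
  back <- read_report(file.path(out, "report.json"))
  expect_equal(back$rms, w2$rms, tolerance = 1e-12)
  expect_equal(nrow(back), nrow(w2))
})
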