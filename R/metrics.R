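# Quantitative assessment: RMS reconstruction error and pixel-wise tumor
# ROC-AUC, cross-validated over training settings that include or exclude
# whole breast-model classes.

#' Root-mean-square reconstruction error over a pixel mask
#'
#' @param pred,truth numeric matrices of identical shape.
#' @param mask logical matrix selecting evaluated pixels; defaults to all.
#' @return `sqrt(mean((pred - truth)^2))` over the mask.
#' @export
rms_error <- function(pred, truth, mask = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop_csinet("pred and truth must share their shape")
  if (is.null(mask)) mask <- array(TRUE, dim(pred))
  if (!any(mask)) stop_csinet("empty evaluation mask")
  sqrt(mean((pred[mask] - truth[mask])^2))
}

#' Pixel-wise ROC curve and AUC for tumor detectability
#'
#' Pixels are pooled across all supplied images; the reconstructed
#' permittivity value is the detection feature (higher = more tumor-like).
#' The AUC is the tie-corrected rank statistic (Mann-Whitney), equal to the
#' probability that a random tumor pixel outranks a random non-tumor pixel.
#'
#' @param features numeric vector/matrix or list of them (feature images).
#' @param tumor_masks logical vector/matrix or list, same shapes.
#' @return list with `auc` and a `roc` data frame (`fpr`, `tpr`,
#'   `threshold`), endpoints (0,0) and (1,1) included.
#' @export
pixel_roc_auc <- function(features, tumor_masks) {
  if (is.list(features)) features <- unlist(lapply(features, as.vector))
  if (is.list(tumor_masks)) tumor_masks <- unlist(lapply(tumor_masks, as.vector))
  x <- as.vector(features); y <- as.logical(tumor_masks)
  stopifnot(length(x) == length(y))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop_csinet("pixel_roc_auc needs both tumor and non-tumor pixels")
  r <- rank(x)  # midranks: ties handled
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # ROC by sweeping thresholds over the unique feature values (descending)
  ord <- order(x, decreasing = TRUE)
  ys <- y[ord]; xs <- x[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- c(xs[-1] != xs[-length(xs)], TRUE)  # threshold boundaries
  roc <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos),
                    threshold = c(Inf, xs[last]))
  list(auc = auc, roc = roc)
}

# geometric transforms used by the robustness protocol (square images)
transform_image <- function(img, transform) {
  switch(transform,
         identity = img,
         rot90 = t(img[nrow(img):1, , drop = FALSE]),
         rot180 = img[nrow(img):1, ncol(img):1, drop = FALSE],
         rot270 = t(img)[nrow(img):1, , drop = FALSE],
         flip_h = img[nrow(img):1, , drop = FALSE],
         flip_v = img[, ncol(img):1, drop = FALSE],
         stop_csinet("unknown transform '%s'", transform))
}

MODEL_SUBSETS <- list("I,II,III" = c("I", "II", "III"),
                      "I" = "I", "II" = "II", "III" = "III",
                      "I,II" = c("I", "II"), "I,III" = c("I", "III"),
                      "II,III" = c("II", "III"))

TRAIN_SETTINGS <- list(A = c("I", "II", "III"), B = c("I", "II"),
                       C = c("I", "III"), D = c("II", "III"))

# ---- enhancer: architecture 1 / 2 wrappers -------------------------------

#' Train a permittivity enhancer on CSI reconstructions
#'
#' Architecture 1 trains two independent single-output networks (one for the
#' real and one for the imaginary part of the true permittivity);
#' architecture 2 trains one network whose three outputs are the magnitude,
#' real and imaginary parts. Both consume the same 3-channel input stack
#' (real, imaginary, magnitude of the CSI reconstruction). Min-max
#' normalisers are fitted on the training split only and stored with the
#' model.
#'
#' @param recons list of reconstructions, each `list(real =, imag =)` image
#'   pair (CSI permittivity, eps' and eps'').
#' @param truths list of matching ground-truth pairs.
#' @param arch architecture, 1 or 2.
#' @param config training configuration: `depth`, `base_filters`, `epochs`,
#'   `batch_size`, `lr`, `seed`, optional `channel_weights` (arch 2).
#' @return a `csinet_enhancer`.
#' @export
train_enhancer <- function(recons, truths, arch = 1,
                           config = list()) {
  cfg <- modifyList(list(depth = 4, base_filters = 32, epochs = 75,
                         batch_size = 10, lr = 1e-3, seed = 1,
                         channel_weights = NULL), config)
  stopifnot(arch %in% c(1, 2), length(recons) == length(truths),
            length(recons) >= 1)
  n <- length(recons)
  d <- dim(recons[[1]]$real)
  X <- array(0, c(d[1], d[2], n, 3))
  for (i in seq_len(n))
    X[, , i, ] <- make_input_stack(recons[[i]]$real, recons[[i]]$imag)
  in_nrm <- fit_normalizer(X)
  Xn <- normalize_stack(in_nrm, X)
  models <- list()
  if (arch == 1) {
    for (part in c("real", "imag")) {
      Yt <- array(0, c(d[1], d[2], n, 1))
      for (i in seq_len(n)) Yt[, , i, 1] <- truths[[i]][[part]]
      t_nrm <- fit_normalizer(Yt)
      net <- build_unet(3, 1, cfg$depth, cfg$base_filters,
                        seed = derive_seed(cfg$seed, paste0("init/", part)))
      net <- train_unet(net, Xn, normalize_stack(t_nrm, Yt),
                        epochs = cfg$epochs, batch_size = cfg$batch_size,
                        lr = cfg$lr,
                        seed = derive_seed(cfg$seed, paste0("shuffle/", part)))
      models[[part]] <- list(net = net, t_nrm = t_nrm)
    }
  } else {
    Yt <- array(0, c(d[1], d[2], n, 3))
    for (i in seq_len(n)) {
      Yt[, , i, 1] <- sqrt(truths[[i]]$real^2 + truths[[i]]$imag^2)
      Yt[, , i, 2] <- truths[[i]]$real
      Yt[, , i, 3] <- truths[[i]]$imag
    }
    t_nrm <- fit_normalizer(Yt)
    net <- build_unet(3, 3, cfg$depth, cfg$base_filters,
                      seed = derive_seed(cfg$seed, "init/joint"))
    net <- train_unet(net, Xn, normalize_stack(t_nrm, Yt),
                      epochs = cfg$epochs, batch_size = cfg$batch_size,
                      lr = cfg$lr, seed = derive_seed(cfg$seed, "shuffle/joint"),
                      channel_weights = cfg$channel_weights)
    models$joint <- list(net = net, t_nrm = t_nrm)
  }
  structure(list(arch = arch, models = models, in_nrm = in_nrm,
                 config = cfg),
            class = "csinet_enhancer")
}

#' @export
print.csinet_enhancer <- function(x, ...) {
  cat(sprintf("<csinet_enhancer> architecture %d (%s), depth %d, %d base filters\n",
              x$arch, paste(names(x$models), collapse = " + "),
              x$config$depth, x$config$base_filters))
  invisible(x)
}

#' Enhance a CSI reconstruction
#'
#' @param enhancer a trained `csinet_enhancer`.
#' @param recon `list(real =, imag =)` CSI permittivity images.
#' @return `list(real =, imag =)` predicted true-permittivity images (plus
#'   `magnitude` for architecture 2).
#' @export
enhance <- function(enhancer, recon) {
  x <- make_input_stack(recon$real, recon$imag, enhancer$in_nrm)
  if (enhancer$arch == 1) {
    out <- lapply(c(real = "real", imag = "imag"), function(part) {
      m <- enhancer$models[[part]]
      p <- predict_unet(m$net, x)
      denormalize_stack(m$t_nrm, p)[, , 1]
    })
    out
  } else {
    m <- enhancer$models$joint
    p <- denormalize_stack(m$t_nrm, predict_unet(m$net, x))
    list(real = p[, , 2], imag = p[, , 3], magnitude = p[, , 1])
  }
}

# ---- evaluation ----------------------------------------------------------

# evaluate one set of predictions against truths on a subset of cases
eval_subset <- function(preds, truths, masks, tumor_masks) {
  out <- list()
  for (part in c("real", "imag")) {
    pr <- lapply(preds, `[[`, part)
    tr <- lapply(truths, `[[`, part)
    se <- 0; np <- 0
    feats <- vector("list", length(pr)); tms <- vector("list", length(pr))
    for (i in seq_along(pr)) {
      m <- masks[[i]]
      se <- se + sum((pr[[i]][m] - tr[[i]][m])^2)
      np <- np + sum(m)
      feats[[i]] <- pr[[i]][m]
      tms[[i]] <- tumor_masks[[i]][m]
    }
    roc <- pixel_roc_auc(feats, tms)
    out[[part]] <- list(rms = sqrt(se / np), auc = roc$auc, roc = roc$roc,
                        n_pixels = np)
  }
  out
}

#' Cross-validated evaluation of CSI and enhanced reconstructions
#'
#' For each requested fold and training setting (A: all models; B/C/D:
#' model III/II/I excluded from training), trains an enhancer on the
#' training folds and evaluates RMS error and pooled pixel-wise ROC-AUC on
#' the hold-out fold, for every model-subset combination, alongside the raw
#' CSI baseline on the same inputs. Evaluation uses breast-interior pixels.
#'
#' @param manifest a `dataset_manifest`.
#' @param recons named list of CSI reconstruction pairs, indexed by manifest
#'   entry (each `list(real =, imag =)`).
#' @param settings subset of `c("A","B","C","D")`.
#' @param arch architecture 1 or 2.
#' @param train_config see [train_enhancer()].
#' @param folds folds to run (default all four).
#' @return an `eval_report` data frame (one row per setting x part x
#'   subset x fold, plus CSI baseline rows) with ROC curves attached.
#' @export
run_cross_validation <- function(manifest, recons, settings = c("A", "B", "C", "D"),
                                 arch = 1, train_config = list(), folds = 0:3) {
  stopifnot(all(settings %in% names(TRAIN_SETTINGS)))
  ent <- manifest$entries
  rows <- list(); rocs <- list()
  truths <- masks <- tmasks <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    pp <- load_phantom(manifest, i)
    truths[[i]] <- list(real = pp$phantom$eps_real, imag = pp$phantom$eps_imag)
    masks[[i]] <- pp$phantom$labels > 0
    tmasks[[i]] <- pp$phantom$tumor_mask
  }
  add_rows <- function(technique, setting, fold, subset_name, idx, preds) {
    ev <- eval_subset(preds[idx], truths[idx], masks[idx], tmasks[idx])
    for (part in c("real", "imag")) {
      key <- paste(technique, setting, fold, subset_name, part, sep = "|")
      rocs[[key]] <<- ev[[part]]$roc
      rows[[length(rows) + 1]] <<- data.frame(
        setting = setting, technique = technique, architecture = arch,
        fold = fold, part = part, subset = subset_name,
        rms = ev[[part]]$rms, auc = ev[[part]]$auc,
        n_pixels = ev[[part]]$n_pixels, n_phantoms = length(idx),
        stringsAsFactors = FALSE)
    }
  }
  for (fold in folds) {
    test_idx <- which(ent$fold == fold)
    if (!length(test_idx)) stop_csinet("fold %d holds no phantoms", fold)
    # CSI baseline on the hold-out
    for (sn in names(MODEL_SUBSETS)) {
      idx <- test_idx[ent$model_id[test_idx] %in% MODEL_SUBSETS[[sn]]]
      if (length(idx)) add_rows("CSI", "N/A", fold, sn, idx, recons)
    }
    for (s in settings) {
      tr_idx <- which(ent$fold != fold & ent$model_id %in% TRAIN_SETTINGS[[s]])
      if (length(tr_idx) < 2)
        stop_csinet("setting %s fold %d: not enough training phantoms", s, fold)
      enh <- train_enhancer(recons[tr_idx], truths[tr_idx], arch,
                            modifyList(train_config,
                                       list(seed = derive_seed(train_config$seed %||% 1,
                                                               paste0("cv/", s, "/", fold)))))
      preds <- vector("list", nrow(ent))
      for (i in test_idx) preds[[i]] <- enhance(enh, recons[[i]])
      for (sn in names(MODEL_SUBSETS)) {
        idx <- test_idx[ent$model_id[test_idx] %in% MODEL_SUBSETS[[sn]]]
        if (length(idx)) add_rows(paste0("U-Net ", s), s, fold, sn, idx, preds)
      }
    }
  }
  rep <- do.call(rbind, rows)
  attr(rep, "rocs") <- rocs
  class(rep) <- c("eval_report", class(rep))
  rep
}

#' Robustness protocol: off-training CSI iteration counts and geometric
#' transforms
#'
#' Evaluates a trained enhancer on every (CSI snapshot, transform) cell:
#' inputs are CSI reconstructions stopped at iteration counts the model was
#' not trained on, and/or rotated/flipped; truth images and masks are
#' transformed identically. The CSI baseline is computed on the same
#' transformed inputs.
#'
#' @param enhancer a trained `csinet_enhancer`.
#' @param recons_by_snapshot named list: snapshot label -> list of recon
#'   pairs (test split).
#' @param truths,masks,tumor_masks lists matching the test split.
#' @param transforms character vector of transforms (default the full grid
#'   including identity).
#' @return an `eval_report` data frame with one row per snapshot x transform
#'   x technique x part.
#' @export
robustness_suite <- function(enhancer, recons_by_snapshot, truths, masks,
                             tumor_masks,
                             transforms = c("identity", "rot90", "rot180",
                                            "rot270", "flip_h", "flip_v")) {
  rows <- list()
  for (snap in names(recons_by_snapshot)) {
    rc <- recons_by_snapshot[[snap]]
    for (tf in transforms) {
      rct <- lapply(rc, function(r) list(real = transform_image(r$real, tf),
                                         imag = transform_image(r$imag, tf)))
      trt <- lapply(truths, function(r) list(real = transform_image(r$real, tf),
                                             imag = transform_image(r$imag, tf)))
      mkt <- lapply(masks, transform_image, transform = tf)
      tmt <- lapply(tumor_masks, transform_image, transform = tf)
      preds <- lapply(rct, function(r) enhance(enhancer, r))
      for (tech in c("CSI", "U-Net")) {
        pr <- if (tech == "CSI") rct else preds
        ev <- eval_subset(pr, trt, mkt, tmt)
        for (part in c("real", "imag")) {
          rows[[length(rows) + 1]] <- data.frame(
            snapshot = snap, transform = tf, technique = tech, part = part,
            rms = ev[[part]]$rms, auc = ev[[part]]$auc,
            n_pixels = ev[[part]]$n_pixels, stringsAsFactors = FALSE)
        }
      }
    }
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("eval_report", class(rep))
  rep
}

#' Write an evaluation report to disk
#'
#' Writes the table as CSV, the full report (including ROC points when
#' present) as JSON, and ROC curve plots as PNG.
#'
#' @param report an `eval_report`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_csinet("cannot create output directory '%s'", out_dir)
  csv <- file.path(out_dir, "report.csv")
  write.csv(as.data.frame(report), csv, row.names = FALSE)
  rocs <- attr(report, "rocs")
  json <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(table = as.data.frame(report), rocs = rocs),
                       json, auto_unbox = TRUE, digits = NA)
  paths <- c(csv, json)
  if (!is.null(rocs) && length(rocs)) {
    png_path <- file.path(out_dir, "roc_curves.png")
    grDevices::png(png_path, width = 900, height = 700)
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = "Pixel-wise tumor ROC")
    graphics::abline(0, 1, lty = 3, col = "grey")
    cols <- grDevices::rainbow(length(rocs))
    for (i in seq_along(rocs))
      graphics::lines(rocs[[i]]$fpr, rocs[[i]]$tpr, col = cols[i])
    graphics::legend("bottomright", legend = names(rocs), col = cols,
                     lwd = 1, cex = 0.6)
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}

#' Read back a JSON evaluation report
#' @param path path to `report.json`.
#' @return an `eval_report`.
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- as.data.frame(j$table)
  attr(rep, "rocs") <- j$rocs
  class(rep) <- c("eval_report", class(rep))
  rep
}
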