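# End-to-end orchestration: generation -> forward -> inversion -> training
# -> evaluation, with per-stage caching keyed by configuration hashes and a
# single master seed from which every stochastic choice is derived.

#' Default run configuration
#'
#' Full-scale settings mirror the study conditions (128 x 128 phantoms at
#' 0.1 cm, 200 + 200 phantoms per model, 250 CSI iterations with snapshots
#' at 20/150/250/500, 75 training epochs); [desk_config()] provides the
#' scaled-down preset used for interactive work and testing.
#'
#' @param out_dir run directory.
#' @param master_seed integer master seed.
#' @param ... named overrides merged into the nested config (e.g.
#'   `csi = list(n_iters = 100)`).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, master_seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    master_seed = as.integer(master_seed),
    physics = list(frequency = 1e9, n_antennas = 24, s_radius = 9.5,
                   background_eps_real = 23, background_eps_imag = 1,
                   d_halfwidth = 6.4, noise_level = 0.05,
                   forward_h = 0.2, inversion_h = 0.3),
    dataset = list(per_model_single = 200, per_model_double = 200,
                   grid_shape = c(128, 128), pixel_size = 0.1, scale = 1,
                   tumor_diameter_range = c(1.1, 1.5), texture_level = 0.05,
                   prior_jitter_px = 2, prior_value_error = 0.05),
    csi = list(n_iters = 250, snapshots = c(20, 150, 250)),
    train = list(arch = 1, epochs = 75, batch_size = 10, lr = 1e-3,
                 depth = 4, base_filters = 32, setting = "A", fold = 0),
    eval = list(settings = c("A", "B", "C", "D"), folds = 0:3,
                robustness = TRUE,
                transforms = c("identity", "rot90", "rot180", "rot270",
                               "flip_h", "flip_v"))
  )
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = "run_config")
}

# merge overrides (possibly with duplicated names, later entries winning)
# into a nested config
merge_config <- function(cfg, overrides) {
  for (k in seq_along(overrides)) {
    nm <- names(overrides)[k]
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[k]]))
      modifyList(cfg[[nm]], overrides[[k]]) else overrides[[k]]
  }
  cfg
}

#' Desk-scale preset
#'
#' 64 x 64 phantoms at 0.2 cm, 40 phantoms per model, 16 antennas, 30 CSI
#' iterations (snapshots 10/20/30), a depth-3 / 8-filter network trained for
#' 15 epochs, single hold-out fold. Completes end-to-end on one CPU in
#' minutes rather than days.
#'
#' @param out_dir run directory.
#' @param master_seed integer master seed.
#' @param ... overrides as in [run_config()].
#' @return a `run_config`.
#' @export
desk_config <- function(out_dir, master_seed = 1, ...) {
  cfg <- run_config(out_dir, master_seed,
                    physics = list(n_antennas = 16, forward_h = 0.32,
                                   inversion_h = 0.5),
                    dataset = list(per_model_single = 20, per_model_double = 20,
                                   grid_shape = c(64, 64), pixel_size = 0.2),
                    csi = list(n_iters = 30, snapshots = c(10, 20, 30)),
                    train = list(epochs = 15, depth = 3, base_filters = 8),
                    eval = list(settings = "A", folds = 0))
  structure(merge_config(unclass(cfg), list(...)), class = "run_config")
}

config_geometry <- function(cfg) {
  p <- cfg$physics
  acquisition_geometry(frequency = p$frequency, n_antennas = p$n_antennas,
                       s_radius = p$s_radius,
                       background_eps = p$background_eps_real -
                         1i * p$background_eps_imag,
                       d_halfwidth = p$d_halfwidth)
}

#' Save / load a run configuration as YAML
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

stage_hash <- function(cfg, stage) {
  dep <- switch(stage,
    generate = cfg[c("master_seed", "dataset")],
    forward  = cfg[c("master_seed", "dataset", "physics")],
    invert   = cfg[c("master_seed", "dataset", "physics", "csi")],
    train    = cfg[c("master_seed", "dataset", "physics", "csi", "train")],
    evaluate = cfg[c("master_seed", "dataset", "physics", "csi", "train", "eval")])
  rlang::hash(dep)
}

stage_fresh <- function(dir, hash) {
  stamp <- file.path(dir, ".stamp")
  file.exists(stamp) && identical(readLines(stamp, warn = FALSE)[1], hash)
}

stamp_stage <- function(dir, hash) writeLines(hash, file.path(dir, ".stamp"))

log_stage <- function(cfg, stage, hash, seconds, skipped = FALSE) {
  line <- jsonlite::toJSON(list(stage = stage, hash = hash,
                                master_seed = cfg$master_seed,
                                wall_seconds = round(seconds, 2),
                                skipped = skipped,
                                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                           auto_unbox = TRUE)
  cat(paste0(line, "\n"), file = file.path(cfg$out_dir, "provenance.jsonl"),
      append = TRUE)
}

#' Run the full pipeline
#'
#' Executes generation, forward simulation, inversion, training and
#' evaluation in order. A stage whose configuration hash matches its stamp
#' (and whose outputs exist) is skipped; deleting a stage directory forces
#' its re-run. A provenance log records hashes, seeds and wall times.
#'
#' @param cfg a `run_config`.
#' @param stages stages to consider (default all, in order).
#' @param verbose print stage progress.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("generate", "forward", "invert",
                                         "train", "evaluate"),
                         verbose = TRUE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  runner <- list(generate = stage_generate, forward = stage_forward,
                 invert = stage_invert, train = stage_train,
                 evaluate = stage_evaluate)
  for (stage in stages) {
    sdir <- file.path(cfg$out_dir, stage_dirname(stage))
    h <- stage_hash(cfg, stage)
    if (stage_fresh(sdir, h)) {
      say("[%s] up to date, skipping", stage)
      log_stage(cfg, stage, h, 0, skipped = TRUE)
      next
    }
    say("[%s] running ...", stage)
    t0 <- proc.time()[3]
    ok <- tryCatch({ runner[[stage]](cfg); TRUE },
                   error = function(e) {
                     stop_csinet("pipeline stage '%s' failed: %s", stage,
                                 conditionMessage(e))
                   })
    stamp_stage(sdir, h)
    log_stage(cfg, stage, h, proc.time()[3] - t0)
    say("[%s] done (%.1f s)", stage, proc.time()[3] - t0)
  }
  invisible(cfg$out_dir)
}

stage_dirname <- function(stage) {
  c(generate = "data", forward = "forward", invert = "recon",
    train = "train", evaluate = "eval")[[stage]]
}

stage_generate <- function(cfg) {
  d <- cfg$dataset
  generate_dataset(d$per_model_single, d$per_model_double,
                   derive_seed(cfg$master_seed, "generate"),
                   file.path(cfg$out_dir, "data"),
                   grid_shape = d$grid_shape, pixel_size = d$pixel_size,
                   scale = d$scale,
                   tumor_diameter_range = d$tumor_diameter_range,
                   texture_level = d$texture_level,
                   prior_jitter_px = d$prior_jitter_px,
                   prior_value_error = d$prior_value_error)
}

pipeline_manifest <- function(cfg) {
  read_manifest(file.path(cfg$out_dir, "data", "manifest.json"))
}

stage_forward <- function(cfg) {
  man <- pipeline_manifest(cfg)
  geo <- config_geometry(cfg)
  dir.create(file.path(cfg$out_dir, "forward"), showWarnings = FALSE)
  mesh <- disk_mesh(geo$omega_radius, cfg$physics$forward_h)
  ctx <- fem_context(geo, mesh)
  for (i in seq_len(nrow(man$entries))) {
    pp <- load_phantom(man, i)
    ds <- forward_scatter(pp$phantom, geo, context = ctx)
    ds <- add_noise(ds, cfg$physics$noise_level,
                    seed = derive_seed(cfg$master_seed, paste0("noise/", i)))
    saveRDS(ds, file.path(cfg$out_dir, "forward", sprintf("scatter_%04d.rds", i)))
  }
}

stage_invert <- function(cfg) {
  man <- pipeline_manifest(cfg)
  geo <- config_geometry(cfg)
  dir.create(file.path(cfg$out_dir, "recon"), showWarnings = FALSE)
  mesh <- disk_mesh(geo$omega_radius, cfg$physics$inversion_h)
  ctx <- fem_context(geo, mesh)
  P <- raster_matrix(mesh, cfg$dataset$grid_shape, cfg$dataset$pixel_size)
  snaps <- cfg$csi$snapshots
  for (i in seq_len(nrow(man$entries))) {
    pp <- load_phantom(man, i)
    ds <- readRDS(file.path(cfg$out_dir, "forward", sprintf("scatter_%04d.rds", i)))
    ops <- build_operators(mesh, pp$prior, geo, context = ctx)
    res <- run_csi(ds, operators = ops, n_iters = cfg$csi$n_iters,
                   snapshot_iters = snaps)
    out <- list(snapshots = list(), cost_history = res$cost_history)
    for (s in names(res$snapshots)) {
      eps <- total_permittivity(res$snapshots[[s]], ops)
      img <- rasterize(eps, mesh, cfg$dataset$grid_shape,
                       cfg$dataset$pixel_size, P = P)
      out$snapshots[[s]] <- list(real = Re(img), imag = -Im(img))
    }
    saveRDS(out, file.path(cfg$out_dir, "recon", sprintf("recon_%04d.rds", i)))
  }
}

# reconstructions (final snapshot by default) for all manifest entries
pipeline_recons <- function(cfg, snapshot = NULL) {
  man <- pipeline_manifest(cfg)
  snapshot <- snapshot %||% as.character(max(cfg$csi$snapshots))
  lapply(seq_len(nrow(man$entries)), function(i) {
    readRDS(file.path(cfg$out_dir, "recon",
                      sprintf("recon_%04d.rds", i)))$snapshots[[snapshot]]
  })
}

stage_train <- function(cfg) {
  man <- pipeline_manifest(cfg)
  dir.create(file.path(cfg$out_dir, "train"), showWarnings = FALSE)
  recons <- pipeline_recons(cfg)
  ent <- man$entries
  tc <- cfg$train
  tr_idx <- which(ent$fold != tc$fold &
                  ent$model_id %in% TRAIN_SETTINGS[[tc$setting]])
  truths <- lapply(tr_idx, function(i) {
    ph <- load_phantom(man, i)$phantom
    list(real = ph$eps_real, imag = ph$eps_imag)
  })
  enh <- train_enhancer(recons[tr_idx], truths, arch = tc$arch,
                        config = list(depth = tc$depth,
                                      base_filters = tc$base_filters,
                                      epochs = tc$epochs,
                                      batch_size = tc$batch_size, lr = tc$lr,
                                      seed = derive_seed(cfg$master_seed, "train")))
  saveRDS(enh, file.path(cfg$out_dir, "train", "enhancer.rds"))
}

stage_evaluate <- function(cfg) {
  man <- pipeline_manifest(cfg)
  dir.create(file.path(cfg$out_dir, "eval"), showWarnings = FALSE)
  recons <- pipeline_recons(cfg)
  rep <- run_cross_validation(man, recons, settings = cfg$eval$settings,
                              arch = cfg$train$arch,
                              train_config = list(depth = cfg$train$depth,
                                                  base_filters = cfg$train$base_filters,
                                                  epochs = cfg$train$epochs,
                                                  batch_size = cfg$train$batch_size,
                                                  lr = cfg$train$lr,
                                                  seed = derive_seed(cfg$master_seed, "cv")),
                              folds = cfg$eval$folds)
  render_report(rep, file.path(cfg$out_dir, "eval"))
  if (isTRUE(cfg$eval$robustness)) {
    enh <- readRDS(file.path(cfg$out_dir, "train", "enhancer.rds"))
    ent <- man$entries
    te_idx <- which(ent$fold == cfg$train$fold)
    by_snap <- lapply(setNames(nm = as.character(cfg$csi$snapshots)),
                      function(s) pipeline_recons(cfg, s)[te_idx])
    truths <- masks <- tmasks <- list()
    for (k in seq_along(te_idx)) {
      ph <- load_phantom(man, te_idx[k])$phantom
      truths[[k]] <- list(real = ph$eps_real, imag = ph$eps_imag)
      masks[[k]] <- ph$labels > 0
      tmasks[[k]] <- ph$tumor_mask
    }
    rob <- robustness_suite(enh, by_snap, truths, masks, tmasks,
                            transforms = cfg$eval$transforms)
    write.csv(as.data.frame(rob),
              file.path(cfg$out_dir, "eval", "robustness.csv"),
              row.names = FALSE)
    jsonlite::write_json(as.data.frame(rob),
                         file.path(cfg$out_dir, "eval", "robustness.json"),
                         auto_unbox = TRUE, digits = NA)
  }
}

# ---- canned fixtures -----------------------------------------------------

#' Deterministic miniature test assets
#'
#' Builds the tiny fixtures used by the test suite: a hand-built 2-node CSI
#' toy problem with operator-consistent data, the analytic-cylinder
#' validation case, a 32 x 32 single-tumor phantom (scale 0.5) and the
#' 6-pixel ROC example. All are constructed in code from fixed seeds.
#'
#' @param out_dir optional directory; when given, fixtures are also written
#'   there (RDS/JSON).
#' @return a named list of fixtures.
#' @export
fixture_suite <- function(out_dir = NULL) {
  # 2x2 hand-built CSI toy with a consistent solution
  G_S <- matrix(c(0.8 + 0.1i, 0.2 - 0.3i, -0.1 + 0.4i, 0.5 + 0.2i), 2, 2)
  G_D <- matrix(c(0.3 + 0.05i, 0.1 - 0.1i, 0.05 + 0.2i, 0.25 - 0.05i), 2, 2)
  einc <- matrix(c(1 + 0i, 0.4 - 0.2i, 0.3 + 0.5i, 0.9 + 0.1i), 2, 2)
  chi_true <- c(0.3 + 0.1i, 0.15 - 0.05i)
  E <- solve(diag(2) - G_D %*% diag(chi_true), einc)
  W <- chi_true * E
  toy <- list(G_S = G_S, G_D = G_D, einc = einc, chi_true = chi_true,
              f = G_S %*% W, W_true = W)

  mie_case <- list(radius = 3, eps_real = 30, eps_imag = 3,
                   frequency = 1e9, n_antennas = 24, s_radius = 9.5,
                   background_eps_real = 23, background_eps_imag = 1)

  lab <- make_base_model("I", c(32, 32), 0.2, seed = 42, scale = 0.5)
  lab <- add_tumors(lab, 1, c(0.55, 0.75), seed = 43)
  phantom32 <- assign_permittivity(lab, texture_level = 0.05, seed = 44)

  roc6 <- list(features = c(1, 2, 3, 4, 3, 5),
               tumor = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))

  fx <- list(toy_csi = toy, mie_case = mie_case, phantom32 = phantom32,
             roc6 = roc6)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(toy, file.path(out_dir, "toy_csi.rds"))
    jsonlite::write_json(mie_case, file.path(out_dir, "mie_case.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(phantom32, file.path(out_dir, "phantom32.rds"))
    jsonlite::write_json(roc6, file.path(out_dir, "roc6.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}
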