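# Desk-scale study shared by the trend and robustness acceptance tests:
# 40 phantoms per model on a 64 x 64 grid, 16 antennas, 30 CSI iterations.
# Built lazily once per test session; the learning stage is re-run per
# training seed by the tests themselves.

.desk_cache <- new.env(parent = emptyenv())

desk_run <- function() {
  if (!is.null(.desk_cache$run)) return(.desk_cache$run)
  dir <- file.path(tempdir(), "desk_acceptance_run")
  cfg <- desk_config(dir, master_seed = 42)
  run_pipeline(cfg, stages = c("generate", "forward", "invert"), verbose = FALSE)
  man <- read_manifest(file.path(dir, "data", "manifest.json"))
  ent <- man$entries
  truths <- masks <- tmasks <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    ph <- csinet:::load_phantom(man, i)$phantom
    truths[[i]] <- list(real = ph$eps_real, imag = ph$eps_imag)
    masks[[i]] <- ph$labels > 0
    tmasks[[i]] <- ph$tumor_mask
  }
  recons <- csinet:::pipeline_recons(cfg)          # 30-iteration inputs
  recons20 <- csinet:::pipeline_recons(cfg, "20")  # early-stopped inputs
  .desk_cache$run <- list(cfg = cfg, man = man, ent = ent, truths = truths,
                          masks = masks, tmasks = tmasks,
                          recons = recons, recons20 = recons20,
                          test_idx = which(ent$fold == 0),
                          train_idx = which(ent$fold != 0))
  .desk_cache$run
}

desk_metrics <- function(preds, run, idx) {
  out <- list()
  for (part in c("real", "imag")) {
    se <- 0; np <- 0; feats <- list(); tms <- list()
    for (k in seq_along(idx)) {
      i <- idx[k]
      m <- run$masks[[i]]
      p <- preds[[k]][[part]]
      se <- se + sum((p[m] - run$truths[[i]][[part]][m])^2)
      np <- np + sum(m)
      feats[[k]] <- p[m]; tms[[k]] <- run$tmasks[[i]][m]
    }
    out[[part]] <- list(rms = sqrt(se / np),
                        auc = pixel_roc_auc(feats, tms)$auc)
  }
  out
}

desk_enhancer <- function(run, seed) {
  key <- paste0("enh", seed)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  tc <- run$cfg$train
  enh <- train_enhancer(run$recons[run$train_idx], run$truths[run$train_idx],
                        arch = 1,
                        config = list(depth = tc$depth,
                                      base_filters = tc$base_filters,
                                      epochs = tc$epochs,
                                      batch_size = tc$batch_size,
                                      lr = tc$lr, seed = seed))
  .desk_cache[[key]] <- enh
  enh
}
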