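# Procedural 2D breast phantoms.
#
# Tissue label codes on the pixel grid:
#   0 exterior (immersion medium), 1 skin, 2 fat, 3 fibroglandular, 4 tumor.
# Three base geometries span the BI-RADS density range: model I is a
# heterogeneously dense breast (10 x 9.5 cm), model II a fatty breast
# (11.2 x 9.6 cm), model III a very dense breast (10 x 5 cm). Each is an
# ellipse outline with a smooth random perturbation, a closed skin ring, a
# fat background, and one contiguous fibroglandular blob whose area fraction
# encodes the density class. Tumors are grown pixel-by-pixel inside the
# fibroglandular region up to a maximum diameter.

LABEL_EXTERIOR <- 0L
LABEL_SKIN <- 1L
LABEL_FAT <- 2L
LABEL_FIBRO <- 3L
LABEL_TUMOR <- 4L

MODEL_SPECS <- list(
  I   = list(dims = c(10.0, 9.5),  fibro_frac = 0.40),
  II  = list(dims = c(11.2, 9.6),  fibro_frac = 0.15),
  III = list(dims = c(10.0, 5.0),  fibro_frac = 0.65)
)

#' Default tissue dielectric table
#'
#' Complex relative permittivity (eps', eps'') per tissue label at the
#' operating frequency. Values are mid-range single-pole literature values
#' for breast tissue around 1 GHz, chosen to give the large
#' fibroglandular/fat contrast characteristic of this imaging problem; they
#' are configurable assumptions, not measured constants.
#'
#' @return a 5 x 2 matrix with rows named by label code `0:4`.
#' @export
default_tissue_table <- function() {
  m <- rbind(`0` = c(23, 1),     # immersion (matching) medium
             `1` = c(36, 4),     # skin
             `2` = c(5, 0.5),    # fat
             `3` = c(35, 6),     # fibroglandular
             `4` = c(50, 10))    # tumor
  colnames(m) <- c("eps_real", "eps_imag")
  m
}

# ellipse radial extent along direction theta for semi-axes (a, b)
ellipse_radius <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# smooth periodic perturbation, max |value| == amp
random_perturbation <- function(n_modes, amp, lowest = 2L) {
  co <- rnorm(n_modes)
  ph <- runif(n_modes, 0, 2 * pi)
  modes <- seq(lowest, length.out = n_modes)
  f <- function(theta) {
    s <- 0
    for (m in seq_len(n_modes)) s <- s + co[m] * cos(modes[m] * theta + ph[m])
    s
  }
  peak <- max(abs(f(seq(0, 2 * pi, length.out = 720))))
  if (peak == 0) return(function(theta) theta * 0)
  function(theta) f(theta) * (amp / peak)
}

#' Generate a base breast tissue label map
#'
#' @param model_id `"I"` (heterogeneously dense), `"II"` (fatty) or
#'   `"III"` (very dense).
#' @param grid_shape integer vector `c(M, N)` of grid dimensions in pixels.
#' @param pixel_size pixel edge length in cm.
#' @param seed integer seed; the map is deterministic given the seed.
#' @param scale multiplier on the physical model dimensions (scaled-down
#'   phantoms for small test grids).
#' @return an integer `M x N` label matrix with attributes `pixel_size`,
#'   `model_id` and `scale`.
#' @export
make_base_model <- function(model_id, grid_shape = c(128, 128),
                            pixel_size = 0.1, seed = NULL, scale = 1) {
  if (!model_id %in% names(MODEL_SPECS))
    stop_csinet("unknown model_id '%s'; valid ids are %s", model_id,
                paste(names(MODEL_SPECS), collapse = ", "))
  spec <- MODEL_SPECS[[model_id]]
  a <- spec$dims[1] * scale / 2
  b <- spec$dims[2] * scale / 2
  M <- grid_shape[1]; N <- grid_shape[2]
  if (2 * a > M * pixel_size || 2 * b > N * pixel_size)
    stop_csinet("grid %d x %d at %g cm/px cannot hold model %s (%g x %g cm)",
                M, N, pixel_size, model_id, 2 * a, 2 * b)
  with_seed(seed, {
    pert <- random_perturbation(4L, 0.015)
    x <- (seq_len(M) - 0.5) * pixel_size - M * pixel_size / 2
    y <- (seq_len(N) - 0.5) * pixel_size - N * pixel_size / 2
    X <- matrix(x, M, N); Y <- matrix(y, M, N, byrow = TRUE)
    TH <- atan2(Y, X)
    R <- sqrt(X^2 + Y^2)
    r_out <- ellipse_radius(TH, a, b) * (1 + pert(TH))
    t_skin <- max(0.2, 1.75 * pixel_size)
    inside <- R <= r_out
    interior <- R <= r_out - t_skin
    labels <- matrix(LABEL_EXTERIOR, M, N)
    labels[inside] <- LABEL_SKIN
    labels[interior] <- LABEL_FAT

    # one contiguous fibroglandular blob, star-shaped in breast-scaled coords
    cx <- runif(1, -0.12, 0.12) * a
    cy <- runif(1, -0.12, 0.12) * b
    bpert <- random_perturbation(4L, 0.30, lowest = 1L)
    U <- (X - cx) / a; V <- (Y - cy) / b
    RU <- sqrt(U^2 + V^2); THU <- atan2(V, U)
    rho0 <- sqrt(spec$fibro_frac)
    fib <- RU <= rho0 * (1 + bpert(THU)) & interior
    labels[fib] <- LABEL_FIBRO
    attr(labels, "pixel_size") <- pixel_size
    attr(labels, "model_id") <- model_id
    attr(labels, "scale") <- scale
    labels
  })
}

#' Grow a tumor mask inside the fibroglandular region
#'
#' Contiguous pixels are grown 4-connectedly from a uniformly sampled
#' fibroglandular start pixel; a candidate pixel is accepted only while the
#' maximum pairwise pixel-centre distance of the mask stays below
#' `max_diameter_cm`. Growth halts when no candidate can be added.
#'
#' @param labels a tissue label map from [make_base_model()].
#' @param max_diameter_cm maximum tumor diameter in cm.
#' @param seed integer seed.
#' @return a logical matrix of the same shape as `labels`.
#' @export
grow_tumor <- function(labels, max_diameter_cm, seed = NULL) {
  px <- attr(labels, "pixel_size")
  elig <- which(labels == LABEL_FIBRO)
  if (length(elig) == 0)
    stop_csinet("no eligible seed pixel: the fibroglandular region is empty")
  M <- nrow(labels); N <- ncol(labels)
  with_seed(seed, {
    start <- elig[sample.int(length(elig), 1)]
    si <- (start - 1) %% M + 1; sj <- (start - 1) %/% M + 1
    region <- matrix(c(si, sj), 1, 2)
    in_region <- matrix(FALSE, M, N)
    in_region[si, sj] <- TRUE
    repeat {
      # frontier: 4-neighbours of the region that are fibroglandular
      cand <- unique(rbind(
        cbind(region[, 1] + 1L, region[, 2]),
        cbind(region[, 1] - 1L, region[, 2]),
        cbind(region[, 1], region[, 2] + 1L),
        cbind(region[, 1], region[, 2] - 1L)))
      ok <- cand[, 1] >= 1 & cand[, 1] <= M & cand[, 2] >= 1 & cand[, 2] <= N
      cand <- cand[ok, , drop = FALSE]
      keep <- labels[cand] == LABEL_FIBRO & !in_region[cand]
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0) break
      # diameter constraint: distance from candidate to every region pixel
      d2max <- (max_diameter_cm / px)^2
      dist2 <- outer(cand[, 1], region[, 1], "-")^2 +
               outer(cand[, 2], region[, 2], "-")^2
      valid <- apply(dist2, 1, max) < d2max
      cand <- cand[valid, , drop = FALSE]
      if (nrow(cand) == 0) break
      pick <- cand[sample.int(nrow(cand), 1), , drop = FALSE]
      region <- rbind(region, pick)
      in_region[pick] <- TRUE
    }
    in_region
  })
}

# add n_tumors tumors to a label map; the second tumor may not touch the
# first (8-connectivity), regrown up to 100 times
add_tumors <- function(labels, n_tumors, diameter_range, seed = NULL) {
  with_seed(seed, {
    d1 <- runif(1, diameter_range[1], diameter_range[2])
    m1 <- grow_tumor(labels, d1)
    out <- labels
    out[m1] <- LABEL_TUMOR
    if (n_tumors >= 2) {
      grown <- FALSE
      for (att in 1:100) {
        d2 <- runif(1, diameter_range[1], diameter_range[2])
        m2 <- grow_tumor(out, d2)  # fibro excludes tumor 1 already
        if (!touches(m2, m1)) { grown <- TRUE; break }
      }
      if (!grown) stop_csinet("could not place a second non-touching tumor in 100 attempts")
      out[m2] <- LABEL_TUMOR
    }
    out
  })
}

# do two masks touch (8-connectivity) or overlap?
touches <- function(a, b) {
  bd <- b
  bd[-1, ] <- bd[-1, ] | b[-nrow(b), ]
  bd[-nrow(b), ] <- bd[-nrow(b), ] | b[-1, ]
  bd[, -1] <- bd[, -1] | bd[, -ncol(b)]
  bd[, -ncol(b)] <- bd[, -ncol(b)] | bd[, -1]
  any(a & bd)
}

# label 4-connected components of a mask (0 = background)
label_components <- function(mask) {
  M <- nrow(mask); N <- ncol(mask)
  lab <- matrix(0L, M, N)
  comp <- 0L
  idx <- which(mask & lab == 0L)
  while (length(idx) > 0) {
    comp <- comp + 1L
    stack <- idx[1]
    while (length(stack) > 0) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] > 0L) next
      lab[p] <- comp
      i <- (p - 1) %% M + 1; j <- (p - 1) %/% M + 1
      for (q in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (q[1] >= 1 && q[1] <= M && q[2] >= 1 && q[2] <= N &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L)
          stack <- c(stack, (q[2] - 1) * M + q[1])
      }
    }
    idx <- which(mask & lab == 0L)
  }
  lab
}

count_components <- function(mask) max(label_components(mask))

#' Convert a label map to a complex-permittivity phantom
#'
#' Per-pixel permittivity is the tissue-table value times `(1 + u)` with
#' `u ~ U(-texture_level, texture_level)` drawn independently per pixel
#' (exterior pixels carry the exact immersion-medium value).
#'
#' @param labels tissue label map (possibly containing tumors).
#' @param tissue_table matrix as from [default_tissue_table()].
#' @param texture_level relative amplitude of the multiplicative
#'   heterogeneity texture (default 0.05).
#' @param seed integer seed.
#' @return a `csinet_phantom` with `eps_real`, `eps_imag` grids, the label
#'   map, the tumor mask and the tumor count.
#' @export
assign_permittivity <- function(labels, tissue_table = default_tissue_table(),
                                texture_level = 0.05, seed = NULL) {
  codes <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.character(codes), rownames(tissue_table))
  if (length(missing) > 0)
    stop_csinet("tissue_table is missing label code(s): %s",
                paste(missing, collapse = ", "))
  if (any(tissue_table[, 1] < 1) || any(tissue_table[, 2] < 0))
    stop_csinet("tissue_table requires eps' >= 1 and eps'' >= 0")
  with_seed(seed, {
    key <- as.character(labels)
    er <- matrix(tissue_table[key, 1], nrow(labels), ncol(labels))
    ei <- matrix(tissue_table[key, 2], nrow(labels), ncol(labels))
    if (texture_level > 0) {
      u <- matrix(1 + runif(length(labels), -texture_level, texture_level),
                  nrow(labels), ncol(labels))
      tissue <- labels != LABEL_EXTERIOR
      er[tissue] <- er[tissue] * u[tissue]
      ei[tissue] <- ei[tissue] * u[tissue]
    }
    mask <- labels == LABEL_TUMOR
    structure(list(eps_real = er, eps_imag = ei, labels = labels,
                   tumor_mask = mask,
                   n_tumors = count_components(mask),
                   tissue_table = tissue_table,
                   texture_level = texture_level),
              class = "csinet_phantom")
  })
}

#' @export
print.csinet_phantom <- function(x, ...) {
  cat(sprintf("<csinet_phantom> model %s, %d x %d px (%.3g cm/px), %d tumor(s)\n",
              attr(x$labels, "model_id") %||% "?", nrow(x$labels), ncol(x$labels),
              attr(x$labels, "pixel_size"), x$n_tumors))
  invisible(x)
}

phantom_eps_complex <- function(phantom) {
  phantom$eps_real - 1i * phantom$eps_imag
}

#' Surrogate three-region prior map
#'
#' Emulates an ultrasound-derived tissue-region prior: the tumor class is
#' removed (relabelled fibroglandular), region boundaries are displaced by a
#' smooth random field bounded by `boundary_jitter_px`, and each region's
#' permittivity is the tissue-table value scaled by one random factor in
#' `1 +/- value_error_frac`. With zero jitter and zero value error the prior
#' equals the texture-free tumor-free phantom exactly.
#'
#' @param phantom a `csinet_phantom`.
#' @param boundary_jitter_px maximum boundary displacement in pixels.
#' @param value_error_frac relative error on per-region permittivity values.
#' @param seed integer seed.
#' @return a `csinet_prior` with `eps_n_real`, `eps_n_imag` grids and
#'   tumor-free `region_labels`.
#' @export
make_prior <- function(phantom, boundary_jitter_px = 2,
                       value_error_frac = 0.05, seed = NULL) {
  labels <- phantom$labels
  M <- nrow(labels); N <- ncol(labels)
  clean <- labels
  clean[clean == LABEL_TUMOR] <- LABEL_FIBRO
  with_seed(seed, {
    if (boundary_jitter_px > 0) {
      dx <- smooth_field(M, N); dy <- smooth_field(M, N)
      nrm <- sqrt(dx^2 + dy^2)
      sc <- boundary_jitter_px / max(nrm)
      dx <- dx * sc; dy <- dy * sc
      si <- pmin(pmax(round(row(clean) + dx), 1), M)
      sj <- pmin(pmax(round(col(clean) + dy), 1), N)
      jl <- matrix(clean[cbind(as.vector(si), as.vector(sj))], M, N)
    } else jl <- clean
    tt <- phantom$tissue_table
    fac <- setNames(1 + runif(nrow(tt), -value_error_frac, value_error_frac),
                    rownames(tt))
    fac["0"] <- 1  # exterior is the known immersion medium
    key <- as.character(jl)
    er <- matrix(tt[key, 1] * fac[key], M, N)
    ei <- matrix(tt[key, 2] * fac[key], M, N)
    attr(jl, "pixel_size") <- attr(labels, "pixel_size")
    attr(jl, "model_id") <- attr(labels, "model_id")
    structure(list(eps_n_real = er, eps_n_imag = ei, region_labels = jl,
                   boundary_jitter = boundary_jitter_px,
                   value_error = value_error_frac),
              class = "csinet_prior")
  })
}

# smooth zero-mean random field on an M x N grid (low-order Fourier modes)
smooth_field <- function(M, N) {
  f <- matrix(0, M, N)
  x <- seq_len(M) / M; y <- seq_len(N) / N
  for (m in 1:3) for (n in 1:3) {
    f <- f + rnorm(1) * outer(cos(2 * pi * m * x + runif(1, 0, 2 * pi)),
                              cos(2 * pi * n * y + runif(1, 0, 2 * pi)))
  }
  f
}

prior_eps_complex <- function(prior) {
  prior$eps_n_real - 1i * prior$eps_n_imag
}

#' Generate a phantom dataset with manifest
#'
#' For each of the three base models, `per_model_single` single-tumor and
#' `per_model_double` two-tumor phantoms are generated (the base geometry is
#' drawn once per model from the master seed; tumors, texture and the
#' surrogate prior vary per phantom). Fold assignment is balanced per model
#' and per tumor count across 4 folds. Everything is reproducible from
#' `master_seed`.
#'
#' @param per_model_single,per_model_double phantom counts per model.
#' @param master_seed integer master seed.
#' @param out_dir output directory; phantom/prior pairs are stored as RDS
#'   files, the manifest as JSON.
#' @param grid_shape,pixel_size,scale pixel grid geometry (see
#'   [make_base_model()]).
#' @param tumor_diameter_range tumor maximum-diameter range in cm.
#' @param texture_level heterogeneity texture amplitude.
#' @param prior_jitter_px,prior_value_error surrogate-prior degradation.
#' @param tissue_table dielectric table.
#' @return a `dataset_manifest` (data frame of entries + master seed).
#' @export
generate_dataset <- function(per_model_single, per_model_double, master_seed,
                             out_dir,
                             grid_shape = c(128, 128), pixel_size = 0.1,
                             scale = 1,
                             tumor_diameter_range = c(1.1, 1.5),
                             texture_level = 0.05,
                             prior_jitter_px = 2, prior_value_error = 0.05,
                             tissue_table = default_tissue_table()) {
  stopifnot(per_model_single >= 0, per_model_double >= 0)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_csinet("cannot create output directory '%s'", out_dir)
  models <- names(MODEL_SPECS)
  entries <- list()
  for (model in models) {
    base <- make_base_model(model, grid_shape, pixel_size,
                            seed = derive_seed(master_seed, paste0("base/", model)),
                            scale = scale)
    n_tot <- per_model_single + per_model_double
    folds <- fold_assignment(per_model_single, per_model_double,
                             derive_seed(master_seed, paste0("folds/", model)))
    for (k in seq_len(n_tot)) {
      n_tum <- if (k <= per_model_single) 1L else 2L
      pseed <- derive_seed(master_seed, sprintf("phantom/%s/%d", model, k))
      lab <- add_tumors(base, n_tum, tumor_diameter_range * scale, seed = pseed)
      ph <- assign_permittivity(lab, tissue_table, texture_level,
                                seed = derive_seed(master_seed, sprintf("tex/%s/%d", model, k)))
      pr <- make_prior(ph, prior_jitter_px, prior_value_error,
                       seed = derive_seed(master_seed, sprintf("prior/%s/%d", model, k)))
      fname <- sprintf("phantom_%s_%03d.rds", model, k)
      saveRDS(list(phantom = ph, prior = pr), file.path(out_dir, fname))
      entries[[length(entries) + 1]] <- data.frame(
        path = fname, model_id = model, n_tumors = n_tum,
        fold = folds[k], seed = pseed, stringsAsFactors = FALSE)
    }
  }
  manifest <- structure(list(entries = do.call(rbind, entries),
                             master_seed = master_seed, dir = out_dir,
                             grid_shape = grid_shape, pixel_size = pixel_size,
                             scale = scale),
                        class = "dataset_manifest")
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

# balanced fold assignment: singles and doubles are shuffled separately and
# dealt to the four folds round-robin
fold_assignment <- function(n_single, n_double, seed) {
  with_seed(seed, {
    f1 <- (seq_len(n_single) - 1L) %% 4L
    f2 <- (seq_len(n_double) - 1L) %% 4L
    c(if (n_single) sample(f1) else integer(0),
      if (n_double) sample(f2) else integer(0))
  })
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d phantoms (%s), master seed %d\n",
              nrow(x$entries),
              paste(sprintf("%s: %d", names(table(x$entries$model_id)),
                            table(x$entries$model_id)), collapse = ", "),
              x$master_seed))
  invisible(x)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(entries = manifest$entries,
                            master_seed = manifest$master_seed,
                            grid_shape = manifest$grid_shape,
                            pixel_size = manifest$pixel_size,
                            scale = manifest$scale),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param path path to `manifest.json`.
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(entries = as.data.frame(j$entries),
                 master_seed = j$master_seed, dir = dirname(path),
                 grid_shape = j$grid_shape, pixel_size = j$pixel_size,
                 scale = j$scale),
            class = "dataset_manifest")
}

load_phantom <- function(manifest, idx) {
  readRDS(file.path(manifest$dir, manifest$entries$path[idx]))
}

# closed-skin invariant: 4-connected flood fill from the grid border over
# non-skin pixels must never reach interior tissue
skin_ring_closed <- function(labels) {
  M <- nrow(labels); N <- ncol(labels)
  passable <- labels != LABEL_SKIN
  reach <- matrix(FALSE, M, N)
  stack <- c(which(row(labels) %in% c(1, M) & passable),
             which(col(labels) %in% c(1, N) & passable))
  reach[stack] <- TRUE
  while (length(stack) > 0) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    i <- (p - 1) %% M + 1; j <- (p - 1) %/% M + 1
    for (q in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (q[1] >= 1 && q[1] <= M && q[2] >= 1 && q[2] <= N) {
        qi <- (q[2] - 1) * M + q[1]
        if (passable[qi] && !reach[qi]) { reach[qi] <- TRUE; stack <- c(stack, qi) }
      }
    }
  }
  !any(reach & labels %in% c(LABEL_FAT, LABEL_FIBRO, LABEL_TUMOR))
}
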