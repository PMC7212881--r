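## Synthetic multiphoton-like image generation.
##
## Both tissue classes are drawn from ONE parametric texture family per
## channel; the two classes differ only in where their parameter vectors sit.
## Class parameters are blended toward the common midpoint by the effect
## size (w_eff = 0.5 + e * (w - 0.5), w = 0 nontumor / 1 tumor), so
## effect_size = 0 makes the classes distributionally identical by
## construction and effect_size = 1 gives the nominal contrast:
##   CARS  - nontumor: ordered axon-like strands + regularly spaced cell
##           blobs on a smooth background; tumor: low-frequency intensity
##           patches + dense, irregularly sized and placed blobs.
##   TPEF  - nontumor: sparse regular punctate fluorescence; tumor: diffuse
##           fluorescence + denser, clustered puncta.
##   SHG   - mostly dark; with some probability a structure appears, which is
##           a fiber bundle (typical of tumor ECM) or a single arc/ellipse
##           (corpus-amylaceum- or vessel-like, typical of nontumor brain).

## Nominal class parameter tables (effect_size = 1). Sizes in micrometres,
## densities per 1000 um^2, amplitudes in arbitrary intensity units.
synthetic_param_table <- function() {
  list(
    nontumor = c(
      cars_bg = 0.50, cars_strand_amp = 0.28, cars_strand_wavelength_um = 8,
      cars_patch_amp = 0.04, cars_blob_density = 1.2, cars_blob_r_um = 3.5,
      cars_blob_r_sd_um = 0.4, cars_blob_amp = 0.35, cars_blob_jitter_um = 1.2,
      tpef_bg = 0.25, tpef_punct_density = 0.9, tpef_punct_r_um = 1.6,
      tpef_punct_r_sd_um = 0.2, tpef_punct_amp = 0.55, tpef_punct_jitter_um = 1.5,
      tpef_patch_amp = 0.03,
      shg_bg = 0.02, shg_presence_prob = 0.15, shg_fiber_frac = 0.08,
      shg_amp = 0.50
    ),
    tumor = c(
      cars_bg = 0.50, cars_strand_amp = 0.04, cars_strand_wavelength_um = 8,
      cars_patch_amp = 0.45, cars_blob_density = 3.2, cars_blob_r_um = 4.5,
      cars_blob_r_sd_um = 1.8, cars_blob_amp = 0.50, cars_blob_jitter_um = 9,
      tpef_bg = 0.25, tpef_punct_density = 2.2, tpef_punct_r_um = 2.4,
      tpef_punct_r_sd_um = 1.0, tpef_punct_amp = 0.50, tpef_punct_jitter_um = 10,
      tpef_patch_amp = 0.30,
      shg_bg = 0.02, shg_presence_prob = 0.60, shg_fiber_frac = 0.92,
      shg_amp = 0.60
    )
  )
}

## Parameters whose values are probabilities (clipped to [0, 1] after jitter).
.prob_params <- c("shg_presence_prob", "shg_fiber_frac")

## Blend the two nominal parameter vectors for a class weight w in [0, 1]
## scaled by the effect size.
blend_params <- function(class_weight, effect_size) {
  tab <- synthetic_param_table()
  w <- 0.5 + effect_size * (class_weight - 0.5)
  p <- (1 - w) * tab$nontumor + w * tab$tumor
  p[.prob_params] <- pmin(1, pmax(0, p[.prob_params]))
  pmax(p, 0)
}

## Multiplicative lognormal per-patient jitter (interpatient variability).
jitter_params <- function(params, jitter_sd) {
  out <- params * exp(rnorm(length(params), 0, jitter_sd))
  out[.prob_params] <- pmin(1, pmax(0, out[.prob_params]))
  out
}

#' Specification of one synthetic FoV draw
#'
#' @param tissue_class `"nontumor"` or `"tumor"`.
#' @param channels Channels to generate (subset of CARS/TPEF/SHG).
#' @param effect_size Scales every class-discriminating parameter difference;
#'   0 makes the classes identical in distribution, 1 is the nominal contrast.
#' @param noise_sd Additive Gaussian detector-noise SD (intensity units).
#' @param cell_density Optional override of the CARS blob density
#'   (blobs per 1000 um^2).
#' @param patch_corr_len_um Correlation length of the tumor intensity patches.
#' @param shg_presence_prob Optional override of the SHG structure-presence
#'   probability.
#' @param fov_rows,fov_cols FoV shape in pixels.
#' @param pixel_size_um Physical pixel size.
#' @param seed Integer seed; spec + seed fully determine every pixel.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(tissue_class = "tumor",
                           channels = c("CARS", "TPEF"),
                           effect_size = 1, noise_sd = 0.05,
                           cell_density = NULL, patch_corr_len_um = 40,
                           shg_presence_prob = NULL,
                           fov_rows = 104L, fov_cols = 208L,
                           pixel_size_um = 1, seed = 1L) {
  tissue_class <- match.arg(tissue_class, MP_CLASSES)
  if (length(channels) == 0L) {
    abort("`channels` must not be empty.", class = "mptexture_validation_error")
  }
  channels <- match.arg(channels, MP_CHANNELS, several.ok = TRUE)
  if (effect_size < 0 || noise_sd < 0) {
    abort("`effect_size` and `noise_sd` must be >= 0.", class = "mptexture_validation_error")
  }
  if (!is.null(shg_presence_prob) &&
      (shg_presence_prob < 0 || shg_presence_prob > 1)) {
    abort("`shg_presence_prob` must be in [0, 1].", class = "mptexture_validation_error")
  }
  structure(list(tissue_class = tissue_class, channels = channels,
                 effect_size = effect_size, noise_sd = noise_sd,
                 cell_density = cell_density,
                 patch_corr_len_um = patch_corr_len_um,
                 shg_presence_prob = shg_presence_prob,
                 fov_rows = as.integer(fov_rows), fov_cols = as.integer(fov_cols),
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Effective parameter vector of a spec (before patient jitter).
spec_params <- function(spec) {
  p <- blend_params(as.numeric(spec$tissue_class == "tumor"), spec$effect_size)
  if (!is.null(spec$cell_density)) p["cars_blob_density"] <- spec$cell_density
  if (!is.null(spec$shg_presence_prob)) p["shg_presence_prob"] <- spec$shg_presence_prob
  p
}

## Add isotropic Gaussian bumps at (cx, cy) um with radii r um to `px`.
add_blobs <- function(px, cx, cy, r, amp, pixel_size_um) {
  nr <- nrow(px); nc <- ncol(px)
  for (k in seq_along(cx)) {
    sig <- max(r[k], 0.8) / 1.8 / pixel_size_um   # px units
    x0 <- cx[k] / pixel_size_um; y0 <- cy[k] / pixel_size_um
    ext <- ceiling(3 * sig)
    r1 <- max(1, floor(y0 - ext)); r2 <- min(nr, ceiling(y0 + ext))
    c1 <- max(1, floor(x0 - ext)); c2 <- min(nc, ceiling(x0 + ext))
    if (r1 > r2 || c1 > c2) next
    rows <- r1:r2
    cols <- c1:c2
    dy <- (rows - y0)^2
    dx <- (cols - x0)^2
    px[rows, cols] <- px[rows, cols] + amp[k] * exp(-outer(dy, dx, "+") / (2 * sig^2))
  }
  px
}

## Blob/puncta centres: lattice spaced for the target density, jittered. Small
## jitter -> regular spacing (nontumor); large jitter -> irregular (tumor).
lattice_points <- function(width_um, height_um, density_per_1000um2, jitter_um) {
  spacing <- sqrt(1000 / max(density_per_1000um2, 1e-6))
  gx <- seq(spacing / 2, width_um, by = spacing)
  gy <- seq(spacing / 2, height_um, by = spacing)
  if (!length(gx) || !length(gy)) return(list(x = numeric(0), y = numeric(0)))
  cx <- rep(gx, times = length(gy)) + rnorm(length(gx) * length(gy), 0, jitter_um)
  cy <- rep(gy, each = length(gx)) + rnorm(length(gx) * length(gy), 0, jitter_um)
  keep <- cx > -spacing & cx < width_um + spacing & cy > -spacing & cy < height_um + spacing
  list(x = cx[keep], y = cy[keep])
}

## One channel's pixel grid, drawn with the current RNG stream.
gen_channel_pixels <- function(channel, params, spec) {
  nr <- spec$fov_rows; nc <- spec$fov_cols
  psz <- spec$pixel_size_um
  w_um <- nc * psz; h_um <- nr * psz
  xs <- (seq_len(nc) - 0.5) * psz
  ys <- (seq_len(nr) - 0.5) * psz
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  px <- switch(
    channel,
    CARS = {
      theta <- runif(1, 0, pi)
      phase <- runif(1, 0, 2 * pi)
      wobble <- smooth_field(nr, nc, 15 / psz)
      u <- cos(theta) * X + sin(theta) * Y
      img <- params[["cars_bg"]] +
        params[["cars_strand_amp"]] *
          sin(2 * pi * u / params[["cars_strand_wavelength_um"]] + phase + 0.8 * wobble) +
        params[["cars_patch_amp"]] * smooth_field(nr, nc, spec$patch_corr_len_um / psz)
      pts <- lattice_points(w_um, h_um, params[["cars_blob_density"]],
                            params[["cars_blob_jitter_um"]])
      n <- length(pts$x)
      if (n) {
        r <- pmax(0.8, rnorm(n, params[["cars_blob_r_um"]], params[["cars_blob_r_sd_um"]]))
        amp <- params[["cars_blob_amp"]] * runif(n, 0.7, 1.3)
        img <- add_blobs(img, pts$x, pts$y, r, amp, psz)
      }
      img
    },
    TPEF = {
      img <- params[["tpef_bg"]] +
        params[["tpef_patch_amp"]] * smooth_field(nr, nc, spec$patch_corr_len_um / psz)
      pts <- lattice_points(w_um, h_um, params[["tpef_punct_density"]],
                            params[["tpef_punct_jitter_um"]])
      n <- length(pts$x)
      if (n) {
        r <- pmax(0.6, rnorm(n, params[["tpef_punct_r_um"]], params[["tpef_punct_r_sd_um"]]))
        amp <- params[["tpef_punct_amp"]] * runif(n, 0.6, 1.4)
        img <- add_blobs(img, pts$x, pts$y, r, amp, psz)
      }
      img
    },
    SHG = {
      img <- matrix(params[["shg_bg"]], nr, nc)
      present <- runif(1) < params[["shg_presence_prob"]]
      is_fiber <- runif(1) < params[["shg_fiber_frac"]]
      if (present) {
        if (is_fiber) {
          # bundle of parallel collagen-like fibers in a band
          theta <- runif(1, 0, pi)
          u <- cos(theta) * X + sin(theta) * Y
          v <- -sin(theta) * X + cos(theta) * Y
          v0 <- runif(1, min(v), max(v))
          bandw <- runif(1, 12, 30)
          lam <- runif(1, 4, 7)
          img <- img + params[["shg_amp"]] *
            pmax(0, sin(2 * pi * u / lam))^2 * exp(-(v - v0)^2 / (2 * bandw^2))
        } else {
          # single arc/ellipse: corpus amylaceum or vessel wall
          cx <- runif(1, 0.2 * w_um, 0.8 * w_um)
          cy <- runif(1, 0.2 * h_um, 0.8 * h_um)
          a <- runif(1, 5, 15); b <- runif(1, 5, 15)
          ringw <- 1.5
          rr <- sqrt(((X - cx) / a)^2 + ((Y - cy) / b)^2)
          img <- img + params[["shg_amp"]] * exp(-(rr - 1)^2 * (a * b) / (2 * ringw^2))
        }
      }
      img
    },
    abort(paste0("unknown channel: ", channel), class = "mptexture_validation_error")
  )
  if (spec$noise_sd > 0) px <- px + rnorm(nr * nc, 0, spec$noise_sd)
  pmax(px, 0)
}

## One multi-channel FoV set with the current RNG stream.
gen_fovset_impl <- function(spec, params, sample_id = "synthetic",
                            grid_row = 0L, grid_col = 0L) {
  out <- lapply(setNames(spec$channels, spec$channels), function(ch) {
    mp_fov(gen_channel_pixels(ch, params, spec),
           pixel_size_um = spec$pixel_size_um, channel = ch,
           sample_id = sample_id, grid_row = grid_row, grid_col = grid_col)
  })
  out
}

#' Generate synthetic multi-channel FoVs
#'
#' Draws `n` fields of view from a [synthetic_spec()]. The spec's seed fully
#' determines every pixel: identical spec + seed give bit-identical images.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of FoV sets to draw.
#' @param sample_id Sample identifier stamped on the FoVs.
#' @return For `n = 1` a named list channel -> [mp_fov()]; otherwise a list of
#'   such sets (grid_row enumerates the draws).
#' @export
gen_fov <- function(spec, n = 1L, sample_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- spec_params(spec)
  sets <- with_seed(spec$seed, {
    lapply(seq_len(n), function(k) {
      gen_fovset_impl(spec, params, sample_id, grid_row = k - 1L)
    })
  })
  if (n == 1L) sets[[1L]] else sets
}

#' Generate a synthetic patient cohort
#'
#' Creates the study-shaped dataset the pipeline is exercised on: tumor and
#' nontumor patients, a fixed number of FoVs each, per-patient lognormal
#' jitter of the texture-recipe parameters (interpatient variability, which
#' makes the patient-level split load-bearing), and a patient-level train/test
#' assignment. FoV pixels are generated lazily (see [cohort_features()],
#' [cohort_fovs()], [write_dataset()]), so large cohorts stay cheap to hold.
#'
#' @param n_tumor,n_nontumor Patients per class (>= 1).
#' @param fovs_per_sample FoVs acquired per patient (default 100).
#' @param effect_size,noise_sd,channels,fov_rows,fov_cols,pixel_size_um,patch_corr_len_um
#'   Passed to [synthetic_spec()].
#' @param jitter_sd SD of the per-patient log-scale parameter jitter.
#' @param proportion_train Fraction of patients per class in the training set.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `mp_cohort` whose `$samples` tibble has one row
#'   per patient (`sample_id`, `label`, `type`, `split`, per-patient seed).
#' @export
gen_cohort <- function(n_tumor = 20L, n_nontumor = 10L, fovs_per_sample = 100L,
                       effect_size = 1, noise_sd = 0.05,
                       channels = c("CARS", "TPEF"),
                       jitter_sd = 0.06, proportion_train = 0.5,
                       fov_rows = 104L, fov_cols = 208L, pixel_size_um = 1,
                       patch_corr_len_um = 40, seed = 1L) {
  if (n_tumor < 1 || n_nontumor < 1 || fovs_per_sample < 1) {
    abort("patient and FoV counts must be >= 1.", class = "mptexture_validation_error")
  }
  n <- n_tumor + n_nontumor
  tumor_types <- c("astrocytoma", "oligodendroglioma", "glioblastoma", "metastasis")
  samples <- tibble::tibble(
    sample_id = sprintf("P%03d", seq_len(n)),
    label = rep(c("tumor", "nontumor"), c(n_tumor, n_nontumor)),
    type = c(rep_len(tumor_types, n_tumor), rep("nontumor brain", n_nontumor))
  )
  seeds <- derive_seeds(seed, n + 1L)
  samples$sample_seed <- seeds[seq_len(n)]
  params <- with_seed(seeds[n + 1L], {
    lapply(seq_len(n), function(i) {
      jitter_params(blend_params(as.numeric(samples$label[i] == "tumor"), effect_size),
                    jitter_sd)
    })
  })
  samples$params <- params
  samples <- split_by_patient(samples, proportion = proportion_train,
                              seed = seeds[n + 1L], stratify = TRUE)
  structure(list(samples = samples, fovs_per_sample = as.integer(fovs_per_sample),
                 channels = channels, effect_size = effect_size,
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 fov_rows = as.integer(fov_rows), fov_cols = as.integer(fov_cols),
                 pixel_size_um = pixel_size_um,
                 patch_corr_len_um = patch_corr_len_um, seed = as.integer(seed)),
            class = "mp_cohort")
}

#' @export
print.mp_cohort <- function(x, ...) {
  cat(sprintf("<mp_cohort> %d patients (%d tumor / %d nontumor) x %d FoVs, channels %s, effect %.2g, seed %d\n",
              nrow(x$samples), sum(x$samples$label == "tumor"),
              sum(x$samples$label == "nontumor"), x$fovs_per_sample,
              paste(x$channels, collapse = "+"), x$effect_size, x$seed))
  invisible(x)
}

## Spec for one patient of a cohort (class identity is in the jittered params).
cohort_sample_spec <- function(cohort, i) {
  synthetic_spec(tissue_class = cohort$samples$label[i],
                 channels = cohort$channels,
                 effect_size = cohort$effect_size, noise_sd = cohort$noise_sd,
                 patch_corr_len_um = cohort$patch_corr_len_um,
                 fov_rows = cohort$fov_rows, fov_cols = cohort$fov_cols,
                 pixel_size_um = cohort$pixel_size_um,
                 seed = cohort$samples$sample_seed[i])
}

#' Materialize the FoVs of one cohort patient
#'
#' @param cohort An [gen_cohort()] object.
#' @param sample_id Patient to generate.
#' @param n Number of FoVs (default the cohort's `fovs_per_sample`).
#' @return List of multi-channel FoV sets.
#' @export
cohort_fovs <- function(cohort, sample_id, n = NULL) {
  i <- match(sample_id, cohort$samples$sample_id)
  if (is.na(i)) abort("unknown sample_id.", class = "mptexture_validation_error")
  n <- n %||% cohort$fovs_per_sample
  spec <- cohort_sample_spec(cohort, i)
  params <- cohort$samples$params[[i]]
  with_seed(spec$seed, {
    lapply(seq_len(n), function(k) {
      gen_fovset_impl(spec, params, sample_id, grid_row = k - 1L)
    })
  })
}

#' Texture feature table of a whole synthetic cohort
#'
#' Generates every patient's FoVs (streaming, pixels discarded after use) and
#' extracts the configured texture features.
#'
#' @param cohort An [gen_cohort()] object.
#' @param config A [texture_config()]; its channel set should match the
#'   cohort's.
#' @return Feature tibble as from [compute_features()], plus `label`, `type`
#'   and `split` columns.
#' @export
cohort_features <- function(cohort, config = texture_config(channels = cohort$channels)) {
  pieces <- lapply(seq_len(nrow(cohort$samples)), function(i) {
    sid <- cohort$samples$sample_id[i]
    fovsets <- cohort_fovs(cohort, sid)
    ft <- compute_features(fovsets, config)
    ft$label <- cohort$samples$label[i]
    ft$type <- cohort$samples$type[i]
    ft$split <- cohort$samples$split[i]
    ft
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "config_hash") <- config$hash
  out
}

#' Write a synthetic cohort to disk as TIFFs + manifest + truth labels
#'
#' Each patient/channel becomes one float TIFF with the FoVs stacked
#' vertically on the tile grid, so [read_manifest()] + [compute_features()]
#' recover exactly the generated FoVs — the synthetic path exercises the same
#' input machinery as real data.
#'
#' @param cohort An [gen_cohort()] object.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cohort$samples))) {
    sid <- cohort$samples$sample_id[i]
    fovsets <- cohort_fovs(cohort, sid)
    for (ch in cohort$channels) {
      img <- untile(lapply(fovsets, `[[`, ch))
      fn <- sprintf("%s_%s.tif", sid, ch)
      write_channel_image(img, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, channel = ch, path = fn,
        label = cohort$samples$label[i])
    }
  }
  manifest <- dplyr::bind_rows(rows)
  man_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, man_path)
  jsonlite::write_json(
    list(samples = cohort$samples[, c("sample_id", "label", "type", "split")],
         seed = cohort$seed, effect_size = cohort$effect_size),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(man_path)
}

#' Generate a synthetic tumor-border section
#'
#' A large tiled scan whose texture parameters ramp from the nontumor to the
#' tumor recipe across a transition band, emulating an imaged tumor border.
#' Tiles left of the band are pure nontumor texture, tiles right of it pure
#' tumor; inside the band the parameter vectors blend linearly. The per-tile
#' truth label is the majority class of the tile (its blend weight).
#'
#' @param width_tiles,height_tiles Section size in tiles.
#' @param transition_center Column position (in tile units, can be
#'   fractional) of the border.
#' @param transition_width Width of the blending band in tiles (0 = sharp).
#' @param effect_size,noise_sd,channels,fov_rows,fov_cols,pixel_size_um,patch_corr_len_um
#'   Passed to the texture recipes.
#' @param seed Integer seed.
#' @return List with `images` (named list channel -> stitched [mp_image()]),
#'   `truth` (tibble `grid_row`, `grid_col`, `weight`, `label`), and the tile
#'   shape.
#' @export
gen_border_section <- function(width_tiles = 8L, height_tiles = 4L,
                               transition_center = NULL, transition_width = 2,
                               effect_size = 1, noise_sd = 0.05,
                               channels = c("CARS", "TPEF"),
                               fov_rows = 104L, fov_cols = 208L,
                               pixel_size_um = 1, patch_corr_len_um = 40,
                               seed = 1L) {
  if (width_tiles < 2 || height_tiles < 1) {
    abort("section must be at least 2 x 1 tiles.", class = "mptexture_validation_error")
  }
  transition_center <- transition_center %||% (width_tiles / 2)
  if (transition_center < 0 || transition_center > width_tiles || transition_width < 0) {
    abort("transition must lie inside the section.", class = "mptexture_validation_error")
  }
  spec <- synthetic_spec(tissue_class = "tumor", channels = channels,
                         effect_size = effect_size, noise_sd = noise_sd,
                         patch_corr_len_um = patch_corr_len_um,
                         fov_rows = fov_rows, fov_cols = fov_cols,
                         pixel_size_um = pixel_size_um, seed = seed)
  truth <- tidyr::expand_grid(grid_row = seq_len(height_tiles) - 1L,
                              grid_col = seq_len(width_tiles) - 1L)
  centers <- truth$grid_col + 0.5
  w <- if (transition_width > 0) {
    pmin(1, pmax(0, (centers - transition_center) / transition_width + 0.5))
  } else {
    as.numeric(centers > transition_center)
  }
  truth$weight <- w
  truth$label <- ifelse(w > 0.5 | (w == 0.5 & centers >= transition_center),
                        "tumor", "nontumor")
  fovs <- with_seed(seed, {
    lapply(seq_len(nrow(truth)), function(k) {
      params <- blend_params(truth$weight[k], effect_size)
      gen_fovset_impl(spec, params, sample_id = "border",
                      grid_row = truth$grid_row[k], grid_col = truth$grid_col[k])
    })
  })
  images <- lapply(setNames(channels, channels), function(ch) {
    untile(lapply(fovs, `[[`, ch))
  })
  list(images = images, truth = truth,
       fov_rows = as.integer(fov_rows), fov_cols = as.integer(fov_cols))
}
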