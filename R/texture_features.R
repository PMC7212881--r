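#' Texture extraction configuration
#'
#' Bundles every convention the 13-parameter texture vector depends on, so a
#' trained model can refuse feature tables extracted under different settings.
#' Defaults follow the common Haralick/graycoprops conventions: 8 gray levels
#' for the co-occurrence matrices, co-occurrence distances of 6 um and 40 um
#' (6 px and 40 px at the nominal 1 um/px), the four standard orientations
#' averaged per distance, and a 256-bin base-2 histogram entropy.
#'
#' @param levels Number of gray levels for GLCM quantization (>= 2).
#' @param distances_um Co-occurrence distances in micrometres.
#' @param orientations_deg Subset of `c(0, 45, 90, 135)`.
#' @param entropy_bins Histogram bins for first-order entropy.
#' @param fov_rows,fov_cols Expected FoV shape in pixels.
#' @param channels Ordered channel set for combined vectors.
#' @return A `texture_config` list with a stable `hash`.
#' @export
texture_config <- function(levels = 8L,
                           distances_um = c(6, 40),
                           orientations_deg = c(0, 45, 90, 135),
                           entropy_bins = 256L,
                           fov_rows = 104L, fov_cols = 208L,
                           channels = c("CARS", "TPEF")) {
  if (levels < 2) abort("`levels` must be >= 2.", class = "mptexture_validation_error")
  if (!all(orientations_deg %in% c(0, 45, 90, 135))) {
    abort("orientations must be among 0, 45, 90, 135 degrees.",
          class = "mptexture_validation_error")
  }
  if (any(distances_um <= 0)) {
    abort("distances must be positive.", class = "mptexture_validation_error")
  }
  channels <- match.arg(channels, MP_CHANNELS, several.ok = TRUE)
  cfg <- list(levels = as.integer(levels),
              distances_um = as.numeric(distances_um),
              orientations_deg = as.numeric(orientations_deg),
              entropy_bins = as.integer(entropy_bins),
              fov_rows = as.integer(fov_rows), fov_cols = as.integer(fov_cols),
              channels = channels)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "texture_config")
}

#' Names of the 13 texture parameters, in frozen order
#'
#' Five first-order parameters (mean gray value, standard deviation, kurtosis,
#' skewness, entropy) followed by, for each co-occurrence distance, contrast,
#' correlation, energy and homogeneity averaged over the configured
#' orientations.
#'
#' @param config A [texture_config()].
#' @param channel Optional channel tag to prefix (e.g. `"CARS_mean"`).
#' @return Character vector of feature names.
#' @export
feature_names <- function(config = texture_config(), channel = NULL) {
  glcm_part <- unlist(lapply(config$distances_um, function(d) {
    paste0(c("contrast", "correlation", "energy", "homogeneity"), "_d",
           format(d, trim = TRUE))
  }))
  nm <- c("mean", "sd", "kurtosis", "skewness", "entropy", glcm_part)
  if (!is.null(channel)) nm <- paste0(channel, "_", nm)
  nm
}

#' Min-max normalize a field of view
#'
#' Maps intensities to \[0, 1\] via `(x - min) / (max - min)`. A constant FoV
#' (expected e.g. for the SHG channel on nontumor parenchyma lacking
#' SHG-active structures) yields an all-zero grid with `degenerate = TRUE`
#' instead of NaNs, so downstream features stay classifier-safe.
#'
#' @param fov An [mp_fov()] or [mp_image()].
#' @return List with `pixels` in \[0, 1\], logical `degenerate`, and the FoV's
#'   provenance fields.
#' @export
minmax_normalize <- function(fov) {
  stopifnot(inherits(fov, "mp_image"))
  px <- fov$pixels
  lo <- min(px); hi <- max(px)
  if (hi > lo) {
    out <- (px - lo) / (hi - lo)
    degenerate <- FALSE
  } else {
    out <- matrix(0, nrow(px), ncol(px))
    degenerate <- TRUE
  }
  list(pixels = out, degenerate = degenerate,
       sample_id = fov$sample_id %||% NA_character_,
       grid_row = fov$grid_row %||% NA_integer_,
       grid_col = fov$grid_col %||% NA_integer_,
       channel = fov$channel)
}

#' First-order texture parameters
#'
#' Mean and standard deviation (N-1 denominator) over all pixels; skewness
#' `m3 / m2^(3/2)` and kurtosis `m4 / m2^2` from population central moments
#' (non-excess, so a Gaussian texture gives kurtosis 3); Shannon entropy in
#' bits over a histogram of \[0, 1\] (`0 log 0 := 0`). A degenerate (constant)
#' FoV returns sd, skewness, kurtosis and entropy of 0.
#'
#' @param norm Output of [minmax_normalize()].
#' @param entropy_bins Number of histogram bins (default 256).
#' @return Named numeric vector `mean`, `sd`, `kurtosis`, `skewness`, `entropy`.
#' @export
first_order_features <- function(norm, entropy_bins = 256L) {
  x <- as.vector(norm$pixels)
  n <- length(x)
  mu <- mean(x)
  s <- stats::sd(x)
  xc <- x - mu
  m2 <- mean(xc^2)
  if (m2 > 0) {
    skew <- mean(xc^3) / m2^1.5
    kurt <- mean(xc^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  # histogram over [0,1]; value 1 falls in the top bin
  bins <- pmin(floor(x * entropy_bins), entropy_bins - 1L) + 1L
  p <- tabulate(bins, nbins = entropy_bins) / n
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  c(mean = mu, sd = s, kurtosis = kurt, skewness = skew, entropy = ent)
}

#' Quantize a normalized FoV to discrete gray levels
#'
#' Uniform binning of \[0, 1\] into `levels` equal intervals; the value 1 maps
#' to the top level. Levels are 0-based (`0 .. levels - 1`).
#'
#' @param norm Output of [minmax_normalize()] (or any matrix in \[0, 1\]).
#' @param levels Integer >= 2.
#' @return Integer matrix of gray levels.
#' @export
quantize <- function(norm, levels = 8L) {
  if (levels < 2) abort("`levels` must be >= 2.", class = "mptexture_validation_error")
  px <- if (is.list(norm)) norm$pixels else norm
  q <- pmin(floor(px * levels), levels - 1L)
  matrix(as.integer(q), nrow(px), ncol(px))
}

## Row/col pixel offset for one orientation at distance d, in matrix
## convention (row index grows downward):
##   0 deg -> ( 0, +d); 45 deg -> (-d, +d); 90 deg -> (-d, 0); 135 deg -> (-d, -d)
orientation_offset <- function(orientation_deg, d) {
  switch(as.character(orientation_deg),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         abort("orientation must be one of 0, 45, 90, 135.",
               class = "mptexture_validation_error"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs (reference pixel, pixel at the orientation/distance
#' offset), asymmetric (each pair counted once in the stated direction),
#' skipping out-of-bounds partners, then optionally normalizes the counts to a
#' joint probability matrix.
#'
#' @param levelimg Integer matrix of gray levels in `0 .. levels - 1`.
#' @param distance_px Pixel distance (>= 1).
#' @param orientation_deg One of 0, 45, 90, 135.
#' @param levels Number of gray levels L (matrix is L x L).
#' @param normalize Normalize counts to probabilities (default `TRUE`).
#' @return L x L matrix with attributes `distance_px`, `orientation_deg`,
#'   `normalized`.
#' @export
glcm <- function(levelimg, distance_px, orientation_deg, levels = max(levelimg) + 1L,
                 normalize = TRUE) {
  if (distance_px < 1) abort("`distance_px` must be >= 1.", class = "mptexture_validation_error")
  d <- as.integer(distance_px)
  off <- orientation_offset(orientation_deg, d)
  nr <- nrow(levelimg); nc <- ncol(levelimg)
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  if (off[1L] < 0) rows <- rows[rows + off[1L] >= 1L]
  if (off[1L] > 0) rows <- rows[rows + off[1L] <= nr]
  if (off[2L] < 0) cols <- cols[cols + off[2L] >= 1L]
  if (off[2L] > 0) cols <- cols[cols + off[2L] <= nc]
  if (length(rows) == 0L || length(cols) == 0L) {
    abort(sprintf("no co-occurring pairs: distance %d px exceeds image extent", d),
          class = "mptexture_validation_error")
  }
  i <- levelimg[rows, cols, drop = FALSE]
  j <- levelimg[rows + off[1L], cols + off[2L], drop = FALSE]
  counts <- tabulate(i * levels + j + 1L, nbins = levels * levels)
  g <- matrix(as.numeric(counts), levels, levels, byrow = TRUE)
  if (normalize) g <- g / sum(g)
  structure(g, distance_px = d, orientation_deg = orientation_deg,
            normalized = normalize)
}

#' Haralick properties of a normalized co-occurrence matrix
#'
#' With `p(i, j)` the joint probability and 0-based levels:
#' contrast `sum p (i - j)^2`; correlation
#' `sum p (i - mu_r)(j - mu_c) / (sigma_r sigma_c)` from the marginal moments;
#' energy `sum p^2` (angular second moment); homogeneity
#' `sum p / (1 + |i - j|)`. A zero-variance marginal (all mass on one level)
#' makes correlation undefined; it is returned as 1 — a constant texture is
#' perfectly predictable — with attribute `correlation_flagged = TRUE`.
#'
#' @param g Normalized GLCM from [glcm()].
#' @return Named numeric vector `contrast`, `correlation`, `energy`,
#'   `homogeneity` (with the flag attribute when degenerate).
#' @export
glcm_properties <- function(g) {
  if (!isTRUE(attr(g, "normalized")) && abs(sum(g) - 1) > 1e-8) {
    abort("GLCM must be normalized to probabilities.", class = "mptexture_validation_error")
  }
  L <- nrow(g)
  idx <- seq_len(L) - 1
  ii <- matrix(idx, L, L)
  jj <- t(ii)
  contrast <- sum(g * (ii - jj)^2)
  energy <- sum(g^2)
  homogeneity <- sum(g / (1 + abs(ii - jj)))
  pr <- rowSums(g); pc <- colSums(g)
  mu_r <- sum(idx * pr); mu_c <- sum(idx * pc)
  var_r <- sum((idx - mu_r)^2 * pr); var_c <- sum((idx - mu_c)^2 * pc)
  flagged <- FALSE
  if (var_r <= 0 || var_c <= 0) {
    correlation <- 1
    flagged <- TRUE
  } else {
    correlation <- sum(g * (ii - mu_r) * (jj - mu_c)) / sqrt(var_r * var_c)
  }
  structure(c(contrast = contrast, correlation = correlation,
              energy = energy, homogeneity = homogeneity),
            correlation_flagged = flagged)
}

#' The 13-parameter texture vector of one channel of one FoV
#'
#' Min-max normalizes the FoV, computes the five first-order parameters, then
#' for each configured distance computes the four co-occurrence properties in
#' each orientation and averages them over orientations.
#'
#' @param fov An [mp_fov()] (or [mp_image()]).
#' @param config A [texture_config()]; distances in um are converted to pixels
#'   through the FoV's `pixel_size_um` (rounded to the nearest integer >= 1).
#' @return Named numeric vector of length 13 (attribute `degenerate` marks
#'   constant FoVs).
#' @export
channel_texture_vector <- function(fov, config = texture_config()) {
  stopifnot(inherits(fov, "mp_image"))
  norm <- minmax_normalize(fov)
  fo <- first_order_features(norm, config$entropy_bins)
  q <- quantize(norm, config$levels)
  d_px <- pmax(1L, as.integer(round(config$distances_um / fov$pixel_size_um)))
  nr <- nrow(q); nc <- ncol(q)
  too_big <- d_px >= min(nr, nc)
  if (any(too_big)) {
    abort(sprintf("FoV (%d x %d px) too small for co-occurrence distance %s px",
                  nr, nc, paste(d_px[too_big], collapse = ", ")),
          class = "mptexture_validation_error")
  }
  glcm_part <- unlist(lapply(seq_along(d_px), function(k) {
    props <- vapply(config$orientations_deg, function(o) {
      glcm_properties(glcm(q, d_px[k], o, levels = config$levels))
    }, numeric(4))
    rowMeans(props)
  }))
  out <- c(fo, glcm_part)
  names(out) <- feature_names(config)
  attr(out, "degenerate") <- norm$degenerate
  out
}

#' Concatenate per-channel texture vectors
#'
#' @param vectors Named list of per-channel 13-vectors (names are channel
#'   tags), in the declared channel order.
#' @return Named numeric vector of length `13 * length(vectors)` with
#'   channel-prefixed names.
#' @export
combine_vectors <- function(vectors) {
  stopifnot(length(vectors) >= 1, !is.null(names(vectors)))
  out <- unlist(lapply(names(vectors), function(ch) {
    v <- vectors[[ch]]
    setNames(as.numeric(v), paste0(ch, "_", names(v)))
  }))
  out
}

## Feature row (named numeric) for one multi-channel FoV set: a named list
## channel -> mp_fov sharing provenance.
fovset_features <- function(fovset, config) {
  chans <- config$channels
  missing <- setdiff(chans, names(fovset))
  if (length(missing)) {
    abort(paste0("FoV set lacks channel(s): ", paste(missing, collapse = ", ")),
          class = "mptexture_validation_error")
  }
  prov <- fovset[[chans[[1L]]]]
  pos <- vapply(chans, function(ch) {
    f <- fovset[[ch]]
    paste(f$sample_id, f$grid_row, f$grid_col)
  }, character(1))
  if (length(unique(pos)) != 1L) {
    abort("channels of one FoV set must share sample and grid position.",
          class = "mptexture_validation_error")
  }
  vecs <- lapply(setNames(chans, chans), function(ch) {
    channel_texture_vector(fovset[[ch]], config)
  })
  deg <- vapply(vecs, function(v) isTRUE(attr(v, "degenerate")), logical(1))
  list(features = combine_vectors(vecs),
       sample_id = prov$sample_id, grid_row = prov$grid_row,
       grid_col = prov$grid_col, degenerate = any(deg))
}

#' Compute the texture feature table
#'
#' The tidy entry point of the extraction stage. Accepts either a manifest
#' tibble (columns `sample_id`, `channel`, `path`, optional `label`; see
#' [read_manifest()]) whose images are read and tiled into FoVs, or a list of
#' multi-channel FoV sets (named lists channel -> [mp_fov()]).
#'
#' @param x Manifest tibble or list of FoV sets.
#' @param config A [texture_config()].
#' @param pixel_size_um Pixel size used when reading images from a manifest.
#' @param labels Optional named vector `sample_id -> label` overriding the
#'   manifest's `label` column.
#' @return A tibble with one row per FoV: `sample_id`, `grid_row`, `grid_col`,
#'   `degenerate`, optional `label`, and one column per channel-prefixed
#'   feature. The texture config hash is attached as attribute `config_hash`.
#' @export
compute_features <- function(x, config = texture_config(), pixel_size_um = 1,
                             labels = NULL) {
  if (is.data.frame(x)) {
    fovsets <- manifest_fovsets(x, config, pixel_size_um)
    if (is.null(labels) && "label" %in% names(x)) {
      labels <- setNames(x$label, x$sample_id)
      labels <- labels[!duplicated(names(labels))]
    }
  } else {
    fovsets <- x
  }
  rows <- lapply(fovsets, fovset_features, config = config)
  feat <- do.call(rbind, lapply(rows, function(r) r$features))
  out <- tibble::tibble(
    sample_id = vapply(rows, function(r) r$sample_id, character(1)),
    grid_row = vapply(rows, function(r) r$grid_row, integer(1)),
    grid_col = vapply(rows, function(r) r$grid_col, integer(1)),
    degenerate = vapply(rows, function(r) r$degenerate, logical(1))
  )
  if (!is.null(labels)) out$label <- unname(labels[out$sample_id])
  out <- dplyr::bind_cols(out, tibble::as_tibble(feat))
  attr(out, "config_hash") <- config$hash
  out
}

## Read + tile every sample of a manifest into multi-channel FoV sets.
manifest_fovsets <- function(manifest, config, pixel_size_um) {
  fovsets <- list()
  for (sid in unique(manifest$sample_id)) {
    sub <- manifest[manifest$sample_id == sid, ]
    per_chan <- list()
    skip <- FALSE
    for (ch in config$channels) {
      row <- sub[sub$channel == ch, ]
      if (nrow(row) == 0L || !file.exists(row$path[[1L]])) {
        warn(sprintf("sample %s: missing %s image, sample skipped", sid, ch))
        skip <- TRUE
        break
      }
      img <- read_channel_image(row$path[[1L]], ch, pixel_size_um)
      per_chan[[ch]] <- tile(img, config$fov_rows, config$fov_cols, sample_id = sid)
    }
    if (skip) next
    n_fov <- length(per_chan[[1L]])
    for (k in seq_len(n_fov)) {
      fovsets[[length(fovsets) + 1L]] <- lapply(per_chan, `[[`, k)
    }
  }
  if (!length(fovsets)) {
    abort("no complete FoV sets found in manifest.", class = "mptexture_data_error")
  }
  fovsets
}

#' Write / read a feature table with its config fingerprint
#'
#' The CSV is accompanied by a `<path>.json` sidecar holding the texture
#' config hash, so [predict.mp_lda()] can refuse tables extracted under a
#' different convention.
#'
#' @param features Feature tibble from [compute_features()].
#' @param path CSV path.
#' @return `path` / the feature tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  jsonlite::write_json(list(config_hash = attr(features, "config_hash")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(out, "config_hash") <- jsonlite::read_json(side)$config_hash
  }
  out
}
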