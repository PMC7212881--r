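#' Construct a single-channel intensity image
#'
#' Light S3 record holding one channel of a multiphoton scan: a nonnegative
#' real intensity matrix plus its physical pixel size and channel tag.
#'
#' @param pixels Numeric matrix of intensities (rows x cols), all finite and
#'   nonnegative, at least 2 x 2.
#' @param pixel_size_um Positive physical pixel size in micrometres per pixel.
#' @param channel One of `"CARS"`, `"TPEF"`, `"SHG"`.
#' @return An object of class `mp_image`.
#' @export
mp_image <- function(pixels, pixel_size_um = 1, channel = "CARS") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "mptexture_validation_error")
  }
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    abort("image must be at least 2 x 2 pixels.", class = "mptexture_validation_error")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    abort("all intensities must be finite and >= 0.", class = "mptexture_validation_error")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.",
          class = "mptexture_validation_error")
  }
  channel <- match.arg(channel, MP_CHANNELS)
  structure(
    list(pixels = unname(pixels), pixel_size_um = pixel_size_um, channel = channel),
    class = "mp_image"
  )
}

#' @export
print.mp_image <- function(x, ...) {
  cat(sprintf("<mp_image> %s, %d x %d px, %.3g um/px\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' @export
dim.mp_image <- function(x) dim(x$pixels)

#' Construct a field of view
#'
#' A field of view (FoV) is the unit of feature extraction and classification:
#' one tile of a scan (default 104 x 208 pixels at 1 um/px) with its grid
#' position and sample of origin.
#'
#' @inheritParams mp_image
#' @param sample_id Sample (patient/biopsy) identifier.
#' @param grid_row,grid_col 0-based tile indices within the scan.
#' @return An object of class `mp_fov` (which also inherits `mp_image`).
#' @export
mp_fov <- function(pixels, pixel_size_um = 1, channel = "CARS",
                   sample_id = "sample", grid_row = 0L, grid_col = 0L) {
  img <- mp_image(pixels, pixel_size_um, channel)
  if (grid_row < 0 || grid_col < 0) {
    abort("grid indices must be nonnegative.", class = "mptexture_validation_error")
  }
  img$sample_id <- as.character(sample_id)
  img$grid_row <- as.integer(grid_row)
  img$grid_col <- as.integer(grid_col)
  class(img) <- c("mp_fov", "mp_image")
  img
}

#' @export
print.mp_fov <- function(x, ...) {
  cat(sprintf("<mp_fov> %s %s (%d,%d), %d x %d px, %.3g um/px\n",
              x$sample_id, x$channel, x$grid_row, x$grid_col,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Read one channel image from a single-plane grayscale TIFF
#'
#' Intensities are returned as stored (integer TIFFs are not rescaled to
#' \[0, 1\]); min-max normalization happens later, per FoV, so the absolute
#' scale is irrelevant downstream.
#'
#' @param path Path to a single-plane grayscale TIFF.
#' @param channel Channel tag to attach (`"CARS"`, `"TPEF"`, `"SHG"`).
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @return An [mp_image()].
#' @export
read_channel_image <- function(path, channel, pixel_size_um = 1) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mptexture_io_error")
  }
  img <- tryCatch(tiff::readTIFF(path, info = TRUE, all = TRUE),
                  error = function(e) {
                    abort(paste0("unreadable TIFF: ", path, " (", conditionMessage(e), ")"),
                          class = "mptexture_io_error")
                  })
  if (length(img) != 1L) {
    abort(paste0("not single-channel: multi-page TIFF ", path),
          class = "mptexture_io_error")
  }
  img <- img[[1L]]
  if (length(dim(img)) != 2L) {
    abort(paste0("not single-channel: ", path, " has ", dim(img)[3L], " samples per pixel"),
          class = "mptexture_io_error")
  }
  bits <- attr(img, "bits.per.sample") %||% 32L
  if (bits < 32L) {
    # integer storage: undo tiff's [0,1] rescale to recover raw counts
    img <- round(matrix(as.numeric(img), nrow(img), ncol(img)) * (2^bits - 1))
  } else {
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
  }
  img[img < 0] <- 0  # guard against float round-off at zero
  mp_image(img, pixel_size_um = pixel_size_um, channel = channel)
}

#' Write one channel image as a 32-bit float TIFF
#'
#' Intensities are in arbitrary units; they are rescaled to the unit interval
#' on write (float TIFF storage is defined on \[0, 1\]). The per-FoV min-max
#' normalization downstream makes absolute scale irrelevant by design.
#'
#' @param image An [mp_image()] or [mp_fov()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(image, path) {
  stopifnot(inherits(image, "mp_image"))
  px <- image$pixels
  m <- max(px)
  if (m > 0) px <- px / m
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}

#' Cut an image into non-overlapping fields of view
#'
#' Tiles are laid on a regular grid anchored at the top-left pixel; partial
#' tiles at the right/bottom edges are discarded (padding would inject
#' artificial texture into the feature statistics). Order is row-major.
#'
#' @param image An [mp_image()].
#' @param fov_rows,fov_cols Tile shape in pixels (default 104 x 208).
#' @param sample_id Sample identifier stamped on each FoV.
#' @return List of [mp_fov()] in row-major grid order.
#' @export
tile <- function(image, fov_rows = 104L, fov_cols = 208L, sample_id = "sample") {
  stopifnot(inherits(image, "mp_image"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (nr < fov_rows || nc < fov_cols) {
    abort(sprintf("image (%d x %d) smaller than one %d x %d tile", nr, nc, fov_rows, fov_cols),
          class = "mptexture_validation_error")
  }
  n_gr <- nr %/% fov_rows
  n_gc <- nc %/% fov_cols
  out <- vector("list", n_gr * n_gc)
  k <- 1L
  for (gr in seq_len(n_gr) - 1L) {
    for (gc in seq_len(n_gc) - 1L) {
      rows <- gr * fov_rows + seq_len(fov_rows)
      cols <- gc * fov_cols + seq_len(fov_cols)
      out[[k]] <- mp_fov(image$pixels[rows, cols, drop = FALSE],
                         pixel_size_um = image$pixel_size_um,
                         channel = image$channel,
                         sample_id = sample_id, grid_row = gr, grid_col = gc)
      k <- k + 1L
    }
  }
  out
}

#' Reassemble tiled fields of view into one image
#'
#' Inverse of [tile()] over the retained region (discarded edge margins are
#' not restored).
#'
#' @param fovs List of [mp_fov()] from the same scan/channel.
#' @return An [mp_image()].
#' @export
untile <- function(fovs) {
  stopifnot(length(fovs) >= 1, all(vapply(fovs, inherits, TRUE, "mp_fov")))
  fr <- nrow(fovs[[1]]$pixels); fc <- ncol(fovs[[1]]$pixels)
  n_gr <- max(vapply(fovs, function(f) f$grid_row, 0L)) + 1L
  n_gc <- max(vapply(fovs, function(f) f$grid_col, 0L)) + 1L
  px <- matrix(0, n_gr * fr, n_gc * fc)
  for (f in fovs) {
    px[f$grid_row * fr + seq_len(fr), f$grid_col * fc + seq_len(fc)] <- f$pixels
  }
  mp_image(px, pixel_size_um = fovs[[1]]$pixel_size_um, channel = fovs[[1]]$channel)
}

#' Block-average downsampling
#'
#' Each output pixel is the arithmetic mean of a `factor` x `factor` block;
#' the pixel size grows by `factor`. Used for the resolution experiment
#' (imaging at finer pitch, analysing at 1 um/px). Trailing rows/columns not
#' filling a block are dropped with a warning.
#'
#' @param image An [mp_image()].
#' @param factor Positive integer downsampling factor.
#' @return An [mp_image()] with `factor`-fold larger pixels.
#' @export
downsample <- function(image, factor) {
  stopifnot(inherits(image, "mp_image"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 || factor != round(factor)) {
    abort("`factor` must be a positive integer.", class = "mptexture_validation_error")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  px <- image$pixels
  nr <- (nrow(px) %/% factor) * factor
  nc <- (ncol(px) %/% factor) * factor
  if (nr < nrow(px) || nc < ncol(px)) {
    warn(sprintf("downsample: dropping %d trailing row(s) and %d column(s) not filling a block",
                 nrow(px) - nr, ncol(px) - nc))
    px <- px[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  # mean over factor x factor blocks via two grouped row-sums
  rowg <- rep(seq_len(nr %/% factor), each = factor)
  colg <- rep(seq_len(nc %/% factor), each = factor)
  out <- rowsum(px, rowg)
  out <- unname(t(rowsum(t(out), colg)) / factor^2)
  res <- if (nrow(out) >= 2 && ncol(out) >= 2) {
    mp_image(out, pixel_size_um = image$pixel_size_um * factor,
             channel = image$channel)
  } else {
    # degenerate (single-row/col) results keep the record shape without the
    # minimum-size invariant; they are terminal, not re-analysed
    structure(list(pixels = out, pixel_size_um = image$pixel_size_um * factor,
                   channel = image$channel), class = "mp_image")
  }
  if (inherits(image, "mp_fov")) {
    res$sample_id <- image$sample_id
    res$grid_row <- image$grid_row
    res$grid_col <- image$grid_col
    class(res) <- c("mp_fov", "mp_image")
  }
  res
}

#' Read a dataset manifest
#'
#' The manifest CSV maps samples and channels to image files:
#' columns `sample_id`, `channel`, `path`, and optionally `label`
#' (`nontumor`/`tumor`). Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble with absolute `path`s.
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "channel", "path")
  if (!all(need %in% names(man))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")),
          class = "mptexture_validation_error")
  }
  bad <- setdiff(unique(man$channel), MP_CHANNELS)
  if (length(bad)) {
    abort(paste0("unknown channel(s) in manifest: ", paste(bad, collapse = ", ")),
          class = "mptexture_validation_error")
  }
  root <- dirname(normalizePath(path))
  man$path <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                     file.path(root, man$path))
  tibble::as_tibble(man)
}
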