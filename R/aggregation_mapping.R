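#' Aggregate FoV probabilities into per-sample diagnostic ratings
#'
#' For each sample the median of its FoV tumor probabilities is the diagnostic
#' rating: `median_p > 0.5` calls tumor, `< 0.5` nontumor, and exactly 0.5 is
#' surfaced as `"indeterminate"` (counted as misclassified in evaluation)
#' rather than silently resolved — intermediate probabilities can technically
#' fall to either class but are clinically ambiguous. The even-n median is the
#' mean of the middle two values.
#'
#' @param predictions Tibble with `sample_id` and `p_tumor` (from
#'   [predict.mp_lda()]); a `label` column, if present, is carried through.
#' @return A tibble with one row per sample: `sample_id`, `median_p`,
#'   `predicted_class`, `n_fovs`, `fraction_fovs_tumor_call`, optional `label`.
#' @export
aggregate_samples <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("sample_id", "p_tumor") %in% names(predictions)))
  if (nrow(predictions) == 0L) {
    abort("no predictions to aggregate.", class = "mptexture_validation_error")
  }
  if (any(predictions$p_tumor < 0 | predictions$p_tumor > 1)) {
    abort("p_tumor must be in [0, 1].", class = "mptexture_validation_error")
  }
  out <- predictions |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      median_p = stats::median(.data$p_tumor),
      n_fovs = dplyr::n(),
      fraction_fovs_tumor_call = mean(.data$p_tumor > 0.5),
      label = if ("label" %in% names(predictions)) .data$label[[1L]] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::mutate(predicted_class = dplyr::case_when(
      .data$median_p > 0.5 ~ "tumor",
      .data$median_p < 0.5 ~ "nontumor",
      TRUE ~ "indeterminate"
    )) |>
    dplyr::select("sample_id", "median_p", "predicted_class", "n_fovs",
                  "fraction_fovs_tumor_call", dplyr::any_of("label"))
  if (all(is.na(out$label))) out$label <- NULL
  out
}

#' Aggregate one sample
#'
#' Convenience scalar form of [aggregate_samples()].
#'
#' @param p_tumor Numeric vector of FoV tumor probabilities of one sample.
#' @param sample_id Sample identifier.
#' @return One-row tibble as in [aggregate_samples()].
#' @export
aggregate_sample <- function(p_tumor, sample_id = "sample") {
  aggregate_samples(tibble::tibble(sample_id = sample_id, p_tumor = p_tumor))
}

#' Fraction of correctly classified FoVs of one sample
#'
#' A FoV is called tumor when `p_tumor > 0.5`; exact ties at 0.5 count as
#' incorrect for either truth.
#'
#' @param p_tumor Numeric vector of FoV probabilities.
#' @param true_label `"nontumor"` or `"tumor"`.
#' @return Fraction in \[0, 1\].
#' @export
fraction_correct_fovs <- function(p_tumor, true_label) {
  if (length(p_tumor) == 0L) {
    abort("no predictions supplied.", class = "mptexture_validation_error")
  }
  true_label <- match.arg(true_label, MP_CLASSES)
  if (true_label == "tumor") mean(p_tumor > 0.5) else mean(p_tumor < 0.5)
}

#' Evaluation report from per-type correct counts
#'
#' The arithmetic core of the evaluation stage: given, per tissue type, the
#' number of cases and the number correctly classified, computes sensitivity
#' (correct rate among tumor types), specificity (correct rate among nontumor
#' types) and the pooled correct rate. Display percentages are rounded half-up
#' to integers; unrounded values are retained.
#'
#' @param counts Tibble with columns `type`, `class`
#'   (`"nontumor"`/`"tumor"`), `n`, `n_correct`.
#' @param level `"sample"` or `"fov"` (annotation only).
#' @return An object of class `mp_eval`.
#' @export
evaluate_counts <- function(counts, level = "sample") {
  stopifnot(is.data.frame(counts),
            all(c("type", "class", "n", "n_correct") %in% names(counts)))
  if (any(counts$n_correct > counts$n) || any(counts$n < 0)) {
    abort("need 0 <= n_correct <= n per type.", class = "mptexture_validation_error")
  }
  per_class <- counts |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = sum(.data$n), n_correct = sum(.data$n_correct),
                     .groups = "drop")
  rate_of <- function(cl) {
    row <- per_class[per_class$class == cl, ]
    if (nrow(row) == 0L || row$n == 0L) return(NA_real_)
    100 * row$n_correct / row$n
  }
  sens <- rate_of("tumor")
  spec <- rate_of("nontumor")
  correct <- 100 * sum(counts$n_correct) / sum(counts$n)
  structure(
    list(level = level,
         sensitivity = sens, specificity = spec, correct_rate = correct,
         sensitivity_pct = round_half_up(sens),
         specificity_pct = round_half_up(spec),
         correct_rate_pct = round_half_up(correct),
         per_type = tibble::as_tibble(counts),
         n = sum(counts$n)),
    class = "mp_eval")
}

#' Evaluate sample ratings against truth
#'
#' Tabulates per-type correct counts from the per-sample predicted classes
#' (`"indeterminate"` counts as incorrect) and reduces them with
#' [evaluate_counts()].
#'
#' @param ratings Tibble from [aggregate_samples()] with a true `label`
#'   column (or supplied via `truth`), optionally a `type` column for
#'   per-type tabulation (defaults to the class itself).
#' @param truth Optional named vector `sample_id -> label`.
#' @param level Annotation, `"sample"` (default) or `"fov"`.
#' @return An `mp_eval` report.
#' @export
evaluate_ratings <- function(ratings, truth = NULL, level = "sample") {
  stopifnot(is.data.frame(ratings),
            all(c("sample_id", "predicted_class") %in% names(ratings)))
  if (!is.null(truth)) ratings$label <- unname(truth[ratings$sample_id])
  if (!"label" %in% names(ratings) || anyNA(ratings$label)) {
    abort("true labels required for evaluation.", class = "mptexture_validation_error")
  }
  if (!"type" %in% names(ratings)) ratings$type <- ratings$label
  counts <- ratings |>
    dplyr::group_by(.data$type, class = .data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     n_correct = sum(.data$predicted_class == .data$label),
                     .groups = "drop")
  evaluate_counts(counts, level = level)
}

#' @export
print.mp_eval <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else paste0(v, "%")
  cat(sprintf("<mp_eval> %s level, n = %d\n", x$level, x$n))
  cat(sprintf("  sensitivity %s | specificity %s | correct rate %s\n",
              fmt(x$sensitivity_pct), fmt(x$specificity_pct), fmt(x$correct_rate_pct)))
  invisible(x)
}

#' @export
tidy.mp_eval <- function(x, ...) x$per_type

#' @export
glance.mp_eval <- function(x, ...) {
  tibble::tibble(level = x$level, n = x$n,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 correct_rate = x$correct_rate,
                 sensitivity_pct = x$sensitivity_pct,
                 specificity_pct = x$specificity_pct,
                 correct_rate_pct = x$correct_rate_pct)
}

#' Tiled probability map of a scan
#'
#' Arranges per-FoV tumor probabilities on their tile grid for tumor-border
#' visualization.
#'
#' @param predictions Tibble with `grid_row`, `grid_col`, `p_tumor`.
#' @return Tibble of class `mp_probmap` (grid positions may be sparse;
#'   missing tiles are simply absent and render neutral).
#' @export
prob_map <- function(predictions) {
  stopifnot(all(c("grid_row", "grid_col", "p_tumor") %in% names(predictions)))
  if (nrow(predictions) == 0L) {
    abort("empty probability grid.", class = "mptexture_validation_error")
  }
  out <- tibble::as_tibble(predictions[, c("grid_row", "grid_col", "p_tumor")])
  class(out) <- c("mp_probmap", class(out))
  out
}

#' Plot a probability map with the blue-to-red diagnostic color code
#'
#' Blue marks nontumor (p = 0), red tumor (p = 1); intermediate probabilities
#' fade through gray, matching the diagnostic color convention. The fill is a
#' continuous monotone function of p with fixed limits \[0, 1\].
#'
#' @param object An `mp_probmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mp_probmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid_col, y = .data$grid_row,
                                       fill = .data$p_tumor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#0000FF", mid = "#808080", high = "#FF0000",
                                  midpoint = 0.5, limits = c(0, 1),
                                  name = "p(tumor)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "tile column", y = "tile row") +
    ggplot2::theme_minimal()
}

#' Map a probability to its display color
#'
#' Linear interpolation between the anchors blue (0), gray (0.5) and red (1).
#'
#' @param p Probabilities in \[0, 1\].
#' @return Hex colors.
#' @export
prob_color <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ramp <- grDevices::colorRamp(c("#0000FF", "#808080", "#FF0000"))
  rgb <- ramp(p)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Render a probability map to a PNG with a JSON sidecar of the raw grid
#'
#' @param map An `mp_probmap` (see [prob_map()]).
#' @param path Output PNG path; `<path>.json` receives the grid values.
#' @param tile_px Pixels per tile edge in the rendered image.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, tile_px = 20) {
  stopifnot(inherits(map, "mp_probmap"))
  plt <- autoplot(map)
  n_r <- max(map$grid_row) + 1L
  n_c <- max(map$grid_col) + 1L
  ggplot2::ggsave(path, plt, width = max(2, n_c * tile_px / 72) + 1.5,
                  height = max(2, n_r * tile_px / 72) + 1, dpi = 72,
                  limitsize = FALSE)
  jsonlite::write_json(
    list(grid_row = map$grid_row, grid_col = map$grid_col, p_tumor = map$p_tumor),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}
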