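#' Simulate a dataset on disk
#'
#' Generates a synthetic cohort and writes it as TIFFs + manifest CSV + truth
#' JSON, fully compatible with the real-data input path ([read_manifest()],
#' [compute_features()]).
#'
#' @param dir Output directory.
#' @param ... Passed to [gen_cohort()].
#' @return The manifest path, invisibly.
#' @export
simulate_dataset <- function(dir, ...) {
  cohort <- gen_cohort(...)
  write_dataset(cohort, dir)
}

#' Fit the classifier on the training split of a feature table
#'
#' Uses only rows with `split == "train"` when a `split` column is present
#' (hard-erroring if any sample leaks across splits), otherwise all rows.
#'
#' @param features Feature tibble with `label` (and ideally `split`).
#' @param priors,lambda Passed to [fit_lda()].
#' @return An `mp_lda` model.
#' @export
train_classifier <- function(features, priors = "empirical", lambda = NULL) {
  stopifnot("label" %in% names(features))
  if ("split" %in% names(features)) {
    leak <- features |>
      dplyr::distinct(.data$sample_id, .data$split) |>
      dplyr::count(.data$sample_id) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(leak)) {
      abort(paste0("patient-level leakage: sample(s) in both splits: ",
                   paste(leak$sample_id, collapse = ", ")),
            class = "mptexture_leakage_error")
    }
    train <- features[features$split == "train", ]
  } else {
    train <- features
  }
  hash <- attr(features, "config_hash")
  attr(train, "config_hash") <- hash
  fit_lda(train, train$label, priors = priors, lambda = lambda)
}

#' FoV-level classification accuracy
#'
#' A FoV is correct when `p_tumor > 0.5` for true tumor or `< 0.5` for true
#' nontumor; exact ties count as incorrect.
#'
#' @param predictions Tibble with `p_tumor` and true `label`.
#' @return Fraction correct in \[0, 1\].
#' @export
fov_accuracy <- function(predictions) {
  stopifnot(all(c("p_tumor", "label") %in% names(predictions)))
  mean(ifelse(predictions$label == "tumor",
              predictions$p_tumor > 0.5, predictions$p_tumor < 0.5))
}

#' Run the full recognition pipeline on a synthetic cohort
#'
#' Feature extraction, training on the cohort's patient-level training split,
#' per-FoV posterior prediction on the held-out patients, median aggregation
#' into sample ratings, and FoV- and sample-level evaluation.
#'
#' @param cohort An [gen_cohort()] object, or a precomputed feature tibble
#'   carrying `label`, `type` and `split` columns.
#' @param config A [texture_config()].
#' @param priors,lambda Passed to [fit_lda()].
#' @return List of class `mp_pipeline_result`: `model`, `features`,
#'   `predictions` (test FoVs), `ratings`, `fov_eval`, `sample_eval`,
#'   `fov_accuracy`.
#' @export
run_pipeline <- function(cohort, config = NULL, priors = "empirical", lambda = NULL) {
  if (inherits(cohort, "mp_cohort")) {
    config <- config %||% texture_config(channels = cohort$channels)
    features <- cohort_features(cohort, config)
  } else {
    features <- cohort
    stopifnot(all(c("label", "split") %in% names(features)))
  }
  model <- train_classifier(features, priors = priors, lambda = lambda)
  test <- features[features$split == "test", ]
  attr(test, "config_hash") <- attr(features, "config_hash")
  preds <- predict(model, test)
  if ("type" %in% names(test)) preds$type <- test$type
  ratings <- aggregate_samples(preds)
  if ("type" %in% names(test)) {
    ratings <- dplyr::left_join(
      ratings, dplyr::distinct(test[, c("sample_id", "type")]), by = "sample_id")
  }
  sample_eval <- evaluate_ratings(ratings, level = "sample")
  fov_counts <- preds |>
    dplyr::group_by(type = if ("type" %in% names(preds)) .data$type else .data$label,
                    class = .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(ifelse(.data$label == "tumor", .data$p_tumor > 0.5,
                             .data$p_tumor < 0.5)),
      .groups = "drop")
  fov_eval <- evaluate_counts(fov_counts, level = "fov")
  structure(list(model = model, features = features, predictions = preds,
                 ratings = ratings, fov_eval = fov_eval,
                 sample_eval = sample_eval,
                 fov_accuracy = fov_accuracy(preds)),
            class = "mp_pipeline_result")
}

#' @export
print.mp_pipeline_result <- function(x, ...) {
  cat(sprintf("<mp_pipeline_result> %d test FoVs, FoV accuracy %.1f%%\n",
              nrow(x$predictions), 100 * x$fov_accuracy))
  print(x$sample_eval)
  invisible(x)
}

#' Bundled per-type classification counts of a 218-biopsy reference test set
#'
#' Per tissue type: the number of test biopsies (`n`) and how many were
#' correctly classified from single-channel (CARS, TPEF, SHG) and combined
#' CARS+TPEF texture parameters. 204 tumor biopsies of ten types plus 14
#' nontumor brain samples. These printed counts are the input for the
#' evaluation-arithmetic checks: [evaluate_counts()] reproduces the published
#' sensitivity/specificity/correct-rate block from them.
#'
#' @return Tibble with columns `type`, `class`, `n`, `cars_correct`,
#'   `tpef_correct`, `shg_correct`, `combined_correct`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_test_counts.csv", package = "mptexture")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Paired feature tables at native and block-averaged resolution
#'
#' Generates each patient's FoVs once, extracts features at the native pixel
#' size and again after block-average downsampling by `factor` — the
#' resolution experiment asking whether coarser pixels (e.g. 1 um instead of
#' 0.5 um) change classification. Co-occurrence distances are specified in um,
#' so both tables probe matched physical scales.
#'
#' @param cohort An [gen_cohort()] object (typically generated at a sub-um
#'   pixel size).
#' @param config A [texture_config()].
#' @param factor Downsampling factor (default 2).
#' @return List with feature tibbles `native` and `downsampled`.
#' @export
resolution_features <- function(cohort, config = texture_config(channels = cohort$channels),
                                factor = 2L) {
  nat <- list(); ds <- list()
  for (i in seq_len(nrow(cohort$samples))) {
    sid <- cohort$samples$sample_id[i]
    fovsets <- cohort_fovs(cohort, sid)
    annotate <- function(ft) {
      ft$label <- cohort$samples$label[i]
      ft$type <- cohort$samples$type[i]
      ft$split <- cohort$samples$split[i]
      ft
    }
    nat[[i]] <- annotate(compute_features(fovsets, config))
    low <- lapply(fovsets, function(fs) lapply(fs, downsample, factor = factor))
    ds[[i]] <- annotate(compute_features(low, config))
  }
  out <- list(native = dplyr::bind_rows(nat), downsampled = dplyr::bind_rows(ds))
  for (nm in names(out)) attr(out[[nm]], "config_hash") <- config$hash
  out
}
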