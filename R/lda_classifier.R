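#' Patient-level train/test split
#'
#' Assigns whole patients (samples) to the training or test set so that no
#' FoV of a patient leaks across the split — classification performance is
#' otherwise inflated by within-patient correlation. By default the draw is
#' stratified by class so both classes are present on both sides even with
#' very few nontumor patients.
#'
#' @param samples Tibble with one row per sample: `sample_id` and `label`
#'   (`"nontumor"`/`"tumor"`).
#' @param proportion Fraction of patients assigned to the training set.
#' @param seed Integer seed; the split is reproducible from it.
#' @param stratify Draw the proportion within each class (default `TRUE`).
#' @return The input tibble with a `split` column (`"train"`/`"test"`).
#' @export
split_by_patient <- function(samples, proportion = 0.5, seed = 1L, stratify = TRUE) {
  stopifnot(is.data.frame(samples), all(c("sample_id", "label") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) {
    abort("`samples` must have one row per sample_id.", class = "mptexture_validation_error")
  }
  if (proportion <= 0 || proportion >= 1) {
    abort("`proportion` must be in (0, 1).", class = "mptexture_validation_error")
  }
  samples <- tibble::as_tibble(samples)
  n <- nrow(samples)
  assign_grp <- function(nn) {
    n_train <- max(1L, min(nn - 1L, round(nn * proportion)))
    smp <- sample.int(nn)
    ifelse(seq_len(nn) %in% smp[seq_len(n_train)], "train", "test")
  }
  samples$split <- with_seed(seed, {
    if (stratify) {
      out <- character(n)
      for (cl in unique(samples$label)) {
        idx <- which(samples$label == cl)
        out[idx] <- assign_grp(length(idx))
      }
      out
    } else {
      assign_grp(n)
    }
  })
  for (side in c("train", "test")) {
    present <- unique(samples$label[samples$split == side])
    if (!all(MP_CLASSES %in% present)) {
      abort(sprintf("class missing from %s set; re-draw with another seed or stratify.", side),
            class = "mptexture_split_error")
    }
  }
  samples
}

#' Fit a two-class linear discriminant on FoV texture vectors
#'
#' Gaussian classifier with a pooled (shared) covariance: class means are the
#' per-class feature means, the pooled covariance is the within-class scatter
#' divided by `N - K`, and a ridge `lambda * I` is added to tolerate
#' near-constant features (e.g. SHG texture in nontumor fields). Class
#' encoding is frozen as 0 = nontumor, 1 = tumor.
#'
#' @param features Data frame or matrix of FoV feature vectors (numeric
#'   columns only; a tibble from [compute_features()] may include its
#'   provenance columns, which are dropped).
#' @param labels Vector of `"nontumor"`/`"tumor"` (or a column name in
#'   `features`).
#' @param priors `"empirical"` (class frequencies, default) or `"uniform"`,
#'   or a numeric pair summing to 1 in (nontumor, tumor) order.
#' @param lambda Ridge added to the covariance diagonal; default
#'   `1e-6 * trace(Sigma) / p`. `lambda = 0` reproduces the strict classical
#'   estimator and errors on a singular covariance.
#' @return An object of class `mp_lda`.
#' @export
fit_lda <- function(features, labels, priors = c("empirical", "uniform"),
                    lambda = NULL) {
  if (is.character(labels) && length(labels) == 1L && is.data.frame(features)) {
    labels <- features[[labels]]
  }
  hash <- attr(features, "config_hash")
  X <- feature_matrix(features)
  labels <- as.character(labels)
  if (!all(labels %in% MP_CLASSES)) {
    abort("labels must be 'nontumor' or 'tumor'.", class = "mptexture_validation_error")
  }
  if (nrow(X) != length(labels)) {
    abort("features and labels disagree in length.", class = "mptexture_validation_error")
  }
  if (anyNA(X) || !all(is.finite(X))) {
    abort("features contain NA/Inf.", class = "mptexture_validation_error")
  }
  counts <- table(factor(labels, levels = MP_CLASSES))
  if (any(counts < 2)) {
    abort("need >= 2 FoVs per class.", class = "mptexture_validation_error")
  }
  p <- ncol(X)
  means <- rbind(colMeans(X[labels == "nontumor", , drop = FALSE]),
                 colMeans(X[labels == "tumor", , drop = FALSE]))
  rownames(means) <- MP_CLASSES
  scatter <- matrix(0, p, p)
  for (cl in MP_CLASSES) {
    Xc <- sweep(X[labels == cl, , drop = FALSE], 2, means[cl, ])
    scatter <- scatter + crossprod(Xc)
  }
  sigma <- scatter / (nrow(X) - 2L)
  if (is.null(lambda)) lambda <- 1e-6 * sum(diag(sigma)) / p
  if (lambda < 0) abort("`lambda` must be >= 0.", class = "mptexture_validation_error")
  sigma_reg <- sigma + diag(lambda, p)
  ch <- tryCatch(chol(sigma_reg), error = function(e) NULL)
  if (is.null(ch)) {
    eg <- eigen(sigma_reg, symmetric = TRUE)
    worst <- which.max(abs(eg$vectors[, p]))
    abort(sprintf(paste0(
      "pooled covariance is singular (deficient direction dominated by '%s'); ",
      "set lambda > 0 (suggestion: %.3g)."),
      colnames(X)[worst], 1e-6 * max(sum(diag(sigma)) / p, 1)),
      class = "mptexture_singular_error")
  }
  if (is.character(priors)) {
    priors <- match.arg(priors)
    pri <- if (priors == "empirical") as.numeric(counts) / sum(counts) else c(0.5, 0.5)
    priors_mode <- priors
  } else {
    if (length(priors) != 2 || any(priors < 0) || abs(sum(priors) - 1) > 1e-12) {
      abort("numeric priors must be two nonnegative values summing to 1.",
            class = "mptexture_validation_error")
    }
    pri <- as.numeric(priors)
    priors_mode <- "explicit"
  }
  names(pri) <- MP_CLASSES
  structure(
    list(class_labels = MP_CLASSES,
         class_means = means,
         pooled_covariance = sigma_reg,
         priors = pri, priors_mode = priors_mode,
         lambda = lambda,
         feature_manifest = colnames(X),
         config_hash = hash,
         chol = ch,
         n = as.integer(nrow(X)), n_per_class = as.integer(counts)),
    class = "mp_lda")
}

## Numeric feature matrix from a feature tibble, dropping provenance columns.
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    X <- features
  } else {
    drop_cols <- c("sample_id", "grid_row", "grid_col", "degenerate", "label", "split")
    keep <- setdiff(names(features), drop_cols)
    keep <- keep[vapply(features[keep], is.numeric, logical(1))]
    X <- as.matrix(features[, keep, drop = FALSE])
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

#' @export
print.mp_lda <- function(x, ...) {
  cat(sprintf("<mp_lda> %d features, n = %d (%d nontumor / %d tumor), lambda = %.3g, priors = %s\n",
              length(x$feature_manifest), x$n, x$n_per_class[1], x$n_per_class[2],
              x$lambda, x$priors_mode))
  invisible(x)
}

#' Posterior probability of class assignment
#'
#' Evaluates the linear discriminant scores
#' `delta_k(x) = x' Sigma^-1 mu_k - mu_k' Sigma^-1 mu_k / 2 + log pi_k`
#' and normalizes over the two classes, giving the probability of class
#' assignment (0 = nontumor, 1 = tumor) for each FoV.
#'
#' @param model An [fit_lda()] model.
#' @param x Numeric feature vector, matrix, or feature tibble whose columns
#'   match the model's feature manifest.
#' @return Numeric vector of `p_tumor` values in \[0, 1\].
#' @export
posterior <- function(model, x) {
  stopifnot(inherits(model, "mp_lda"))
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1,
                                                    dimnames = list(NULL, names(x)))
  X <- feature_matrix(x)
  if (ncol(X) != length(model$feature_manifest)) {
    abort(sprintf("feature dimension %d does not match model manifest (%d).",
                  ncol(X), length(model$feature_manifest)),
          class = "mptexture_validation_error")
  }
  if (!is.null(colnames(X)) && !is.null(model$feature_manifest) &&
      all(model$feature_manifest %in% colnames(X))) {
    X <- X[, model$feature_manifest, drop = FALSE]
  }
  # scores via the Cholesky factor of the pooled covariance
  Minv <- backsolve(model$chol, forwardsolve(t(model$chol), t(model$class_means)))
  lin <- X %*% Minv                                   # n x 2
  quad <- colSums(t(model$class_means) * Minv) / 2    # length 2
  scores <- sweep(lin, 2, quad) +
    matrix(log(model$priors), nrow(X), 2, byrow = TRUE)
  m <- pmax(scores[, 1], scores[, 2])
  ez <- exp(scores - m)
  unname(ez[, 2] / (ez[, 1] + ez[, 2]))
}

#' Predict tumor probabilities for a table of FoV feature vectors
#'
#' Batch, order-preserving wrapper around [posterior()]. When both the model
#' and the feature table carry a texture-config fingerprint they must agree —
#' mixing feature conventions is refused rather than silently tolerated.
#'
#' @param object An `mp_lda` model.
#' @param newdata Feature tibble ([compute_features()]) or numeric matrix.
#' @param ... Unused.
#' @return A tibble with the provenance columns of `newdata` (when present)
#'   and `p_tumor`.
#' @export
predict.mp_lda <- function(object, newdata, ...) {
  hash <- attr(newdata, "config_hash")
  if (!is.null(hash) && !is.null(object$config_hash) &&
      !identical(hash, object$config_hash)) {
    abort("texture config of the feature table differs from the model's; refusing to mix conventions.",
          class = "mptexture_config_mismatch")
  }
  p <- posterior(object, newdata)
  prov <- c("sample_id", "grid_row", "grid_col", "label")
  if (is.data.frame(newdata)) {
    out <- tibble::as_tibble(newdata[, intersect(prov, names(newdata)), drop = FALSE])
  } else {
    out <- tibble::tibble(.rows = length(p))
  }
  out$p_tumor <- p
  out
}

#' @export
tidy.mp_lda <- function(x, ...) {
  # discriminant direction Sigma^-1 (mu_tumor - mu_nontumor) per feature
  w <- backsolve(x$chol, forwardsolve(t(x$chol), x$class_means["tumor", ] -
                                       x$class_means["nontumor", ]))
  tibble::tibble(
    term = x$feature_manifest,
    mean_nontumor = unname(x$class_means["nontumor", ]),
    mean_tumor = unname(x$class_means["tumor", ]),
    discriminant_weight = as.numeric(w)
  )
}

#' @export
glance.mp_lda <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_nontumor = x$n_per_class[1], n_tumor = x$n_per_class[2],
    n_features = length(x$feature_manifest),
    lambda = x$lambda, priors_mode = x$priors_mode,
    prior_tumor = unname(x$priors["tumor"])
  )
}

#' Serialize / restore a fitted discriminant as JSON
#'
#' The JSON carries the class means, pooled covariance, priors, ridge, and the
#' frozen feature manifest with the texture-config hash, making trained models
#' portable across sessions.
#'
#' @param model An `mp_lda` model.
#' @param path JSON path.
#' @return `path` / the restored `mp_lda`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mp_lda"))
  obj <- list(class_labels = model$class_labels,
              class_means = list(nontumor = unname(model$class_means["nontumor", ]),
                                 tumor = unname(model$class_means["tumor", ])),
              pooled_covariance = lapply(seq_len(nrow(model$pooled_covariance)),
                                         function(i) unname(model$pooled_covariance[i, ])),
              priors = as.list(model$priors), priors_mode = model$priors_mode,
              lambda = model$lambda,
              feature_manifest = model$feature_manifest,
              config_hash = model$config_hash,
              n = model$n, n_per_class = model$n_per_class,
              created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- rbind(as.numeric(unlist(obj$class_means[["nontumor"]])),
                 as.numeric(unlist(obj$class_means[["tumor"]])))
  sigma <- obj$pooled_covariance
  if (is.list(sigma)) sigma <- do.call(rbind, sigma)
  rownames(means) <- MP_CLASSES
  colnames(means) <- obj$feature_manifest
  dimnames(sigma) <- NULL
  structure(
    list(class_labels = MP_CLASSES,
         class_means = means,
         pooled_covariance = sigma,
         priors = setNames(as.numeric(unlist(obj$priors)), MP_CLASSES),
         priors_mode = obj$priors_mode,
         lambda = obj$lambda,
         feature_manifest = obj$feature_manifest,
         config_hash = if (length(obj$config_hash)) obj$config_hash else NULL,
         chol = chol(sigma),
         n = obj$n, n_per_class = obj$n_per_class),
    class = "mp_lda")
}
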