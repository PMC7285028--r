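#' Exaggerate image contrast
#'
#' Linearly rescales each channel so its observed minimum maps to 0 and
#' maximum to 255, the "contrast exaggeration" step applied before spectral
#' thresholding. Constant channels are left unchanged. The map is idempotent:
#' a stretched image stretches to itself.
#'
#' @param image An [rgb_image()].
#' @return The stretched `rgb_image`.
#' @export
contrast_stretch <- function(image) {
  arr <- unclass(image)
  for (ch in 1:3) {
    v <- arr[, , ch]
    rng <- range(v)
    if (rng[2] > rng[1]) {
      arr[, , ch] <- (v - rng[1]) / (rng[2] - rng[1]) * 255
    }
  }
  rgb_image(arr, condition = image_condition(image))
}

#' Excess-green score of an image
#'
#' Per-pixel greenness `2G - R - B`, the spectral value used to separate
#' green vegetation from soil background.
#'
#' @param image An [rgb_image()].
#' @return Numeric matrix of scores in `[-510, 510]`.
#' @export
excess_green <- function(image) {
  arr <- unclass(image)
  matrix(2 * arr[, , 2] - arr[, , 1] - arr[, , 3], dim(arr)[1], dim(arr)[2])
}

#' Binary thresholding classification
#'
#' The simplest workflow: after contrast exaggeration, pixels whose
#' excess-green score exceeds a cutoff are classified as weed and everything
#' else as non-weed. Green-tinged soil features pass the cutoff too, which is
#' why this baseline over-detects.
#'
#' @param image An [rgb_image()], ordinarily already passed through
#'   [contrast_stretch()].
#' @param threshold Excess-green cutoff (default 30).
#' @return A logical matrix (`TRUE` = weed).
#' @export
threshold_classify <- function(image, threshold = 30) {
  excess_green(image) > threshold
}

#' Fit per-class Gaussian color statistics (a reference file)
#'
#' Estimates, for each labeled class, the mean RGB vector and sample
#' covariance (denominator `n - 1`) of its training pixels, with a ridge term
#' added to the diagonal to guarantee invertibility for low-variance classes.
#' This is the "reference file" a supervised maximum-likelihood classification
#' reuses across images.
#'
#' @param training Tibble of training pixels with columns `label`, `r`, `g`,
#'   `b` (e.g. from [generate_training_samples()]).
#' @param ridge Nonnegative scalar added to the covariance diagonal
#'   (default `1e-6` on the 0--255 scale).
#' @param priors Optional named per-label prior probabilities; default
#'   uniform.
#' @param condition Light condition this reference represents.
#' @return A `class_stats` object: `labels`, `means` (labels x 3 matrix),
#'   `covs` (list of 3 x 3 matrices), `priors`, `ridge`, `condition`.
#' @export
fit_class_stats <- function(training, ridge = 1e-6, priors = NULL,
                            condition = c("cloudy", "sunny")) {
  condition <- match.arg(condition)
  if (ridge < 0) abort("`ridge` must be >= 0.")
  labels <- unique(training$label)
  counts <- table(training$label)
  small <- labels[counts[labels] < 2]
  if (length(small)) {
    abort(paste0("Labels with fewer than 2 training pixels: ",
                 paste(small, collapse = ", ")))
  }
  means <- matrix(NA_real_, length(labels), 3,
                  dimnames = list(labels, c("r", "g", "b")))
  covs <- vector("list", length(labels))
  names(covs) <- labels
  for (lbl in labels) {
    x <- as.matrix(training[training$label == lbl, c("r", "g", "b")])
    means[lbl, ] <- colMeans(x)
    s <- cov(x) + diag(ridge, 3)
    if (!all(is.finite(s))) {
      abort(sprintf("Covariance for label '%s' is not finite.", lbl))
    }
    covs[[lbl]] <- s  # invertibility is enforced at classification time
  }
  if (is.null(priors)) {
    priors <- setNames(rep(1 / length(labels), length(labels)), labels)
  } else {
    if (!setequal(names(priors), labels)) abort("`priors` must name every label.")
    priors <- priors[labels] / sum(priors)
  }
  structure(list(labels = labels, means = means, covs = covs,
                 priors = priors, ridge = ridge, condition = condition),
            class = "class_stats")
}

#' @export
print.class_stats <- function(x, ...) {
  cat(sprintf("<class_stats> %d labels (%s), condition: %s, ridge: %g\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              x$condition, x$ridge))
  invisible(x)
}

#' Maximum-likelihood supervised classification
#'
#' Assigns every pixel the label maximizing `log prior` plus the multivariate
#' Gaussian log density of its RGB triple under that class's fitted color
#' model (a full quadratic discriminant with per-class covariance). Ties are
#' broken toward the lowest label index.
#'
#' @param image An [rgb_image()].
#' @param stats A `class_stats` reference from [fit_class_stats()].
#' @return A [label_raster()] with the reference's labels.
#' @export
ml_classify <- function(image, stats) {
  stopifnot(inherits(stats, "class_stats"))
  if (length(stats$labels) < 2) abort("Need at least 2 labels to classify.")
  arr <- unclass(image)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  x <- cbind(as.vector(arr[, , 1]), as.vector(arr[, , 2]), as.vector(arr[, , 3]))
  scores <- matrix(NA_real_, nrow(x), length(stats$labels))
  for (j in seq_along(stats$labels)) {
    lbl <- stats$labels[j]
    s <- stats$covs[[lbl]]
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(ch)) abort(sprintf("Covariance for label '%s' is not invertible.", lbl))
    centered <- sweep(x, 2, stats$means[lbl, ])
    z <- backsolve(ch, t(centered), transpose = TRUE)  # solves t(ch) %*% z = t(centered)
    maha <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    scores[, j] <- log(stats$priors[[lbl]]) - 0.5 * logdet - 0.5 * maha
  }
  best <- max.col(scores, ties.method = "first")
  label_raster(matrix(best, h, w), stats$labels)
}

#' Select the reference file matching an image's light condition
#'
#' Field protocols keep separate reference files for sunny and overcast days
#' because lighting shifts every class's colors; sunny references carry the
#' extra `shadows` class.
#'
#' @param stats_by_condition Named list mapping `"sunny"`/`"cloudy"` to
#'   `class_stats` objects.
#' @param image An [rgb_image()] whose condition tag picks the reference.
#' @return The matching `class_stats`.
#' @export
select_reference <- function(stats_by_condition, image) {
  cond <- image_condition(image)
  if (!cond %in% names(stats_by_condition)) {
    abort(sprintf("No reference file for condition '%s'.", cond))
  }
  stats_by_condition[[cond]]
}

#' Serialize a reference file to JSON
#'
#' @param stats A `class_stats` object.
#' @param path JSON file path.
#' @return `write_class_stats()` returns `path` invisibly;
#'   `read_class_stats()` the reconstructed `class_stats`.
#' @export
write_class_stats <- function(stats, path) {
  obj <- list(labels = stats$labels,
              means = apply(stats$means, 1, identity, simplify = FALSE),
              covariances = lapply(stats$covs, function(m) unname(apply(m, 1, identity, simplify = FALSE))),
              priors = as.list(stats$priors),
              ridge = stats$ridge,
              condition = stats$condition)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_class_stats
#' @export
read_class_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.matrix(m)) m else do.call(rbind, m)
  labels <- obj$labels
  means <- as_mat(obj$means[labels])
  dimnames(means) <- list(labels, c("r", "g", "b"))
  covs <- lapply(obj$covariances[labels], function(m) unname(as_mat(m)))
  structure(list(labels = labels, means = means, covs = covs,
                 priors = unlist(obj$priors[labels]), ridge = obj$ridge,
                 condition = obj$condition),
            class = "class_stats")
}

#' Weed mask from a label raster
#'
#' @param raster A [label_raster()].
#' @param target_label Label treated as weed (default `"weed"`).
#' @return Logical matrix.
#' @export
raster_to_mask <- function(raster, target_label = "weed") {
  labels <- raster_labels(raster)
  idx <- match(target_label, labels)
  if (is.na(idx)) abort(sprintf("Label '%s' not present in raster.", target_label))
  matrix(unclass(raster) == idx, nrow(raster))
}
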