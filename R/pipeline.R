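#' Pipeline run configuration
#'
#' Bundles every setting of the end-to-end workflow: the classification
#' method, postclassification settings, pixel standardization, model families
#' to fit, and (when simulating) the synthetic scene and emergence truth.
#' Identical configurations with identical seeds reproduce outputs exactly.
#'
#' @param method `"thresholding"`, `"supervised"`, or `"supervised_post"`
#'   (supervised classification followed by majority filtering and component
#'   area filtering) — the three workflows of increasing processing
#'   intensity.
#' @param seed Master seed recorded in every output.
#' @param scene A [scene_config()] for simulation.
#' @param truth An [emergence_truth()] for simulation; the default is a
#'   Gompertz season (`x0 = 60`, `b = 18` days) of 600 seedlings over 12
#'   biweekly imaging dates.
#' @param n_quadrats Number of quadrats to simulate.
#' @param conditions Optional per-day light conditions.
#' @param image_dir,training_file Paths for running on stored images instead
#'   of simulating (PNG images plus a ground-truth CSV; see
#'   [run_pipeline()]).
#' @param out_dir Optional output directory; when set, all intermediate
#'   tables, fit JSONs and the summary report are written there.
#' @param write_images Also write simulated images/masks as PNG (off by
#'   default).
#' @param standard_size Standard frame size for pixel standardization.
#' @param threshold Excess-green cutoff for the thresholding method.
#' @param radius,min_area,max_area,connectivity Postclassification settings.
#' @param families Model families to fit.
#' @param n_starts Multi-start count for fitting.
#' @param n_samples_per_label Training sample groups per class.
#' @return A validated `run_config` list.
#' @export
run_config <- function(method = c("supervised", "thresholding", "supervised_post"),
                       seed = 1,
                       scene = scene_config(),
                       truth = default_truth(),
                       n_quadrats = 6,
                       conditions = NULL,
                       image_dir = NULL,
                       training_file = NULL,
                       out_dir = NULL,
                       write_images = FALSE,
                       standard_size = 12500000,
                       threshold = 30,
                       radius = 15, min_area = 50, max_area = 20000,
                       connectivity = 8,
                       families = c("logistic", "gompertz", "weibull", "biphasic"),
                       n_starts = 12,
                       n_samples_per_label = 20) {
  method <- match.arg(method)
  if (!is.null(image_dir) && !dir.exists(image_dir)) {
    abort(sprintf("Image directory '%s' does not exist.", image_dir))
  }
  if (!is.null(training_file) && !file.exists(training_file)) {
    abort(sprintf("Training file '%s' does not exist.", training_file))
  }
  if (is.null(image_dir) && is.null(scene)) {
    abort("Provide either an image directory or a synthetic scene block.")
  }
  families <- vapply(families, function(f) {
    match.arg(f, c("logistic", "gompertz", "weibull", "biphasic"))
  }, character(1), USE.NAMES = FALSE)
  if (radius < 1) abort("`radius` must be >= 1.")
  if (min_area > max_area) abort("`min_area` must not exceed `max_area`.")
  structure(list(method = method, seed = seed, scene = scene, truth = truth,
                 n_quadrats = n_quadrats, conditions = conditions,
                 image_dir = image_dir, training_file = training_file,
                 out_dir = out_dir, write_images = write_images,
                 standard_size = standard_size, threshold = threshold,
                 radius = radius, min_area = min_area, max_area = max_area,
                 connectivity = connectivity, families = families,
                 n_starts = n_starts,
                 n_samples_per_label = n_samples_per_label),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_truth <- function() {
  emergence_truth("gompertz", list(a = 1, x0 = 60, b = 18),
                  total_seedlings = 600, image_days = seq(0, 154, by = 14))
}

run_config_keys <- list(
  top = c("method", "seed", "image_dir", "training_file", "out_dir",
          "write_images", "standard_size", "threshold", "post", "fit",
          "scene", "truth", "n_quadrats", "conditions",
          "n_samples_per_label"),
  post = c("radius", "min_area", "max_area", "connectivity"),
  fit = c("families", "n_starts"),
  scene = c("width", "height", "seedling_area", "noise_sd", "condition",
            "distractor_density", "shadow_factor"),
  truth = c("family", "params", "total_seedlings", "image_days")
)

#' Load and validate a YAML run configuration
#'
#' Reads a pipeline configuration from YAML, applies defaults, and rejects
#' unknown keys (typos fail loudly rather than being silently ignored).
#' Nested blocks: `post` (radius, min_area, max_area, connectivity), `fit`
#' (families, n_starts), `scene`, `truth`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
  raw <- yaml::read_yaml(path)
  check_keys <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      abort(sprintf("Unknown %s key(s): %s", where,
                    paste(unknown, collapse = ", ")))
    }
  }
  check_keys(raw, run_config_keys$top, "config")
  for (blk in c("post", "fit", "scene", "truth")) {
    if (!is.null(raw[[blk]])) check_keys(raw[[blk]], run_config_keys[[blk]], blk)
  }
  scene <- if (!is.null(raw$scene)) do.call(scene_config, raw$scene) else scene_config()
  truth <- if (!is.null(raw$truth)) {
    do.call(emergence_truth, raw$truth)
  } else {
    default_truth()
  }
  args <- raw[setdiff(names(raw), c("post", "fit", "scene", "truth"))]
  args <- c(args, raw$post, raw$fit, list(scene = scene, truth = truth))
  do.call(run_config, args)
}

# build one training reference per light condition, from a dedicated scene
# rendered densely enough that every class has sample pixels
train_references <- function(config, conditions_needed) {
  refs <- list()
  for (cond in conditions_needed) {
    sc <- config$scene
    sc$condition <- cond
    sc$distractor_density <- pmax(sc$distractor_density, 6)
    labels <- condition_labels(cond)
    ok <- FALSE
    for (attempt in 1:10) {
      seed <- child_seed(config$seed, 7000 + attempt +
                           ifelse(cond == "sunny", 500, 0))
      res <- render_quadrat_image(sc, n_new_seedlings = 25, seed = seed)
      masks <- masks_from_truth(res$truth_raster)[labels]
      if (all(vapply(masks, sum, numeric(1)) >= config$n_samples_per_label)) {
        samples <- generate_training_samples(
          res$image, masks, n_samples_per_label = config$n_samples_per_label,
          seed = child_seed(config$seed, 8000 + attempt))
        refs[[cond]] <- fit_class_stats(samples, condition = cond)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf("Could not render a training scene with all %s classes.", cond))
    }
  }
  refs
}

# apply the configured classification method to one image
classify_one <- function(image, config, refs) {
  if (config$method == "thresholding") {
    return(list(mask = threshold_classify(contrast_stretch(image),
                                          config$threshold),
                components = NULL))
  }
  stats <- select_reference(refs, image)
  raster <- ml_classify(image, stats)
  if (config$method == "supervised") {
    return(list(mask = raster_to_mask(raster, "weed"), components = NULL))
  }
  raster <- majority_filter(raster, radius = config$radius)
  comp <- extract_components(raster, "weed", connectivity = config$connectivity)
  mask <- area_filter(comp, config$min_area, config$max_area, dim = dim(raster))
  list(mask = mask, components = attr(mask, "components"))
}

# read a stored image series: ground_truth.csv + <quadrat>_d<day>.png files
load_series <- function(config) {
  gt_path <- file.path(config$image_dir, "ground_truth.csv")
  if (!file.exists(gt_path)) {
    abort(sprintf("Missing ground truth table '%s'.", gt_path))
  }
  gt <- tibble::as_tibble(read.csv(gt_path, stringsAsFactors = FALSE))
  gt$image <- purrr::map2(gt$quadrat_id, gt$day, function(q, d) {
    p <- file.path(config$image_dir,
                   sprintf("%s_d%03d.png", q, as.integer(round(d))))
    if (!file.exists(p)) abort(sprintf("Missing image '%s'.", p))
    read_image_png(p, condition = gt$condition[gt$quadrat_id == q & gt$day == d][1])
  })
  gt
}

#' Run the full emergence-modelling pipeline
#'
#' Executes classify -> (optional) postclassify -> emergence series -> model
#' fit -> validation for one configured method. In simulation mode the image
#' series, ground truth and training references are generated from the
#' config's scene and truth blocks; otherwise images and a ground-truth CSV
#' are read from `image_dir`. Identical config and seed reproduce every
#' output exactly.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list: `observations` (per-image pixel counts),
#'   `pixel_series` and `count_series` (relative cumulative tibbles), `fits`
#'   (named list of validated `emergence_fit`s), `comparison`
#'   (AIC-ranked table), `best_family`, `seed` and `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  series <- if (is.null(config$image_dir)) {
    generate_series(config$scene, config$truth, config$n_quadrats,
                    seed = config$seed, conditions = config$conditions)
  } else {
    load_series(config)
  }
  refs <- NULL
  if (config$method %in% c("supervised", "supervised_post")) {
    refs <- train_references(config, unique(series$condition))
  }
  cls <- purrr::map(seq_len(nrow(series)), function(i) {
    tryCatch(classify_one(series$image[[i]], config, refs),
             error = function(e) {
               abort(sprintf("Classification failed for %s day %s: %s",
                             series$quadrat_id[i], series$day[i],
                             conditionMessage(e)))
             })
  })
  obs <- quadrat_observations(series, purrr::map(cls, "mask"),
                              standard_size = config$standard_size)
  pixel_series <- build_relative_cumulative(obs, .data$standardized_pixels,
                                            source = "pixels")
  count_series <- build_relative_cumulative(obs, .data$true_count,
                                            source = "counts")
  pooled <- merge_quadrats(pixel_series)
  fits <- lapply(setNames(config$families, config$families), function(fam) {
    fit <- fit_emergence_model(pooled, fam, n_starts = config$n_starts,
                               seed = child_seed(config$seed, 31))
    validate_against_counts(fit, count_series)
  })
  comparison <- compare_models(fits)
  report <- structure(list(
    method = config$method,
    observations = obs,
    pixel_series = pixel_series,
    count_series = count_series,
    fits = fits,
    comparison = comparison,
    best_family = comparison$family[1],
    seed = config$seed,
    # hash covers everything that influences the numbers; not output paths
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      c("out_dir", "write_images"))])
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    write_report(report, series, cls, config)
  }
  report
}

write_report <- function(report, series, cls, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stamp <- function(df) {
    df$config_hash <- report$config_hash
    df$seed <- config$seed
    df
  }
  write.csv(stamp(report$observations), out("observations.csv"), row.names = FALSE)
  write.csv(stamp(tibble::as_tibble(report$pixel_series)),
            out("pixel_series.csv"), row.names = FALSE)
  write.csv(stamp(tibble::as_tibble(report$count_series)),
            out("count_series.csv"), row.names = FALSE)
  for (fam in names(report$fits)) {
    write_fit_json(report$fits[[fam]], out(sprintf("fit_%s.json", fam)))
  }
  write.csv(stamp(tibble::as_tibble(report$comparison)),
            out("model_comparison.csv"), row.names = FALSE)
  if (config$method == "supervised_post") {
    comp_all <- purrr::imap(cls, function(cl, i) {
      if (is.null(cl$components) || !nrow(cl$components)) return(NULL)
      dplyr::mutate(dplyr::select(cl$components, -"pixels"),
                    quadrat_id = series$quadrat_id[i], day = series$day[i],
                    .before = 1)
    })
    comp_all <- dplyr::bind_rows(comp_all)
    write.csv(stamp(comp_all), out("components.csv"), row.names = FALSE)
  }
  if (isTRUE(config$write_images)) {
    for (i in seq_len(nrow(series))) {
      nm <- sprintf("%s_d%03d", series$quadrat_id[i],
                    as.integer(round(series$day[i])))
      write_image_png(series$image[[i]], out(paste0(nm, ".png")))
      if (!is.null(series$weed_mask)) {
        write_mask_png(series$weed_mask[[i]], out(paste0(nm, "_mask.png")))
      }
    }
    gt <- series[, intersect(c("quadrat_id", "day", "condition", "true_count",
                               "weed_pixel_area"), names(series))]
    write.csv(gt, out("ground_truth.csv"), row.names = FALSE)
  }
  summary <- list(
    method = report$method,
    seed = config$seed,
    config_hash = report$config_hash,
    best_family = report$best_family,
    models = lapply(report$fits, function(f) {
      as.list(glance(f)[1, ])
    })
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> method: %s, seed: %s\n", x$method, x$seed))
  cat(sprintf("  %d observations, best family by AIC: %s\n",
              nrow(x$observations), x$best_family))
  print(x$comparison)
  invisible(x)
}

#' Compare classification workflows against true counts
#'
#' Runs the image-analysis stage of the pipeline once per requested method on
#' the same simulated image series, then regresses each method's pixel-derived
#' relative cumulative values against the count-derived values across all
#' quadrat-days, tabulating RMSE (on the identity scale) and the regression
#' R-squared. This is the method-screening computation used to choose a
#' workflow before emergence modelling.
#'
#' @param config A [run_config()]; its scene/truth/seed define the shared
#'   image series.
#' @param methods Two or more of `"thresholding"`, `"supervised"`,
#'   `"supervised_post"`.
#' @param count_table Optional external true-count table (`quadrat_id`,
#'   `day`, `true_count`); defaults to the simulated ground truth. Its
#'   quadrat-day keys must match the image series.
#' @return A `method_comparison` tibble: `method`, `n`, `rmse`, `r_squared`.
#' @export
compare_methods <- function(config,
                            methods = c("thresholding", "supervised"),
                            count_table = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(methods) < 2) abort("Request at least 2 methods to compare.")
  series <- generate_series(config$scene, config$truth, config$n_quadrats,
                            seed = config$seed, conditions = config$conditions)
  if (is.null(count_table)) {
    count_table <- series[, c("quadrat_id", "day", "true_count")]
  } else {
    key <- function(d) paste(d$quadrat_id, d$day)
    missing <- setdiff(key(series), key(count_table))
    if (length(missing)) {
      abort(paste("Count table is missing quadrat-day keys:",
                  paste(missing, collapse = "; ")))
    }
  }
  count_series <- build_relative_cumulative(count_table, .data$true_count,
                                            source = "counts")
  counts <- merge_quadrats(count_series)
  refs <- NULL
  if (any(methods %in% c("supervised", "supervised_post"))) {
    refs <- train_references(config, unique(series$condition))
  }
  rows <- lapply(methods, function(m) {
    cfg <- config
    cfg$method <- m
    masks <- purrr::map(series$image, function(img) classify_one(img, cfg, refs)$mask)
    obs <- quadrat_observations(series, masks,
                                standard_size = config$standard_size)
    pix <- merge_quadrats(build_relative_cumulative(
      obs, .data$standardized_pixels, source = "pixels"))
    j <- dplyr::inner_join(dplyr::rename(pix, y_pix = "y"),
                           dplyr::rename(counts, y_cnt = "y"),
                           by = c("quadrat_id", "day"))
    sse <- sum((j$y_pix - j$y_cnt)^2)
    r2 <- if (stats::sd(j$y_pix) > 0 && stats::sd(j$y_cnt) > 0) {
      stats::cor(j$y_pix, j$y_cnt)^2
    } else {
      NA_real_
    }
    tibble::tibble(method = m, n = nrow(j), rmse = sqrt(sse / nrow(j)),
                   r_squared = r2)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("method_comparison", class(out))
  out
}
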