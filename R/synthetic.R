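#' Synthetic quadrat scene configuration
#'
#' Describes the scenes the generator renders: high-density single-species
#' seedling quadrats on a textured soil background with the distractor
#' features that confuse pixel classifiers in real photographs (sand patches,
#' rocks, sticks, and cast shadows on sunny days). Each class has a Gaussian
#' RGB color model; seedlings are drawn as paired ellipse cotyledons.
#'
#' @param width,height Image size in pixels (minimum 64). The default
#'   512 x 512 keeps test pipelines fast; the 18-megapixel field frame size
#'   (5184 x 3456) remains configurable.
#' @param palette Named list mapping class names (`weed`, `sand`, `soil`,
#'   `sticks`, `rocks`) to `list(mean = c(r, g, b), sd = scalar)` color models
#'   on the 0--255 scale. Defaults give well-separated classes with
#'   green-tinged rocks and warm sand, whose excess-green scores sit near a
#'   thresholding cutoff (the over-detection regime supervised classification
#'   fixes).
#' @param distractor_density Named expected counts per image for `sand`,
#'   `sticks`, `rocks` and (sunny only) `shadows` features; actual counts are
#'   Poisson draws.
#' @param seedling_area Length-2 numeric, minimum and maximum pixel area of a
#'   rendered seedling (both cotyledons together). Minimum must be at least 4.
#' @param cotyledon_eccentricity Ratio of minor to major ellipse axis for each
#'   cotyledon.
#' @param noise_sd Per-channel additive Gaussian noise applied to the finished
#'   scene.
#' @param condition `"cloudy"` or `"sunny"`. Sunny scenes add cast shadows and
#'   a sixth `shadows` class.
#' @param shadow_factor Multiplicative darkening inside shadow regions.
#' @param placement_attempts Rejection-sampling attempts used to place each
#'   seedling without overlap; when crowded, overlap is permitted (emulating
#'   leaf overlap at high densities).
#' @param min_weed_soil_distance Required Euclidean distance between the weed
#'   and soil color means; guards against degenerate configurations.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 512, height = 512,
                         palette = default_palette(),
                         distractor_density = c(sand = 6, sticks = 5,
                                                rocks = 8, shadows = 2),
                         seedling_area = c(600, 1400),
                         cotyledon_eccentricity = 0.55,
                         noise_sd = 3,
                         condition = c("cloudy", "sunny"),
                         shadow_factor = 0.55,
                         placement_attempts = 40,
                         min_weed_soil_distance = 40) {
  condition <- match.arg(condition)
  if (width < 64 || height < 64) abort("Scene must be at least 64 x 64.")
  needed <- c("weed", "sand", "soil", "sticks", "rocks")
  if (!all(needed %in% names(palette))) {
    abort(paste("Palette must define classes:", paste(needed, collapse = ", ")))
  }
  for (nm in names(palette)) {
    m <- palette[[nm]]$mean
    if (length(m) != 3 || any(m < 0 | m > 255)) {
      abort(sprintf("Palette mean for '%s' must be an RGB triple in [0, 255].", nm))
    }
  }
  if (length(seedling_area) != 2 || seedling_area[1] < 4 ||
      seedling_area[1] > seedling_area[2]) {
    abort("`seedling_area` must be c(min, max) with min >= 4.")
  }
  sep <- sqrt(sum((palette$weed$mean - palette$soil$mean)^2))
  if (sep <= min_weed_soil_distance) {
    abort(sprintf(
      "Weed and soil color means are %.1f apart; must exceed %.1f.",
      sep, min_weed_soil_distance))
  }
  structure(list(width = width, height = height, palette = palette,
                 distractor_density = distractor_density,
                 seedling_area = seedling_area,
                 cotyledon_eccentricity = cotyledon_eccentricity,
                 noise_sd = noise_sd, condition = condition,
                 shadow_factor = shadow_factor,
                 placement_attempts = placement_attempts,
                 min_weed_soil_distance = min_weed_soil_distance),
            class = "scene_config")
}

#' @rdname scene_config
#' @export
default_palette <- function() {
  list(
    weed   = list(mean = c(60, 140, 50),   sd = 8),
    sand   = list(mean = c(194, 178, 128), sd = 10),
    soil   = list(mean = c(120, 85, 60),   sd = 10),
    sticks = list(mean = c(90, 70, 48),    sd = 8),
    rocks  = list(mean = c(105, 125, 100), sd = 8)
  )
}

#' Class labels present under a light condition
#'
#' Cloudy scenes carry five classes; sunny scenes add `shadows` as a sixth.
#'
#' @param condition `"cloudy"` or `"sunny"`.
#' @return Character vector of labels in canonical order.
#' @export
condition_labels <- function(condition = c("cloudy", "sunny")) {
  condition <- match.arg(condition)
  base <- c("weed", "sand", "soil", "sticks", "rocks")
  if (condition == "sunny") c(base, "shadows") else base
}

#' Known emergence truth for a synthetic season
#'
#' Defines the underlying relative cumulative emergence curve, the season
#' total seedling count, and the imaging schedule from which per-date new
#' seedling counts are sampled.
#'
#' @param family Curve family: `"logistic"`, `"gompertz"`, `"weibull"` or
#'   `"biphasic"`.
#' @param params Named list/vector of that family's parameters (see
#'   [emergence_curve()]).
#' @param total_seedlings Season total number of seedlings (>= 0).
#' @param image_days Strictly increasing numeric vector of imaging days.
#' @return An `emergence_truth` list.
#' @export
emergence_truth <- function(family, params, total_seedlings, image_days) {
  family <- match.arg(family, c("logistic", "gompertz", "weibull", "biphasic"))
  if (total_seedlings < 0) abort("`total_seedlings` must be >= 0.")
  if (length(image_days) < 1 || any(diff(image_days) <= 0)) {
    abort("`image_days` must be strictly increasing.")
  }
  # check the curve is evaluable and non-decreasing over the schedule
  y <- emergence_curve(image_days, family, params)
  if (any(!is.finite(y))) abort("Curve not evaluable at all image days.")
  if (any(diff(c(0, y)) < -1e-9)) {
    abort("Curve decreases between image days; not a valid emergence curve.")
  }
  structure(list(family = family, params = as.list(params),
                 total_seedlings = as.integer(total_seedlings),
                 image_days = as.numeric(image_days)),
            class = "emergence_truth")
}

#' Sample a per-date emergence schedule from a truth curve
#'
#' Inverts a cumulative emergence curve into counts of newly emerged
#' seedlings at each imaging date: the curve's increments between consecutive
#' dates (the first measured from zero) are normalized into multinomial cell
#' probabilities and `total_seedlings` seedlings are allocated among dates.
#'
#' @param truth An [emergence_truth()].
#' @param seed Integer seed; fixed seeds give identical schedules.
#' @return Integer vector of new seedlings per image day, summing to the
#'   season total.
#' @export
sample_emergence_schedule <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "emergence_truth"))
  y <- emergence_curve(truth$image_days, truth$family, truth$params)
  inc <- diff(c(0, y))
  if (any(inc < -1e-9)) abort("Curve decreases between image days.")
  inc <- pmax(inc, 0)
  n_days <- length(truth$image_days)
  if (truth$total_seedlings == 0L) return(integer(n_days))
  if (sum(inc) <= 0) abort("Curve has no mass over the imaging schedule.")
  p <- inc / sum(inc)
  with_seed(seed, as.integer(rmultinom(1, truth$total_seedlings, p)))
}

# pixel set of a filled rotated ellipse, clipped to the image
ellipse_pixels <- function(h, w, cx, cy, a, b, theta) {
  r_ext <- max(a, b)
  rows <- max(1L, floor(cy - r_ext)):min(h, ceiling(cy + r_ext))
  cols <- max(1L, floor(cx - r_ext)):min(w, ceiling(cx + r_ext))
  if (!length(rows) || !length(cols)) return(cbind(row = integer(), col = integer()))
  gr <- rep(rows, times = length(cols))
  gc <- rep(cols, each = length(rows))
  dx <- gc - cx
  dy <- gr - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = gr[keep], col = gc[keep])
}

# stamp class-colored pixels (mean + per-pixel Gaussian spread) onto channels
stamp_pixels <- function(channels, px, mean, sd) {
  if (nrow(px) == 0) return(channels)
  idx <- cbind(px[, "row"], px[, "col"])
  for (ch in 1:3) {
    channels[[ch]][idx] <- mean[ch] + rnorm(nrow(px), 0, sd)
  }
  channels
}

#' Render one synthetic quadrat image
#'
#' Draws a soil background, distractor features, optional shadows (sunny
#' condition), and exactly `n_new_seedlings` seedlings (paired ellipse
#' cotyledons in the weed color model), returning the image together with the
#' ground-truth weed mask and a full class truth raster.
#'
#' @param config A [scene_config()].
#' @param n_new_seedlings Number of seedlings to render (>= 0).
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @param condition Optional override of the config's light condition.
#' @return A list with elements `image` ([rgb_image()]), `weed_mask` (logical
#'   matrix marking exactly the seedling pixels), `truth_raster`
#'   ([label_raster()] of the drawn class at every pixel) and `n_rendered`.
#' @export
render_quadrat_image <- function(config, n_new_seedlings, seed = 1,
                                 condition = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (n_new_seedlings < 0) abort("`n_new_seedlings` must be >= 0.")
  condition <- condition %||% config$condition
  condition <- match.arg(condition, c("cloudy", "sunny"))
  h <- config$height; w <- config$width
  pal <- config$palette
  # feasibility: one seedling must fit well inside the frame
  max_axis <- sqrt(config$seedling_area[2] /
                     (2 * pi * config$cotyledon_eccentricity)) * 2
  if (max_axis * 2 > min(h, w)) {
    abort("Seedling area range is infeasible for the image size.")
  }
  labels <- condition_labels(condition)

  with_seed(seed, {
    channels <- lapply(1:3, function(ch) {
      matrix(pal$soil$mean[ch] + rnorm(h * w, 0, pal$soil$sd), h, w)
    })
    truth <- matrix(match("soil", labels), h, w)

    draw_blobs <- function(class, n, ax_range, ecc_range) {
      for (i in seq_len(n)) {
        a <- runif(1, ax_range[1], ax_range[2])
        b <- a * runif(1, ecc_range[1], ecc_range[2])
        px <- ellipse_pixels(h, w, runif(1, 1, w), runif(1, 1, h), a, b,
                             runif(1, 0, pi))
        channels <<- stamp_pixels(channels, px, pal[[class]]$mean,
                                  pal[[class]]$sd)
        if (nrow(px)) truth[cbind(px[, 1], px[, 2])] <<- match(class, labels)
      }
    }
    dens <- config$distractor_density
    draw_blobs("sand",   rpois(1, dens[["sand"]]),   c(10, 28), c(0.5, 0.9))
    draw_blobs("rocks",  rpois(1, dens[["rocks"]]),  c(4, 10),  c(0.6, 1.0))
    draw_blobs("sticks", rpois(1, dens[["sticks"]]), c(15, 40), c(0.05, 0.12))

    if (condition == "sunny") {
      n_sh <- max(1L, rpois(1, dens[["shadows"]]))
      for (i in seq_len(n_sh)) {
        a <- runif(1, 0.15, 0.35) * min(h, w)
        px <- ellipse_pixels(h, w, runif(1, 1, w), runif(1, 1, h), a,
                             a * runif(1, 0.5, 0.9), runif(1, 0, pi))
        if (nrow(px)) {
          idx <- cbind(px[, 1], px[, 2])
          for (ch in 1:3) channels[[ch]][idx] <- channels[[ch]][idx] * config$shadow_factor
          truth[idx] <- match("shadows", labels)
        }
      }
    }

    # seedlings: two touching ellipse cotyledons along a random axis
    weed_mask <- matrix(FALSE, h, w)
    ecc <- config$cotyledon_eccentricity
    placed <- matrix(numeric(0), ncol = 3)  # cx, cy, radius
    margin <- max_axis
    for (s in seq_len(n_new_seedlings)) {
      area <- runif(1, config$seedling_area[1] + 0.1 * diff(config$seedling_area),
                    config$seedling_area[2] - 0.1 * diff(config$seedling_area))
      a_e <- sqrt(area / (2 * pi * ecc))
      b_e <- a_e * ecc
      rad <- 2 * a_e
      cx <- cy <- NA_real_
      for (try in seq_len(config$placement_attempts)) {
        cx <- runif(1, margin, w - margin)
        cy <- runif(1, margin, h - margin)
        if (nrow(placed) == 0) break
        d <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        if (all(d > placed[, 3] + rad)) break
      }
      placed <- rbind(placed, c(cx, cy, rad))
      theta <- runif(1, 0, pi)
      for (sgn in c(-1, 1)) {
        px <- ellipse_pixels(h, w, cx + sgn * a_e * cos(theta),
                             cy + sgn * a_e * sin(theta), a_e, b_e, theta)
        channels <- stamp_pixels(channels, px, pal$weed$mean, pal$weed$sd)
        if (nrow(px)) {
          idx <- cbind(px[, 1], px[, 2])
          weed_mask[idx] <- TRUE
          truth[idx] <- match("weed", labels)
        }
      }
    }

    if (config$noise_sd > 0) {
      for (ch in 1:3) channels[[ch]] <- channels[[ch]] + rnorm(h * w, 0, config$noise_sd)
    }
    # quantize to whole intensities, as a camera would; keeps PNG I/O lossless
    arr <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) arr[, , ch] <- round(pmin(pmax(channels[[ch]], 0), 255))

    list(image = rgb_image(arr, condition = condition),
         weed_mask = weed_mask,
         truth_raster = label_raster(truth, labels),
         n_rendered = as.integer(n_new_seedlings))
  })
}

#' Generate a full synthetic quadrat image series
#'
#' Emulates the field protocol: at each imaging date seedlings that have newly
#' emerged since the previous visit are photographed, counted and removed, so
#' each date's image contains only that date's new seedlings. The season total
#' is divided evenly among quadrats and each quadrat receives its own sampled
#' schedule.
#'
#' @param scene A [scene_config()].
#' @param truth An [emergence_truth()].
#' @param n_quadrats Number of quadrats (>= 1).
#' @param seed Master seed; per-quadrat and per-image seeds are derived from
#'   it reproducibly.
#' @param conditions Optional character vector (length 1 or one per image day)
#'   of light conditions; defaults to the scene's condition for every day.
#' @return A tibble with one row per quadrat per day: `quadrat_id`, `day`,
#'   `condition`, `true_count`, `weed_pixel_area`, and list-columns `image`,
#'   `weed_mask`, `truth_raster`.
#' @export
generate_series <- function(scene, truth, n_quadrats = 6, seed = 1,
                            conditions = NULL) {
  stopifnot(inherits(scene, "scene_config"), inherits(truth, "emergence_truth"))
  if (n_quadrats < 1) abort("`n_quadrats` must be >= 1.")
  days <- truth$image_days
  conditions <- conditions %||% scene$condition
  if (length(conditions) == 1) conditions <- rep(conditions, length(days))
  if (length(conditions) != length(days)) {
    abort("`conditions` must have one entry per image day.")
  }
  # even split of the season total, remainder to the first quadrats
  base <- truth$total_seedlings %/% n_quadrats
  extra <- truth$total_seedlings %% n_quadrats
  share <- rep(base, n_quadrats) + c(rep(1L, extra), rep(0L, n_quadrats - extra))

  rows <- list()
  for (q in seq_len(n_quadrats)) {
    q_truth <- truth
    q_truth$total_seedlings <- share[q]
    schedule <- sample_emergence_schedule(q_truth, seed = child_seed(seed, q))
    for (i in seq_along(days)) {
      res <- render_quadrat_image(scene, schedule[i],
                                  seed = child_seed(seed, q * 100000 + i),
                                  condition = conditions[i])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        quadrat_id = sprintf("Q%02d", q),
        day = days[i],
        condition = conditions[i],
        true_count = schedule[i],
        weed_pixel_area = sum(res$weed_mask),
        image = list(res$image),
        weed_mask = list(res$weed_mask),
        truth_raster = list(res$truth_raster)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truth
  attr(out, "scene") <- scene
  attr(out, "seed") <- seed
  out
}

#' Class masks from a truth raster
#'
#' @param truth_raster A [label_raster()] of ground-truth classes.
#' @return Named list of disjoint logical matrices, one per label present in
#'   the raster's label set.
#' @export
masks_from_truth <- function(truth_raster) {
  labels <- raster_labels(truth_raster)
  setNames(lapply(seq_along(labels), function(i) {
    m <- unclass(truth_raster) == i
    attr(m, "labels") <- NULL
    matrix(m, nrow(truth_raster))
  }), labels)
}

#' Draw labeled training samples from ground-truth regions
#'
#' Emulates an analyst highlighting small training regions of one image per
#' class to build a reference file: for each class a fixed number of sample
#' groups are drawn without replacement from that class's true pixels, each
#' group being the 3 x 3 window around a sampled pixel intersected with the
#' class region.
#'
#' @param image An [rgb_image()].
#' @param masks Named list of disjoint logical class masks (e.g.
#'   [masks_from_truth()]).
#' @param n_samples_per_label Sample groups per class (default 20, the field
#'   protocol's count).
#' @param seed Integer seed.
#' @return A tibble of pixel samples: `label`, `sample`, `row`, `col`, `r`,
#'   `g`, `b`.
#' @export
generate_training_samples <- function(image, masks, n_samples_per_label = 20,
                                      seed = 1) {
  stopifnot(is.list(masks), !is.null(names(masks)))
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1L)) abort("Class masks must be disjoint.")
  arr <- unclass(image)
  with_seed(seed, {
    out <- purrr::map(names(masks), function(lbl) {
      cand <- which(masks[[lbl]], arr.ind = TRUE)
      if (nrow(cand) < n_samples_per_label) {
        abort(sprintf(
          "Class '%s' has only %d candidate pixels; %d sample groups needed.",
          lbl, nrow(cand), n_samples_per_label))
      }
      seeds <- cand[sample.int(nrow(cand), n_samples_per_label), , drop = FALSE]
      purrr::map(seq_len(n_samples_per_label), function(s) {
        r0 <- seeds[s, 1]; c0 <- seeds[s, 2]
        rows <- pmax(1L, r0 - 1L):pmin(nrow(masks[[lbl]]), r0 + 1L)
        cols <- pmax(1L, c0 - 1L):pmin(ncol(masks[[lbl]]), c0 + 1L)
        win <- expand.grid(row = rows, col = cols)
        win <- win[masks[[lbl]][cbind(win$row, win$col)], , drop = FALSE]
        tibble::tibble(label = lbl, sample = s,
                       row = win$row, col = win$col,
                       r = arr[cbind(win$row, win$col, 1)],
                       g = arr[cbind(win$row, win$col, 2)],
                       b = arr[cbind(win$row, win$col, 3)])
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    out
  })
}
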