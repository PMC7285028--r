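#' Standardize weed pixel counts to a fixed image size
#'
#' Classified image areas vary between photographs, so weed pixel counts are
#' converted to the proportion of classified pixels and re-expressed for a
#' standard-size frame of 12,500,000 pixels (roughly the average classified
#' area of an 18 MP quadrat photograph).
#'
#' @param weed_pixels Count of pixels classified as the weed (vectorized).
#' @param total_pixels Total classified pixels in the image (>= 1).
#' @param standard_size Standard frame size (default 12,500,000).
#' @return `weed_pixels / total_pixels * standard_size`.
#' @export
standardize_pixels <- function(weed_pixels, total_pixels,
                               standard_size = 12500000) {
  if (any(total_pixels < 1)) abort("`total_pixels` must be >= 1.")
  if (any(weed_pixels < 0 | weed_pixels > total_pixels)) {
    abort("Need 0 <= weed_pixels <= total_pixels.")
  }
  weed_pixels / total_pixels * standard_size
}

#' Relative cumulative emergence series
#'
#' Converts per-date values (standardized weed pixels, or true seedling
#' counts) into a running cumulative sum divided by the season total, one
#' series per quadrat. The resulting `[0, 1]` curve is the quantity emergence
#' models are fitted to, and is invariant to rescaling a quadrat's values by
#' any positive constant — the property that lets pixel areas stand in for
#' seedling counts. Quadrats whose season total is zero yield an all-zero
#' series flagged `degenerate`.
#'
#' @param data Tibble with columns `quadrat_id`, `day` and the value column.
#' @param value Column to accumulate (tidy-eval), e.g. `standardized_pixels`
#'   or `true_count`.
#' @param source `"pixels"` or `"counts"`; recorded on the result.
#' @return An `emergence_series` tibble: `quadrat_id`, `day`, `value`,
#'   `rel_cum`, `degenerate`, with a `source` attribute.
#' @export
build_relative_cumulative <- function(data, value, source = c("pixels", "counts")) {
  source <- match.arg(source)
  val <- dplyr::pull(dplyr::transmute(data, v = {{ value }}), "v")
  if (any(val < 0)) abort("Values must be >= 0.")
  out <- data |>
    dplyr::transmute(quadrat_id = .data$quadrat_id, day = .data$day, value = val) |>
    dplyr::group_by(.data$quadrat_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      if (any(diff(d$day) <= 0)) abort("Days must be strictly increasing within a quadrat.")
      tot <- sum(d$value)
      if (tot == 0) {
        d$rel_cum <- 0
        d$degenerate <- TRUE
      } else {
        d$rel_cum <- cumsum(d$value) / tot
        d$degenerate <- FALSE
      }
      d
    }) |>
    dplyr::ungroup()
  structure(out, source = source,
            class = c("emergence_series", class(out)))
}

#' @rdname build_relative_cumulative
#' @param series An `emergence_series`.
#' @export
series_source <- function(series) attr(series, "source")

#' Pool quadrat series for model fitting
#'
#' Stacks per-quadrat relative cumulative series into one long observation
#' table; each quadrat contributes its own points, no averaging. Degenerate
#' (all-zero) quadrats are dropped with a warning. All series must share a
#' source type (pixels cannot be pooled with counts).
#'
#' @param series An `emergence_series` or list of them.
#' @return Tibble with columns `quadrat_id`, `day`, `y`, carrying the shared
#'   `source` attribute.
#' @export
merge_quadrats <- function(series) {
  if (inherits(series, "emergence_series")) series <- list(series)
  sources <- unique(vapply(series, series_source, character(1)))
  if (length(sources) != 1) {
    abort(paste("Cannot pool series with mixed sources:",
                paste(sources, collapse = ", ")))
  }
  pooled <- dplyr::bind_rows(lapply(series, function(s) {
    tibble::as_tibble(s)[, c("quadrat_id", "day", "rel_cum", "degenerate")]
  }))
  if (any(pooled$degenerate)) {
    bad <- unique(pooled$quadrat_id[pooled$degenerate])
    warn(paste("Dropping degenerate all-zero quadrats:",
               paste(bad, collapse = ", ")))
    pooled <- pooled[!pooled$degenerate, ]
  }
  out <- dplyr::transmute(pooled, quadrat_id = .data$quadrat_id,
                          day = .data$day, y = .data$rel_cum)
  attr(out, "source") <- sources
  out
}

#' Per-image weed pixel observations from classified images
#'
#' Convenience assembler: given a synthetic series tibble and per-image weed
#' masks produced by a classification method, builds the observation table
#' (weed pixels, total pixels, standardized pixels, true counts).
#'
#' @param series Tibble from [generate_series()].
#' @param masks List of logical weed masks, one per row of `series`.
#' @param standard_size Standard frame size for [standardize_pixels()].
#' @return Tibble of quadrat observations.
#' @export
quadrat_observations <- function(series, masks, standard_size = 12500000) {
  stopifnot(length(masks) == nrow(series))
  tibble::tibble(
    quadrat_id = series$quadrat_id,
    day = series$day,
    weed_pixels = vapply(masks, sum, numeric(1)),
    total_pixels = vapply(masks, length, numeric(1)),
    true_count = series$true_count
  ) |>
    dplyr::mutate(standardized_pixels = standardize_pixels(
      .data$weed_pixels, .data$total_pixels, standard_size))
}
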