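# offsets (drow, dcol) of the disc of Euclidean radius r around the origin
disc_offsets <- function(radius) {
  d <- -floor(radius):floor(radius)
  g <- expand.grid(dr = d, dc = d)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Circular-neighborhood majority filter
#'
#' Post-classification cleanup: every pixel is re-labeled to the most
#' frequent class within the circular neighborhood of the given radius
#' (pixels at Euclidean distance `<= radius`; neighborhoods are truncated at
#' image borders, no padding). When the maximal count is shared by more than
#' one label the pixel keeps its original label. A 15-pixel radius removes
#' isolated misclassified pixels while preserving seedling-scale regions.
#'
#' @param raster A [label_raster()].
#' @param radius Neighborhood radius in pixels (>= 1, default 15).
#' @param passes Number of filter passes (default 1).
#' @return The filtered [label_raster()].
#' @export
majority_filter <- function(raster, radius = 15, passes = 1) {
  stopifnot(inherits(raster, "label_raster"))
  if (radius < 1) abort("`radius` must be >= 1.")
  labels <- raster_labels(raster)
  n_lab <- length(labels)
  # disc kernel as an odd-sized matrix for linear filtering
  side <- 2L * floor(radius) + 1L
  ctr <- floor(radius) + 1L
  kern <- matrix(0, side, side)
  off <- disc_offsets(radius)
  kern[cbind(off$dr + ctr, off$dc + ctr)] <- 1
  cur <- matrix(unclass(raster), nrow(raster))
  for (p in seq_len(passes)) {
    h <- nrow(cur); w <- ncol(cur)
    # zero-pad when the kernel exceeds the image so truncation still holds
    pad <- c(max(0L, side - h), max(0L, side - w))
    counts <- array(0L, dim = c(h, w, n_lab))
    for (j in seq_len(n_lab)) {
      ind <- matrix(0, h + 2 * pad[1], w + 2 * pad[2])
      ind[pad[1] + seq_len(h), pad[2] + seq_len(w)] <- as.numeric(cur == j)
      full <- round(EBImage::filter2(ind, kern, boundary = 0))
      counts[, , j] <- as.integer(full[pad[1] + seq_len(h), pad[2] + seq_len(w)])
    }
    maxc <- counts[, , 1]
    for (j in seq_len(n_lab)[-1]) maxc <- pmax(maxc, counts[, , j])
    argmax <- matrix(0L, nrow(cur), ncol(cur))
    n_at_max <- matrix(0L, nrow(cur), ncol(cur))
    for (j in rev(seq_len(n_lab))) {
      hit <- counts[, , j] == maxc
      argmax[hit] <- j            # descending loop leaves the lowest index
      n_at_max <- n_at_max + hit
    }
    cur <- matrix(as.integer(ifelse(n_at_max > 1L, cur, argmax)), nrow(cur))
  }
  label_raster(cur, labels)
}

#' Connected components of one class ("polygons")
#'
#' Converts the pixels of a target class into connected components, the
#' raster analogue of polygonizing a classified map. 8-connectivity by
#' default (diagonal neighbors touch), configurable to 4.
#'
#' @param raster A [label_raster()] or a logical mask.
#' @param target_label Class to extract (ignored for logical masks).
#' @param connectivity 8 (default) or 4.
#' @return A tibble with one row per component: `component_id`, `area`,
#'   `min_row`, `max_row`, `min_col`, `max_col`, and a list-column `pixels`
#'   of (row, col) matrices.
#' @export
extract_components <- function(raster, target_label = "weed", connectivity = 8) {
  if (inherits(raster, "label_raster")) {
    mask <- raster_to_mask(raster, target_label)
  } else {
    mask <- raster
  }
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  lab <- label_components(mask, connectivity)
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(tibble::tibble(component_id = integer(), area = integer(),
                          min_row = integer(), max_row = integer(),
                          min_col = integer(), max_col = integer(),
                          pixels = list()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[idx]
  purrr::map(seq_len(n_comp), function(k) {
    px <- idx[comp == k, , drop = FALSE]
    tibble::tibble(component_id = k, area = nrow(px),
                   min_row = min(px[, 1]), max_row = max(px[, 1]),
                   min_col = min(px[, 2]), max_col = max(px[, 2]),
                   pixels = list(unname(px)))
  }) |> dplyr::bind_rows()
}

# connected-component labeling; EBImage::bwlabel provides 4-connectivity,
# 8-connectivity is obtained by merging diagonally adjacent 4-components
label_components <- function(mask, connectivity = 8) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab4 <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(mask),
                                                    nrow(mask)))),
                 nrow(mask))
  if (connectivity == 8) {
    n4 <- max(lab4)
    # union-find over 4-component ids linked by a diagonal touch
    parent <- seq_len(n4)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    h <- nrow(lab4); w <- ncol(lab4)
    a1 <- lab4[-h, -w]; b1 <- lab4[-1, -1]   # down-right diagonal
    a2 <- lab4[-1, -w]; b2 <- lab4[-h, -1]   # up-right diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                            pairs[, 1] != pairs[, 2], , drop = FALSE])
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
    roots <- vapply(seq_len(n4), find, integer(1))
    relabel <- match(roots, unique(roots))
    out <- lab4
    out[lab4 > 0] <- relabel[lab4[lab4 > 0]]
    return(out)
  }
  lab4
}

#' Filter components by area and rebuild a mask
#'
#' Retains only components whose pixel area lies within plausible seedling
#' bounds, eliminating both isolated-pixel noise and shapes too large to be a
#' single seedling.
#'
#' @param components Component tibble from [extract_components()].
#' @param min_area,max_area Inclusive area bounds in pixels (defaults 50 and
#'   20000 at the 512 x 512 synthetic scale).
#' @param dim Image dimensions `c(height, width)` for the output mask.
#' @return A logical mask containing exactly the pixels of retained
#'   components, with a `components` attribute: the input tibble plus a
#'   `retained` flag.
#' @export
area_filter <- function(components, min_area = 50, max_area = 20000, dim) {
  if (min_area > max_area || min_area < 0) {
    abort("Need 0 <= min_area <= max_area.")
  }
  mask <- matrix(FALSE, dim[1], dim[2])
  retained <- components$area >= min_area & components$area <= max_area
  for (k in which(retained)) {
    mask[components$pixels[[k]]] <- TRUE
  }
  attr(mask, "components") <- dplyr::mutate(components, retained = retained)
  mask
}

#' Write a component table to CSV
#'
#' @param mask Output of [area_filter()] (carries the component table).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(mask, path) {
  comp <- attr(mask, "components")
  if (is.null(comp)) abort("Mask carries no component table.")
  write.csv(dplyr::select(comp, -"pixels"), path, row.names = FALSE)
  invisible(path)
}
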