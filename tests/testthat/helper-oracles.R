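# Independent brute-force oracles and small fixtures used across tests.
# These deliberately avoid the package's computational paths: the classifier
# oracle evaluates the Gaussian discriminant pixel by pixel, the majority
# oracle enumerates disc offsets, and the component oracle is a stack-based
# flood fill.

# small, fast scene for pipeline-level tests
tiny_scene <- function(...) {
  scene_config(width = 128, height = 128, seedling_area = c(60, 140),
               distractor_density = c(sand = 2, sticks = 2, rocks = 3,
                                      shadows = 1), ...)
}

tiny_truth <- function(total = 80, days = seq(0, 100, by = 20)) {
  emergence_truth("gompertz", list(a = 1, x0 = 40, b = 12),
                  total_seedlings = total, image_days = days)
}

random_image <- function(h = 16, w = 16) {
  rgb_image(array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)))
}

# random positive-definite class statistics
random_stats <- function(n_classes) {
  labels <- paste0("c", seq_len(n_classes))
  means <- matrix(runif(n_classes * 3, 0, 255), n_classes, 3,
                  dimnames = list(labels, c("r", "g", "b")))
  covs <- lapply(labels, function(l) {
    m <- matrix(rnorm(9, 0, 8), 3)
    m %*% t(m) + diag(5, 3)
  })
  names(covs) <- labels
  structure(list(labels = labels, means = means, covs = covs,
                 priors = setNames(rep(1 / n_classes, n_classes), labels),
                 ridge = 0, condition = "cloudy"),
            class = "class_stats")
}

# per-pixel, per-class evaluation of log prior + Gaussian log density
oracle_ml <- function(image, stats) {
  arr <- unclass(image)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  out <- matrix(NA_integer_, h, w)
  inv <- lapply(stats$covs, solve)
  ldet <- lapply(stats$covs, function(s) determinant(s, logarithm = TRUE)$modulus)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      px <- arr[i, j, ]
      sc <- vapply(seq_along(stats$labels), function(k) {
        lbl <- stats$labels[k]
        d <- px - stats$means[lbl, ]
        log(stats$priors[[lbl]]) - 0.5 * as.numeric(ldet[[lbl]]) -
          0.5 * as.numeric(t(d) %*% inv[[lbl]] %*% d)
      }, numeric(1))
      out[i, j] <- which.max(sc)  # which.max = first max = lowest index
    }
  }
  out
}

# plurality vote over the disc of Euclidean radius r, truncated at borders;
# ties (max count shared by >1 label) keep the center's label
oracle_majority <- function(raster, radius) {
  m <- matrix(unclass(raster), nrow(raster))
  n_lab <- length(raster_labels(raster))
  h <- nrow(m); w <- ncol(m)
  d <- -floor(radius):floor(radius)
  off <- expand.grid(dr = d, dc = d)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  out <- m
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      rr <- i + off$dr; cc <- j + off$dc
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      votes <- tabulate(m[cbind(rr[ok], cc[ok])], nbins = n_lab)
      mx <- max(votes)
      winners <- which(votes == mx)
      out[i, j] <- if (length(winners) > 1) m[i, j] else winners
    }
  }
  out
}

# stack-based flood fill; returns number of connected components
oracle_component_count <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  } else {
    nb <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  count <- 0L
  for (start in which(mask)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      cell <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (cell - 1L) %% h + 1L
      cc <- (cell - 1L) %/% h + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- r + nb$dr[k]; c2 <- cc + nb$dc[k]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          cell2 <- (c2 - 1L) * h + r2
          if (mask[cell2] && !seen[cell2]) {
            seen[cell2] <- TRUE
            stack <- c(stack, cell2)
          }
        }
      }
    }
  }
  count
}

random_label_raster <- function(h, w, n_lab) {
  label_raster(matrix(sample.int(n_lab, h * w, replace = TRUE), h, w),
               paste0("L", seq_len(n_lab)))
}
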