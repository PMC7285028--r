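test_that("contrast stretch maps channel extremes to [0, 255] and is idempotent", {
  arr <- array(0, dim = c(2, 2, 3))
  arr[, , 1] <- c(100, 120, 130, 150)  # spans [100, 150]
  arr[, , 2] <- 77                      # constant channel
  arr[, , 3] <- c(0, 255, 10, 20)
  img <- rgb_image(arr)
  out <- unclass(contrast_stretch(img))
  expect_equal(range(out[, , 1]), c(0, 255))
  expect_equal(out[, , 2], arr[, , 2])  # constant channel untouched

  set.seed(1)
  for (i in 1:5) {
    img <- random_image(8, 8)
    once <- contrast_stretch(img)
    expect_equal(unclass(contrast_stretch(once)), unclass(once))
  }
})

test_that("excess-green thresholding follows the greenness score exactly", {
  arr <- array(0, dim = c(1, 2, 3))
  arr[1, 1, ] <- c(0, 255, 0)   # pure green
  arr[1, 2, ] <- c(80, 80, 80)  # gray
  img <- rgb_image(arr)
  mask <- threshold_classify(img, threshold = 30)
  expect_true(mask[1, 1])
  expect_false(mask[1, 2])

  set.seed(2)
  img <- random_image(12, 12)
  for (thr in c(-50, 0, 30, 200)) {
    mask <- threshold_classify(img, thr)
    arr <- unclass(img)
    oracle <- matrix(FALSE, 12, 12)
    for (i in 1:12) for (j in 1:12) {
      oracle[i, j] <- (2 * arr[i, j, 2] - arr[i, j, 1] - arr[i, j, 3]) > thr
    }
    expect_identical(mask, oracle)
  }
})

test_that("class statistics are the sample moments with ridge regularization", {
  tr <- tibble::tibble(label = rep(c("a", "b"), each = 2),
                       r = c(5, 5, 0, 2), g = c(5, 5, 0, 2),
                       b = c(5, 5, 0, 2))
  st <- fit_class_stats(tr, ridge = 1e-3)
  # identical pixels: covariance collapses to ridge * identity
  expect_equal(unname(st$covs$a), diag(1e-3, 3))
  # hand-computed sample covariance of (0,0,0),(2,2,2): every entry 2
  st0 <- fit_class_stats(tr[3:4, ], ridge = 0)
  expect_equal(unname(st0$covs$b), matrix(2, 3, 3))
  # the singular ridge-free covariance is only refused when classifying
  st2 <- fit_class_stats(tr, ridge = 0)
  expect_error(ml_classify(random_image(2, 2), st2), "not invertible")
  # uniform priors by default
  tr5 <- tibble::tibble(label = rep(letters[1:5], each = 2),
                        r = rnorm(10, 100), g = rnorm(10, 100), b = rnorm(10, 100))
  expect_equal(unname(fit_class_stats(tr5)$priors), rep(0.2, 5))
  # a label with < 2 pixels is refused
  expect_error(fit_class_stats(tr[c(1, 3, 4), ]), "fewer than 2")
})

test_that("maximum-likelihood classification maximizes the discriminant", {
  set.seed(3)
  st <- random_stats(3)
  # pixel at a class mean with shared covariance and equal priors -> that class
  shared <- st
  shared$covs <- lapply(shared$covs, function(x) diag(10, 3))
  arr <- array(0, dim = c(1, 3, 3))
  for (k in 1:3) arr[1, k, ] <- shared$means[k, ]
  got <- ml_classify(rgb_image(pmin(pmax(arr, 0), 255)), shared)
  expect_equal(as.integer(got), 1:3)
  # two identical classes: tie broken to the lower index
  twin <- shared
  twin$means[2, ] <- twin$means[1, ]
  got <- ml_classify(rgb_image(pmin(pmax(arr, 0), 255)), twin)
  expect_equal(got[1, 1], 1L)
})

test_that("classification agrees exactly with the per-pixel oracle", {
  set.seed(4)
  for (rep in 1:8) {
    st <- random_stats(sample(3:6, 1))
    img <- random_image(16, 16)
    expect_identical(matrix(as.integer(ml_classify(img, st)), 16),
                     oracle_ml(img, st))
  }
})

test_that("uniform priors contribute nothing to assignments", {
  set.seed(5)
  st <- random_stats(4)
  img <- random_image(10, 10)
  no_prior <- st
  no_prior$priors <- setNames(rep(1, 4), st$labels)  # unnormalized constant
  no_prior$priors <- no_prior$priors / sum(no_prior$priors)
  expect_identical(as.integer(ml_classify(img, st)),
                   as.integer(ml_classify(img, no_prior)))
})

test_that("well-separated noise-free scenes classify almost perfectly", {
  sc <- tiny_scene(noise_sd = 0.5)
  res <- render_quadrat_image(sc, 5, seed = 21)
  masks <- masks_from_truth(res$truth_raster)
  keep <- names(masks)[vapply(masks, sum, numeric(1)) >= 20]
  tr <- generate_training_samples(res$image, masks[keep], 20, seed = 2)
  st <- fit_class_stats(tr)
  got <- ml_classify(res$image, st)
  truth_lbl <- raster_labels(res$truth_raster)[unclass(res$truth_raster)]
  got_lbl <- raster_labels(got)[unclass(got)]
  acc <- mean(got_lbl == truth_lbl)
  expect_gt(acc, 0.98)
})

test_that("thresholding never beats supervised classification on weed F1", {
  sc <- tiny_scene()
  res <- render_quadrat_image(sc, 6, seed = 31)
  masks <- masks_from_truth(res$truth_raster)
  keep <- names(masks)[vapply(masks, sum, numeric(1)) >= 20]
  tr <- generate_training_samples(res$image, masks[keep], 20, seed = 3)
  st <- fit_class_stats(tr)
  f1 <- function(pred, truth) {
    tp <- sum(pred & truth)
    2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
  }
  ml <- f1(raster_to_mask(ml_classify(res$image, st)), res$weed_mask)
  th <- f1(threshold_classify(contrast_stretch(res$image)), res$weed_mask)
  expect_gte(ml, th)
})

test_that("reference selection respects the light condition", {
  tr <- function(labels) {
    tibble::tibble(label = rep(labels, each = 3),
                   r = rnorm(3 * length(labels), 120, 15),
                   g = rnorm(3 * length(labels), 110, 15),
                   b = rnorm(3 * length(labels), 90, 15))
  }
  set.seed(6)
  refs <- list(cloudy = fit_class_stats(tr(condition_labels("cloudy")),
                                        condition = "cloudy"),
               sunny = fit_class_stats(tr(condition_labels("sunny")),
                                       condition = "sunny"))
  img_c <- random_image(4, 4)  # defaults to cloudy
  expect_length(select_reference(refs, img_c)$labels, 5)
  img_s <- rgb_image(unclass(img_c), condition = "sunny")
  expect_length(select_reference(refs, img_s)$labels, 6)
  expect_error(select_reference(refs["sunny"], img_c), "cloudy")
})

test_that("reference files survive a JSON round trip", {
  set.seed(7)
  st <- random_stats(5)
  path <- withr::local_tempfile(fileext = ".json")
  write_class_stats(st, path)
  back <- read_class_stats(path)
  expect_equal(back$labels, st$labels)
  expect_equal(unname(back$means), unname(st$means))
  for (l in st$labels) expect_equal(back$covs[[l]], unname(st$covs[[l]]))
  img <- random_image(6, 6)
  expect_identical(as.integer(ml_classify(img, st)),
                   as.integer(ml_classify(img, back)))
})
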