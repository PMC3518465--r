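test_that("set-level normalization equalizes mean and RMS contrast", {
  withr::with_seed(4, {
    a <- matrix(runif(64^2, 0.1, 0.5), 64)   # mean 0.3
    b <- matrix(runif(64^2, 0.3, 0.7), 64)   # mean 0.5
  })
  out <- normalize_luminance_contrast(list(a, b))
  expect_equal(mean(out[[1]]), (mean(a) + mean(b)) / 2, tolerance = 1e-7)
  expect_equal(mean(out[[1]]), mean(out[[2]]), tolerance = 1e-7)
  expect_equal(sd(out[[1]]), sd(out[[2]]), tolerance = 1e-7)

  # single image is already at the set average
  solo <- normalize_luminance_contrast(list(a))[[1]]
  expect_equal(solo, a, tolerance = 1e-9)

  # constant image is degenerate
  expect_error(normalize_luminance_contrast(list(a, matrix(0.5, 64, 64))),
               "constant")
})

test_that("generated image sets are normalized, balanced and deterministic", {
  imgs <- generate_scene_images(4, image_size = 64, seed = 12)
  means <- vapply(imgs, function(i) mean(i$pixels), numeric(1))
  sds <- vapply(imgs, function(i) sd(i$pixels), numeric(1))
  expect_lt(diff(range(means)), 1e-6)
  expect_lt(diff(range(sds)), 1e-6)

  cats <- vapply(imgs, function(i) i$category, character(1))
  expect_equal(unname(table(cats)[c("animal", "manmade", "natural",
                                    "vehicle")]),
               rep(4L, 4), ignore_attr = TRUE)
  # object categories: half natural / half man-made backgrounds, with masks
  for (cat in c("animal", "vehicle")) {
    sel <- imgs[cats == cat]
    bg <- vapply(sel, function(i) i$background_context, character(1))
    expect_equal(sum(bg == "natural"), 2)
    expect_true(all(vapply(sel, function(i) any(i$object_mask), logical(1))))
  }
  # scene categories carry no mask
  expect_true(all(vapply(imgs[cats %in% c("natural", "manmade")],
                         function(i) is.null(i$object_mask), logical(1))))

  again <- generate_scene_images(4, image_size = 64, seed = 12)
  expect_identical(imgs, again)
  expect_error(generate_scene_images(3, image_size = 64), "even")
})

test_that("object geometry follows the closed-form cases", {
  px <- matrix(0.5, 400, 400)
  sq <- matrix(FALSE, 400, 400)
  sq[181:220, 181:220] <- TRUE   # centered 40x40 square
  img <- sacchoice:::stimulus_image(px, "animal", "natural", sq)
  stats <- object_geometry_stats(list(img), n_resamples = 50)
  expect_equal(stats$per_image$size_pct, 1.0)
  expect_equal(stats$per_image$centroid_x, 200.5 / 400, tolerance = 1e-6)
  expect_equal(stats$per_image$centroid_y, 200.5 / 400, tolerance = 1e-6)

  # full-frame mask: 100% of the image
  full <- sacchoice:::stimulus_image(px, "vehicle", "manmade",
                                     matrix(TRUE, 400, 400))
  expect_equal(object_geometry_stats(list(full),
                                     n_resamples = 50)$per_image$size_pct, 100)

  # two equal blobs: reported centroid is the average of the blob centroids
  two <- matrix(FALSE, 400, 400)
  two[96:105, 96:105] <- TRUE     # centroid (100.5, 100.5)
  two[296:305, 296:305] <- TRUE   # centroid (300.5, 300.5)
  img2 <- sacchoice:::stimulus_image(px, "animal", "natural", two)
  st <- object_geometry_stats(list(img2), n_resamples = 50)
  expect_equal(st$per_image$centroid_x, 200.5 / 400, tolerance = 1e-6)

  empty <- sacchoice:::stimulus_image(px, "animal", "natural",
                                      matrix(FALSE, 400, 400))
  expect_error(object_geometry_stats(list(empty)), "empty")
})

test_that("scene categories separate more than object categories", {
  # Fisher criterion on the mean-difference projection of oriented-energy
  # features: the generator is built to make global scene statistics easier
  # than object statistics
  fisher <- function(X, y) {
    g1 <- y == unique(y)[1]
    w <- colMeans(X[g1, , drop = FALSE]) - colMeans(X[!g1, , drop = FALSE])
    p <- X %*% w
    (mean(p[g1]) - mean(p[!g1]))^2 / (stats::var(p[g1]) + stats::var(p[!g1]))
  }
  imgs <- generate_scene_images(12, image_size = 64, seed = 20)
  cats <- vapply(imgs, function(i) i$category, character(1))
  X <- t(vapply(imgs, gist_features, numeric(512)))
  sc <- cats %in% c("natural", "manmade")
  expect_gt(fisher(X[sc, ], cats[sc]), fisher(X[!sc, ], cats[!sc]))
})

test_that("zero separation removes the category signal", {
  imgs <- generate_scene_images(8, image_size = 64, separation = 0, seed = 6)
  cats <- vapply(imgs, function(i) i$category, character(1))
  X <- t(vapply(imgs, gist_features, numeric(512)))
  sc <- cats %in% c("natural", "manmade")
  # with identical texture processes the held-out classifier is at chance
  proto <- cv_protocol(n_train = 12, n_test = 4, folds = 3, repeats = 20,
                       seed = 5)
  acc <- evaluate_model(X[sc, ], cats[sc], proto)$mean_accuracy
  expect_lt(abs(acc - 50), 3 * 100 * sqrt(0.25 / (4 * 20)))
})
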