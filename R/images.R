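#' Synthetic scene images
#'
#' Stand-in stimuli for a grayscale scene set: spectrally shaped textures
#' whose orientation spectrum separates natural (isotropic / oblique-rich)
#' from man-made (horizontal/vertical-dominated) backgrounds, with optional
#' composited object regions — a smooth closed blob for animals, a
#' rectilinear assembly for vehicles — recorded in a binary mask. Pixel
#' values live in [0, 1].
#'
#' @name stimulus_image
NULL

stimulus_image <- function(pixels, category, background_context = "none",
                           object_mask = NULL) {
  stopifnot(is.matrix(pixels),
            category %in% c("natural", "manmade", "animal", "vehicle"))
  structure(list(pixels = pixels, category = category,
                 background_context = background_context,
                 object_mask = object_mask),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image> %s (%s background), %dx%d px%s\n",
              x$category, x$background_context, nrow(x$pixels),
              ncol(x$pixels),
              if (!is.null(x$object_mask))
                sprintf(", object %.1f%% of image",
                        100 * mean(x$object_mask)) else ""))
  invisible(x)
}

as_pixels <- function(img) {
  if (inherits(img, "stimulus_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a stimulus_image or a numeric matrix", call. = FALSE)
}

# 1/f texture with an orientation-dependent amplitude gain.
# cardinal_gain > 0 boosts horizontal/vertical energy (man-made look),
# < 0 boosts obliques (natural look).
shaped_texture <- function(n, cardinal_gain, falloff = 1.2) {
  f <- c(0, seq_len(n - 1)) / n
  f <- ifelse(f > 0.5, f - 1, f)
  fx <- matrix(f, n, n)
  fy <- t(fx)
  fr <- sqrt(fx^2 + fy^2)
  theta <- atan2(fy, fx)
  amp <- ifelse(fr > 0, fr^(-falloff), 0) *
    (1 + cardinal_gain * cos(4 * theta))
  z <- matrix(stats::rnorm(n * n), n, n)
  img <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (n * n)
  # standardize to a mid-grey working range; the set-level normalization
  # fixes the final statistics
  img <- (img - mean(img)) / stats::sd(img)
  pmin(pmax(0.5 + 0.12 * img, 0), 1)
}

# smooth closed contour: radius as a low-order Fourier series of angle
animal_mask <- function(n, center, r0) {
  k <- 2:5
  a <- stats::rnorm(length(k), 0, 0.12 / sqrt(k))
  ph <- stats::runif(length(k), 0, 2 * pi)
  x <- matrix(seq_len(n), n, n) - center[1]
  y <- t(matrix(seq_len(n), n, n)) - center[2]
  phi <- atan2(y, x)
  r <- r0 * (1 + Reduce(`+`, lapply(seq_along(k),
                                    function(i) a[i] * cos(k[i] * phi + ph[i]))))
  sqrt(x^2 + y^2) < r
}

# rectilinear assembly: body rectangle plus an offset cabin block
vehicle_mask <- function(n, center, r0) {
  mask <- matrix(FALSE, n, n)
  half_w <- round(1.3 * r0); half_h <- round(0.7 * r0)
  xr <- pmax(1, center[1] - half_w):pmin(n, center[1] + half_w)
  yr <- pmax(1, center[2] - half_h):pmin(n, center[2] + half_h)
  mask[xr, yr] <- TRUE
  cab_w <- round(0.5 * half_w); cab_h <- round(0.8 * half_h)
  cx <- center[1] + round(0.3 * half_w)
  xr2 <- pmax(1, cx - cab_w):pmin(n, cx + cab_w)
  yr2 <- pmax(1, center[2] - half_h - cab_h):pmin(n, center[2] - half_h)
  mask[xr2, yr2] <- TRUE
  mask
}

#' Generate a balanced synthetic scene-image set
#'
#' Produces `n_per_category` images for each of the four categories. Scene
#' categories (natural, man-made) are pure backgrounds; object categories
#' (animal, vehicle) composite an object region into a background, half of
#' them natural and half man-made, with the object mask recorded. The whole
#' set is then luminance/contrast-equalized with
#' [normalize_luminance_contrast()]. `separation` scales the
#' orientation-spectrum distance between the two background processes;
#' at 0 the background processes are identical and the object regions
#' blend into them, so no category carries any signal.
#'
#' @param n_per_category images per category; must be even for the object
#'   categories (background balance).
#' @param image_size side length in pixels.
#' @param separation nonnegative scale of the category separation (1 =
#'   default).
#' @param categories subset of categories to generate.
#' @param seed integer seed; the set is deterministic given all arguments.
#' @return list of [stimulus_image] objects.
#' @export
generate_scene_images <- function(n_per_category, image_size = 128,
                                  separation = 1,
                                  categories = c("natural", "manmade",
                                                 "animal", "vehicle"),
                                  seed = 1L) {
  stopifnot(n_per_category >= 1, image_size >= 32, separation >= 0)
  if (any(categories %in% c("animal", "vehicle")) && n_per_category %% 2 != 0)
    stop("n_per_category must be even for object categories ",
         "(half natural / half man-made backgrounds)", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    n <- image_size
    gain <- function(context) {
      # man-made: cardinal-dominated; natural: oblique-rich
      0.45 * separation * (if (context == "manmade") 1 else -1)
    }
    make_background <- function(context) shaped_texture(n, gain(context))
    out <- list()
    for (cat in categories) {
      for (i in seq_len(n_per_category)) {
        if (cat %in% c("natural", "manmade")) {
          out[[length(out) + 1]] <-
            stimulus_image(make_background(cat), cat, "none")
        } else {
          context <- if (i <= n_per_category / 2) "natural" else "manmade"
          bg <- make_background(context)
          r0 <- n * stats::runif(1, 0.09, 0.13)
          center <- round(stats::runif(2, 0.3 * n, 0.7 * n))
          mask <- if (cat == "animal") animal_mask(n, center, r0)
                  else vehicle_mask(n, center, r0)
          # object interior: its own texture, contrast scaled with the
          # category separation so separation = 0 removes the object signal
          obj_tex <- shaped_texture(n, gain(if (cat == "animal") "natural"
                                            else "manmade"))
          w <- min(0.8 * separation, 1)
          bg[mask] <- (1 - w) * bg[mask] +
            w * pmin(pmax(obj_tex[mask] + 0.12 * separation, 0), 1)
          out[[length(out) + 1]] <- stimulus_image(bg, cat, context, mask)
        }
      }
    }
    normalize_luminance_contrast(out)
  })
}

#' Equalize mean luminance and RMS contrast across an image set
#'
#' Rescales every image to the set-average mean luminance and set-average
#' RMS contrast (standard deviation of pixel values) of the inputs, clipping
#' to [0, 1] and iterating until both statistics hold within `tol` on every
#' image.
#'
#' @param images list of [stimulus_image] objects (or numeric matrices).
#' @param tol convergence tolerance on the per-image mean and contrast.
#' @param max_iter iteration cap; failure to converge (heavy clipping) is an
#'   error.
#' @return the input list with equalized pixel values.
#' @export
normalize_luminance_contrast <- function(images, tol = 1e-7, max_iter = 200) {
  stopifnot(length(images) >= 1)
  mats <- lapply(images, as_pixels)
  sds <- vapply(mats, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant-valued image: contrast rescaling undefined", call. = FALSE)
  target_mean <- mean(vapply(mats, mean, numeric(1)))
  target_sd <- mean(sds)
  for (iter in seq_len(max_iter)) {
    mats <- lapply(mats, function(m) {
      m <- (m - mean(m)) / stats::sd(m) * target_sd + target_mean
      pmin(pmax(m, 0), 1)
    })
    dev_mean <- max(abs(vapply(mats, mean, numeric(1)) - target_mean))
    dev_sd <- max(abs(vapply(mats, stats::sd, numeric(1)) - target_sd))
    if (dev_mean < tol && dev_sd < tol) break
    if (iter == max_iter)
      stop("luminance/contrast equalization did not converge ",
           "(clipping removes too much mass)", call. = FALSE)
  }
  for (i in seq_along(images)) {
    if (inherits(images[[i]], "stimulus_image"))
      images[[i]]$pixels <- mats[[i]]
    else images[[i]] <- mats[[i]]
  }
  images
}

#' Object size and centroid statistics
#'
#' For every image with an object mask: object size as a percentage of the
#' image area, and the object centroid. Images with several disconnected
#' blobs report the unweighted average of the blob centroids. The summary
#' gives the per-category mean size with a 95% percentile-bootstrap CI.
#'
#' @param images list of [stimulus_image] objects; each needs a non-empty
#'   `object_mask`.
#' @param n_resamples bootstrap resamples for the summary CI.
#' @return list with `per_image` (tibble: category, background, centroid x/y
#'   as image fractions, size %) and `summary` (per-category mean size and
#'   CI).
#' @export
object_geometry_stats <- function(images, n_resamples = 2000) {
  images <- Filter(function(im) inherits(im, "stimulus_image"), images)
  images <- Filter(function(im) !is.null(im$object_mask), images)
  if (length(images) == 0) stop("no images with object masks", call. = FALSE)
  rows <- lapply(images, function(im) {
    mask <- im$object_mask
    if (!any(mask)) stop("empty object mask", call. = FALSE)
    labels <- EBImage::bwlabel(mask)
    cents <- vapply(seq_len(max(labels)), function(l) {
      idx <- which(labels == l, arr.ind = TRUE)
      colMeans(idx)
    }, numeric(2))
    cent <- unname(rowMeans(cents))
    tibble::tibble(category = im$category,
                   background_context = im$background_context,
                   centroid_x = cent[1] / nrow(mask),
                   centroid_y = cent[2] / ncol(mask),
                   size_pct = 100 * mean(mask))
  })
  per_image <- dplyr::bind_rows(rows)
  boot_mean_ci <- function(x) {
    res <- vapply(seq_len(n_resamples),
                  function(i) mean(sample(x, replace = TRUE)), numeric(1))
    percentile_ci(res)
  }
  summary <- dplyr::bind_rows(lapply(
    split(per_image, per_image$category), function(g) {
      ci <- boot_mean_ci(g$size_pct)
      tibble::tibble(category = g$category[1], n = nrow(g),
                     mean_size_pct = mean(g$size_pct),
                     ci_lower = ci[1], ci_upper = ci[2])
    }))
  list(per_image = per_image, summary = summary)
}

#' Write a stimulus image (and its mask) as PNG
#'
#' @param image a [stimulus_image].
#' @param path output path; the mask, if present, goes to
#'   `<path>_mask.png`.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(image, path) {
  stopifnot(inherits(image, "stimulus_image"))
  EBImage::writeImage(EBImage::Image(image$pixels), path)
  if (!is.null(image$object_mask))
    EBImage::writeImage(EBImage::Image(image$object_mask * 1),
                        sub("\\.png$", "_mask.png", path))
  invisible(path)
}
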