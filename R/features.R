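#' Feedforward feature models
#'
#' Four classic global feature extractors used to ask how far simple
#' feedforward statistics go on the scene (natural vs man-made) and object
#' (animal vs vehicle) tasks: oriented-energy layout (GIST), gradient
#' Weibull statistics, a center-surround saliency map, and HMAX up to the
#' C1 complex-cell stage with a random-prototype readout. All extractors
#' are pure functions of the image (plus, for HMAX, a seed-fixed prototype
#' dictionary).
#'
#' @name feature_models
NULL

# frequency-domain log-polar Gabor bank (orientation defined mod pi)
gabor_bank_fft <- function(size, n_scales = 4, n_orient = 8) {
  f <- c(0, seq_len(size - 1)) / size
  f <- ifelse(f > 0.5, f - 1, f)
  fx <- matrix(f, size, size)
  fy <- t(fx)
  fr <- sqrt(fx^2 + fy^2)
  theta <- atan2(fy, fx)
  filters <- vector("list", n_scales * n_orient)
  sigma_theta <- (pi / n_orient) * 0.4
  k <- 1
  for (s in seq_len(n_scales)) {
    f0 <- 0.25 / 2^(s - 1)
    radial <- exp(-(fr - f0)^2 / (2 * (0.4 * f0)^2))
    for (o in seq_len(n_orient)) {
      th0 <- (o - 1) * pi / n_orient
      dth <- abs(((theta - th0 + pi / 2) %% pi) - pi / 2)
      g <- radial * exp(-dth^2 / (2 * sigma_theta^2))
      g[1, 1] <- 0
      filters[[k]] <- g
      k <- k + 1
    }
  }
  attr(filters, "n_scales") <- n_scales
  attr(filters, "n_orient") <- n_orient
  filters
}

pool_grid <- function(m, grid) {
  n <- nrow(m)
  cuts <- ceiling(seq_len(n) / (n / grid))
  rowsum_m <- rowsum(m, cuts)
  t(rowsum(t(rowsum_m), cuts)) / (n / grid)^2
}

#' GIST: pooled oriented-energy layout
#'
#' Removes the DC component, filters the image with a Gabor bank (default
#' 4 scales x 8 orientations, frequency domain) and averages each channel's
#' energy magnitude over a `grid x grid` spatial grid, giving
#' `n_scales * n_orient * grid^2` values (512 under the defaults).
#'
#' @param img a [stimulus_image] or numeric matrix (square).
#' @param n_scales,n_orient,grid bank and pooling geometry.
#' @return named numeric feature vector.
#' @export
gist_features <- function(img, n_scales = 4, n_orient = 8, grid = 4) {
  x <- as_pixels(img)
  n <- nrow(x)
  stopifnot(n == ncol(x))
  if (n < 2^(n_scales - 1) * 8)
    stop("image too small for the largest filter scale", call. = FALSE)
  x <- x - mean(x)
  X <- stats::fft(x)
  bank <- gabor_bank_fft(n, n_scales, n_orient)
  feats <- vapply(bank, function(g) {
    e <- Mod(stats::fft(X * g, inverse = TRUE)) / (n * n)
    as.numeric(pool_grid(e, grid))
  }, numeric(grid^2))
  out <- as.numeric(feats)
  names(out) <- paste0("g", seq_along(out))
  out
}

#' Weibull contrast statistics
#'
#' Fits a two-parameter Weibull to the distribution of gradient magnitudes
#' (central differences) by maximum likelihood and returns the scale `beta`
#' and shape `gamma`. Doubling the image contrast doubles `beta` and leaves
#' `gamma` unchanged.
#'
#' @param img a [stimulus_image] or numeric matrix.
#' @return numeric vector `c(beta, gamma)`.
#' @export
weibull_features <- function(img) {
  x <- as_pixels(img)
  if (stats::sd(x) == 0)
    stop("constant image: gradient distribution is degenerate", call. = FALSE)
  n <- nrow(x); m <- ncol(x)
  gx <- (x[c(2:n, n), ] - x[c(1, 1:(n - 1)), ]) / 2
  gy <- (x[, c(2:m, m)] - x[, c(1, 1:(m - 1))]) / 2
  gm <- sqrt(gx^2 + gy^2)
  gm <- gm[gm > 0]
  fit <- fitdistrplus::fitdist(gm, "weibull")
  est <- fit$estimate
  c(beta = unname(est["scale"]), gamma = unname(est["shape"]))
}

resize_map <- function(m, w, h) {
  as.matrix(EBImage::resize(EBImage::Image(m), w = w, h = h))
}

normalize_map <- function(m) {
  rng <- max(m) - min(m)
  if (rng == 0) return(m * 0)
  m <- (m - min(m)) / rng
  # promote maps with one dominant peak, demote uniform ones
  m * (max(m) - mean(m))^2
}

#' Center-surround saliency map features
#'
#' Builds a dyadic pyramid, takes center-surround differences on the
#' intensity channel and on four oriented-energy channels, normalizes each
#' map by its peak-vs-mean contrast, combines them into a saliency map, and
#' returns the map downsampled to `grid x grid` (64 values by default).
#'
#' @param img a [stimulus_image] or numeric matrix.
#' @param grid output grid side.
#' @return numeric feature vector of length `grid^2`.
#' @export
saliency_features <- function(img, grid = 8) {
  x <- as_pixels(img)
  n <- nrow(x)
  if (n < 32) stop("image too small for the pyramid", call. = FALSE)
  depth <- min(4L, floor(log2(n / 8)))
  pyr <- vector("list", depth + 1)
  pyr[[1]] <- x
  for (l in seq_len(depth))
    pyr[[l + 1]] <- resize_map(pyr[[l]], ncol(pyr[[l]]) %/% 2,
                               nrow(pyr[[l]]) %/% 2)
  orient_maps <- function(m) {
    sz <- nrow(m)
    X <- stats::fft(m - mean(m))
    bank <- gabor_bank_fft(sz, n_scales = 1, n_orient = 4)
    lapply(bank, function(g) Mod(stats::fft(X * g, inverse = TRUE)) / sz^2)
  }
  pyr_orient <- lapply(pyr, orient_maps)
  out_size <- ncol(pyr[[min(3, depth + 1)]])
  sal <- matrix(0, out_size, out_size)
  cs_pairs <- expand.grid(c = 1:2, d = 2:3)
  for (i in seq_len(nrow(cs_pairs))) {
    c_lvl <- cs_pairs$c[i]
    s_lvl <- cs_pairs$c[i] + cs_pairs$d[i]
    if (s_lvl > depth + 1) next
    cs <- function(center, surround) {
      d <- abs(center - resize_map(surround, ncol(center), nrow(center)))
      resize_map(normalize_map(d), out_size, out_size)
    }
    sal <- sal + cs(pyr[[c_lvl]], pyr[[s_lvl]])
    for (o in 1:4)
      sal <- sal + 0.25 * cs(pyr_orient[[c_lvl]][[o]],
                             pyr_orient[[s_lvl]][[o]])
  }
  out <- as.numeric(resize_map(sal, grid, grid))
  names(out) <- paste0("s", seq_along(out))
  out
}

# spatial Gabor patch (odd size), zero-mean, unit-norm
spatial_gabor <- function(size, theta, lambda = 0.8 * size,
                          sigma = 0.35 * size, gamma_asp = 0.5) {
  r <- (size - 1) / 2
  gx <- matrix(-r:r, size, size)
  gy <- t(gx)
  xr <- gx * cos(theta) + gy * sin(theta)
  yr <- -gx * sin(theta) + gy * cos(theta)
  g <- exp(-(xr^2 + gamma_asp^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / lambda)
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

max_pool <- function(m, pool) {
  n <- nrow(m)
  grid <- n %/% pool
  idx <- rep(seq_len(grid), each = pool)[seq_len(grid * pool)]
  m <- m[seq_len(grid * pool), seq_len(grid * pool)]
  # max over pool x pool blocks
  apply_rows <- vapply(split(seq_len(grid * pool), idx),
                       function(r) apply(m[r, , drop = FALSE], 2, max),
                       numeric(grid * pool))
  t(vapply(split(seq_len(grid * pool), idx),
           function(cset) apply(apply_rows[cset, , drop = FALSE], 2, max),
           numeric(grid)))
}

#' HMAX C1 maps
#'
#' S1: spatial Gabor filtering at `length(scales)` filter sizes and
#' `n_orient` orientations (absolute response); C1: max over pairs of
#' adjacent scales and max-pooling over non-overlapping `pool x pool`
#' neighbourhoods. Returns one band per scale pair, each an array
#' `grid x grid x n_orient`.
#'
#' @param img a [stimulus_image] or numeric matrix.
#' @param scales odd S1 filter sizes in pixels (paired consecutively into
#'   bands).
#' @param n_orient number of orientations.
#' @param pool C1 pooling neighbourhood (pixels).
#' @return list of C1 band arrays.
#' @export
hmax_c1_maps <- function(img, scales = c(7, 9, 11, 13), n_orient = 4,
                         pool = 8) {
  x <- as_pixels(img)
  if (nrow(x) < 4 * max(scales))
    stop("image too small for the S1 filters", call. = FALSE)
  s1 <- lapply(scales, function(sz)
    lapply(seq_len(n_orient) - 1, function(o) {
      g <- spatial_gabor(sz, o * pi / n_orient)
      abs(as.matrix(EBImage::filter2(EBImage::Image(x), g)))
    }))
  bands <- seq(1, length(scales) - 1, by = 2)
  lapply(bands, function(b) {
    maps <- lapply(seq_len(n_orient), function(o)
      max_pool(pmax(s1[[b]][[o]], s1[[b + 1]][[o]]), pool))
    array(unlist(maps), dim = c(dim(maps[[1]]), n_orient))
  })
}

#' Seed-fixed random C1 patch prototypes
#'
#' Draws prototype patches by running [hmax_c1_maps()] on seed-generated
#' noise images and sampling `patch x patch x n_orient` sub-blocks of the
#' first band, each normalized to unit norm. The dictionary plays the role
#' of an S2 template set.
#'
#' @param n_prototypes dictionary size.
#' @param patch spatial side of a prototype (C1 grid cells).
#' @param n_orient orientations (must match [hmax_c1_maps()]).
#' @param image_size size of the noise images the patches are cut from.
#' @param seed integer; the dictionary is a pure function of the arguments.
#' @return list of prototype arrays.
#' @export
hmax_prototypes <- function(n_prototypes = 32, patch = 2, n_orient = 4,
                            image_size = 128, seed = 99L) {
  withr::with_seed(as.integer(seed), {
    protos <- vector("list", n_prototypes)
    i <- 1
    while (i <= n_prototypes) {
      c1 <- hmax_c1_maps(shaped_texture(image_size, 0), n_orient = n_orient)[[1]]
      g <- dim(c1)[1]
      for (k in seq_len(4)) {
        if (i > n_prototypes) break
        at <- sample.int(g - patch + 1, 2)
        p <- c1[at[1]:(at[1] + patch - 1), at[2]:(at[2] + patch - 1), ,
                drop = FALSE]
        nrm <- sqrt(sum(p^2))
        if (nrm > 0) {
          protos[[i]] <- p / nrm
          i <- i + 1
        }
      }
    }
    protos
  })
}

#' HMAX C1 + random-prototype features
#'
#' Computes the C1 maps and, for each prototype, takes the maximum dot
#' product between the (unit-norm) prototype and every C1 patch position in
#' the first band — an S2-like template match max-pooled over space. A
#' uniform image has zero C1 activity and maps to the zero vector.
#'
#' @param img a [stimulus_image] or numeric matrix.
#' @param prototypes dictionary from [hmax_prototypes()]; built on the fly
#'   (seed-fixed default) when omitted.
#' @param ... passed to [hmax_c1_maps()].
#' @return numeric feature vector, one value per prototype.
#' @export
hmax_c1_features <- function(img, prototypes = NULL, ...) {
  if (is.null(prototypes)) prototypes <- hmax_prototypes()
  c1 <- hmax_c1_maps(img, ...)[[1]]
  g <- dim(c1)[1]
  patch <- dim(prototypes[[1]])[1]
  out <- vapply(prototypes, function(p) {
    best <- 0
    for (i in seq_len(g - patch + 1))
      for (j in seq_len(g - patch + 1)) {
        v <- sum(c1[i:(i + patch - 1), j:(j + patch - 1), ] * p)
        if (v > best) best <- v
      }
    best
  }, numeric(1))
  names(out) <- paste0("h", seq_along(out))
  out
}

#' Extract a feature matrix from an image set
#'
#' @param images list of [stimulus_image] objects.
#' @param model one of `"gist"`, `"weibull"`, `"saliency"`, `"hmax_c1"`.
#' @param ... passed to the extractor.
#' @return numeric matrix, one row per image, with the image categories in
#'   attribute `"category"`.
#' @export
extract_features <- function(images,
                             model = c("gist", "weibull", "saliency",
                                       "hmax_c1"), ...) {
  model <- match.arg(model)
  fun <- switch(model, gist = gist_features, weibull = weibull_features,
                saliency = saliency_features, hmax_c1 = hmax_c1_features)
  extra <- list(...)
  if (model == "hmax_c1" && is.null(extra$prototypes))
    extra$prototypes <- hmax_prototypes()
  rows <- lapply(images, function(im) do.call(fun, c(list(im), extra)))
  dims <- vapply(rows, length, integer(1))
  if (length(unique(dims)) != 1)
    stop("feature dimension differs across images", call. = FALSE)
  mat <- do.call(rbind, rows)
  attr(mat, "category") <- vapply(images, function(im) im$category,
                                  character(1))
  attr(mat, "model") <- model
  mat
}
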