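# Seeded generator of a six-class synthetic "leaf disease" image set.  The
# renderers are parametric, not photo-realistic: their contract is that class
# identity is statistically recoverable from simple image features, and that
# increasing background clutter makes recovery harder.

#' Specification of a synthetic leaf-image set
#'
#' Six categories mirror the corn study: `FA` (ragged chewed edges), `GLS`
#' (circular gray spots), `LB` (elongated tan streaks), `LH` (healthy, no
#' lesions), `NLS` (large dark blotches), `RL` (dense small orange pustules).
#'
#' @param n_per_class images per class (>= 2).
#' @param resolution square image side in pixels (>= 32).
#' @param background_clutter in `[0, 1]`; scales the number and contrast of
#'   distractor blobs and background noise.
#' @param seed master seed; the whole set is reproducible from it.
#' @return a `synth_spec` object.
#' @export
synth_spec <- function(n_per_class = 30L, resolution = 64L,
                       background_clutter = 0.3, seed = 1L) {
  if (n_per_class < 2L) abort("n_per_class must be >= 2")
  if (resolution < 32L) abort("resolution must be >= 32")
  if (background_clutter < 0 || background_clutter > 1)
    abort("background_clutter must be in [0, 1]")
  structure(list(classes = c("FA", "GLS", "LB", "LH", "NLS", "RL"),
                 n_per_class = as.integer(n_per_class),
                 resolution = as.integer(resolution),
                 background_clutter = background_clutter,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# paint a (possibly rotated) filled ellipse onto img (H,W,3)
paint_ellipse <- function(img, cy, cx, ry, rx, angle, col, alpha = 1) {
  d <- dim(img)
  yy <- matrix(seq_len(d[1]), d[1], d[2]) - cy
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx
  u <- cos(angle) * yy + sin(angle) * xx
  v <- -sin(angle) * yy + cos(angle) * xx
  inside <- (u / ry)^2 + (v / rx)^2 <= 1
  for (c in 1:3) {
    ch <- img[, , c]
    ch[inside] <- (1 - alpha) * ch[inside] + alpha * col[c]
    img[, , c] <- ch
  }
  img
}

leaf_mask <- function(res, cy, cx, ry, rx, angle) {
  yy <- matrix(seq_len(res), res, res) - cy
  xx <- matrix(seq_len(res), res, res, byrow = TRUE) - cx
  u <- cos(angle) * yy + sin(angle) * xx
  v <- -sin(angle) * yy + cos(angle) * xx
  (u / ry)^2 + (v / rx)^2 <= 1
}

# one image; assumes the RNG state is already set
render_leaf <- function(class, res, clutter) {
  jitter <- function(x, s) x + stats::rnorm(length(x), sd = s)
  # background: soil tones plus clutter blobs
  base <- c(0.45, 0.38, 0.30) + stats::rnorm(3, sd = 0.03)
  img <- array(rep(pmin(pmax(base, 0), 1), each = res * res), c(res, res, 3))
  n_blobs <- round(20 * clutter)
  for (b in seq_len(n_blobs)) {
    col <- pmin(pmax(c(stats::runif(1, 0.1, 0.7), stats::runif(1, 0.2, 0.7),
                       stats::runif(1, 0.05, 0.5)), 0), 1)
    img <- paint_ellipse(img, stats::runif(1, 1, res), stats::runif(1, 1, res),
                         stats::runif(1, res / 24, res / 6),
                         stats::runif(1, res / 24, res / 6),
                         stats::runif(1, 0, pi), col,
                         alpha = 0.25 + 0.6 * clutter)
  }
  # the leaf
  cy <- res / 2 + stats::rnorm(1, sd = res / 24)
  cx <- res / 2 + stats::rnorm(1, sd = res / 24)
  ry <- res * stats::runif(1, 0.33, 0.39)
  rx <- res * stats::runif(1, 0.17, 0.21)
  angle <- stats::runif(1, -pi / 8, pi / 8)
  leaf_col <- pmin(pmax(jitter(c(0.18, 0.52, 0.16), 0.02), 0), 1)
  img <- paint_ellipse(img, cy, cx, ry, rx, angle, leaf_col)
  mask <- leaf_mask(res, cy, cx, ry, rx, angle)
  # central vein
  img <- paint_ellipse(img, cy, cx, ry * 0.92, rx * 0.06, angle,
                       pmin(leaf_col + 0.12, 1))
  rand_in_leaf <- function(shrink = 0.75) {
    t <- stats::runif(1, 0, 2 * pi); r <- sqrt(stats::runif(1)) * shrink
    u <- r * ry * cos(t); v <- r * rx * sin(t)
    c(cy + cos(angle) * u - sin(angle) * v,
      cx + sin(angle) * u + cos(angle) * v)
  }
  if (class == "GLS") {
    for (s in seq_len(sample(10:14, 1))) {
      p <- rand_in_leaf()
      r <- max(res * stats::runif(1, 0.045, 0.065), 1.5)
      img <- paint_ellipse(img, p[1], p[2], r, r, 0,
                           jitter(c(0.70, 0.70, 0.66), 0.02))
    }
  } else if (class == "LB") {
    for (s in seq_len(sample(4:6, 1))) {
      p <- rand_in_leaf(0.6)
      img <- paint_ellipse(img, p[1], p[2], res * stats::runif(1, 0.14, 0.22),
                           max(res * stats::runif(1, 0.025, 0.045), 1.2),
                           angle + stats::rnorm(1, sd = 0.1),
                           jitter(c(0.72, 0.58, 0.28), 0.02))
    }
  } else if (class == "RL") {
    for (s in seq_len(sample(45:60, 1))) {
      p <- rand_in_leaf(0.85)
      r <- max(res * stats::runif(1, 0.015, 0.03), 1.2)
      img <- paint_ellipse(img, p[1], p[2], r, r, 0,
                           jitter(c(0.85, 0.38, 0.05), 0.03))
    }
  } else if (class == "NLS") {
    for (s in seq_len(sample(3:4, 1))) {
      p <- rand_in_leaf(0.55)
      img <- paint_ellipse(img, p[1], p[2], res * stats::runif(1, 0.10, 0.15),
                           res * stats::runif(1, 0.08, 0.12),
                           stats::runif(1, 0, pi),
                           jitter(c(0.22, 0.14, 0.06), 0.02))
    }
  } else if (class == "FA") {
    # ragged chewed edge: carve bites centred on the leaf boundary
    for (s in seq_len(sample(9:13, 1))) {
      t <- stats::runif(1, 0, 2 * pi)
      u <- ry * cos(t); v <- rx * sin(t)
      by <- cy + cos(angle) * u - sin(angle) * v
      bx <- cx + sin(angle) * u + cos(angle) * v
      r <- max(res * stats::runif(1, 0.07, 0.12), 2.5)
      img <- paint_ellipse(img, by, bx, r, r, 0, base)
    }
  }
  noise <- array(stats::rnorm(res * res * 3, sd = 0.012 + 0.04 * clutter),
                 c(res, res, 3))
  pmin(pmax(img + noise, 0), 1)
}

#' Generate the synthetic leaf-image set
#'
#' Renders `6 * n_per_class` images deterministically from the spec seed.
#' With `dir`, images are written as PNG under one directory per class and a
#' `manifest.csv` is written alongside; the same seed always produces
#' byte-identical files.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory (image-folder layout).
#' @return list with `images` (`(res, res, 3, N)` array), `manifest` (tibble
#'   `class`, `index`, and `path` when written), and `spec`.
#' @export
generate_synthetic_leaves <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  res <- spec$resolution
  n_total <- length(spec$classes) * spec$n_per_class
  set.seed(spec$seed)
  image_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  images <- array(0, c(res, res, 3L, n_total))
  manifest <- tibble::tibble(
    class = rep(spec$classes, each = spec$n_per_class),
    index = rep(seq_len(spec$n_per_class), times = length(spec$classes)))
  for (i in seq_len(n_total)) {
    set.seed(image_seeds[i])
    images[, , , i] <- render_leaf(manifest$class[i], res,
                                   spec$background_clutter)
  }
  if (!is.null(dir)) {
    paths <- character(n_total)
    for (cl in spec$classes)
      dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_total)) {
      paths[i] <- file.path(dir, manifest$class[i],
                            sprintf("%s_%03d.png", manifest$class[i],
                                    manifest$index[i]))
      png::writePNG(images[, , , i], paths[i])
    }
    manifest$path <- paths
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest, spec = spec)
}

#' Split the synthetic set into train/valid/test arrays
#'
#' Applies the per-class 8:1:1 rule (or any ratios) with a seeded
#' permutation and returns arrays ready for [train()].
#'
#' @param synth result of [generate_synthetic_leaves()].
#' @param ratios train/valid/test proportions.
#' @param seed permutation seed.
#' @return list of `train`, `valid`, `test` (each `list(x, y)`), plus
#'   `class_names`.
#' @export
synth_split <- function(synth, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  man <- synth$manifest
  man$row <- seq_len(nrow(man))
  counts <- split_dataset(stats::setNames(
    as.integer(table(man$class)), names(table(man$class))), ratios, seed)
  set.seed(seed)
  subset <- character(nrow(man))
  for (cl in counts$class) {
    rows <- man$row[man$class == cl]
    cc <- counts[counts$class == cl, ]
    labs <- sample(rep(c("train", "valid", "test"),
                       times = c(cc$train, cc$valid, cc$test)))
    subset[rows] <- labs
  }
  classes <- sort(unique(man$class))
  take <- function(which) {
    rows <- man$row[subset == which]
    list(x = synth$images[, , , rows, drop = FALSE],
         y = match(man$class[rows], classes))
  }
  list(train = take("train"), valid = take("valid"), test = take("test"),
       class_names = classes)
}

#' Simple image features for the linear separability probe
#'
#' Per-image channel means and standard deviations, edge density (mean
#' absolute spatial gradient of the green channel), and dark/orange pixel
#' fractions — deliberately crude features a linear classifier can use.
#'
#' @param images array `(H, W, 3, N)`.
#' @return tibble with one row per image.
#' @export
leaf_features <- function(images) {
  n <- dim(images)[4]
  purrr::map_dfr(seq_len(n), function(i) {
    im <- images[, , , i]
    g <- im[, , 2]
    edge <- mean(abs(diff(g))) + mean(abs(t(diff(t(g)))))
    lum <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
    tibble::tibble(
      mean_r = mean(im[, , 1]), mean_g = mean(g), mean_b = mean(im[, , 3]),
      sd_r = stats::sd(im[, , 1]), sd_g = stats::sd(g), sd_b = stats::sd(im[, , 3]),
      edge = edge,
      frac_dark = mean(lum < 0.25),
      frac_orange = mean(im[, , 1] > 0.6 & im[, , 2] < 0.5 & im[, , 3] < 0.3),
      frac_gray = mean(abs(im[, , 1] - g) < 0.06 & abs(g - im[, , 3]) < 0.12 &
                         lum > 0.35 & lum < 0.7))
  })
}

#' Linear-probe accuracy of the synthetic set
#'
#' Fits a multinomial logistic regression on [leaf_features()] of a training
#' half and reports held-out accuracy; used to certify that the generated
#' classes are learnable and that clutter makes them harder.
#'
#' @param synth result of [generate_synthetic_leaves()].
#' @param seed split seed.
#' @return held-out accuracy in `[0, 1]`.
#' @export
linear_probe_accuracy <- function(synth, seed = 1L) {
  if (!requireNamespace("nnet", quietly = TRUE))
    abort("nnet is required for the linear probe")
  feats <- leaf_features(synth$images)
  feats$class <- factor(synth$manifest$class)
  set.seed(seed)
  n <- nrow(feats)
  idx <- sample.int(n, n %/% 2)
  fit <- nnet::multinom(class ~ ., data = feats[idx, ], trace = FALSE,
                        maxit = 300)
  pred <- stats::predict(fit, newdata = feats[-idx, ])
  mean(pred == feats$class[-idx])
}
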