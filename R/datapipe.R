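# Dataset splitting, online augmentation (Cutout, GridMask, Random Erasing)
# and the photometric robustness transforms, over an image-folder layout
# (`root/<class>/*.png`).

round_half_up <- function(x) floor(x + 0.5)

#' Split a dataset per class
#'
#' Splits each class into train/valid/test at the given ratios.  Valid and
#' test counts are `round(ratio * n)` with half-up rounding; train takes the
#' remainder, so counts always sum to `n`.  With a manifest the per-image
#' assignment is a seeded permutation, deterministic for a fixed seed.
#'
#' Published per-class counts that do not follow a single rounding rule can
#' be reproduced verbatim by passing `explicit_counts`.
#'
#' @param data either a named integer vector of per-class totals or a
#'   manifest data frame with columns `path` and `class`.
#' @param ratios length-3 numeric `(train, valid, test)` summing to 1.
#' @param seed permutation seed.
#' @param explicit_counts optional data frame with columns `class`, `train`,
#'   `valid`, `test` overriding the rounding rule.
#' @return a tibble of per-class counts (`class`, `total`, `train`, `valid`,
#'   `test`); with a manifest input, the per-image assignment is attached as
#'   attribute `"assignment"` (a tibble `path`, `class`, `subset`).
#' @export
split_dataset <- function(data, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          explicit_counts = NULL) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  manifest <- NULL
  if (is.data.frame(data)) {
    manifest <- tibble::as_tibble(data)
    totals <- table(manifest$class)
    totals <- stats::setNames(as.integer(totals), names(totals))
  } else {
    totals <- data
  }
  if (any(totals < 3L)) abort("every class needs at least 3 images")
  counts <- tibble::tibble(class = names(totals), total = as.integer(totals)) |>
    dplyr::mutate(
      valid = as.integer(round_half_up(.data$total * ratios[2])),
      test = as.integer(round_half_up(.data$total * ratios[3])),
      train = .data$total - .data$valid - .data$test) |>
    dplyr::select("class", "total", "train", "valid", "test")
  if (!is.null(explicit_counts)) {
    ec <- tibble::as_tibble(explicit_counts)
    stopifnot(all(c("class", "train", "valid", "test") %in% names(ec)))
    counts <- counts |>
      dplyr::select("class", "total") |>
      dplyr::left_join(ec[, c("class", "train", "valid", "test")], by = "class")
    if (any(counts$train + counts$valid + counts$test != counts$total))
      abort("explicit_counts do not sum to the class totals")
  }
  if (!is.null(manifest)) {
    set.seed(seed)
    assignment <- manifest |>
      dplyr::group_by(.data$class) |>
      dplyr::group_modify(function(df, key) {
        cc <- counts[counts$class == key$class[[1]], ]
        subs <- rep(c("train", "valid", "test"),
                    times = c(cc$train, cc$valid, cc$test))
        df$subset <- sample(subs)
        df
      }) |>
      dplyr::ungroup()
    attr(counts, "assignment") <- assignment
  }
  counts
}

#' Read an image-folder manifest
#'
#' @param root directory containing one sub-directory per class with
#'   `.png`/`.jpg` images.
#' @return tibble with `path` and `class`.
#' @export
read_image_folder <- function(root) {
  classes <- list.dirs(root, recursive = FALSE)
  if (!length(classes)) abort("no class directories found")
  purrr::map_dfr(classes, function(d) {
    files <- list.files(d, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                        full.names = TRUE)
    tibble::tibble(path = files, class = basename(d))
  })
}

#' Load images from a manifest
#'
#' Reads PNG images into an `(H, W, 3, N)` array in `[0, 1]`, resizing
#' bilinearly to `resolution` when needed (via EBImage).
#'
#' @param manifest tibble with a `path` column.
#' @param resolution target square size in pixels.
#' @return array `(resolution, resolution, 3, nrow(manifest))`.
#' @export
load_images <- function(manifest, resolution) {
  n <- nrow(manifest)
  out <- array(0, dim = c(resolution, resolution, 3L, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(manifest$path[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img <- img[, , 1:3, drop = FALSE]
    if (dim(img)[1] != resolution || dim(img)[2] != resolution) {
      if (!requireNamespace("EBImage", quietly = TRUE))
        abort("EBImage is required to resize images")
      img <- EBImage::resize(img, w = resolution, h = resolution)
      img <- array(img, c(resolution, resolution, 3L))
    }
    out[, , , i] <- img
  }
  out
}

check_image <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L)
    abort("expected an (H, W, C) image array")
  d
}

#' Cutout augmentation
#'
#' Zeroes one axis-aligned square of side `size`; the square's center is
#' uniform over the image, so the region may overhang the border and is
#' clipped (zeroed pixel count is then below `size^2`).
#'
#' @param image `(H, W, C)` array in `[0, 1]`.
#' @param size square side in pixels (`<= min(H, W)`).
#' @param seed optional seed for the region draw.
#' @return augmented image, same shape.
#' @export
cutout <- function(image, size, seed = NULL) {
  d <- check_image(image)
  stopifnot(size >= 0, size <= min(d[1], d[2]))
  if (size == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  cy <- sample.int(d[1], 1L); cx <- sample.int(d[2], 1L)
  half <- size %/% 2L
  rows <- max(1L, cy - half):min(d[1], cy - half + size - 1L)
  cols <- max(1L, cx - half):min(d[2], cx - half + size - 1L)
  image[rows, cols, ] <- 0
  image
}

#' GridMask augmentation
#'
#' Multiplies the image by a periodic binary mask of the same resolution:
#' within every `period x period` cell one square of side
#' `round(period * sqrt(1 - ratio))` is zeroed (with a random cell offset),
#' so the kept fraction approximates `ratio` up to period quantization.
#'
#' @param image `(H, W, C)` array.
#' @param ratio kept fraction in `[0, 1]` (1 keeps everything).
#' @param period grid period in pixels (>= 2).
#' @param seed optional seed for the grid offset.
#' @return masked image, same shape.
#' @export
grid_mask <- function(image, ratio, period, seed = NULL) {
  d <- check_image(image)
  stopifnot(ratio >= 0, ratio <= 1, period >= 2)
  side <- round(period * sqrt(1 - ratio))
  if (side == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  off_y <- sample.int(period, 1L) - 1L
  off_x <- sample.int(period, 1L) - 1L
  yy <- ((seq_len(d[1]) - 1L + off_y) %% period) < side
  xx <- ((seq_len(d[2]) - 1L + off_x) %% period) < side
  mask <- 1 - outer(yy, xx) # FALSE where kept
  image * array(rep(mask, d[3]), dim = d)
}

#' Random Erasing augmentation
#'
#' With probability `prob`, overwrites one rectangle (area a uniform draw
#' within `area_range` of the image, aspect ratio in `[0.3, 1/0.3]`) with
#' uniform random values; otherwise returns the image unchanged.
#' Deterministic given `seed`.
#'
#' @param image `(H, W, C)` array.
#' @param prob probability of erasing.
#' @param area_range length-2 fractions `(lo, hi)` of image area.
#' @param seed optional seed.
#' @return augmented image, same shape.
#' @export
random_erasing <- function(image, prob = 0.5, area_range = c(0.02, 0.33),
                           seed = NULL) {
  d <- check_image(image)
  stopifnot(prob >= 0, prob <= 1, area_range[1] > 0, area_range[2] <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (stats::runif(1) > prob) return(image)
  for (attempt in 1:20) {
    area <- stats::runif(1, area_range[1], area_range[2]) * d[1] * d[2]
    aspect <- exp(stats::runif(1, log(0.3), log(1 / 0.3)))
    h <- as.integer(round(sqrt(area * aspect)))
    w <- as.integer(round(sqrt(area / aspect)))
    if (h >= 1 && w >= 1 && h <= d[1] && w <= d[2]) {
      y0 <- sample.int(d[1] - h + 1L, 1L)
      x0 <- sample.int(d[2] - w + 1L, 1L)
      image[y0:(y0 + h - 1L), x0:(x0 + w - 1L), ] <-
        stats::runif(h * w * d[3])
      return(image)
    }
  }
  image
}

#' Photometric brightness / contrast transform
#'
#' `brightness`: `clip(factor * x)`.  `contrast`: `clip(mean + factor * (x -
#' mean))` with the per-image mean.  Values are clipped to `[0, 1]`; factor 1
#' is the identity for both kinds.
#'
#' @param image `(H, W, C)` array in `[0, 1]`.
#' @param kind `"brightness"` or `"contrast"`.
#' @param factor positive enhancement factor (the robustness protocol uses
#'   0.5, 0.67, 1.5 and 2).
#' @return transformed image, same shape.
#' @export
photometric_transform <- function(image, kind = c("brightness", "contrast"),
                                  factor) {
  kind <- match.arg(kind)
  check_image(image)
  stopifnot(factor > 0)
  out <- if (kind == "brightness") factor * image
         else mean(image) + factor * (image - mean(image))
  pmin(pmax(out, 0), 1)
}

#' The photometric robustness protocol grid
#'
#' Eight perturbed test-set conditions: brightness and contrast, each at
#' factors 0.5, 0.67, 1.5 and 2.
#'
#' @return tibble with columns `kind` and `factor`.
#' @export
robustness_protocol <- function() {
  tidyr::expand_grid(kind = c("brightness", "contrast"),
                     factor = c(0.5, 0.67, 1.5, 2))
}

#' Online training augmentation policy
#'
#' Returns a `function(img)` that applies exactly one of Cutout, GridMask or
#' Random Erasing (chosen uniformly) to each training image; validation and
#' test images are never augmented.
#'
#' @param cutout_size Cutout square side in pixels.
#' @param gridmask_ratio kept fraction for GridMask.
#' @param gridmask_period GridMask period in pixels.
#' @param erase_prob,erase_area_range Random-Erasing parameters.
#' @return a single-image augmentation function.
#' @export
augment_online <- function(cutout_size = 16L, gridmask_ratio = 0.6,
                           gridmask_period = 16L, erase_prob = 1,
                           erase_area_range = c(0.02, 0.33)) {
  function(img) {
    u <- stats::runif(1)
    if (u < 1 / 3) cutout(img, cutout_size)
    else if (u < 2 / 3) grid_mask(img, gridmask_ratio, gridmask_period)
    else random_erasing(img, erase_prob, erase_area_range)
  }
}
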