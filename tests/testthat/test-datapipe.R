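test_that("per-class 8:1:1 split follows the half-up rounding rule", {
  counts <- split_dataset(c("Fall Armyworm" = 432L), seed = 1)
  expect_equal(unlist(counts[1, c("train", "valid", "test")],
                      use.names = FALSE), c(346L, 43L, 43L))
  # conservation for arbitrary totals
  set.seed(3)
  ns <- sample(10:2000, 30)
  cc <- split_dataset(stats::setNames(ns, paste0("c", seq_along(ns))))
  expect_true(all(cc$train + cc$valid + cc$test == cc$total))
  expect_true(all(cc$train >= 0 & cc$valid >= 0 & cc$test >= 0))
  # degenerate ratios: everything in train
  all_train <- split_dataset(c(a = 50L), ratios = c(1, 0, 0))
  expect_equal(all_train$train, 50L)
  expect_error(split_dataset(c(a = 2L)), "at least 3")
})

test_that("published split counts are reproduced (explicit for the odd row)", {
  totals <- corn_class_totals()
  rule <- split_dataset(stats::setNames(totals$total, totals$class), seed = 1)
  # five of six classes follow the rounding rule exactly
  merged <- merge(rule, totals, by = "class", suffixes = c("_rule", "_paper"))
  match_rows <- merged$train_rule == merged$train_paper
  expect_equal(sum(match_rows), 5)
  expect_equal(merged$class[!match_rows], "Rust Leaf")
  # explicit counts reproduce the published table verbatim
  verbatim <- split_dataset(stats::setNames(totals$total, totals$class),
                            explicit_counts = totals)
  merged2 <- merge(verbatim, totals, by = "class", suffixes = c("_got", "_want"))
  expect_equal(merged2$train_got, merged2$train_want)
  expect_equal(merged2$valid_got, merged2$valid_want)
  expect_equal(merged2$test_got, merged2$test_want)
})

test_that("per-image assignment is a seeded partition", {
  manifest <- tibble::tibble(
    path = sprintf("img%03d.png", 1:50),
    class = rep(c("a", "b"), each = 25))
  c1 <- split_dataset(manifest, seed = 7)
  a1 <- attr(c1, "assignment")
  expect_equal(nrow(a1), 50)
  expect_equal(anyDuplicated(a1$path), 0)
  expect_equal(sort(unique(a1$subset)), c("test", "train", "valid"))
  a2 <- attr(split_dataset(manifest, seed = 7), "assignment")
  expect_identical(dplyr::arrange(a1, .data$path), dplyr::arrange(a2, .data$path))
  a3 <- attr(split_dataset(manifest, seed = 8), "assignment")
  expect_false(identical(dplyr::arrange(a1, .data$path)$subset,
                         dplyr::arrange(a3, .data$path)$subset))
})

test_that("cutout zeroes one square and nothing else", {
  img <- array(1, c(64, 64, 3))
  expect_identical(cutout(img, 0), img)
  # find a seed whose region is fully interior, then the count is exact
  for (s in 1:100) {
    out <- cutout(img, 16, seed = s)
    nz <- sum(out == 0)
    expect_lte(nz, 16 * 16 * 3)
    if (nz == 16 * 16 * 3) break
  }
  expect_equal(nz, 16 * 16 * 3)
  # zeroed pixels form one contiguous rectangle; everything else untouched
  mask <- out[, , 1] == 0
  rows <- range(which(rowSums(mask) > 0)); cols <- range(which(colSums(mask) > 0))
  expect_true(all(mask[rows[1]:rows[2], cols[1]:cols[2]]))
  expect_equal(sum(out != img), nz)
})

test_that("grid mask multiplies by a same-resolution periodic binary mask", {
  set.seed(4)
  img <- array(runif(48 * 48 * 3, min = 0.2), c(48, 48, 3))
  expect_identical(grid_mask(img, ratio = 1, period = 8), img)
  out <- grid_mask(img, ratio = 0.6, period = 8, seed = 2)
  expect_equal(dim(out), dim(img))
  # every pixel is either kept exactly or zeroed (binary mask)
  kept <- out == img
  expect_true(all(kept | out == 0))
  masked_frac <- mean(out[, , 1] == 0)
  side <- round(8 * sqrt(1 - 0.6))
  expect_equal(masked_frac, (side / 8)^2, tolerance = 0.1)
})

test_that("random erasing is seeded and bounded", {
  img <- array(0.5, c(64, 64, 3))
  expect_identical(random_erasing(img, prob = 0, seed = 1), img)
  o1 <- random_erasing(img, prob = 1, seed = 42)
  o2 <- random_erasing(img, prob = 1, seed = 42)
  expect_identical(o1, o2)
  changed <- mean(o1[, , 1] != 0.5)
  expect_gte(changed, 0.01)
  expect_lte(changed, 0.40)
})

test_that("photometric transforms match their closed forms", {
  set.seed(5)
  img <- array(runif(32 * 32 * 3, 0, 0.5), c(32, 32, 3))
  expect_equal(photometric_transform(img, "brightness", 1), img)
  expect_equal(photometric_transform(img, "contrast", 1), img)
  expect_equal(photometric_transform(img, "brightness", 2), 2 * img)
  ct <- photometric_transform(img, "contrast", 1.5)
  expect_equal(ct, pmin(pmax(mean(img) + 1.5 * (img - mean(img)), 0), 1))
  bright <- photometric_transform(array(0.9, c(4, 4, 3)), "brightness", 2)
  expect_true(all(bright <= 1))
  proto <- robustness_protocol()
  expect_equal(nrow(proto), 8)
  expect_setequal(unique(proto$factor), c(0.5, 0.67, 1.5, 2))
})

test_that("image folder write/read/load round-trips", {
  dir <- file.path(tempdir(), "synthfolder")
  unlink(dir, recursive = TRUE)
  synth <- generate_synthetic_leaves(
    synth_spec(n_per_class = 2, resolution = 32, seed = 4), dir = dir)
  man <- read_image_folder(dir)
  expect_equal(nrow(man), 12)
  expect_setequal(unique(man$class), c("FA", "GLS", "LB", "LH", "NLS", "RL"))
  imgs <- load_images(man[1:3, ], 32)
  expect_equal(dim(imgs), c(32, 32, 3, 3))
  expect_true(all(imgs >= 0 & imgs <= 1))
})
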