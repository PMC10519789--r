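test_that("generator is seeded, uniform over classes, and in range", {
  spec <- synth_spec(n_per_class = 3, resolution = 32, seed = 21)
  s1 <- generate_synthetic_leaves(spec)
  s2 <- generate_synthetic_leaves(spec)
  expect_identical(s1$images, s2$images)   # byte-identical per seed
  expect_equal(dim(s1$images), c(32, 32, 3, 18))
  expect_equal(as.vector(table(s1$manifest$class)), rep(3L, 6))
  expect_true(all(is.finite(s1$images)))
  expect_gte(min(s1$images), 0); expect_lte(max(s1$images), 1)
  s3 <- generate_synthetic_leaves(synth_spec(n_per_class = 3, resolution = 32,
                                             seed = 22))
  expect_false(identical(s1$images, s3$images))
  expect_error(synth_spec(n_per_class = 1), "n_per_class")
  expect_error(synth_spec(resolution = 16), "resolution")
})

test_that("written files are byte-identical for the same seed", {
  spec <- synth_spec(n_per_class = 2, resolution = 32, seed = 5)
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_synthetic_leaves(spec, dir = d1)
  generate_synthetic_leaves(spec, dir = d2)
  f1 <- list.files(d1, pattern = "png$", recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, pattern = "png$", recursive = TRUE, full.names = TRUE)
  expect_equal(length(f1), 12)
  expect_identical(lapply(f1, function(f) readBin(f, "raw", 1e6)),
                   lapply(f2, function(f) readBin(f, "raw", 1e6)))
})

test_that("classes are linearly separable from crude features", {
  skip_if_not_installed("nnet")
  synth <- generate_synthetic_leaves(
    synth_spec(n_per_class = 20, resolution = 48, background_clutter = 0.2,
               seed = 31))
  acc <- linear_probe_accuracy(synth, seed = 1)
  expect_gte(acc, 0.5)   # far above the 1/6 chance level
})

test_that("background clutter is a difficulty dial for the probe", {
  skip_if_not_installed("nnet")
  accs <- sapply(c(0, 1), function(cl)
    linear_probe_accuracy(generate_synthetic_leaves(
      synth_spec(n_per_class = 20, resolution = 48, background_clutter = cl,
                 seed = 33)), seed = 2))
  expect_gt(accs[1], accs[2])
})

test_that("synth_split partitions the set 8:1:1 per class", {
  synth <- generate_synthetic_leaves(synth_spec(n_per_class = 10,
                                                resolution = 32, seed = 3))
  data <- synth_split(synth, seed = 3)
  expect_equal(length(data$train$y), 48)
  expect_equal(length(data$valid$y), 6)
  expect_equal(length(data$test$y), 6)
  expect_equal(sort(unique(data$train$y)), 1:6)
  expect_equal(dim(data$train$x)[4], 48)
})
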