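test_that("metrics reproduce the published per-class evaluation", {
  ref <- corn_reference_counts()
  cm <- cm_from_counts(ref$tp, ref$fp, ref$fn, ref$class)
  expect_equal(sum(cm), 325)
  met <- compute_metrics(cm)
  pc <- met$per_class
  # reconstructed counts match the published ones, including TN
  expect_equal(pc$tp, ref$tp); expect_equal(pc$fp, ref$fp)
  expect_equal(pc$fn, ref$fn); expect_equal(pc$tn, ref$tn)
  # per-class precision / recall / F1 at printed precision
  expect_equal(round(pc$precision, 4), c(0.9773, 1, 0.9857, 1, 1, 0.9545))
  expect_equal(round(pc$recall, 4), c(1, 0.9672, 1, 0.9815, 1, 0.9767))
  expect_equal(round(pc$f1, 4), c(0.9885, 0.9833, 0.9928, 0.9907, 1, 0.9655))
  # macro averages as printed
  expect_equal(round(met$macro_precision, 4), 0.9863)
  expect_equal(round(met$macro_recall, 4), 0.9876)
  expect_equal(round(met$macro_f1, 4), 0.9868)
  expect_equal(round(met$accuracy, 4), 0.9877)
  expect_equal(met$accuracy, 321 / 325)
})

test_that("identity confusion matrix scores 1 everywhere; degenerate cases warn", {
  cm <- structure(diag(c(10L, 20L, 30L)),
                  class = c("confusion_matrix", "matrix"))
  met <- compute_metrics(cm)
  expect_equal(met$accuracy, 1)
  expect_equal(met$per_class$f1, rep(1, 3))
  expect_equal(met$macro_precision, 1)
  # a class never predicted: zero-denominator precision -> 0 with warning
  m <- matrix(c(5L, 0L, 3L, 0L), 2, 2)
  expect_warning(met0 <- compute_metrics(structure(m, class = c("confusion_matrix", "matrix"))),
                 "zero denominator")
  expect_equal(met0$per_class$precision[2], 0)
  expect_error(compute_metrics(structure(matrix(0L, 2, 2),
                                         class = c("confusion_matrix", "matrix"))),
               "empty")
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(10)
  for (k in c(3, 5)) {
    truth <- factor(sample(letters[1:k], 300, replace = TRUE))
    pred <- truth
    flip <- sample(300, 90)
    pred[flip] <- sample(factor(letters[1:k]), 90, replace = TRUE)
    cm <- confusion_matrix(truth, pred, levels = letters[1:k])
    met <- compute_metrics(cm)
    ref <- caret::confusionMatrix(factor(pred, letters[1:k]),
                                  factor(truth, letters[1:k]))
    expect_equal(met$accuracy, as.numeric(ref$overall["Accuracy"]),
                 tolerance = 1e-12)
    ref_by <- ref$byClass
    expect_equal(met$per_class$recall, unname(ref_by[, "Sensitivity"]),
                 tolerance = 1e-12)
    prec_ref <- unname(ref_by[, "Precision"])
    prec_ref[is.na(prec_ref)] <- 0
    expect_equal(met$per_class$precision, prec_ref, tolerance = 1e-12)
  }
})

test_that("accuracy from per-class counts matches the off-diagonal rule", {
  ref <- corn_reference_counts()
  expect_equal(round(accuracy_from_per_class(ref$tp, ref$fp, 325), 4), 0.9877)
  expect_equal(accuracy_from_per_class(c(10, 20), c(0, 0), 30), 1)
  expect_equal(accuracy_from_per_class(c(0, 0), c(15, 15), 30), 0)
  expect_error(accuracy_from_per_class(c(10, 10), c(1, 1), 20), "inconsistent")
})

test_that("grad-cam matches the closed-form head-layer oracle", {
  m <- build_model(tiny_spec(), seed = 4)
  img <- tiny_images(1, 32, seed = 9)[, , , 1]
  cam <- grad_cam(m, img, target_class = 2, layer = "head")
  # oracle: for the head layer, d logit_c / d A[h,w,k] = fc_w[k,c] / (H*W),
  # so channel weights are fc_w[, c] / (H*W) up to the constant pool factor
  collect <- new.env()
  invisible(fcaenet:::forward_model(m, array(img, c(dim(img), 1)),
                                    collect = collect))
  ad <- dim(collect$head$v)
  hw <- ad[1] * ad[2]
  wts <- m$children$fc$params$w$v[, 2] / hw
  oracle <- matrix(matrix(collect$head$v, hw, ad[3]) %*% wts, ad[1], ad[2])
  oracle <- fcaenet:::bilinear_resize(pmax(oracle, 0), 32, 32)
  if (max(oracle) > min(oracle))
    oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  else oracle[] <- 0
  expect_equal(unclass(cam), oracle, tolerance = 1e-8)
})

test_that("grad-cam output is a normalized map of the input size", {
  m <- build_model(tiny_spec(), seed = 5)
  img <- tiny_images(1, 32, seed = 10)[, , , 1]
  cam <- grad_cam(m, img, target_class = 1)  # default deepest-stage layer
  expect_equal(dim(cam), c(32, 32))
  expect_gte(min(cam), 0)
  expect_lte(max(cam), 1)
  expect_error(grad_cam(m, img, target_class = 9), "out of range")
  expect_error(grad_cam(m, img, 1, layer = "nope"), "unknown layer")
})

test_that("confusion matrix builder and tidiers are consistent", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         levels = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = list(truth = c("a", "b"),
                                                   pred = c("a", "b"))))
  td <- tidy(cm)
  expect_equal(sum(td$n), 3)
  g <- glance(compute_metrics(cm))
  expect_equal(g$n, 3)
  expect_s3_class(autoplot(cm), "ggplot")
})
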