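test_that("learning-rate schedule: linear warmup then exponential decay", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 0.00005)
  expect_equal(lr_at(19, cfg), 0.001)
  expect_equal(lr_at(20, cfg), 0.001)
  expect_equal(lr_at(21, cfg), 0.00099)
  expect_equal(lr_at(60, cfg), 0.001 * 0.99^40)
  expect_error(lr_at(-1, cfg), "out of range")
  expect_error(lr_at(200, cfg), "out of range")
  # monotone: non-decreasing through warmup, strictly decreasing after
  lrs <- lr_at(0:199, cfg)
  expect_true(all(diff(lrs[1:21]) >= 0))
  expect_true(all(diff(lrs[21:200]) < 0))
  expect_error(train_config(warmup_epochs = 30, epochs = 20), "warmup")
  expect_error(train_config(gamma = 0), "gamma")
})

test_that("a short training run logs history and stays finite", {
  set.seed(20)
  x <- tiny_images(12, 32, seed = 20)
  y <- rep(1:3, 4)
  m <- build_model(tiny_spec(), seed = 2)
  cfg <- train_config(epochs = 2, warmup_epochs = 1, batch_size = 6, seed = 3)
  fit <- train(m, list(x = x, y = y), list(x = x[, , , 1:6], y = y[1:6]),
               cfg, verbose = FALSE)
  h <- tidy(fit)
  expect_equal(nrow(h), 2)
  expect_true(all(is.finite(h$train_loss)))
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  expect_equal(h$lr, lr_at(0:1, cfg))
  expect_s3_class(glance(fit), "tbl_df")
  expect_error(train(m, list(x = x, y = rep(9L, 12)),
                     list(x = x, y = y), cfg, verbose = FALSE),
               "class count")
})

test_that("training is reproducible for a fixed seed", {
  x <- tiny_images(12, 32, seed = 21)
  y <- rep(1:3, 4)
  run_once <- function() {
    m <- build_model(tiny_spec(), seed = 7)
    cfg <- train_config(epochs = 2, warmup_epochs = 1, batch_size = 6, seed = 5)
    fit <- train(m, list(x = x, y = y), list(x = x[, , , 1:6], y = y[1:6]),
                 cfg, augment = augment_online(cutout_size = 8), verbose = FALSE)
    fit$history$train_loss
  }
  expect_identical(run_once(), run_once())
})

test_that("one optimizer pass overfits a single batch", {
  set.seed(22)
  m <- build_model(tiny_spec(), seed = 6)
  m$classifier_dropout <- 0
  x <- tiny_images(6, 32, seed = 22)
  y <- rep(1:3, 2)
  params <- fcaenet:::model_param_list(m)
  st <- fcaenet:::adam_state(params)
  losses <- numeric(50)
  for (it in 1:50) {
    rec <- fcaenet:::ag_with_tape({
      o <- fcaenet:::forward_model(m, x, training = TRUE)
      fcaenet:::op_softmax_xent(o$logits, y)
    })
    losses[it] <- rec$value$v
    fcaenet:::ag_zero_grad(params)
    fcaenet:::ag_backward(rec$value, rec$tape)
    fcaenet:::adam_step(params, st, 1e-3)
  }
  expect_lt(min(losses), 0.2 * losses[1])
})

test_that("checkpoint round-trip preserves validation metrics exactly", {
  x <- tiny_images(9, 32, seed = 23)
  y <- rep(1:3, 3)
  m <- build_model(tiny_spec(), seed = 8)
  cfg <- train_config(epochs = 2, warmup_epochs = 1, batch_size = 9, seed = 4)
  fit <- train(m, list(x = x, y = y), list(x = x, y = y), cfg, verbose = FALSE)
  before <- evaluate_model(fit$model, x, y)
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  m2 <- load_model(path)
  after <- evaluate_model(m2, x, y)
  expect_identical(before$loss, after$loss)
  expect_identical(before$pred, after$pred)
})

test_that("non-finite loss aborts with a diagnostic", {
  x <- tiny_images(6, 32, seed = 24)
  y <- rep(1:3, 2)
  m <- build_model(tiny_spec(), seed = 9)
  # poison one weight to force divergence
  m$children$fc$params$w$v[] <- 1e308
  cfg <- train_config(epochs = 1, warmup_epochs = 0.5, batch_size = 6, seed = 2)
  expect_error(train(m, list(x = x, y = y), list(x = x, y = y), cfg,
                     verbose = FALSE), "diverged")
})
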