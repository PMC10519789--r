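test_that("swish matches its defining form and limits", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(swish(1), 4), 0.7311)
  expect_lt(abs(swish(-50)), 1e-15)
  x <- seq(-4, 4, by = 0.25)
  expect_equal(swish(x), x * (1 / (1 + exp(-x))))
})

test_that("gelu is the exact normal-CDF form", {
  expect_equal(gelu(0), 0)
  expect_equal(gelu(1), 1 * pnorm(1), tolerance = 1e-9)
  expect_equal(round(gelu(1), 4), 0.8413)
  big <- c(8, 10, 20)
  expect_equal(gelu(big), big, tolerance = 1e-9)
  x <- seq(-4, 4, by = 0.2)
  expect_equal(gelu(x), x * pnorm(x), tolerance = 1e-9)
})

test_that("normalization obeys its statistic scope", {
  set.seed(1)
  # constant input -> zeros for gamma = 1, beta = 0
  xconst <- array(3.7, c(4, 4, 2))
  for (mode in c("BN", "LN")) {
    p <- norm_params(mode, 2)
    expect_equal(max(abs(normalize(xconst, p))), 0, tolerance = 1e-6)
  }
  # LN: per-sample mean ~ 0, variance ~ 1
  x <- array(rnorm(6 * 6 * 3 * 4, mean = 2, sd = 3), c(6, 6, 3, 4))
  y <- normalize(x, norm_params("LN", 3))
  ym <- matrix(y, 6 * 6 * 3, 4)
  expect_equal(colMeans(ym), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(ym, 2, function(z) mean(z^2)), rep(1, 4),
               tolerance = 1e-3)
  expect_error(norm_params("LN", 3, eps = 0), "positive")
})

test_that("LN is bit-identical across batch composition; BN is not", {
  set.seed(2)
  x1 <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  batch <- array(rnorm(5 * 5 * 4 * 8), c(5, 5, 4, 8))
  batch[, , , 3] <- x1
  ln <- norm_params("LN", 4)
  alone <- normalize(x1, ln)
  inside <- normalize(batch, ln)[, , , 3]
  expect_identical(alone, inside)   # bit-identical, not just close
  bn <- norm_params("BN", 4)
  expect_gt(max(abs(normalize(x1, bn) - normalize(batch, bn)[, , , 3])), 1e-3)
})

test_that("fca attention equals the per-pixel brute-force oracle", {
  for (case in list(c(h = 4, w = 4, c = 2), c(h = 8, w = 6, c = 4),
                    c(h = 5, w = 8, c = 3))) {
    set.seed(sum(case))
    mod <- fca_params(case["c"], case["h"], case["w"], reduction = 16,
                      activation = "GELU")
    x <- array(rnorm(prod(case)), dim = c(case["h"], case["w"], case["c"]))
    got <- fca_attention(x, mod)
    want <- fca_oracle(x, mod)$y
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("fca gates lie in (0,1) and zeroed gate weights give exactly 0.5", {
  set.seed(3)
  mod <- fca_params(4, 6, 6)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  orc <- fca_oracle(x, mod)
  expect_true(all(orc$gh > 0 & orc$gh < 1))
  expect_true(all(orc$gw > 0 & orc$gw < 1))
  # zero every gate-producing weight: sigmoid(0) = 0.5 everywhere
  mod$children$gate_h$params$w$v[] <- 0
  mod$children$gate_w$params$w$v[] <- 0
  y <- fca_attention(x, mod)
  expect_equal(y, x * 0.25, tolerance = 1e-12)
})

test_that("fca rejects inputs that differ from its build-time size", {
  mod <- fca_params(2, 4, 4)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  expect_error(fca_attention(x, mod), "built for")
})

test_that("unit gates leave the feature map unchanged", {
  set.seed(4)
  x <- fcaenet:::ag_tensor(array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2)))
  ones_h <- fcaenet:::ag_tensor(array(1, c(4, 1, 3, 2)))
  ones_w <- fcaenet:::ag_tensor(array(1, c(1, 5, 3, 2)))
  expect_equal(fcaenet:::op_scale_hw(x, ones_h, ones_w)$v, x$v)
})

test_that("mbconv residual identity, stride-2 shape, and parameter count", {
  set.seed(5)
  cfg <- block_config(8, 8, expansion = 6, kernel = 3, stride = 1,
                      attention = "FCA", drop_rate = 0.5)
  blk <- mbconv_module(cfg, c(6, 6), norm = "LN", act = "GELU")
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  # forced branch drop: the block is exactly the identity
  expect_identical(fca_mbconv(x, blk, training = TRUE, force_drop = TRUE), x)
  # stride 2 halves space, no residual
  cfg2 <- block_config(8, 12, stride = 2, attention = "FCA")
  blk2 <- mbconv_module(cfg2, c(6, 6), norm = "LN", act = "GELU")
  y2 <- fca_mbconv(x, blk2)
  expect_equal(dim(y2), c(3, 3, 12))
  # parameter hand count for a toy block
  cfg3 <- block_config(4, 10, expansion = 6, kernel = 3, stride = 1,
                       attention = "FCA")
  blk3 <- mbconv_module(cfg3, c(8, 8), norm = "BN", act = "Swish")
  expect_equal(count_params(blk3),
               mbconv_param_oracle(4, 10, 6, 3, 8, "FCA"))
  cfg4 <- block_config(4, 10, attention = "SE")
  blk4 <- mbconv_module(cfg4, c(8, 8), norm = "BN", act = "Swish")
  expect_equal(count_params(blk4), mbconv_param_oracle(4, 10, 6, 3, 8, "SE"))
  expect_error(fca_mbconv(array(0, c(6, 6, 5)), blk), "channel")
})

test_that("adaptive fusion reduces to each branch and matches a hand computation", {
  set.seed(6)
  af <- af_module(in_channels = 1, out_channels = 1, pool = 2)
  # identity 1x1 projection
  af$children$proj$params$w$v[] <- 1
  af$children$proj$params$b$v[] <- 0
  x <- array(rnorm(4 * 4), c(4, 4, 1))
  backbone <- array(rnorm(2 * 2), c(2, 2, 1))
  pooled <- array(0, c(2, 2, 1))
  for (i in 1:2) for (j in 1:2)
    pooled[i, j, 1] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), 1])
  expect_equal(adaptive_fusion(x, backbone, af, w = c(0, 1)), backbone)
  expect_equal(adaptive_fusion(x, backbone, af, w = c(1, 0)), pooled)
  expect_equal(adaptive_fusion(x, backbone, af, w = c(0.5, 0.5)),
               (pooled + backbone) / 2)
  bad <- array(rnorm(3 * 3), c(3, 3, 1))
  expect_error(adaptive_fusion(x, bad, af), "match")
})
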