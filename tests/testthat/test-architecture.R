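test_that("classifier head size moves the count by exactly the fc delta", {
  b6 <- build_model(spec_efficientnet_b0(), seed = 1)
  b1000 <- build_model(spec_efficientnet_b0(num_classes = 1000), seed = 1)
  # arithmetic oracle: only the fully connected layer changes
  expect_equal(count_params(b1000),
               count_params(b6) - (1280 * 6 + 6) + (1280 * 1000 + 1000))
  expect_equal(round(count_params(b1000) / 1e6, 2), 5.29)
})

test_that("a single bias-free 1x1 conv counts its weights exactly", {
  m <- fcaenet:::mod_conv(3L, 6L, 1L, bias = FALSE)
  expect_equal(count_params(m), 18)
  m1 <- fcaenet:::mod_conv(1L, 1L, 1L, bias = FALSE)
  expect_equal(count_params(m1), 1)
})

test_that("stage-trim deltas are pure block-count multiples", {
  counts <- sapply(list(c(2, 2, 2), c(2, 2, 3), c(2, 2, 4),
                        c(2, 3, 2), c(3, 2, 2)), function(l)
    count_params(build_model(arch_spec(layers_567 = l), seed = 1)))
  d7a <- counts[2] - counts[1]
  d7b <- counts[3] - counts[2]
  expect_equal(d7a, d7b)                       # one stage-7 block each
  a6 <- counts[4] - counts[1]
  a5 <- counts[5] - counts[1]
  # the three per-stage tail-block sizes are distinct and ordered by depth
  expect_true(a5 < a6 && a6 < d7a)
})

test_that("adding adaptive fusion changes the count by < 0.005M at any node", {
  base <- count_params(build_model(
    arch_spec(attention = "SE", norm = "BN", activation = "Swish",
              af_node = "none", layers_567 = c(3, 3, 4)), seed = 1))
  for (node in c("node1", "node2", "node3")) {
    withaf <- count_params(build_model(
      arch_spec(attention = "SE", norm = "BN", activation = "Swish",
                af_node = node, layers_567 = c(3, 3, 4)), seed = 1))
    expect_lt(withaf - base, 5000)
    expect_gt(withaf - base, 0)
  }
})

test_that("search space enumerates the twelve printed triples in order", {
  grid <- enumerate_search_space()
  expect_equal(nrow(grid), 12)
  expect_equal(unlist(grid[4, c("s5", "s6", "s7")], use.names = FALSE),
               c(2, 3, 2))
  expect_equal(unlist(grid[12, c("s5", "s6", "s7")], use.names = FALSE),
               c(3, 3, 4))
  expect_true(all(grid$s5 <= 3 & grid$s6 <= 3 & grid$s7 <= 4))
  expect_true(all(grid$s5 >= 2 & grid$s6 >= 2 & grid$s7 >= 2))
})

test_that("building twice from one spec and seed is identical", {
  spec <- tiny_spec()
  m1 <- build_model(spec, seed = 9)
  m2 <- build_model(spec, seed = 9)
  expect_identical(fcaenet:::snapshot_params(m1), fcaenet:::snapshot_params(m2))
  x <- tiny_images(2, 32, seed = 5)
  o1 <- fcaenet:::forward_model(m1, x)$logits$v
  o2 <- fcaenet:::forward_model(m2, x)$logits$v
  expect_identical(o1, o2)
})

test_that("forward pass yields per-class logits whose softmax sums to one", {
  m <- build_model(tiny_spec(), seed = 2)
  x <- tiny_images(3, 32, seed = 6)
  z <- fcaenet:::forward_model(m, x)$logits$v
  expect_equal(dim(z), c(3L, 3L))
  p <- apply(z, 2, function(col) exp(col - max(col)) / sum(exp(col - max(col))))
  expect_equal(colSums(p), rep(1, 3))
  expect_error(fcaenet:::forward_model(m, tiny_images(1, 64)), "expected input")
})

test_that("stage outputs follow the published resolution plan at 224", {
  m <- build_model(arch_spec(layers_567 = c(2, 3, 2)), seed = 1)
  collect <- new.env()
  x <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  invisible(fcaenet:::forward_model(m, x, collect = collect))
  dims <- function(nm) dim(collect[[nm]]$v)[1:3]
  expect_equal(dims("stem"), c(112, 112, 32))
  expect_equal(dims("s2b1"), c(112, 112, 16))
  expect_equal(dims("s3b2"), c(56, 56, 24))
  expect_equal(dims("s4b2"), c(28, 28, 40))
  expect_equal(dims("s5b2"), c(14, 14, 80))
  expect_equal(dims("s6b3"), c(14, 14, 112))
  expect_equal(dims("s7b2"), c(7, 7, 192))
  expect_equal(dims("s8b1"), c(7, 7, 320))
  expect_equal(dims("head"), c(7, 7, 1280))
})

test_that("stochastic-depth rates reproduce the published per-stage factors", {
  m <- build_model(arch_spec(layers_567 = c(2, 3, 2)), seed = 1)
  meta <- m$block_meta
  rate_of <- function(key) meta[[key]]$cfg$drop_rate
  expect_equal(rate_of("s2b1"), 0.0125)
  expect_equal(rate_of("s3b1"), 0.025)
  expect_equal(rate_of("s4b1"), 0.05)
  expect_equal(rate_of("s5b1"), 0.075)
  expect_equal(rate_of("s6b1"), 0.1)
  expect_equal(rate_of("s7b1"), 0.1375)
  expect_equal(rate_of("s8b1"), 0.1625)
})

test_that("invalid specs are rejected with a message", {
  expect_error(arch_spec(layers_567 = c(4, 3, 2)), "layers_567")
  expect_error(arch_spec(layers_567 = c(0, 3, 2)), "layers_567")
  expect_error(arch_spec(af_node = "node9"))
  expect_error(arch_spec(input_resolution = 100), "multiple of 32")
})

test_that("config files round-trip through yaml and json", {
  spec <- arch_spec(attention = "CA", norm = "BN", activation = "Swish",
                    af_node = "node1", layers_567 = c(3, 2, 4),
                    num_classes = 4, input_resolution = 96)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_arch_config(spec, path)
    spec2 <- read_arch_config(path)
    expect_equal(spec2[setdiff(names(spec2), "class_names")],
                 spec[setdiff(names(spec), "class_names")])
  }
})

test_that("model summary mirrors the layer-plan table", {
  m <- build_model(arch_spec(layers_567 = c(2, 3, 2)), seed = 1)
  s <- model_summary(m)
  expect_equal(nrow(s), 9)
  expect_equal(s$channels, c(32L, 16L, 24L, 40L, 80L, 112L, 192L, 320L, 1280L))
  expect_equal(s$layers[2:8], c(1L, 2L, 2L, 2L, 3L, 2L, 1L))
  expect_equal(s$resolution[1], "224x224")
  expect_equal(attr(s, "total_params"), count_params(m))
  g <- glance(m)
  expect_equal(g$params, count_params(m))
})
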