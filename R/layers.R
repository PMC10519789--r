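# Module constructors.  A module is a list: type, cfg (static configuration),
# params (named list of ag_tensor), children (named list of sub-modules), and
# a forward(mod, x, ctx) function.  ctx is an environment carrying `training`,
# an optional `collect` environment for named activations (Grad-CAM), and the
# test-only `force_drop` switch for stochastic depth.

new_module <- function(type, cfg = list(), params = list(), children = list(),
                       forward) {
  structure(list(type = type, cfg = cfg, params = params,
                 children = children, forward = forward),
            class = "fcaenet_module")
}

run_module <- function(mod, x, ctx) mod$forward(mod, x, ctx)

init_conv_w <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cout))
  ag_tensor(array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                  dim = c(kh, kw, cin, cout)), requires_grad = TRUE)
}

init_dwconv_w <- function(kh, kw, c) {
  sd <- sqrt(2 / (kh * kw))
  ag_tensor(array(stats::rnorm(kh * kw * c, sd = sd), dim = c(kh, kw, c)),
            requires_grad = TRUE)
}

zeros_param <- function(n) ag_tensor(array(0, dim = n), requires_grad = TRUE)
ones_param <- function(n) ag_tensor(array(1, dim = n), requires_grad = TRUE)

mod_conv <- function(cin, cout, k = 1L, stride = 1L, pad = "same", bias = FALSE) {
  params <- list(w = init_conv_w(k, k, cin, cout))
  if (bias) params$b <- zeros_param(cout)
  new_module("conv",
             cfg = list(cin = cin, cout = cout, k = k, stride = stride,
                        pad = pad, bias = bias),
             params = params,
             forward = function(mod, x, ctx)
               op_conv2d(x, mod$params$w, mod$params$b, mod$cfg$stride, mod$cfg$pad))
}

mod_dwconv <- function(c, kh, kw = kh, stride = 1L, pad = "same", bias = FALSE) {
  params <- list(w = init_dwconv_w(kh, kw, c))
  if (bias) params$b <- zeros_param(c)
  new_module("dwconv",
             cfg = list(c = c, kh = kh, kw = kw, stride = stride, pad = pad,
                        bias = bias),
             params = params,
             forward = function(mod, x, ctx)
               op_dwconv2d(x, mod$params$w, mod$params$b, mod$cfg$stride, mod$cfg$pad))
}

#' Normalization parameters
#'
#' Bundles the learnable per-channel scale/shift and the statistic scope for a
#' normalization layer: `"BN"` (batch statistics per channel over batch and
#' space, with running statistics for inference) or `"LN"` (per-sample
#' statistics over all channels and positions, batch-size independent).
#'
#' @param mode `"BN"` or `"LN"`.
#' @param channels number of feature channels.
#' @param eps small positive stabilizer added to the variance.
#' @param gamma,beta optional per-channel scale and shift (default 1 and 0).
#' @return a normalization module usable with [normalize()].
#' @export
norm_params <- function(mode = c("BN", "LN"), channels, eps = NULL,
                        gamma = NULL, beta = NULL) {
  mode <- match.arg(mode)
  if (is.null(eps)) eps <- if (mode == "BN") 1e-5 else 1e-6
  if (eps <= 0) abort("epsilon must be positive")
  g <- if (is.null(gamma)) ones_param(channels) else {
    stopifnot(length(gamma) == channels)
    ag_tensor(array(gamma, channels), requires_grad = TRUE)
  }
  b <- if (is.null(beta)) zeros_param(channels) else {
    stopifnot(length(beta) == channels)
    ag_tensor(array(beta, channels), requires_grad = TRUE)
  }
  running <- new.env(parent = emptyenv())
  running$mean <- rep(0, channels); running$var <- rep(1, channels)
  new_module("norm",
             cfg = list(mode = mode, channels = channels, eps = eps,
                        momentum = 0.1, running = running),
             params = list(gamma = g, beta = b),
             forward = function(mod, x, ctx) {
               if (mod$cfg$mode == "BN")
                 op_batchnorm(x, mod$params$gamma, mod$params$beta, mod$cfg$eps,
                              running = mod$cfg$running,
                              momentum = mod$cfg$momentum,
                              training = isTRUE(ctx$training))
               else
                 op_layernorm(x, mod$params$gamma, mod$params$beta, mod$cfg$eps)
             })
}

mod_act <- function(kind) {
  f <- activation_op(kind)
  new_module("act", cfg = list(kind = kind),
             forward = function(mod, x, ctx) f(x))
}

mod_linear <- function(cin, cout) {
  bound <- 1 / sqrt(cin)
  new_module("linear", cfg = list(cin = cin, cout = cout),
             params = list(
               w = ag_tensor(matrix(stats::runif(cin * cout, -bound, bound), cin, cout),
                             requires_grad = TRUE),
               b = zeros_param(cout)),
             forward = function(mod, x, ctx)
               op_linear(x, mod$params$w, mod$params$b))
}

# Sequential helper
run_seq <- function(mods, x, ctx) {
  for (m in mods) x <- run_module(m, x, ctx)
  x
}

module_params <- function(mod, prefix = "") {
  out <- list()
  if (length(mod$params))
    out <- stats::setNames(mod$params, paste0(prefix, names(mod$params)))
  for (nm in names(mod$children))
    out <- c(out, module_params(mod$children[[nm]], paste0(prefix, nm, ".")))
  out
}

n_params <- function(mod) sum(vapply(module_params(mod), function(p) length(p$v), 0))
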