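# The network's computational units: activations, attention modules
# (squeeze-excitation, coordinate attention, fully convolutional coordinate
# attention), the inverted-residual block built around them, and the
# adaptive-fusion stem.  Each has a functional, array-in/array-out surface
# for direct use and testing, plus the module form used by the model builder.

#' Swish activation
#'
#' Elementwise `x * sigmoid(x)`.
#'
#' @param x numeric vector or array.
#' @return object of the same shape.
#' @export
#' @examples
#' swish(c(-5, 0, 1))
swish <- function(x) {
  stopifnot(all(is.finite(x)))
  x / (1 + exp(-x))
}

#' Exact GELU activation
#'
#' Elementwise `x * pnorm(x)` — the exact Gaussian-CDF form, not the tanh
#' approximation.
#'
#' @inheritParams swish
#' @return object of the same shape.
#' @export
#' @examples
#' gelu(c(0, 1))
gelu <- function(x) {
  stopifnot(all(is.finite(x)))
  x * stats::pnorm(x)
}

# promote (H,W,C) to (H,W,C,1); remember whether to drop the batch dim
with_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    abort("expected an (H, W, C) or (H, W, C, N) array")
  if (length(d) == 3L) list(x = array(x, c(d, 1L)), drop = TRUE)
  else list(x = x, drop = FALSE)
}

drop_batch <- function(v, drop) {
  if (drop) array(v, dim(v)[1:3]) else v
}

#' Apply batch or layer normalization
#'
#' Normalizes `(x - mean) / sqrt(var + eps) * gamma + beta` under the
#' statistic scope declared in `params`: per-channel batch statistics for
#' `"BN"`, per-sample statistics over all `C*H*W` elements for `"LN"`.  LN
#' output for a sample is independent of the other samples in the batch; BN
#' output generally is not.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)`.
#' @param params a module from [norm_params()].
#' @param training for BN, whether to use batch statistics (and update the
#'   running ones) or the stored running statistics.
#' @return normalized array of the same shape.
#' @export
normalize <- function(x, params, training = TRUE) {
  b <- with_batch(x)
  ctx <- new.env(parent = emptyenv()); ctx$training <- training
  y <- run_module(params, ag_tensor(b$x), ctx)
  drop_batch(y$v, b$drop)
}

# --- attention modules -----------------------------------------------------

# Squeeze-and-excitation: global average pool -> bottleneck of width
# max(1, block_cin / 4) -> gate.  Bottleneck convs carry biases, matching the
# reference EfficientNet.
mod_se <- function(cexp, cin_block, act_kind) {
  sq <- max(1L, cin_block %/% 4L)
  new_module("se", cfg = list(cexp = cexp, sq = sq),
             children = list(
               fc1 = mod_conv(cexp, sq, 1L, bias = TRUE),
               act = mod_act(act_kind),
               fc2 = mod_conv(sq, cexp, 1L, bias = TRUE)),
             forward = function(mod, x, ctx) {
               s <- op_gap_keep(x)
               s <- run_module(mod$children$fc1, s, ctx)
               s <- run_module(mod$children$act, s, ctx)
               s <- op_sigmoid(run_module(mod$children$fc2, s, ctx))
               op_scale_c(x, s)
             })
}

# Coordinate attention (kind = "CA") pools the expanded map along each
# spatial direction; its fully convolutional variant (kind = "FCA") replaces
# the directional average pooling with full-extent directional depthwise
# convolutions (kernels 1 x W and H x 1, no padding), which binds the module
# to its build-time spatial size.  Both then share the bottleneck: the H x 1
# and (transposed) W x 1 maps are concatenated along the spatial axis, mixed
# by a 1x1 convolution down to max(C/r, 8) channels with the model-wide
# activation, split back, and expanded to per-direction sigmoid gates.
mod_coord_attention <- function(kind, cexp, h, w, reduction, act_kind) {
  mid <- max(cexp %/% reduction, 8L)
  children <- list(
    mix = mod_conv(cexp, mid, 1L, bias = FALSE),
    act = mod_act(act_kind),
    gate_h = mod_conv(mid, cexp, 1L, bias = FALSE),
    gate_w = mod_conv(mid, cexp, 1L, bias = FALSE))
  if (kind == "FCA") {
    children$dir_w <- mod_dwconv(cexp, 1L, w, pad = "valid", bias = FALSE)  # 1 x W -> (H, 1)
    children$dir_h <- mod_dwconv(cexp, h, 1L, pad = "valid", bias = FALSE)  # H x 1 -> (1, W)
  }
  new_module("coord_att",
             cfg = list(kind = kind, cexp = cexp, h = h, w = w, mid = mid,
                        reduction = reduction),
             children = children,
             forward = function(mod, x, ctx) {
               d <- dim(x$v)
               if (mod$cfg$kind == "FCA" &&
                   (d[1] != mod$cfg$h || d[2] != mod$cfg$w))
                 abort(sprintf(
                   "fca_attention: input is %dx%d but directional kernels were built for %dx%d",
                   d[1], d[2], mod$cfg$h, mod$cfg$w))
               if (mod$cfg$kind == "FCA") {
                 zh <- run_module(mod$children$dir_w, x, ctx)   # (H, 1, C)
                 zw <- run_module(mod$children$dir_h, x, ctx)   # (1, W, C)
               } else {
                 zh <- op_mean_w(x)
                 zw <- op_mean_h(x)
               }
               u <- op_concat_h(zh, op_transpose_hw(zw))        # (H+W, 1, C)
               f <- run_module(mod$children$act,
                               run_module(mod$children$mix, u, ctx), ctx)
               fh <- op_slice_h(f, seq_len(d[1]))
               fw <- op_transpose_hw(op_slice_h(f, d[1] + seq_len(d[2])))
               gh <- op_sigmoid(run_module(mod$children$gate_h, fh, ctx))
               gw <- op_sigmoid(run_module(mod$children$gate_w, fw, ctx))
               op_scale_hw(x, gh, gw)
             })
}

mod_attention <- function(kind, cexp, cin_block, h, w, reduction, act_kind) {
  switch(kind,
    SE = mod_se(cexp, cin_block, act_kind),
    CA = mod_coord_attention("CA", cexp, h, w, reduction, act_kind),
    FCA = mod_coord_attention("FCA", cexp, h, w, reduction, act_kind),
    none = new_module("identity", forward = function(mod, x, ctx) x),
    abort(paste0("unknown attention kind '", kind, "'")))
}

#' Build a fully convolutional coordinate-attention module
#'
#' @param channels expanded channel width the module operates on.
#' @param height,width spatial size the directional kernels are built for;
#'   inputs of any other size are rejected.
#' @param reduction channel reduction ratio `r`; the bottleneck width is
#'   `max(channels / r, 8)`.  The default 16 is the width at which the
#'   module's parameter cost matches the published complexity of the
#'   architecture family (see the package vignette).
#' @param activation nonlinearity after the mixing convolution.
#' @return an attention module; apply it with [fca_attention()].
#' @export
fca_params <- function(channels, height, width, reduction = 16L,
                       activation = c("GELU", "Swish", "ReLU")) {
  activation <- match.arg(activation)
  mod_coord_attention("FCA", channels, height, width, reduction, activation)
}

#' Apply (fully convolutional) coordinate attention
#'
#' Computes directional descriptors of the expanded feature map (full-extent
#' depthwise convolutions `1 x W` and `H x 1`), mixes them through a reduced
#' 1x1 convolution, and rescales the input by the resulting per-row and
#' per-column sigmoid gates: `y[i, j] = x[i, j] * g_h[i] * g_w[j]`.
#'
#' @param xhat array `(H, W, C)` or `(H, W, C, N)` — the expanded feature map.
#' @param params module from [fca_params()] (or `ca_params()` for the pooled
#'   variant).
#' @return array of the same shape as `xhat`.
#' @export
fca_attention <- function(xhat, params) {
  b <- with_batch(xhat)
  ctx <- new.env(parent = emptyenv()); ctx$training <- FALSE
  y <- run_module(params, ag_tensor(b$x), ctx)
  drop_batch(y$v, b$drop)
}

#' @rdname fca_params
#' @export
ca_params <- function(channels, reduction = 16L,
                      activation = c("GELU", "Swish", "ReLU")) {
  activation <- match.arg(activation)
  mod_coord_attention("CA", channels, NA_integer_, NA_integer_, reduction,
                      activation)
}

# --- inverted residual block ----------------------------------------------

#' Configuration of one inverted-residual block
#'
#' @param in_channels,out_channels channel widths.
#' @param expansion expansion factor `t` (1 or 6); the expanded width is
#'   `t * in_channels` and the 1x1 expansion convolution is omitted at t = 1.
#' @param kernel depthwise kernel size (3 or 5).
#' @param stride 1 or 2; the residual connection exists iff `stride == 1` and
#'   `in_channels == out_channels`.
#' @param attention one of `"SE"`, `"CA"`, `"FCA"`, `"none"`.
#' @param drop_rate stochastic-depth rate for the residual branch, in `[0, 1)`.
#' @return a `block_config` list.
#' @export
block_config <- function(in_channels, out_channels, expansion = 6L,
                         kernel = 3L, stride = 1L,
                         attention = c("FCA", "SE", "CA", "none"),
                         drop_rate = 0) {
  attention <- match.arg(attention)
  stopifnot(expansion %in% c(1L, 6L), kernel %in% c(3L, 5L),
            stride %in% c(1L, 2L), drop_rate >= 0, drop_rate < 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 expansion = as.integer(expansion), kernel = as.integer(kernel),
                 stride = as.integer(stride), attention = attention,
                 drop_rate = drop_rate),
            class = "block_config")
}

# h_in/w_in: input spatial size (needed to size FCA's directional kernels,
# which see the post-stride map)
mod_mbconv <- function(cfg, norm_mode, act_kind, h_in, w_in, reduction = 16L) {
  cexp <- cfg$in_channels * cfg$expansion
  h_out <- if (cfg$stride == 2L) ceiling(h_in / 2) else h_in
  w_out <- if (cfg$stride == 2L) ceiling(w_in / 2) else w_in
  children <- list()
  if (cfg$expansion > 1L) {
    children$expand <- mod_conv(cfg$in_channels, cexp, 1L)
    children$expand_norm <- norm_params(norm_mode, cexp)
  }
  children$dw <- mod_dwconv(cexp, cfg$kernel, stride = cfg$stride)
  children$dw_norm <- norm_params(norm_mode, cexp)
  children$act <- mod_act(act_kind)
  children$att <- mod_attention(cfg$attention, cexp, cfg$in_channels,
                                h_out, w_out, reduction, act_kind)
  children$project <- mod_conv(cexp, cfg$out_channels, 1L)
  children$project_norm <- norm_params(norm_mode, cfg$out_channels)
  residual <- cfg$stride == 1L && cfg$in_channels == cfg$out_channels
  new_module("mbconv",
             cfg = list(block = cfg, residual = residual, h_in = h_in,
                        w_in = w_in, h_out = h_out, w_out = w_out,
                        cexp = cexp, norm = norm_mode, act = act_kind),
             children = children,
             forward = function(mod, x, ctx) {
               ch <- mod$children
               if (dim(x$v)[3] != mod$cfg$block$in_channels)
                 abort("mbconv: input channel count does not match configuration")
               x0 <- x
               if (!is.null(ch$expand))
                 x <- run_module(ch$act,
                                 run_module(ch$expand_norm,
                                            run_module(ch$expand, x, ctx), ctx), ctx)
               x <- run_module(ch$act,
                               run_module(ch$dw_norm,
                                          run_module(ch$dw, x, ctx), ctx), ctx)
               if (!is.null(ctx$collect) && !is.null(mod$cfg$name_xhat))
                 ctx$collect[[mod$cfg$name_xhat]] <- x
               x <- run_module(ch$att, x, ctx)
               x <- run_module(ch$project_norm,
                               run_module(ch$project, x, ctx), ctx)
               if (mod$cfg$residual) {
                 x <- op_stochastic_depth(x, mod$cfg$block$drop_rate,
                                          training = isTRUE(ctx$training),
                                          force_drop = isTRUE(ctx$force_drop))
                 x <- op_add(x0, x)
               }
               x
             })
}

#' Build and apply one attention-equipped inverted-residual block
#'
#' The block expands channels with a 1x1 convolution (factor `t`), applies a
#' `k x k` depthwise convolution (normalization + activation after each),
#' rescales the expanded map with the configured attention module, projects
#' back down with a 1x1 convolution (normalization, no activation), and — when
#' stride is 1 and channel widths match — adds the input back after
#' stochastic-depth dropout of the branch.
#'
#' @param cfg a [block_config()].
#' @param input_size spatial size `c(H, W)` of the block input (sizes the
#'   directional attention kernels).
#' @param norm `"BN"` or `"LN"`.
#' @param act `"Swish"` or `"GELU"`.
#' @return a block module for [fca_mbconv()].
#' @export
mbconv_module <- function(cfg, input_size, norm = c("BN", "LN"),
                          act = c("Swish", "GELU")) {
  norm <- match.arg(norm); act <- match.arg(act)
  mod_mbconv(cfg, norm, act, input_size[1],
             if (length(input_size) > 1) input_size[2] else input_size[1])
}

#' @rdname mbconv_module
#' @param x input array `(H, W, C)` or `(H, W, C, N)`.
#' @param block a module from [mbconv_module()].
#' @param training whether stochastic depth / batch statistics are live.
#' @param force_drop if `TRUE`, the residual branch is dropped deterministically
#'   (the block becomes the identity when the residual connection exists).
#' @export
fca_mbconv <- function(x, block, training = FALSE, force_drop = FALSE) {
  b <- with_batch(x)
  ctx <- new.env(parent = emptyenv())
  ctx$training <- training; ctx$force_drop <- force_drop
  y <- run_module(block, ag_tensor(b$x), ctx)
  drop_batch(y$v, b$drop)
}

# --- adaptive fusion -------------------------------------------------------

mod_af <- function(cin_img, cout, pool_k = 2L) {
  new_module("af", cfg = list(cin = cin_img, cout = cout, pool_k = pool_k),
             params = list(w1 = ones_param(1L), w2 = ones_param(1L)),
             children = list(proj = mod_conv(cin_img, cout, 1L, bias = TRUE)),
             forward = function(mod, inputs, ctx) {
               ym <- op_maxpool(inputs$image, mod$cfg$pool_k, mod$cfg$pool_k)
               ym <- run_module(mod$children$proj, ym, ctx)
               if (!all(dim(ym$v) == dim(inputs$backbone$v)))
                 abort("adaptive_fusion: pooled/projected branch does not match backbone shape")
               op_add(op_scalar_mul(mod$params$w1, ym),
                      op_scalar_mul(mod$params$w2, inputs$backbone))
             })
}

#' Build and apply the adaptive-fusion stem
#'
#' Fuses a max-pooled, 1x1-projected copy of the network input with the
#' backbone feature map as `w1 * y_m + w2 * y_f`, where `w1`, `w2` are
#' unconstrained learnable scalars (both initialized to 1).
#'
#' @param in_channels channels of the raw input branch (3 for RGB).
#' @param out_channels channels of the backbone map being fused into.
#' @param pool pooling size/stride of the input branch (2 halves the input).
#' @return an adaptive-fusion module.
#' @export
af_module <- function(in_channels = 3L, out_channels = 16L, pool = 2L) {
  mod_af(in_channels, out_channels, pool)
}

#' @rdname af_module
#' @param x_input raw input array (the pre-stem image), `(H, W, C)` or
#'   `(H, W, C, N)`.
#' @param backbone_out backbone feature map to fuse into.
#' @param af module from [af_module()].
#' @param w optional length-2 numeric overriding the learned `c(w1, w2)`.
#' @export
adaptive_fusion <- function(x_input, backbone_out, af, w = NULL) {
  bi <- with_batch(x_input); bb <- with_batch(backbone_out)
  if (!is.null(w)) {
    af$params$w1$v <- array(w[1], 1L)
    af$params$w2$v <- array(w[2], 1L)
  }
  ctx <- new.env(parent = emptyenv()); ctx$training <- FALSE
  y <- run_module(af, list(image = ag_tensor(bi$x), backbone = ag_tensor(bb$x)), ctx)
  drop_batch(y$v, bb$drop)
}
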