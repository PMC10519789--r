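#' @useDynLib fcaenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort warn `%||%`
NULL

# ---------------------------------------------------------------------------
# Minimal define-by-run reverse-mode autodiff.
#
# A "tensor" is an environment holding the value (`v`, a numeric array), an
# accumulated gradient (`grad`), and - while recording - the parent tensors
# together with one vector-Jacobian product closure per parent.  Operations
# executed while the tape is active append their output node to the tape;
# `ag_backward()` walks the tape in reverse creation order, which is a valid
# topological order for a define-by-run graph.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL       # list of nodes, grown while recording
.ag$recording <- FALSE

ag_recording <- function() .ag$recording

ag_with_tape <- function(expr) {
  old_tape <- .ag$tape; old_rec <- .ag$recording
  .ag$tape <- list(); .ag$recording <- TRUE
  on.exit({ .ag$tape <- old_tape; .ag$recording <- old_rec }, add = TRUE)
  value <- force(expr)
  list(value = value, tape = .ag$tape)
}

ag_tensor <- function(v, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$grad <- NULL
  t$requires_grad <- requires_grad
  t$parents <- NULL
  t$vjps <- NULL
  class(t) <- "ag_tensor"
  t
}

is_tensor <- function(x) inherits(x, "ag_tensor")

as_tensor <- function(x) if (is_tensor(x)) x else ag_tensor(x)

# Register an op result. `vjps` is a list of functions(grad) -> gradient for
# the corresponding parent, evaluated lazily during backward.
ag_node <- function(v, parents, vjps) {
  out <- ag_tensor(v)
  if (.ag$recording) {
    out$parents <- parents
    out$vjps <- vjps
    .ag$tape[[length(.ag$tape) + 1L]] <- out
  }
  out
}

ag_accum <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(t)
}

# Backward from `loss` (a scalar tensor) through `tape` (as returned by
# ag_with_tape).  Gradients accumulate into every tensor with
# requires_grad = TRUE and into any tensor listed in `wrt`.
ag_backward <- function(loss, tape, seed = 1) {
  loss$grad <- array(seed, dim = dim(loss$v) %||% 1L)
  for (i in rev(seq_along(tape))) {
    node <- tape[[i]]
    if (is.null(node$grad) || is.null(node$parents)) next
    g <- node$grad
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      pg <- node$vjps[[j]](g)
      if (!is.null(pg)) ag_accum(p, pg)
    }
    if (!isTRUE(node$retain_grad)) node$grad <- NULL # free as we go
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- elementwise ops -------------------------------------------------------

op_add <- function(a, b) {
  ag_node(a$v + b$v, list(a, b), list(function(g) g, function(g) g))
}

# y = s * x with s a length-1 parameter tensor (adaptive-fusion weights)
op_scalar_mul <- function(s, x) {
  ag_node(as.numeric(s$v) * x$v, list(s, x),
          list(function(g) sum(g * x$v), function(g) as.numeric(s$v) * g))
}

op_swish <- function(x) {
  f <- cpp_swish_fwd(x$v)
  ag_node(f$y, list(x), list(function(g) cpp_swish_bwd(x$v, f$sig, g)))
}

op_gelu <- function(x) {
  f <- cpp_gelu_fwd(x$v)
  ag_node(f$y, list(x), list(function(g) cpp_gelu_bwd(x$v, f$phi, g)))
}

op_relu <- function(x) {
  mask <- x$v > 0
  ag_node(x$v * mask, list(x), list(function(g) g * mask))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_node(s, list(x), list(function(g) g * s * (1 - s)))
}

op_identity <- function(x) x

activation_op <- function(kind) {
  switch(kind,
    Swish = op_swish, GELU = op_gelu, ReLU = op_relu,
    Sigmoid = op_sigmoid, identity = op_identity,
    abort(paste0("unknown activation '", kind, "'")))
}

# --- convolution wrappers --------------------------------------------------

# TensorFlow-style 'same' padding for stride s: output ceil(H/s); the extra
# pad row/col (odd totals) goes at the bottom/right.
same_pad <- function(size, k, stride) {
  out <- ceiling(size / stride)
  total <- max((out - 1L) * stride + k - size, 0L)
  beg <- total %/% 2L
  c(beg = beg, out = out)
}

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = "same") {
  d <- dim(x$v); kh <- dim(w$v)[1]; kw <- dim(w$v)[2]
  if (identical(pad, "same")) {
    ph <- same_pad(d[1], kh, stride); pw <- same_pad(d[2], kw, stride)
    pt <- ph["beg"]; pl <- pw["beg"]; ho <- ph["out"]; wo <- pw["out"]
  } else {
    pt <- 0L; pl <- 0L
    ho <- (d[1] - kh) %/% stride + 1L; wo <- (d[2] - kw) %/% stride + 1L
  }
  bv <- if (is.null(b)) NULL else as.numeric(b$v)
  y <- cpp_conv2d_fwd(x$v, w$v, bv, stride, pt, pl, ho, wo)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  xv <- x$v; wv <- w$v
  bwd_cache <- new.env(parent = emptyenv())
  run_bwd <- function(g) {
    if (is.null(bwd_cache$res))
      bwd_cache$res <- cpp_conv2d_bwd(xv, wv, g, stride, pt, pl, TRUE, !is.null(b))
    bwd_cache$res
  }
  vjps <- c(list(function(g) run_bwd(g)$gx,
                 function(g) run_bwd(g)$gw),
            if (!is.null(b)) list(function(g) {
              r <- run_bwd(g)$gb; dim(r) <- length(r); r
            }))
  ag_node(y, parents, vjps)
}

op_dwconv2d <- function(x, w, b = NULL, stride = 1L, pad = "same") {
  d <- dim(x$v); kh <- dim(w$v)[1]; kw <- dim(w$v)[2]
  if (identical(pad, "same")) {
    ph <- same_pad(d[1], kh, stride); pw <- same_pad(d[2], kw, stride)
    pt <- ph["beg"]; pl <- pw["beg"]; ho <- ph["out"]; wo <- pw["out"]
  } else {
    pt <- 0L; pl <- 0L
    ho <- (d[1] - kh) %/% stride + 1L; wo <- (d[2] - kw) %/% stride + 1L
  }
  bv <- if (is.null(b)) NULL else as.numeric(b$v)
  y <- cpp_dwconv2d_fwd(x$v, w$v, bv, stride, pt, pl, ho, wo)
  xv <- x$v; wv <- w$v
  bwd_cache <- new.env(parent = emptyenv())
  run_bwd <- function(g) {
    if (is.null(bwd_cache$res))
      bwd_cache$res <- cpp_dwconv2d_bwd(xv, wv, g, stride, pt, pl, TRUE, !is.null(b))
    bwd_cache$res
  }
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  vjps <- c(list(function(g) run_bwd(g)$gx,
                 function(g) run_bwd(g)$gw),
            if (!is.null(b)) list(function(g) {
              r <- run_bwd(g)$gb; dim(r) <- length(r); r
            }))
  ag_node(y, parents, vjps)
}

op_maxpool <- function(x, k = 2L, stride = 2L) {
  res <- cpp_maxpool_fwd(x$v, k, stride)
  xdim <- dim(x$v)
  ag_node(res$y, list(x),
          list(function(g) cpp_maxpool_bwd(g, res$idx, xdim)))
}

# --- normalization ---------------------------------------------------------

# Batch norm over (H, W, N) per channel.  gamma/beta are length-C tensors.
op_batchnorm <- function(x, gamma, beta, eps, running = NULL, momentum = 0.1,
                         training = TRUE) {
  d <- dim(x$v); C <- d[3]
  m <- d[1] * d[2] * d[4]
  csum <- function(a) rowSums(colSums(array(a, c(d[1] * d[2], C, d[4]))))
  if (training || is.null(running)) {
    mu <- csum(x$v) / m
    va <- csum(x$v^2) / m - mu^2
    if (!is.null(running)) {
      running$mean <- (1 - momentum) * running$mean + momentum * mu
      n_unbias <- if (m > 1) m / (m - 1) else 1
      running$var <- (1 - momentum) * running$var + momentum * va * n_unbias
    }
  } else {
    mu <- running$mean; va <- running$var
  }
  inv <- 1 / sqrt(va + eps)
  bc <- function(vec) array(rep(rep(vec, each = d[1] * d[2]), d[4]), dim = d)
  xhat <- (x$v - bc(mu)) * bc(inv)
  y <- xhat * bc(as.numeric(gamma$v)) + bc(as.numeric(beta$v))
  if (!training) return(ag_node(y, list(x), list(function(g) g * bc(as.numeric(gamma$v) * inv))))
  ag_node(y, list(x, gamma, beta), list(
    function(g) {
      gxh <- g * bc(as.numeric(gamma$v))
      sum_g <- csum(gxh)
      sum_gx <- csum(gxh * xhat)
      (gxh - bc(sum_g / m) - xhat * bc(sum_gx / m)) * bc(inv)
    },
    function(g) { r <- csum(g * xhat); dim(r) <- C; r },
    function(g) { r <- csum(g); dim(r) <- C; r }))
}

# Layer norm: statistics per sample over all C*H*W elements; per-channel affine.
op_layernorm <- function(x, gamma, beta, eps) {
  C <- dim(x$v)[3]
  f <- cpp_layernorm_fwd(x$v, as.numeric(gamma$v), as.numeric(beta$v), eps)
  bwd_cache <- new.env(parent = emptyenv())
  run_bwd <- function(g) {
    if (is.null(bwd_cache$res))
      bwd_cache$res <- cpp_layernorm_bwd(x$v, as.numeric(gamma$v), f$mu, f$inv, g)
    bwd_cache$res
  }
  ag_node(f$y, list(x, gamma, beta), list(
    function(g) run_bwd(g)$gx,
    function(g) { r <- run_bwd(g)$ggamma; dim(r) <- C; r },
    function(g) { r <- run_bwd(g)$gbeta; dim(r) <- C; r }))
}

# --- attention helpers -----------------------------------------------------

# y[i,j,c,n] = x[i,j,c,n] * gh[i,1,c,n] * gw[1,j,c,n]
op_scale_hw <- function(x, gh, gw) {
  y <- cpp_scale_hw_fwd(x$v, gh$v, gw$v)
  bwd_cache <- new.env(parent = emptyenv())
  run_bwd <- function(g) {
    if (is.null(bwd_cache$res))
      bwd_cache$res <- cpp_scale_hw_bwd(x$v, gh$v, gw$v, g)
    bwd_cache$res
  }
  ag_node(y, list(x, gh, gw), list(
    function(g) run_bwd(g)$gx,
    function(g) run_bwd(g)$ggh,
    function(g) run_bwd(g)$ggw))
}

# y[i,j,c,n] = x[i,j,c,n] * s[1,1,c,n]  (squeeze-excitation gating)
op_scale_c <- function(x, s) {
  d <- dim(x$v)
  sf <- s$v[rep(1L, d[1]), , , , drop = FALSE][, rep(1L, d[2]), , , drop = FALSE]
  ag_node(x$v * sf, list(x, s), list(
    function(g) g * sf,
    function(g) array(colSums(matrix(g * x$v, d[1] * d[2], d[3] * d[4])),
                      dim = c(1, 1, d[3], d[4]))))
}

# mean over width (dim 2) keeping shape (H, 1, C, N); likewise over height
op_mean_w <- function(x) {
  d <- dim(x$v)
  y <- array(apply(x$v, c(1, 3, 4), mean), dim = c(d[1], 1, d[3], d[4]))
  ag_node(y, list(x), list(function(g) g[, rep(1L, d[2]), , , drop = FALSE] / d[2]))
}

op_mean_h <- function(x) {
  d <- dim(x$v)
  y <- array(apply(x$v, c(2, 3, 4), mean), dim = c(1, d[2], d[3], d[4]))
  ag_node(y, list(x), list(function(g) g[rep(1L, d[1]), , , , drop = FALSE] / d[1]))
}

# transpose the two spatial dims
op_transpose_hw <- function(x) {
  ag_node(aperm(x$v, c(2, 1, 3, 4)), list(x),
          list(function(g) aperm(g, c(2, 1, 3, 4))))
}

# concatenate along dim 1 (height)
op_concat_h <- function(a, b) {
  da <- dim(a$v); db <- dim(b$v)
  y <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  y[seq_len(da[1]), , , ] <- a$v
  y[da[1] + seq_len(db[1]), , , ] <- b$v
  ag_node(y, list(a, b), list(
    function(g) g[seq_len(da[1]), , , , drop = FALSE],
    function(g) g[da[1] + seq_len(db[1]), , , , drop = FALSE]))
}

op_slice_h <- function(x, rows) {
  d <- dim(x$v)
  ag_node(x$v[rows, , , , drop = FALSE], list(x), list(function(g) {
    gx <- array(0, dim = d); gx[rows, , , ] <- g; gx
  }))
}

# --- pooling / head --------------------------------------------------------

# global average pool (H, W, C, N) -> (C, N)
op_gap <- function(x) {
  d <- dim(x$v)
  y <- colMeans(matrix(x$v, d[1] * d[2], d[3] * d[4]))
  dim(y) <- c(d[3], d[4])
  ag_node(y, list(x), list(function(g) {
    array(rep(as.numeric(g), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  }))
}

# global average pool keeping spatial singleton dims -> (1, 1, C, N)
op_gap_keep <- function(x) {
  d <- dim(x$v)
  y <- array(colMeans(matrix(x$v, d[1] * d[2], d[3] * d[4])),
             dim = c(1, 1, d[3], d[4]))
  ag_node(y, list(x), list(function(g) {
    array(rep(as.numeric(g), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  }))
}

# linear layer on (C, N): y = t(W) %*% x + b, W is (C, K)
op_linear <- function(x, w, b) {
  y <- crossprod(w$v, x$v) + as.numeric(b$v)
  ag_node(y, list(x, w, b), list(
    function(g) w$v %*% g,
    function(g) x$v %*% t(g),
    function(g) { r <- rowSums(g); dim(r) <- length(r); r }))
}

op_dropout <- function(x, p, training = TRUE) {
  if (!training || p <= 0) return(x)
  mask <- array(stats::rbinom(length(x$v), 1L, 1 - p) / (1 - p), dim = dim(x$v))
  ag_node(x$v * mask, list(x), list(function(g) g * mask))
}

# stochastic depth on the residual branch: per-sample keep/drop with
# inverse-probability scaling ("row" mode)
op_stochastic_depth <- function(x, p, training = TRUE, force_drop = FALSE) {
  if (!training && !force_drop) return(x)
  d <- dim(x$v); N <- d[4]
  keep <- if (force_drop) rep(0, N) else stats::rbinom(N, 1L, 1 - p) / (1 - p)
  mask <- array(rep(keep, each = d[1] * d[2] * d[3]), dim = d)
  ag_node(x$v * mask, list(x), list(function(g) g * mask))
}

# fused softmax + cross-entropy; labels are 1-based integers of length N
op_softmax_xent <- function(logits, labels) {
  z <- logits$v
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  n <- ncol(z)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  node <- ag_node(loss, list(logits), list(function(g) {
    gp <- p
    gp[cbind(labels, seq_len(n))] <- gp[cbind(labels, seq_len(n))] - 1
    gp * (as.numeric(g) / n)
  }))
  node$probs <- p
  node
}
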