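# Brute-force oracles and small fixtures shared across tests.  The oracles
# re-derive each operation from its defining equations with plain loops and
# never touch the package's convolution kernels.

# Per-pixel evaluation of fully convolutional coordinate attention:
# directional full-extent depthwise convolutions, spatial concat, 1x1 mixing
# with activation, per-direction 1x1 gate convolutions, sigmoid gates,
# y[i,j,c] = x[i,j,c] * gh[i,c] * gw[j,c].
fca_oracle <- function(x, mod, act = function(z) z * pnorm(z)) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  kw <- mod$children$dir_w$params$w$v   # (1, W, C)
  kh <- mod$children$dir_h$params$w$v   # (H, 1, C)
  mixw <- mod$children$mix$params$w$v   # (1, 1, C, mid)
  gwh <- mod$children$gate_h$params$w$v # (1, 1, mid, C)
  gww <- mod$children$gate_w$params$w$v # (1, 1, mid, C)
  mid <- dim(mixw)[4]
  zh <- matrix(0, H, C); zw <- matrix(0, W, C)
  for (c in seq_len(C)) {
    for (i in seq_len(H)) zh[i, c] <- sum(x[i, , c] * kw[1, , c])
    for (j in seq_len(W)) zw[j, c] <- sum(x[, j, c] * kh[, 1, c])
  }
  u <- rbind(zh, zw)                    # (H + W, C)
  f <- matrix(0, H + W, mid)
  for (p in seq_len(H + W)) for (m in seq_len(mid))
    f[p, m] <- sum(u[p, ] * mixw[1, 1, , m])
  f <- act(f)
  sig <- function(z) 1 / (1 + exp(-z))
  gh <- matrix(0, H, C); gw <- matrix(0, W, C)
  for (c in seq_len(C)) {
    for (i in seq_len(H)) gh[i, c] <- sig(sum(f[i, ] * gwh[1, 1, , c]))
    for (j in seq_len(W)) gw[j, c] <- sig(sum(f[H + j, ] * gww[1, 1, , c]))
  }
  y <- array(0, d)
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W))
    y[i, j, c] <- x[i, j, c] * gh[i, c] * gw[j, c]
  list(y = y, gh = gh, gw = gw)
}

# Hand count of one inverted-residual block's trainable scalars, from the
# layer plan alone (norm affine = 2/channel, attention convs bias-free,
# squeeze-excitation convs biased).
mbconv_param_oracle <- function(cin, cout, t, k, h_out, attention = "FCA",
                                reduction = 16) {
  cexp <- cin * t
  n <- 0
  if (t > 1) n <- n + cin * cexp + 2 * cexp         # expand conv + norm
  n <- n + k^2 * cexp + 2 * cexp                    # depthwise conv + norm
  if (attention == "FCA") {
    mid <- max(cexp %/% reduction, 8)
    n <- n + 2 * cexp * h_out                       # directional kernels
    n <- n + cexp * mid + 2 * mid * cexp            # mix + two gate convs
  } else if (attention == "SE") {
    sq <- max(1, cin %/% 4)
    n <- n + cexp * sq + sq + sq * cexp + cexp
  }
  n + cexp * cout + 2 * cout                        # project conv + norm
}

tiny_spec <- function(...) {
  arch_spec(input_resolution = 32, num_classes = 3, layers_567 = c(1, 1, 1),
            ...)
}

tiny_images <- function(n = 4, res = 32, seed = 1) {
  set.seed(seed)
  array(runif(res * res * 3 * n), c(res, res, 3, n))
}
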