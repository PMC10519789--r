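# Declarative model family: EfficientNet-B0 and its coordinate-attention /
# adaptive-fusion / layer-trimmed derivatives, built from an ArchitectureSpec.

# Base stage plan (stage, operator, kernel, expansion, channels, repeats,
# stride of first block).  Stages 5-7 take their repeats from layers_567.
base_stage_plan <- function(layers_567 = c(3L, 3L, 4L)) {
  tibble::tibble(
    stage = 2:8,
    kernel = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
    expansion = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
    channels = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
    repeats = c(1L, 2L, 2L, layers_567[1], layers_567[2], layers_567[3], 1L),
    stride = c(1L, 2L, 2L, 2L, 1L, 2L, 1L))
}

#' Architecture specification
#'
#' Describes one member of the model family: the attention mechanism in every
#' inverted-residual block, the normalization and activation used throughout,
#' the adaptive-fusion node, the repeat counts of stages 5-7, the class count
#' and the (build-time, fixed) input resolution.
#'
#' The default arguments give the final trimmed model: fully convolutional
#' coordinate attention, layer normalization, exact GELU, fusion at node 2,
#' and 2/3/2 layers in stages 5/6/7.  `spec_efficientnet_b0()` gives the
#' squeeze-excitation baseline.
#'
#' @param attention `"FCA"`, `"CA"` or `"SE"`.
#' @param norm `"LN"` or `"BN"`.
#' @param activation `"GELU"` or `"Swish"`.
#' @param af_node `"none"`, `"node1"` (after the stem convolution), `"node2"`
#'   (after the first inverted-residual block) or `"node3"` (after the second).
#' @param layers_567 integer triple of repeats for stages 5, 6, 7; each at
#'   least 1 and at most the original `c(3, 3, 4)`.
#' @param num_classes number of output classes.
#' @param input_resolution square input size in pixels (directional attention
#'   kernels are sized for it).
#' @param class_names optional character vector of class labels.
#' @return an `arch_spec` object.
#' @export
arch_spec <- function(attention = c("FCA", "SE", "CA"),
                      norm = c("LN", "BN"),
                      activation = c("GELU", "Swish"),
                      af_node = c("node2", "none", "node1", "node3"),
                      layers_567 = c(2L, 3L, 2L),
                      num_classes = 6L,
                      input_resolution = 224L,
                      class_names = NULL) {
  attention <- match.arg(attention); norm <- match.arg(norm)
  activation <- match.arg(activation); af_node <- match.arg(af_node)
  layers_567 <- as.integer(layers_567)
  if (length(layers_567) != 3L || any(layers_567 < 1L) ||
      any(layers_567 > c(3L, 3L, 4L)))
    abort("layers_567 must be a triple with 1 <= entries <= c(3, 3, 4)")
  if (input_resolution < 32L || input_resolution %% 32L != 0L)
    abort("input_resolution must be a positive multiple of 32")
  if (!is.null(class_names) && length(class_names) != num_classes)
    abort("class_names length must equal num_classes")
  structure(list(attention = attention, norm = norm, activation = activation,
                 af_node = af_node, layers_567 = layers_567,
                 num_classes = as.integer(num_classes),
                 input_resolution = as.integer(input_resolution),
                 class_names = class_names),
            class = "arch_spec")
}

#' @rdname arch_spec
#' @param ... passed on to [arch_spec()] to override baseline fields.
#' @export
spec_efficientnet_b0 <- function(...) {
  defaults <- list(attention = "SE", norm = "BN", activation = "Swish",
                   af_node = "none", layers_567 = c(3L, 3L, 4L))
  args <- utils::modifyList(defaults, list(...))
  do.call(arch_spec, args)
}

#' @rdname arch_spec
#' @export
spec_fca_efficientnet <- function(...) do.call(arch_spec, list(...))

#' @export
print.arch_spec <- function(x, ...) {
  cat("<arch_spec>", x$attention, "/", x$norm, "/", x$activation,
      "| AF:", x$af_node,
      "| stages 5-7:", paste(x$layers_567, collapse = ","),
      "| classes:", x$num_classes,
      "| input:", paste0(x$input_resolution, "x", x$input_resolution), "\n")
  invisible(x)
}

af_node_stage <- function(af_node) {
  switch(af_node, none = NA_integer_, node1 = 1L, node2 = 2L, node3 = 3L)
}

#' Build a model from an architecture specification
#'
#' Constructs the full classifier: a 3x3 stride-2 stem convolution to 32
#' channels, the seven inverted-residual stages with the configured
#' attention/normalization/activation, the adaptive-fusion node if any, a 1x1
#' convolution to 1280 channels, global average pooling, dropout 0.2, and a
#' fully connected classification layer.  Weight initialization is drawn from
#' R's RNG, so the build is reproducible for a fixed `seed`.
#'
#' Stochastic-depth rates on residual branches are `0.2 * i / 16` with `i` the
#' 1-based block index in the (possibly trimmed) model and 16 the original
#' block count, which reproduces the published per-stage dropout factors.
#'
#' @param spec an [arch_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `fcaenet_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  set.seed(seed)
  plan <- base_stage_plan(spec$layers_567)
  res <- spec$input_resolution
  children <- list(
    stem_conv = mod_conv(3L, 32L, 3L, stride = 2L),
    stem_norm = norm_params(spec$norm, 32L),
    act = mod_act(spec$activation))
  h <- res %/% 2L
  cin <- 32L
  block_meta <- list()
  idx <- 0L
  for (si in seq_len(nrow(plan))) {
    row <- plan[si, ]
    for (b in seq_len(row$repeats)) {
      idx <- idx + 1L
      s <- if (b == 1L) row$stride else 1L
      cfg <- block_config(cin, row$channels, row$expansion, row$kernel, s,
                          spec$attention, drop_rate = 0.2 * idx / 16)
      key <- sprintf("s%db%d", row$stage, b)
      children[[key]] <- mod_mbconv(cfg, spec$norm, spec$activation, h, h)
      # residual blocks start as identities: zero-init the scale of the
      # projection norm so early optimization is well-conditioned
      if (children[[key]]$cfg$residual)
        children[[key]]$children$project_norm$params$gamma$v[] <- 0
      block_meta[[key]] <- list(stage = row$stage, h_in = h,
                                h_out = if (s == 2L) h %/% 2L else h, cfg = cfg)
      h <- if (s == 2L) h %/% 2L else h
      cin <- row$channels
    }
  }
  af_stage <- af_node_stage(spec$af_node)
  if (!is.na(af_stage)) {
    af_cout <- c(32L, 16L, 24L)[af_stage]
    af_res <- c(res %/% 2L, res %/% 2L, res %/% 4L)[af_stage]
    children$af <- mod_af(3L, af_cout, pool_k = res %/% af_res)
  }
  children$head_conv <- mod_conv(cin, 1280L, 1L)
  children$head_norm <- norm_params(spec$norm, 1280L)
  children$fc <- mod_linear(1280L, spec$num_classes)
  model <- structure(
    list(spec = spec, children = children, block_meta = block_meta,
         classifier_dropout = 0.2, seed = seed),
    class = "fcaenet_model")
  model
}

# Forward pass.  x: (H, W, C, N) array in [0, 1].  Returns a list with the
# logits tensor; per-stage activations are written to ctx$collect when a
# collect environment is supplied.
forward_model <- function(model, x, training = FALSE, collect = NULL,
                          force_drop = FALSE) {
  d <- dim(x)
  res <- model$spec$input_resolution
  if (length(d) != 4L || d[1] != res || d[2] != res || d[3] != 3L)
    abort(sprintf("expected input (H, W, 3, N) with H = W = %d", res))
  ch <- model$children
  ctx <- new.env(parent = emptyenv())
  ctx$training <- training; ctx$force_drop <- force_drop; ctx$collect <- collect
  img <- ag_tensor(x)
  out <- run_module(ch$act,
                    run_module(ch$stem_norm,
                               run_module(ch$stem_conv, img, ctx), ctx), ctx)
  af_stage <- af_node_stage(model$spec$af_node)
  fuse <- function(out) run_module(ch$af, list(image = img, backbone = out), ctx)
  if (!is.na(af_stage) && af_stage == 1L) out <- fuse(out)
  if (!is.null(collect)) collect$stem <- out
  block_no <- 0L
  for (key in names(model$block_meta)) {
    out <- run_module(ch[[key]], out, ctx)
    block_no <- block_no + 1L
    if (!is.na(af_stage) && af_stage == 2L && block_no == 1L) out <- fuse(out)
    if (!is.na(af_stage) && af_stage == 3L && block_no == 2L) out <- fuse(out)
    if (!is.null(collect)) collect[[key]] <- out
  }
  if (!is.null(collect)) {
    last8 <- rev(grep("^s8", names(model$block_meta), value = TRUE))[1]
    collect$stage8 <- collect[[last8]]
  }
  out <- run_module(ch$act,
                    run_module(ch$head_norm,
                               run_module(ch$head_conv, out, ctx), ctx), ctx)
  if (!is.null(collect)) collect$head <- out
  pooled <- op_gap(out)
  pooled <- op_dropout(pooled, model$classifier_dropout, training = training)
  logits <- run_module(ch$fc, pooled, ctx)
  list(logits = logits, ctx = ctx)
}

model_param_list <- function(model) {
  out <- list()
  for (nm in names(model$children))
    out <- c(out, module_params(model$children[[nm]], paste0(nm, ".")))
  out
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution and linear weights and
#' biases, normalization scales/shifts, attention weights, fusion scalars).
#'
#' @param model an `fcaenet_model` (or any single module).
#' @return integer count.
#' @export
count_params <- function(model) {
  if (inherits(model, "fcaenet_module")) return(n_params(model))
  sum(vapply(model_param_list(model), function(p) length(p$v), 0))
}

#' Count multiply-accumulate operations
#'
#' Multiply-accumulates of one forward pass at the model's input resolution.
#' Convolutions contribute `k^2 * C_in * C_out * H_out * W_out` (depthwise:
#' `k^2 * C * H_out * W_out`), the classifier `C_in * C_out`.  By default
#' normalization layers are also charged 2 operations per output element,
#' matching the convention of common network profilers and the published
#' complexity figures for this family; set `include_norm = FALSE` for the
#' bare convolution + linear count.
#'
#' @param model an `fcaenet_model`.
#' @param input_resolution must equal the build resolution (directional
#'   attention kernels are size-bound); defaults to it.
#' @param include_norm charge normalization layers 2 ops/element.
#' @return numeric MAC count.
#' @export
count_macs <- function(model, input_resolution = NULL, include_norm = TRUE) {
  res <- model$spec$input_resolution
  if (!is.null(input_resolution) && input_resolution != res)
    abort("model is resolution-bound; rebuild with a different input_resolution")
  macs <- 0; norm_elems <- 0
  h <- res %/% 2L
  macs <- macs + 9 * 3 * 32 * h^2
  norm_elems <- norm_elems + 32 * h^2
  for (meta in model$block_meta) {
    cfg <- meta$cfg
    cexp <- cfg$in_channels * cfg$expansion
    hi <- meta$h_in; ho <- meta$h_out
    if (cfg$expansion > 1L) {
      macs <- macs + cfg$in_channels * cexp * hi^2
      norm_elems <- norm_elems + cexp * hi^2
    }
    macs <- macs + cfg$kernel^2 * cexp * ho^2
    norm_elems <- norm_elems + cexp * ho^2
    if (cfg$attention == "SE") {
      sq <- max(1L, cfg$in_channels %/% 4L)
      macs <- macs + 2 * cexp * sq
    } else if (cfg$attention %in% c("CA", "FCA")) {
      mid <- max(cexp %/% 16L, 8L)
      if (cfg$attention == "FCA") macs <- macs + 2 * cexp * ho^2
      macs <- macs + 2 * ho * cexp * mid + 2 * ho * mid * cexp
    }
    macs <- macs + cexp * cfg$out_channels * ho^2
    norm_elems <- norm_elems + cfg$out_channels * ho^2
  }
  if (!is.null(model$children$af)) {
    af <- model$children$af$cfg
    macs <- macs + af$cin * af$cout * (res %/% af$pool_k)^2
  }
  hf <- res %/% 32L
  last_c <- model$children$head_conv$cfg$cin
  macs <- macs + last_c * 1280 * hf^2
  norm_elems <- norm_elems + 1280 * hf^2
  macs <- macs + 1280 * model$spec$num_classes
  if (include_norm) macs <- macs + 2 * norm_elems
  macs
}

#' Enumerate the stage-trimming search space
#'
#' All twelve repeat-count triples for stages 5-7 (stage 5 and 6 in `{2, 3}`,
#' stage 7 in `{2, 3, 4}`), in lexicographic order; row 12 is the original
#' (3, 3, 4) plan and row 4 the selected (2, 3, 2).
#'
#' @param ... fields passed to [arch_spec()] for every variant.
#' @return tibble with columns `row`, `s5`, `s6`, `s7`, `spec` (list column).
#' @export
enumerate_search_space <- function(...) {
  grid <- tidyr::expand_grid(s5 = 2:3, s6 = 2:3, s7 = 2:4)
  grid$row <- seq_len(nrow(grid))
  grid$spec <- purrr::pmap(grid[, c("s5", "s6", "s7")], function(s5, s6, s7)
    arch_spec(layers_567 = c(s5, s6, s7), ...))
  grid[, c("row", "s5", "s6", "s7", "spec")]
}

#' Per-stage summary table
#'
#' One row per stage with operator, input resolution, output channels, layer
#' count and parameter count, mirroring the layer-plan tables used for this
#' model family.
#'
#' @param model an `fcaenet_model`.
#' @return a tibble; total parameters and MACs are attached as attributes and
#'   shown by the print method of [glance.fcaenet_model()].
#' @export
model_summary <- function(model) {
  spec <- model$spec
  res <- spec$input_resolution
  att <- spec$attention
  stage_params <- function(keys)
    sum(vapply(keys, function(k) n_params(model$children[[k]]), 0))
  meta <- model$block_meta
  stages <- sort(unique(vapply(meta, function(m) m$stage, 0L)))
  rows <- purrr::map_dfr(stages, function(st) {
    keys <- names(meta)[vapply(meta, function(m) m$stage == st, TRUE)]
    first <- meta[[keys[1]]]
    op <- if (first$cfg$expansion == 1L)
      sprintf("%s-MBConv1, k%dx%d", att, first$cfg$kernel, first$cfg$kernel)
    else
      sprintf("%s-MBConv6, k%dx%d", att, first$cfg$kernel, first$cfg$kernel)
    if (st == 2L && spec$af_node == "node2") op <- paste("AF &", op)
    tibble::tibble(stage = st, operator = op,
                   resolution = sprintf("%dx%d", first$h_in, first$h_in),
                   channels = first$cfg$out_channels,
                   layers = length(keys),
                   params = stage_params(keys))
  })
  stem <- tibble::tibble(stage = 1L, operator = "Conv3x3",
                         resolution = sprintf("%dx%d", res, res),
                         channels = 32L, layers = 1L,
                         params = stage_params(c("stem_conv", "stem_norm")))
  head_keys <- intersect(c("head_conv", "head_norm", "fc", "af"),
                         names(model$children))
  head <- tibble::tibble(stage = 9L, operator = "Conv1x1 & Pooling & FC",
                         resolution = sprintf("%dx%d", res %/% 32L, res %/% 32L),
                         channels = 1280L, layers = 1L,
                         params = stage_params(head_keys))
  out <- dplyr::bind_rows(stem, rows, head)
  attr(out, "total_params") <- count_params(model)
  attr(out, "total_macs") <- count_macs(model)
  out
}

#' @export
print.fcaenet_model <- function(x, ...) {
  cat("<fcaenet_model>\n")
  print(x$spec)
  cat(sprintf("  params: %.2fM   MACs: %.2fM\n",
              count_params(x) / 1e6, count_macs(x) / 1e6))
  invisible(x)
}

#' Predict class probabilities for a batch of images
#'
#' @param object an `fcaenet_model`.
#' @param images array `(H, W, 3, N)` (or a single `(H, W, 3)` image) at the
#'   model's input resolution, values in `[0, 1]`.
#' @param ... unused.
#' @return tibble with one row per image: predicted class and per-class
#'   probabilities.
#' @export
predict.fcaenet_model <- function(object, images, ...) {
  b <- with_batch(images)
  out <- forward_model(object, b$x, training = FALSE)
  z <- out$logits$v
  z <- sweep(z, 2, apply(z, 2, max))
  p <- sweep(exp(z), 2, colSums(exp(z)), "/")
  labels <- object$spec$class_names %||% paste0("class", seq_len(nrow(p)))
  probs <- tibble::as_tibble(stats::setNames(as.data.frame(t(p)), labels))
  dplyr::bind_cols(
    tibble::tibble(image = seq_len(ncol(p)),
                   pred = labels[apply(p, 2, which.max)]),
    probs)
}

# --- configuration files ---------------------------------------------------

#' Read / write an architecture configuration file
#'
#' YAML or JSON with keys `attention`, `norm`, `activation`, `af_node`,
#' `layers_567`, `num_classes`, `input_resolution`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return [read_arch_config()] returns an [arch_spec()].
#' @export
read_arch_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  keep <- intersect(names(cfg), c("attention", "norm", "activation", "af_node",
                                  "layers_567", "num_classes",
                                  "input_resolution", "class_names"))
  do.call(arch_spec, cfg[keep])
}

#' @rdname read_arch_config
#' @param spec an [arch_spec()] to serialize.
#' @export
write_arch_config <- function(spec, path) {
  x <- unclass(spec)
  x$class_names <- x$class_names %||% NULL
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}
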