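# Confusion-matrix metrics (accuracy, per-class and macro precision /
# recall / F1) and Grad-CAM heatmaps.

#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth,pred factors or vectors of class labels (or 1-based integers).
#' @param levels optional class levels fixing the order.
#' @return a `confusion_matrix` (K x K integer matrix).
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(pred))))
  t <- factor(as.character(truth), levels = levels)
  p <- factor(as.character(pred), levels = levels)
  m <- unclass(table(truth = t, pred = p))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Confusion matrix from per-class one-vs-rest counts
#'
#' Reconstructs a consistent K x K matrix from per-class true-positive,
#' false-positive and false-negative counts by distributing each class's
#' false negatives over the classes with spare false-positive capacity.  The
#' resulting matrix reproduces the given TP/FP/FN exactly (metrics depend on
#' nothing else).
#'
#' @param tp,fp,fn integer vectors (one entry per class; `sum(fp) == sum(fn)`).
#' @param classes optional class names.
#' @return a `confusion_matrix`.
#' @export
cm_from_counts <- function(tp, fp, fn, classes = NULL) {
  k <- length(tp)
  stopifnot(length(fp) == k, length(fn) == k, sum(fp) == sum(fn))
  m <- diag(tp)
  fp_left <- fp
  # distribute FN units over off-diagonal cells: most-constrained class first,
  # each unit to the donor class with the largest remaining FP capacity
  order_i <- order(sapply(seq_len(k), function(i) sum(fp_left[-i])))
  for (i in order_i) {
    need <- fn[i]
    while (need > 0L) {
      cap <- fp_left; cap[i] <- 0L
      j <- which.max(cap)
      if (cap[j] == 0L)
        abort("counts are inconsistent: FN cannot be distributed over FP")
      m[i, j] <- m[i, j] + 1L
      fp_left[j] <- fp_left[j] - 1L
      need <- need - 1L
    }
  }
  if (is.null(classes)) classes <- paste0("class", seq_len(k))
  dimnames(m) <- list(truth = classes, pred = classes)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Metrics from a confusion matrix
#'
#' Per-class one-vs-rest precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)`; overall accuracy `trace/total`; macro averages are
#' unweighted means over classes (macro-F1 is the mean of per-class F1, not
#' the harmonic mean of the macro P and R).  Zero-denominator metrics are 0
#' with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report`: list with `per_class` (tibble: class, tp, fp,
#'   fn, tn, precision, recall, f1), `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `total`.
#' @export
compute_metrics <- function(cm) {
  m <- unclass(cm)
  if (is.null(dim(m)) || nrow(m) == 0L) abort("empty confusion matrix")
  total <- sum(m)
  if (total == 0L) abort("empty confusion matrix")
  tp <- unname(diag(m))
  fp <- unname(colSums(m)) - tp
  fn <- unname(rowSums(m)) - tp
  tn <- total - tp - fp - fn
  zero_den <- character(0)
  safe_div <- function(num, den, what) {
    if (any(den == 0)) zero_den <<- c(zero_den, what)
    ifelse(den > 0, num / den, 0)
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  if (length(zero_den))
    warn(paste0("zero denominator in ", paste(unique(zero_den), collapse = ", "),
                "; reporting 0"))
  classes <- rownames(m) %||% paste0("class", seq_len(nrow(m)))
  per_class <- tibble::tibble(class = classes, tp = as.integer(tp),
                              fp = as.integer(fp), fn = as.integer(fn),
                              tn = as.integer(tn),
                              precision = precision, recall = recall, f1 = f1)
  structure(list(per_class = per_class,
                 accuracy = sum(tp) / total,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f | macro P %.4f R %.4f F1 %.4f (n = %d)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$total))
  print(x$per_class)
  invisible(x)
}

#' Overall accuracy from per-class counts
#'
#' `(total - sum(fp)) / total`: every false positive is exactly one
#' misclassified image, so the off-diagonal total is `sum(fp)`.
#'
#' @param tp,fp per-class true-positive and false-positive counts.
#' @param total number of evaluated images.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_from_per_class <- function(tp, fp, total) {
  if (sum(tp) + sum(fp) > total || sum(tp) + sum(fp) < 0)
    abort("inconsistent counts: sum(tp) + sum(fp) must lie in [0, total]")
  if (sum(tp) != total - sum(fp))
    abort("inconsistent counts: tp and fp do not partition the evaluated images")
  (total - sum(fp)) / total
}

# --- published reference tables (used as inputs) ---------------------------

#' Reference per-class test counts of the corn-disease study
#'
#' Per-class one-vs-rest counts of the published test-set evaluation of the
#' final model (six corn-leaf categories, 325 test images).
#'
#' @return tibble with `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
corn_reference_counts <- function() {
  tibble::tibble(
    class = c("Fall Armyworm", "Gray Leaf Spot", "Leaf Blight", "Leaf Healthy",
              "Northern Leaf Spot", "Rust Leaf"),
    tp = c(43L, 59L, 69L, 53L, 55L, 42L),
    fp = c(1L, 0L, 1L, 0L, 0L, 2L),
    fn = c(0L, 2L, 0L, 1L, 0L, 1L),
    tn = c(281L, 264L, 255L, 271L, 270L, 280L))
}

#' Reference class totals and published split of the corn-disease study
#'
#' Class totals (3258 images over six categories) and the published
#' train/valid/test counts.
#'
#' @return tibble with `class`, `total`, `train`, `valid`, `test`.
#' @export
corn_class_totals <- function() {
  tibble::tibble(
    class = c("Fall Armyworm", "Gray Leaf Spot", "Leaf Blight", "Leaf Healthy",
              "Northern Leaf Spot", "Rust Leaf"),
    total = c(432L, 613L, 688L, 537L, 551L, 437L),
    train = c(346L, 491L, 550L, 429L, 441L, 351L),
    valid = c(43L, 61L, 69L, 54L, 55L, 43L),
    test = c(43L, 61L, 69L, 54L, 55L, 43L))
}

# --- Grad-CAM --------------------------------------------------------------

#' Grad-CAM class-activation heatmap
#'
#' Backpropagates the target-class logit to the chosen layer's activation,
#' weights each activation channel by the spatial mean of its gradient, sums,
#' rectifies, upsamples bilinearly to the input size and min-max normalizes
#' to `[0, 1]` (an all-zero map is returned unchanged when gradients vanish).
#'
#' @param model an `fcaenet_model`.
#' @param image `(H, W, 3)` array at the model resolution.
#' @param target_class 1-based class index.
#' @param layer activation name: `"stem"`, a block key such as `"s8b1"`, the
#'   alias `"stage8"` (deepest block, default) or `"head"`.
#' @return a `cam_heatmap` (H x W matrix in `[0, 1]`).
#' @export
grad_cam <- function(model, image, target_class, layer = "stage8") {
  if (target_class < 1L || target_class > model$spec$num_classes)
    abort("target_class out of range")
  b <- with_batch(image)
  collect <- new.env(parent = emptyenv())
  rec <- ag_with_tape({
    out <- forward_model(model, b$x, training = FALSE, collect = collect)
    out$logits
  })
  if (is.null(collect[[layer]]))
    abort(sprintf("unknown layer '%s'", layer))
  act <- collect[[layer]]
  act$retain_grad <- TRUE
  logits <- rec$value
  seed <- array(0, dim = dim(logits$v))
  seed[target_class, 1] <- 1
  ag_backward(logits, rec$tape, seed = seed)
  g <- act$grad
  if (is.null(g)) g <- array(0, dim = dim(act$v))
  ad <- dim(act$v)
  hw <- ad[1] * ad[2]
  wts <- colMeans(matrix(g, hw, ad[3]))
  cam <- matrix(matrix(act$v, hw, ad[3]) %*% wts, ad[1], ad[2])
  cam <- pmax(cam, 0)
  cam <- bilinear_resize(cam, dim(b$x)[1], dim(b$x)[2])
  rng <- range(cam)
  if (rng[2] > rng[1]) cam <- (cam - rng[1]) / (rng[2] - rng[1])
  else cam[] <- 0  # constant (vanished-gradient) maps carry no localization
  structure(cam, class = c("cam_heatmap", "matrix"))
}

# simple separable bilinear upsampling of a matrix
bilinear_resize <- function(m, h, w) {
  src_h <- nrow(m); src_w <- ncol(m)
  if (src_h == h && src_w == w) return(m)
  yi <- (seq_len(h) - 0.5) / h * src_h + 0.5
  xi <- (seq_len(w) - 0.5) / w * src_w + 0.5
  interp_idx <- function(pos, n) {
    lo <- pmin(pmax(floor(pos - 0.5) + 0.5, 0.5), n - 0.5)
    hi <- pmin(lo + 1, n - 0.5)
    fr <- pmin(pmax(pos - lo, 0), 1)
    list(lo = pmax(ceiling(lo), 1L), hi = pmax(ceiling(hi), 1L), fr = fr)
  }
  y <- interp_idx(yi, src_h); x <- interp_idx(xi, src_w)
  m_y <- m[y$lo, , drop = FALSE] * (1 - y$fr) + m[y$hi, , drop = FALSE] * y$fr
  m_y[, x$lo, drop = FALSE] * rep(1 - x$fr, each = h) +
    m_y[, x$hi, drop = FALSE] * rep(x$fr, each = h)
}
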