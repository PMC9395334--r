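# A small LeNet-style convolutional classifier for w x w image patches,
# implemented directly in R matrix algebra: two 3x3 convolution stages (16
# and 32 filters) each followed by ReLU and 2x2 max-pooling, one 64-unit
# hidden dense stage, and a softmax output, trained with Adam on the
# cross-entropy loss. At the 10x10 patch sizes this package works with,
# each stage is a handful of small matrix products, so plain BLAS is fast
# enough for desk-scale training.

#' Classifier specification
#'
#' Describes the patch classifier's input geometry, class count,
#' architecture and training protocol. The defaults are the training
#' protocol used throughout the package: optimizer Adam, batch size 256,
#' 30 epochs, 6 classes; the learning rate (which the protocol leaves
#' open) defaults to Adam's conventional 1e-3.
#'
#' @param w patch side length in pixels.
#' @param channels input channels C.
#' @param n_classes number of classes L (>= 2).
#' @param conv_filters filters in the two convolution stages.
#' @param kernel convolution kernel side (odd).
#' @param dense_units hidden dense units.
#' @param batch_size,epochs,learning_rate Adam training protocol.
#' @param seed integer seed for initialization and batch shuffling.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(w = 10, channels = 3, n_classes = 6,
                            conv_filters = c(16L, 32L), kernel = 3L,
                            dense_units = 64L, batch_size = 256L,
                            epochs = 30L, learning_rate = 1e-3, seed = 1L) {
  structure(list(
    w = check_count(w, "w", 1L), channels = check_count(channels, "channels", 1L),
    n_classes = check_count(n_classes, "n_classes", 2L),
    conv_filters = as.integer(conv_filters), kernel = check_count(kernel, "kernel", 1L),
    dense_units = check_count(dense_units, "dense_units", 1L),
    batch_size = check_count(batch_size, "batch_size", 1L),
    epochs = check_count(epochs, "epochs", 1L),
    learning_rate = check_number(learning_rate, "learning_rate", lower = 1e-12),
    seed = as.integer(seed)
  ), class = "classifier_spec")
}

# Spatial sizes down the two conv+pool stages; NULL if the geometry is
# infeasible (a stage shrinks below 1 or hits an odd size before pooling).
stage_sizes <- function(w, k) {
  s1 <- w - k + 1L
  if (s1 < 2L || s1 %% 2L != 0L) return(NULL)
  p1 <- s1 %/% 2L
  s2 <- p1 - k + 1L
  if (s2 < 2L || s2 %% 2L != 0L) return(NULL)
  list(s1 = s1, p1 = p1, s2 = s2, p2 = s2 %/% 2L)
}

minimal_patch_size <- function(k) {
  for (w in seq(k + 1L, 128L)) if (!is.null(stage_sizes(w, k))) return(w)
  NA_integer_
}

#' Build an (untrained) patch classifier
#'
#' Allocates and deterministically initializes the network weights (He
#' initialization for the ReLU stages, Glorot for the softmax output)
#' under the spec's seed. The returned model is untrained; [train_classifier()]
#' fits it.
#'
#' @param spec a [classifier_spec()].
#' @return A `patch_cnn` model object; `$param_count` reports the number
#'   of learnable parameters.
#' @examples
#' m <- build_classifier(classifier_spec(w = 10, channels = 3, n_classes = 6))
#' m$param_count
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  sz <- stage_sizes(spec$w, spec$kernel)
  if (is.null(sz)) {
    stop_validation("patch size w = %d cannot pass two conv(%d)+pool stages; smallest feasible w is %d",
                    spec$w, spec$kernel, minimal_patch_size(spec$kernel))
  }
  k <- spec$kernel; C <- spec$channels
  f1 <- spec$conv_filters[1L]; f2 <- spec$conv_filters[2L]
  flat <- f2 * sz$p2^2
  he <- function(fan_in) sqrt(2 / fan_in)
  glorot <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))
  params <- with_seed(spec$seed, list(
    W1 = array(rnorm(k * k * C * f1, sd = he(k * k * C)), c(k, k, C, f1)),
    b1 = numeric(f1),
    W2 = array(rnorm(k * k * f1 * f2, sd = he(k * k * f1)), c(k, k, f1, f2)),
    b2 = numeric(f2),
    Wd = matrix(rnorm(flat * spec$dense_units, sd = he(flat)), flat, spec$dense_units),
    bd = numeric(spec$dense_units),
    Wo = matrix(runif(spec$dense_units * spec$n_classes,
                      -glorot(spec$dense_units, spec$n_classes),
                      glorot(spec$dense_units, spec$n_classes)),
                spec$dense_units, spec$n_classes),
    bo = numeric(spec$n_classes)
  ))
  structure(list(
    spec = spec, params = params, sizes = sz,
    param_count = sum(vapply(params, length, 1L)),
    trained = FALSE, history = NULL, norm = NULL,
    classes = seq_len(spec$n_classes) - 1L
  ), class = "patch_cnn")
}

#' @export
print.patch_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<patch_cnn> %dx%dx%d -> conv%d(%d)/pool -> conv%d(%d)/pool -> dense(%d) -> softmax(%d)\n",
              s$w, s$w, s$channels, s$kernel, s$conv_filters[1L], s$kernel,
              s$conv_filters[2L], s$dense_units, s$n_classes))
  cat(sprintf("  %d parameters, %s\n", x$param_count,
              if (x$trained) sprintf("trained %d epoch(s)", nrow(x$history)) else "untrained"))
  invisible(x)
}

# ---- layer primitives (arrays are h x w x C x B) ----------------------

conv_forward <- function(X, W, b) {
  d <- dim(X); k <- dim(W)[1L]; Cin <- dim(W)[3L]; f <- dim(W)[4L]
  oh <- d[1L] - k + 1L; ow <- d[2L] - k + 1L; B <- d[4L]
  acc <- matrix(0, f, oh * ow * B)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    Xsub <- X[ki:(ki + oh - 1L), kj:(kj + ow - 1L), , , drop = FALSE]
    Xm <- matrix(aperm(Xsub, c(3L, 1L, 2L, 4L)), nrow = Cin)
    acc <- acc + crossprod(matrix(W[ki, kj, , ], nrow = Cin), Xm)
  }
  aperm(array(acc + b, c(f, oh, ow, B)), c(2L, 3L, 1L, 4L))
}

conv_backward <- function(dOut, X, W) {
  d <- dim(X); k <- dim(W)[1L]; Cin <- dim(W)[3L]; f <- dim(W)[4L]
  o <- dim(dOut); oh <- o[1L]; ow <- o[2L]; B <- o[4L]
  dOutm <- matrix(aperm(dOut, c(3L, 1L, 2L, 4L)), nrow = f)
  dW <- array(0, dim(W)); dX <- array(0, d)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    Xsub <- X[ki:(ki + oh - 1L), kj:(kj + ow - 1L), , , drop = FALSE]
    Xm <- matrix(aperm(Xsub, c(3L, 1L, 2L, 4L)), nrow = Cin)
    dW[ki, kj, , ] <- Xm %*% t(dOutm)
    dXm <- matrix(W[ki, kj, , ], nrow = Cin) %*% dOutm
    dXsub <- aperm(array(dXm, c(Cin, oh, ow, B)), c(2L, 3L, 1L, 4L))
    dX[ki:(ki + oh - 1L), kj:(kj + ow - 1L), , ] <-
      dX[ki:(ki + oh - 1L), kj:(kj + ow - 1L), , , drop = FALSE] + dXsub
  }
  list(dX = dX, dW = dW, db = rowSums(dOutm))
}

maxpool_forward <- function(X) {
  d <- dim(X)
  i1 <- seq(1L, d[1L], by = 2L); j1 <- seq(1L, d[2L], by = 2L)
  x11 <- X[i1, j1, , , drop = FALSE]; x12 <- X[i1, j1 + 1L, , , drop = FALSE]
  x21 <- X[i1 + 1L, j1, , , drop = FALSE]; x22 <- X[i1 + 1L, j1 + 1L, , , drop = FALSE]
  P <- pmax(x11, x12, x21, x22)
  # first-wins tie-break so the gradient is routed to exactly one cell
  m11 <- x11 == P
  m12 <- (x12 == P) & !m11
  m21 <- (x21 == P) & !m11 & !m12
  m22 <- !(m11 | m12 | m21)
  list(P = P, masks = list(m11, m12, m21, m22))
}

maxpool_backward <- function(dP, cache, d_in) {
  dX <- array(0, d_in)
  i1 <- seq(1L, d_in[1L], by = 2L); j1 <- seq(1L, d_in[2L], by = 2L)
  dX[i1, j1, , ] <- dP * cache$masks[[1L]]
  dX[i1, j1 + 1L, , ] <- dP * cache$masks[[2L]]
  dX[i1 + 1L, j1, , ] <- dP * cache$masks[[3L]]
  dX[i1 + 1L, j1 + 1L, , ] <- dP * cache$masks[[4L]]
  dX
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

cnn_forward <- function(params, X, keep_cache = FALSE) {
  A1 <- conv_forward(X, params$W1, params$b1)
  R1 <- pmax(A1, 0)
  P1 <- maxpool_forward(R1)
  A2 <- conv_forward(P1$P, params$W2, params$b2)
  R2 <- pmax(A2, 0)
  P2 <- maxpool_forward(R2)
  B <- dim(X)[4L]
  Xf <- matrix(P2$P, ncol = B)                      # flat x B
  H_pre <- crossprod(params$Wd, Xf) + params$bd
  H <- pmax(H_pre, 0)
  O <- crossprod(params$Wo, H) + params$bo          # L x B
  probs <- softmax_cols(O)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, X = X, A1 = A1, R1 = R1, P1 = P1, A2 = A2, R2 = R2,
       P2 = P2, Xf = Xf, H_pre = H_pre, H = H)
}

cnn_backward <- function(params, cache, Y) {
  B <- ncol(Y)
  dO <- (cache$probs - Y) / B                       # L x B
  gWo <- cache$H %*% t(dO)
  gbo <- rowSums(dO)
  dH <- (params$Wo %*% dO) * (cache$H_pre > 0)
  gWd <- cache$Xf %*% t(dH)
  gbd <- rowSums(dH)
  dXf <- params$Wd %*% dH
  dP2 <- array(dXf, dim(cache$P2$P))
  dR2 <- maxpool_backward(dP2, cache$P2, dim(cache$R2))
  dA2 <- dR2 * (cache$A2 > 0)
  c2 <- conv_backward(dA2, cache$P1$P, params$W2)
  dR1 <- maxpool_backward(c2$dX, cache$P1, dim(cache$R1))
  dA1 <- dR1 * (cache$A1 > 0)
  c1 <- conv_backward(dA1, cache$X, params$W1)
  list(W1 = c1$dW, b1 = c1$db, W2 = c2$dW, b2 = c2$db,
       Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training and prediction ------------------------------------------

patches_xy <- function(data, spec, need_labels = TRUE) {
  if (inherits(data, "patch_set")) {
    x <- data$patches
    y <- data$info$label
  } else if (is.list(data) && all(c("x", "y") %in% names(data))) {
    x <- data$x; y <- data$y
  } else {
    stop_validation("training data must be a labeled patch_set or list(x=, y=)")
  }
  d <- dim(x)
  if (d[1L] != spec$w || d[2L] != spec$w || d[3L] != spec$channels) {
    stop_validation("patch dims %dx%dx%d do not match the spec's %dx%dx%d",
                    d[1L], d[2L], d[3L], spec$w, spec$w, spec$channels)
  }
  if (need_labels) {
    if (d[4L] == 0L) stop_validation("empty training set")
    if (anyNA(y)) stop_validation("training patches must all be labeled")
    if (any(y < 0L | y >= spec$n_classes)) {
      stop_validation("labels must lie in 0..%d", spec$n_classes - 1L)
    }
  }
  list(x = x, y = as.integer(y))
}

standardize <- function(x, norm) {
  for (c in seq_len(dim(x)[3L])) {
    x[, , c, ] <- (x[, , c, ] - norm$mean[c]) / norm$sd[c]
  }
  x
}

#' Train the patch classifier
#'
#' Minimizes the cross-entropy by mini-batch Adam under the spec's
#' protocol. Patch intensities are standardized per channel with
#' training-set statistics, which are stored in the model and re-applied
#' at prediction time. The per-epoch history records training loss and
#' accuracy (averaged over the epoch's batches), validation metrics when a
#' validation set is given, and the number of optimizer steps.
#'
#' @param model a `patch_cnn` from [build_classifier()].
#' @param train_set labeled [patch_set()] (or `list(x = array, y = labels)`).
#' @param validation_set optional labeled patch set evaluated after each
#'   epoch.
#' @param epochs,batch_size,learning_rate override the spec's protocol.
#' @param verbose print per-epoch progress.
#' @return The trained `patch_cnn`; `$history` is a tibble with one row
#'   per epoch.
#' @export
train_classifier <- function(model, train_set, validation_set = NULL,
                             epochs = NULL, batch_size = NULL,
                             learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "patch_cnn"))
  spec <- model$spec
  epochs <- epochs %||% spec$epochs
  batch_size <- batch_size %||% spec$batch_size
  lr <- learning_rate %||% spec$learning_rate
  tr <- patches_xy(train_set, spec)
  n <- length(tr$y)
  model$norm <- list(
    mean = vapply(seq_len(spec$channels), function(c) mean(tr$x[, , c, ]), 1),
    sd = pmax(vapply(seq_len(spec$channels), function(c) sd(as.vector(tr$x[, , c, ])), 1), 1e-8)
  )
  x <- standardize(tr$x, model$norm)
  val <- if (!is.null(validation_set)) patches_xy(validation_set, spec) else NULL
  params <- model$params
  state <- adam_init(params)
  L <- spec$n_classes
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(spec$seed, 100L + ep), sample.int(n))
    losses <- c(); accs <- c(); steps <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      Xb <- x[, , , idx, drop = FALSE]
      Y <- matrix(0, L, length(idx))
      Y[cbind(tr$y[idx] + 1L, seq_along(idx))] <- 1
      cache <- cnn_forward(params, Xb, keep_cache = TRUE)
      p_true <- cache$probs[cbind(tr$y[idx] + 1L, seq_along(idx))]
      losses <- c(losses, -mean(log(pmax(p_true, 1e-12))))
      accs <- c(accs, mean(max.col(t(cache$probs), ties.method = "first") - 1L == tr$y[idx]))
      grads <- cnn_backward(params, cache, Y)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      steps <- steps + 1L
    }
    row <- tibble(epoch = ep, loss = mean(losses), accuracy = mean(accs),
                  steps = steps, val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(val)) {
      model$params <- params
      vp <- predict_proba_params(params, standardize(val$x, model$norm))
      vt <- vp[cbind(seq_len(nrow(vp)), val$y + 1L)]
      row$val_loss <- -mean(log(pmax(vt, 1e-12)))
      row$val_accuracy <- mean(max.col(vp, ties.method = "first") - 1L == val$y)
    }
    hist[[ep]] <- row
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.4f%s\n", ep, row$loss, row$accuracy,
                  if (!is.null(val)) sprintf("  val_acc %.4f", row$val_accuracy) else ""))
    }
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model
}

# probabilities as an n x L matrix, batched to bound memory
predict_proba_params <- function(params, x, batch = 1024L) {
  n <- dim(x)[4L]
  out <- matrix(0, n, length(params$bo))
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    out[idx, ] <- t(cnn_forward(params, x[, , , idx, drop = FALSE])$probs)
  }
  out
}

#' Classify patches
#'
#' Applies a trained model: each patch gets the full class probability
#' vector, the argmax label (ties broken toward the lowest class index)
#' and the top probability as `confidence`. Input order is preserved.
#'
#' @param model a trained `patch_cnn`.
#' @param patches a [patch_set()] or a `w x w x C x n` array.
#' @return A tibble with columns `label`, `confidence` and `p_0 .. p_{L-1}`.
#' @export
classify_patches <- function(model, patches) {
  stopifnot(inherits(model, "patch_cnn"))
  if (!isTRUE(model$trained)) stop_state("classifier has not been trained")
  x <- if (inherits(patches, "patch_set")) patches$patches else patches
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  spec <- model$spec
  if (d[1L] != spec$w || d[2L] != spec$w || d[3L] != spec$channels) {
    stop_validation("patch dims %dx%dx%d do not match the model's %dx%dx%d",
                    d[1L], d[2L], d[3L], spec$w, spec$w, spec$channels)
  }
  probs <- predict_proba_params(model$params, standardize(x, model$norm))
  lab <- max.col(probs, ties.method = "first") - 1L
  out <- tibble(label = lab, confidence = probs[cbind(seq_len(nrow(probs)), lab + 1L)])
  colnames(probs) <- paste0("p_", seq_len(spec$n_classes) - 1L)
  dplyr::bind_cols(out, as_tibble(probs))
}

#' Evaluate a classifier
#'
#' Top-1 and top-k accuracy plus the L x L confusion matrix (rows = true
#' class, columns = predicted). A top-k hit means the true label is among
#' the k highest-probability classes, with ties resolved by lowest class
#' index first, so top-k >= top-1 always.
#'
#' @param model a trained `patch_cnn`.
#' @param test_set labeled [patch_set()] (or `list(x=, y=)`).
#' @param k_top k for the top-k accuracy (default 5).
#' @return An `eval_report`: list with `top1`, `topk`, `k_top`,
#'   `confusion`, `n`, `per_class_recall`. See [glance()].
#' @export
evaluate_classifier <- function(model, test_set, k_top = 5L) {
  stopifnot(inherits(model, "patch_cnn"))
  if (!isTRUE(model$trained)) stop_state("classifier has not been trained")
  te <- patches_xy(test_set, model$spec)
  if (!length(te$y)) stop_validation("empty test set")
  probs <- predict_proba_params(model$params, standardize(te$x, model$norm))
  L <- model$spec$n_classes
  k_top <- min(as.integer(k_top), L)
  pred <- max.col(probs, ties.method = "first") - 1L
  topk_hit <- vapply(seq_along(te$y), function(i) {
    ranking <- order(-probs[i, ], seq_len(L))[seq_len(k_top)] - 1L
    te$y[i] %in% ranking
  }, logical(1))
  conf <- table(factor(te$y, levels = 0:(L - 1L)), factor(pred, levels = 0:(L - 1L)))
  recall <- diag(conf) / pmax(rowSums(conf), 1L)
  structure(list(top1 = mean(pred == te$y), topk = mean(topk_hit), k_top = k_top,
                 confusion = unclass(conf), n = length(te$y),
                 per_class_recall = as.numeric(recall)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d: top-1 %.2f%%, top-%d %.2f%%\n",
              x$n, 100 * x$top1, x$k_top, 100 * x$topk))
  invisible(x)
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(n = x$n, top1 = x$top1, topk = x$topk, k_top = x$k_top)
}

#' @method tidy patch_cnn
#' @export
tidy.patch_cnn <- function(x, ...) {
  if (is.null(x$history)) stop_state("model has no training history yet")
  x$history
}

#' @method glance patch_cnn
#' @export
glance.patch_cnn <- function(x, ...) {
  tibble(parameters = x$param_count, trained = x$trained,
         epochs = if (is.null(x$history)) 0L else nrow(x$history),
         final_loss = if (is.null(x$history)) NA_real_ else dplyr::last(x$history$loss),
         final_accuracy = if (is.null(x$history)) NA_real_ else dplyr::last(x$history$accuracy))
}

#' Save / load a trained classifier
#'
#' A single checkpoint file (RDS) holding the spec, weights, normalization
#' statistics and history; loading restores a model whose predictions are
#' identical to the saved one's.
#'
#' @param model a `patch_cnn`.
#' @param path checkpoint file path.
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   the restored model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "patch_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "patch_cnn")) stop_validation("'%s' is not a classifier checkpoint", path)
  model
}
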