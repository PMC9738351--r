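# Network runtime. Because every conv/pool kernel has height 1, the 19
# electrode rows are independent through the feature extractor: a batch of n
# tensors is laid out as one tall matrix with B = n * 19 logical rows, each
# carrying T time steps and C feature planes. Row index = (b - 1) * T + t,
# column = plane. Convolutions become im2col gathers followed by one BLAS
# matmul; pooling is an elementwise max over shifted row sets. Dense layers
# act on the per-sample flattened features.

# --- layer planning ---------------------------------------------------------

same_pad_left <- function(w, k, s) {
  out <- ceiling(w / s)
  total <- max((out - 1L) * s + k - w, 0L)
  total %/% 2L
}

# Index matrix (T_out x k): input time index per output step and kernel
# offset; 0 marks padding.
window_index_matrix <- function(t_in, k, s, padding) {
  t_out <- conv_out_width(t_in, k, s, padding)
  pad_l <- if (padding == "same") same_pad_left(t_in, k, s) else 0L
  idx <- outer(seq_len(t_out) - 1L, seq_len(k) - 1L,
               function(a, b) a * s + b + 1L - pad_l)
  idx[idx < 1L | idx > t_in] <- 0L
  storage.mode(idx) <- "integer"
  idx
}

build_plans <- function(spec) {
  tr <- shape_trace(spec)
  h <- spec$input_shape[1]
  shp <- spec$input_shape
  plans <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv2d") {
      plans[[i]] <- list(t_in = shp[2], c_in = shp[3],
                         idx = window_index_matrix(shp[2], l$kernel[2],
                                                   l$stride[2], l$padding))
    } else if (l$kind == "maxpool2d") {
      plans[[i]] <- list(t_in = shp[2], c_in = shp[3],
                         idx = window_index_matrix(shp[2], l$pool[2],
                                                   l$stride[2], l$padding))
    } else if (l$kind == "flatten") {
      plans[[i]] <- list(t_in = shp[2], c_in = shp[3], h = h)
    }
    shp <- tr$shape[[i]]
  }
  plans
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Instantiate a trainable network from a specification
#'
#' Allocates seeded Glorot-uniform weights and zero biases for every
#' parameterized layer. The per-layer array sizes always equal the closed
#' form of [count_parameters()].
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed for weight initialization.
#' @return An `emdnet_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  trace <- shape_trace(spec)  # also validates shapes
  plans <- build_plans(spec)
  set.seed(seed)
  params <- vector("list", length(spec$layers))
  shp <- spec$input_shape
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv2d") {
      kc <- l$kernel[2] * shp[3]
      params[[i]] <- list(W = glorot_uniform(kc, l$kernel[2] * l$filters,
                                             c(kc, l$filters)),
                          b = numeric(l$filters))
    } else if (l$kind == "dense") {
      params[[i]] <- list(W = glorot_uniform(shp[1], l$units, c(shp[1], l$units)),
                          b = numeric(l$units))
    }
    shp <- trace$shape[[i]]
  }
  structure(list(spec = spec, params = params, plans = plans, trace = trace,
                 seed = as.integer(seed), normalize = "none", trained = FALSE),
            class = "emdnet_model")
}

#' Trainable parameter counts of an instantiated model
#'
#' Counted from the allocated weight arrays themselves; the independent
#' closed form is [count_parameters()].
#'
#' @param model An `emdnet_model`.
#' @return Integer vector, one entry per layer.
#' @export
model_parameter_counts <- function(model) {
  vapply(model$params, function(p) {
    if (is.null(p)) 0L else length(p$W) + length(p$b)
  }, integer(1))
}

# --- forward / backward -----------------------------------------------------

# X: array (n, H, T0, C0) -> planes x positions matrix (C0 x (n*H*T0)),
# position index ordered t fastest, then electrode row h, then sample i.
input_to_planes <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(4, 3, 2, 1)), nrow = d[4])
}

# Reusable buffer pool: the conv-stage intermediates are tens to hundreds of
# MB per mini-batch, so the training loop allocates them once per distinct
# batch size and the kernels write into them in place.
new_workspace <- function() new.env(parent = emptyenv())

ws_mat <- function(ws, key, nr, nc) {
  b <- ws[[key]]
  if (is.null(b) || nrow(b) != nr || ncol(b) != nc) {
    b <- matrix(0, nr, nc)
    ws[[key]] <- b
  }
  b
}

ws_imat <- function(ws, key, nr, nc) {
  b <- ws[[key]]
  if (is.null(b) || nrow(b) != nr || ncol(b) != nc) {
    b <- matrix(0L, nr, nc)
    ws[[key]] <- b
  }
  b
}

ws_vec <- function(ws, key, n) {
  b <- ws[[key]]
  if (is.null(b) || length(b) != n) {
    b <- numeric(n)
    ws[[key]] <- b
  }
  b
}

forward_pass <- function(model, x, training = FALSE, ws = new_workspace()) {
  n <- dim(x)[1]
  h <- model$spec$input_shape[1]
  a <- input_to_planes(x)
  n_b <- n * h  # logical rows through the conv stage
  caches <- vector("list", length(model$spec$layers))
  for (i in seq_along(model$spec$layers)) {
    l <- model$spec$layers[[i]]
    p <- model$params[[i]]
    pl <- model$plans[[i]]
    if (l$kind == "conv2d") {
      n_pos <- n_b * nrow(pl$idx)
      pm <- ws_mat(ws, sprintf("P%d_%d", i, n_b), ncol(pl$idx) * pl$c_in, n_pos)
      z <- ws_mat(ws, sprintf("Z%d_%d", i, n_b), l$filters, n_pos)
      cpp_conv_forward(a, p$W, p$b, pl$idx, n_b, pl$t_in,
                       l$activation == "relu", pm, z)
      a <- z
      caches[[i]] <- list(P = pm, out = a)
    } else if (l$kind == "maxpool2d") {
      n_pos <- n_b * nrow(pl$idx)
      out <- ws_mat(ws, sprintf("M%d_%d", i, n_b), pl$c_in, n_pos)
      wch <- ws_imat(ws, sprintf("Mw%d_%d", i, n_b), pl$c_in, n_pos)
      cpp_maxpool_forward(a, pl$idx, n_b, pl$t_in, out, wch)
      a <- out
      caches[[i]] <- list(which = wch)
    } else if (l$kind == "flatten") {
      a <- matrix(aperm(array(a, c(pl$c_in, pl$t_in, pl$h, n)), c(4, 1, 2, 3)),
                  nrow = n)
      caches[[i]] <- list()
    } else if (l$kind == "dense") {
      z <- a %*% p$W
      z <- z + rep(p$b, each = nrow(z))
      caches[[i]] <- list(inp = a)
      a <- switch(l$activation,
                  relu = pmax(z, 0),
                  softmax = softmax_rows(z),
                  z)
      caches[[i]]$out <- a
    } else if (l$kind == "dropout") {
      if (training) {
        mask <- matrix(stats::runif(length(a)) >= l$rate, nrow(a), ncol(a))
        a <- a * mask / (1 - l$rate)
        caches[[i]] <- list(mask = mask, rate = l$rate)
      } else {
        caches[[i]] <- list()
      }
    }
  }
  list(out = a, caches = caches, n = n, n_b = n_b)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# d_out: gradient wrt final softmax logits (probs - Y)/n.
backward_pass <- function(model, fw, d_out, ws = new_workspace()) {
  layers <- model$spec$layers
  grads <- vector("list", length(layers))
  da <- d_out
  n <- fw$n
  h <- model$spec$input_shape[1]
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    p <- model$params[[i]]
    pl <- model$plans[[i]]
    cc <- fw$caches[[i]]
    if (l$kind == "dense") {
      dz <- if (l$activation == "relu") da * (cc$out > 0) else da
      grads[[i]] <- list(W = crossprod(cc$inp, dz), b = colSums(dz))
      da <- tcrossprod(dz, p$W)
    } else if (l$kind == "dropout") {
      if (!is.null(cc$mask)) da <- da * cc$mask / (1 - cc$rate)
    } else if (l$kind == "flatten") {
      da <- matrix(aperm(array(da, c(n, pl$c_in, pl$t_in, pl$h)), c(2, 3, 4, 1)),
                   nrow = pl$c_in)
    } else if (l$kind == "maxpool2d") {
      g <- ws_mat(ws, sprintf("dM%d_%d", i, fw$n_b), pl$c_in, fw$n_b * pl$t_in)
      cpp_maxpool_backward(da, cc$which, pl$idx, fw$n_b, pl$t_in, g)
      da <- g
    } else if (l$kind == "conv2d") {
      dW <- ws_mat(ws, sprintf("dW%d", i), nrow(p$W), ncol(p$W))
      db <- ws_vec(ws, sprintf("db%d", i), length(p$b))
      need_input_grad <- i > 1L  # layer 1 sits on the data: skip its dX
      if (need_input_grad) {
        dP <- ws_mat(ws, sprintf("dP%d_%d", i, fw$n_b), nrow(p$W), ncol(da))
        dAprev <- ws_mat(ws, sprintf("dA%d_%d", i, fw$n_b), pl$c_in,
                         fw$n_b * pl$t_in)
      } else {
        dP <- matrix(0, 0L, 0L)
        dAprev <- matrix(0, 0L, 0L)
      }
      cpp_conv_backward(cc$P, cc$out, p$W, da, pl$idx, fw$n_b, pl$t_in,
                        l$activation == "relu", dW, db, need_input_grad,
                        dP, dAprev)
      grads[[i]] <- list(W = dW, b = db)
      da <- if (need_input_grad) dAprev else NULL
    }
  }
  grads
}

# --- training ---------------------------------------------------------------

#' Training configuration
#'
#' Adam optimizer with the hyperparameters used throughout:
#' learning rate `1e-2`, first-moment decay 0.9, second-moment decay 0.999;
#' categorical cross-entropy on the softmax output.
#'
#' @param learning_rate Adam step size (default `1e-2`).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9, 0.999).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training passes over the data (default 50).
#' @param seed Seed driving shuffling and dropout.
#' @param loss Only `"categorical_cross_entropy"` is implemented.
#' @param normalize `"none"` (default) or `"zscore"`: per-epoch, per-channel,
#'   per-plane standardization of the input tensors before training; the
#'   fitted model remembers the mode and applies it at prediction time.
#' @param epsilon Adam denominator offset.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-2, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 32L, epochs = 50L, seed = 1L,
                         loss = "categorical_cross_entropy",
                         normalize = c("none", "zscore"), epsilon = 1e-8) {
  loss <- match.arg(loss, "categorical_cross_entropy")
  normalize <- match.arg(normalize)
  stopifnot(learning_rate >= 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), loss = loss, normalize = normalize,
                 epsilon = epsilon),
            class = "train_config")
}

# Per-epoch, per-channel, per-plane z-scoring over the time axis.
normalize_tensors <- function(x, mode) {
  if (mode == "none") return(x)
  d <- dim(x)
  xt <- aperm(x, c(3, 1, 2, 4))          # (T, n, H, C)
  m <- matrix(xt, nrow = d[3])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2)
  sdv[sdv < 1e-8] <- 1e-8
  m <- (m - rep(mu, each = d[3])) / rep(sdv, each = d[3])
  aperm(array(m, dim(xt)), c(2, 3, 1, 4))
}

as_tensor_array <- function(x) {
  if (inherits(x, "imf_tensor_set")) x$data else x
}

labels_for <- function(x, y = NULL) {
  if (!is.null(y)) return(class_code(y))
  if (inherits(x, "imf_tensor_set")) return(class_code(x$manifest$label))
  stop("labels required: pass y or an imf_tensor_set", call. = FALSE)
}

#' Train the classifier
#'
#' Mini-batch Adam on categorical cross-entropy. All randomness (shuffling,
#' dropout) is driven by `cfg$seed`, so a fixed `(model, data, cfg)` triple
#' reproduces the loss history exactly.
#'
#' @param model An `emdnet_model` from [build_model()].
#' @param x Tensors: array `(n, 19, 1280, 3)` or an `imf_tensor_set`.
#' @param y Class labels (codes 0:2 or `"ES"/"PNES"/"CS"`); taken from the
#'   manifest when `x` is an `imf_tensor_set`.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch mean training loss.
#' @return The trained model, with `$history` (mean training loss per epoch).
#' @export
train_model <- function(model, x, y = NULL, cfg = train_config(),
                        verbose = FALSE) {
  labels <- labels_for(x, y)
  x <- as_tensor_array(x)
  n <- dim(x)[1]
  if (length(labels) != n) stop("length(y) must match number of tensors", call. = FALSE)
  if (length(unique(labels)) < 3L) {
    stop("stratification error: all 3 classes must appear in the training set",
         call. = FALSE)
  }
  x <- normalize_tensors(x, cfg$normalize)
  model$normalize <- cfg$normalize
  yh <- matrix(0, n, 3)
  yh[cbind(seq_len(n), labels + 1L)] <- 1

  # Parameters and Adam state are updated in place by cpp_adam_step; deep-copy
  # the weights first so the caller's model object is left untouched.
  model$params <- lapply(model$params, function(p) {
    if (is.null(p)) NULL else list(W = p$W + 0, b = p$b + 0)
  })
  mom <- lapply(model$params, function(p) {
    if (is.null(p)) NULL else list(mW = p$W * 0, vW = p$W * 0,
                                   mb = p$b * 0, vb = p$b * 0)
  })
  tstep <- 0L
  history <- numeric(cfg$epochs)
  ws <- new_workspace()
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    splits <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    ep_loss <- 0
    for (bidx in splits) {
      xb <- x[bidx, , , , drop = FALSE]
      yb <- yh[bidx, , drop = FALSE]
      fw <- forward_pass(model, xb, training = TRUE, ws = ws)
      probs <- fw$out
      loss <- -mean(log(pmax(rowSums(probs * yb), 1e-12)))
      ep_loss <- ep_loss + loss * length(bidx)
      grads <- backward_pass(model, fw, (probs - yb) / length(bidx), ws = ws)
      tstep <- tstep + 1L
      bc1 <- 1 - cfg$beta1^tstep
      bc2 <- 1 - cfg$beta2^tstep
      for (i in seq_along(model$params)) {
        if (is.null(model$params[[i]])) next
        g <- grads[[i]]
        st <- mom[[i]]
        cpp_adam_step(model$params[[i]]$W, st$mW, st$vW, g$W,
                      cfg$learning_rate, cfg$beta1, cfg$beta2, bc1, bc2,
                      cfg$epsilon)
        cpp_adam_step(model$params[[i]]$b, st$mb, st$vb, g$b,
                      cfg$learning_rate, cfg$beta1, cfg$beta2, bc1, bc2,
                      cfg$epsilon)
      }
    }
    history[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs,
                                 history[ep]))
  }
  model$history <- history
  model$trained <- TRUE
  rm(ws, x)
  gc(verbose = FALSE)  # release the workspace pool promptly
  model
}

#' Predict class probabilities and labels
#'
#' Deterministic (dropout off); ties in the argmax break toward the lowest
#' class code. Input is processed in chunks to bound memory.
#'
#' @param model A (typically trained) `emdnet_model`.
#' @param x Array `(n, 19, 1280, 3)` or `imf_tensor_set`.
#' @param chunk Chunk size for batched inference (bounds peak memory).
#' @return List with `prob` (n x 3 matrix, columns ES/PNES/CS) and `label`
#'   (integer codes 0:2).
#' @export
predict_classes <- function(model, x, chunk = 32L) {
  x <- as_tensor_array(x)
  d <- dim(x)
  if (length(d) != 4L || !all(d[2:4] == model$spec$input_shape)) {
    stop("shape error: expected tensors of ",
         paste(model$spec$input_shape, collapse = " x "), call. = FALSE)
  }
  x <- normalize_tensors(x, model$normalize)
  n <- d[1]
  prob <- matrix(0, n, 3, dimnames = list(NULL, class_levels()))
  ws <- new_workspace()
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    fw <- forward_pass(model, x[s:e, , , , drop = FALSE], training = FALSE,
                       ws = ws)
    prob[s:e, ] <- fw$out
  }
  list(prob = prob, label = max.col(prob, ties.method = "first") - 1L)
}

#' @export
predict.emdnet_model <- function(object, newdata, ...) {
  predict_classes(object, newdata, ...)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file; a JSON sidecar (same path, `.json`) records
#' the seed, normalization mode and per-layer parameter counts for audit.
#'
#' @param model An `emdnet_model`.
#' @param path Path to an `.rds` file.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(seed = model$seed, normalize = model$normalize,
               trained = model$trained,
               parameters = model_parameter_counts(model),
               total_parameters = sum(model_parameter_counts(model)))
  jsonlite::write_json(side, sub("\\.rds$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "emdnet_model")) stop("not an emdnet_model checkpoint", call. = FALSE)
  m
}
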