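# Declarative network description. Convolution and pooling kernels always
# have height 1: the 19 electrode rows are never mixed by the feature
# extractor, only by the dense layers after flattening.

layer_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' Layer constructors
#'
#' Building blocks for [model_spec()]. Kernels, pools and strides are
#' `(height, width)` pairs; height must be 1 for conv/pool layers (the
#' channel dimension is never mixed).
#'
#' @param filters Number of convolution filters.
#' @param kernel,pool `(h, w)` integer pair.
#' @param stride `(h, w)` integer pair.
#' @param padding `"same"` or `"valid"`.
#' @param activation `"relu"`, `"softmax"` or `"none"`.
#' @param units Dense layer width.
#' @param rate Dropout fraction in (0, 1).
#' @return A `layer_spec`.
#' @name layers
NULL

#' @rdname layers
#' @export
conv2d_layer <- function(filters, kernel, stride = c(1L, 1L),
                         padding = c("same", "valid"), activation = "relu") {
  padding <- match.arg(padding)
  stopifnot(filters >= 1, length(kernel) == 2, length(stride) == 2,
            all(stride >= 1))
  if (kernel[1] != 1L) stop("conv kernel height must be 1", call. = FALSE)
  layer_spec("conv2d", filters = as.integer(filters),
             kernel = as.integer(kernel), stride = as.integer(stride),
             padding = padding, activation = activation)
}

#' @rdname layers
#' @export
maxpool2d_layer <- function(pool, stride = pool, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  stopifnot(length(pool) == 2, length(stride) == 2, all(stride >= 1))
  if (pool[1] != 1L) stop("pool height must be 1", call. = FALSE)
  layer_spec("maxpool2d", pool = as.integer(pool), stride = as.integer(stride),
             padding = padding)
}

#' @rdname layers
#' @export
flatten_layer <- function() layer_spec("flatten")

#' @rdname layers
#' @export
dense_layer <- function(units, activation = "relu") {
  stopifnot(units >= 1)
  layer_spec("dense", units = as.integer(units), activation = activation)
}

#' @rdname layers
#' @export
dropout_layer <- function(rate) {
  stopifnot(rate > 0, rate < 1)
  layer_spec("dropout", rate = rate)
}

#' Assemble a model specification
#'
#' @param layers List of `layer_spec` objects, in order.
#' @param input_shape `(channels, samples, planes)` triple; default
#'   `c(19, 1280, 3)`.
#' @return A `model_spec`.
#' @export
model_spec <- function(layers, input_shape = c(19L, 1280L, 3L)) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  if (!all(vapply(layers, inherits, logical(1), "layer_spec"))) {
    stop("layers must be layer_spec objects", call. = FALSE)
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape)),
            class = "model_spec")
}

#' The default three-way EEG classifier architecture
#'
#' Two convolution+pooling stages over the time axis followed by three dense
#' layers with a dropout stage and a softmax output:
#' conv(64 filters, 1x6, stride 1x2, same, ReLU) -> maxpool(1x2, stride 1x2,
#' valid) -> conv(32, 1x3, stride 1x2, same, ReLU) -> maxpool(1x3, stride
#' 1x2, same) -> flatten -> dense(128, ReLU) -> dense(32, ReLU) ->
#' dropout(0.3) -> dense(16, ReLU) -> dense(3, softmax).
#'
#' With the 19 x 1280 x 3 IMF-tensor input this traces shapes
#' 19x640x64 -> 19x320x64 -> 19x160x32 -> 19x80x32, flattens to 48,640
#' features, and has 6,238,147 trainable parameters.
#'
#' @return A `model_spec`.
#' @export
default_model_spec <- function() {
  model_spec(list(
    conv2d_layer(64L, c(1L, 6L), stride = c(1L, 2L), padding = "same"),
    maxpool2d_layer(c(1L, 2L), stride = c(1L, 2L), padding = "valid"),
    conv2d_layer(32L, c(1L, 3L), stride = c(1L, 2L), padding = "same"),
    maxpool2d_layer(c(1L, 3L), stride = c(1L, 2L), padding = "same"),
    flatten_layer(),
    dense_layer(128L),
    dense_layer(32L),
    dropout_layer(0.3),
    dense_layer(16L),
    dense_layer(3L, activation = "softmax")
  ), input_shape = c(19L, 1280L, 3L))
}

# Output width of a windowed op along the time axis.
conv_out_width <- function(w, k, s, padding) {
  out <- if (padding == "same") ceiling(w / s) else floor((w - k) / s) + 1
  if (out < 1) {
    stop(sprintf("shape error: width %d too small for kernel %d stride %d (%s)",
                 w, k, s, padding), call. = FALSE)
  }
  as.integer(out)
}

layer_name <- function(l, i) {
  switch(l$kind,
         conv2d = sprintf("conv2d_%d", i),
         maxpool2d = sprintf("maxpool2d_%d", i),
         flatten = "flatten",
         dense = sprintf("dense_%d", i),
         dropout = "dropout",
         l$kind)
}

#' Symbolic per-layer output shapes
#'
#' Propagates the input shape through the spec without instantiating any
#' weights. `"same"` padding gives output width `ceiling(w / stride)`;
#' `"valid"` gives `floor((w - k) / stride) + 1`.
#'
#' @param spec A `model_spec`.
#' @return Data frame with `layer`, `kind`, and `output` (printable shape) plus
#'   list-column `shape` of integer vectors.
#' @export
shape_trace <- function(spec) {
  shp <- spec$input_shape  # (channels, width, planes)
  rows <- list()
  counters <- c(conv2d = 0L, maxpool2d = 0L, dense = 0L)
  for (l in spec$layers) {
    if (l$kind %in% names(counters)) counters[l$kind] <- counters[l$kind] + 1L
    nm <- layer_name(l, counters[l$kind])
    if (l$kind == "conv2d") {
      if (l$kernel[2] > shp[2] && l$padding == "valid") {
        stop("shape error at ", nm, ": kernel wider than input", call. = FALSE)
      }
      shp <- c(shp[1], conv_out_width(shp[2], l$kernel[2], l$stride[2], l$padding),
               l$filters)
    } else if (l$kind == "maxpool2d") {
      if (l$pool[2] > shp[2] && l$padding == "valid") {
        stop("shape error at ", nm, ": pool wider than input", call. = FALSE)
      }
      shp <- c(shp[1], conv_out_width(shp[2], l$pool[2], l$stride[2], l$padding),
               shp[3])
    } else if (l$kind == "flatten") {
      shp <- prod(shp)
    } else if (l$kind == "dense") {
      if (length(shp) != 1L) stop("shape error: dense layer needs flat input", call. = FALSE)
      shp <- l$units
    } # dropout: shape unchanged
    rows[[length(rows) + 1L]] <-
      list(layer = nm, kind = l$kind,
           output = paste(shp, collapse = " x "), shape = as.integer(shp))
  }
  out <- data.frame(layer = vapply(rows, `[[`, "", "layer"),
                    kind = vapply(rows, `[[`, "", "kind"),
                    output = vapply(rows, `[[`, "", "output"),
                    stringsAsFactors = FALSE)
  out$shape <- lapply(rows, `[[`, "shape")
  out
}

#' Closed-form trainable parameter counts
#'
#' Convolution: `(kh * kw * c_in + 1) * filters`; dense: `(n_in + 1) * units`;
#' pooling, dropout, flatten and the softmax nonlinearity have none.
#'
#' @param spec A `model_spec`.
#' @return Data frame with `layer`, `output`, `parameters`; the total is in
#'   attribute `"total"` and via [total_parameters()].
#' @export
count_parameters <- function(spec) {
  tr <- shape_trace(spec)
  shp_in <- spec$input_shape
  params <- integer(nrow(tr))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv2d") {
      c_in <- shp_in[3]
      params[i] <- (l$kernel[1] * l$kernel[2] * c_in + 1L) * l$filters
    } else if (l$kind == "dense") {
      params[i] <- (shp_in[1] + 1L) * l$units  # shp_in is flat here
    }
    shp_in <- tr$shape[[i]]
  }
  out <- data.frame(layer = tr$layer, output = tr$output,
                    parameters = params, stringsAsFactors = FALSE)
  attr(out, "total") <- sum(params)
  out
}

#' @rdname count_parameters
#' @export
total_parameters <- function(spec) attr(count_parameters(spec), "total")

#' @export
print.model_spec <- function(x, ...) {
  tr <- count_parameters(x)
  cat(sprintf("<model_spec> input %s\n", paste(x$input_shape, collapse = " x ")))
  print(tr, row.names = FALSE)
  cat(sprintf("total trainable parameters: %s\n",
              format(attr(tr, "total"), big.mark = ",")))
  invisible(x)
}
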