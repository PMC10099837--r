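#' Declarative CNN-LSTM architecture specification
#'
#' Builds the layer-by-layer description of the deep sequence classifier
#' used for this task — an embedding layer, two convolution + max-pooling
#' blocks, a recurrent LSTM memory layer, a fully connected layer and a
#' softmax output whose width equals the number of classes — together with
#' an early-stopping policy.  This is a pure specification object: the core
#' package performs no training, and the spec can be serialized to JSON and
#' handed to any deep learning plugin.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param vocab_size,embedding_dim Embedding layer shape.
#' @param conv_filters,kernel_size,pool_size Convolution block
#'   hyperparameters (each block uses the same settings).
#' @param lstm_units LSTM layer width.
#' @param dense_units Fully connected layer width.
#' @param early_stopping `NULL` to omit, or a list with `patience` and
#'   `monitor` (e.g. `list(patience = 3, monitor = "val_loss")`).
#' @return An object of class `snprex_arch_spec`.
#' @export
build_cnn_lstm_spec <- function(n_classes = 3L, vocab_size = 20000L,
                                embedding_dim = 128L, conv_filters = 64L,
                                kernel_size = 5L, pool_size = 2L,
                                lstm_units = 64L, dense_units = 64L,
                                early_stopping = list(patience = 3L,
                                                      monitor = "val_loss")) {
  if (n_classes < 2L) abort("an architecture needs at least 2 output classes.")
  conv_block <- function(i) {
    list(
      list(type = "conv1d", filters = conv_filters,
           kernel_size = kernel_size, activation = "relu",
           name = sprintf("conv_%d", i)),
      list(type = "max_pooling1d", pool_size = pool_size,
           name = sprintf("pool_%d", i))
    )
  }
  layers <- c(
    list(list(type = "embedding", vocab_size = vocab_size,
              dim = embedding_dim, name = "embedding")),
    conv_block(1), conv_block(2),
    list(
      list(type = "lstm", units = lstm_units, name = "lstm"),
      list(type = "dense", units = dense_units, activation = "relu",
           name = "dense"),
      list(type = "dense", units = n_classes, activation = "softmax",
           name = "output")
    )
  )
  structure(
    list(layers = layers, n_classes = as.integer(n_classes),
         early_stopping = early_stopping),
    class = "snprex_arch_spec"
  )
}

#' Serialize / parse an architecture spec
#'
#' @param spec A `snprex_arch_spec`.
#' @param json A JSON string from `arch_spec_to_json()`.
#' @return `arch_spec_to_json()` returns a JSON string;
#'   `arch_spec_from_json()` the reconstructed spec (round-trip equal).
#' @export
arch_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "snprex_arch_spec"))
  as.character(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, null = "null"))
}

#' @rdname arch_spec_to_json
#' @export
arch_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  x$n_classes <- as.integer(x$n_classes)
  x$layers <- lapply(x$layers, function(l) {
    lapply(l, function(v) if (is.numeric(v)) as.integer(v) else v)
  })
  if (!is.null(x$early_stopping$patience)) {
    x$early_stopping$patience <- as.integer(x$early_stopping$patience)
  }
  structure(x, class = "snprex_arch_spec")
}

#' @export
print.snprex_arch_spec <- function(x, ...) {
  cat("<snprex_arch_spec>", length(x$layers), "layers ->", x$n_classes,
      "classes\n")
  for (l in x$layers) cat("  -", l$type, "\n")
  if (is.null(x$early_stopping)) {
    cat("  early stopping: absent\n")
  } else {
    cat("  early stopping:", x$early_stopping$monitor, "patience",
        x$early_stopping$patience, "\n")
  }
  invisible(x)
}
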