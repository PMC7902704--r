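#' CNN configuration
#'
#' Hyperparameters of the compact LeNet-style classifier: four 3x3
#' convolution blocks of 8, 16, 32 and 64 filters (stride 1, same padding,
#' ReLU), each followed by 2x2 max-pooling; dropout 0.3 between the third
#' pooling stage and the last convolution; a 128-unit fully connected ReLU
#' layer with dropout 0.5; and a softmax output over the species. Training
#' minimises categorical cross-entropy with Adam.
#'
#' `pool_stride` defaults to 2 so every pooling stage halves the feature
#' maps; stride-1 pooling is accepted for experimentation but leaves the
#' maps nearly full size and makes the flatten layer enormous.
#'
#' @param input_shape `(rows, cols, channels)` of the input images.
#' @param conv_filters filter counts of the four convolution layers.
#' @param kernel_size odd convolution kernel width.
#' @param pool_size,pool_stride max-pooling window and stride.
#' @param conv_stride convolution stride (the engine implements stride 1).
#' @param dropout_conv,dropout_dense dropout rates in `[0, 1)`.
#' @param dense_units width of the fully connected layer.
#' @param n_classes number of species.
#' @param learning_rate,batch_size,epochs Adam step size, mini-batch size,
#'   training epochs.
#' @param seed integer seed for weight initialisation, shuffling and
#'   dropout.
#' @return A `cnn_config` object (validated list).
#' @export
cnn_config <- function(input_shape = c(150L, 100L, 1L),
                       conv_filters = c(8L, 16L, 32L, 64L),
                       kernel_size = 3L, pool_size = 2L, pool_stride = 2L,
                       conv_stride = 1L, dropout_conv = 0.3, dropout_dense = 0.5,
                       dense_units = 128L, n_classes = 7L,
                       learning_rate = 1e-3, batch_size = 32L, epochs = 50L,
                       seed = 1L) {
  cfg <- list(
    input_shape = as.integer(input_shape), conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size), pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride), conv_stride = as.integer(conv_stride),
    dropout_conv = as.numeric(dropout_conv), dropout_dense = as.numeric(dropout_dense),
    dense_units = as.integer(dense_units), n_classes = as.integer(n_classes),
    learning_rate = as.numeric(learning_rate), batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), seed = as.integer(seed)
  )
  if (length(cfg$input_shape) != 3 || any(cfg$input_shape < 1)) {
    abort("`input_shape` must be (rows, cols, channels), all positive.")
  }
  if (cfg$input_shape[3] != 1L) abort("The engine handles single-channel (grayscale) input.")
  if (length(cfg$conv_filters) != 4 || any(cfg$conv_filters < 1)) {
    abort("`conv_filters` must give four positive filter counts.")
  }
  if (cfg$kernel_size %% 2L != 1L || cfg$kernel_size < 1L) abort("`kernel_size` must be odd.")
  if (cfg$conv_stride != 1L) abort("The engine implements convolution stride 1 only.")
  if (cfg$n_classes < 2L) abort("`n_classes` must be >= 2.")
  if (cfg$dropout_conv < 0 || cfg$dropout_conv >= 1 ||
      cfg$dropout_dense < 0 || cfg$dropout_dense >= 1) {
    abort("Dropout rates must be in [0, 1).")
  }
  if (cfg$pool_stride < 1L || cfg$pool_size < 1L) abort("Pooling window and stride must be >= 1.")
  if (cfg$epochs < 0L) abort("`epochs` must be >= 0.")
  structure(cfg, class = "cnn_config")
}

pool_out <- function(d, p, s) as.integer(floor((d - p) / s) + 1L)

# layer-by-layer shapes and parameter counts for a config
model_summary_tbl <- function(cfg) {
  rows <- list()
  add <- function(type, detail, shape, params) {
    rows[[length(rows) + 1]] <<- tibble(
      layer = length(rows) + 1L, type = type, detail = detail,
      output_shape = paste(shape, collapse = "x"), n_params = as.integer(params))
  }
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]; cin <- cfg$input_shape[3]
  k <- cfg$kernel_size
  for (i in seq_along(cfg$conv_filters)) {
    f <- cfg$conv_filters[i]
    add("conv2d", sprintf("%d filters %dx%d, relu", f, k, k), c(h, w, f),
        (k * k * cin + 1) * f)
    if (h < cfg$pool_size || w < cfg$pool_size) {
      abort(sprintf("Input %dx%d is too small for pooling stage %d.",
                    cfg$input_shape[1], cfg$input_shape[2], i))
    }
    h <- pool_out(h, cfg$pool_size, cfg$pool_stride)
    w <- pool_out(w, cfg$pool_size, cfg$pool_stride)
    add("maxpool2d", sprintf("%dx%d stride %d", cfg$pool_size, cfg$pool_size, cfg$pool_stride),
        c(h, w, f), 0)
    if (i == 3) add("dropout", sprintf("rate %.1f", cfg$dropout_conv), c(h, w, f), 0)
    cin <- f
  }
  flat <- h * w * cin
  add("flatten", "", flat, 0)
  add("dense", sprintf("%d units, relu", cfg$dense_units), cfg$dense_units,
      (flat + 1) * cfg$dense_units)
  add("dropout", sprintf("rate %.1f", cfg$dropout_dense), cfg$dense_units, 0)
  add("dense", sprintf("%d units, softmax", cfg$n_classes), cfg$n_classes,
      (cfg$dense_units + 1) * cfg$n_classes)
  dplyr::bind_rows(rows)
}

#' Build the CNN
#'
#' Instantiates the network for a configuration: validates that the input
#' survives all four pooling stages, computes the machine-readable layer
#' summary (type, output shape, parameter count) and draws the initial
#' weights (He-normal, seeded by `config$seed`).
#'
#' @param config a [cnn_config()].
#' @return A `cnn_model`: list with `config`, `summary` (tibble) and
#'   `weights`.
#' @examples
#' m <- build_model(cnn_config(input_shape = c(32, 32, 1)))
#' m$summary
#' @export
build_model <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  smry <- model_summary_tbl(config)  # errors if input too small
  k <- config$kernel_size
  weights <- with_seed_(config$seed, {
    w <- list()
    cin <- config$input_shape[3]
    h <- config$input_shape[1]; wd <- config$input_shape[2]
    for (i in seq_along(config$conv_filters)) {
      f <- config$conv_filters[i]
      fan_in <- k * k * cin
      w[[paste0("W", i)]] <- matrix(rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f)
      w[[paste0("b", i)]] <- numeric(f)
      h <- pool_out(h, config$pool_size, config$pool_stride)
      wd <- pool_out(wd, config$pool_size, config$pool_stride)
      cin <- f
    }
    flat <- h * wd * cin
    w$Wd1 <- matrix(rnorm(flat * config$dense_units, sd = sqrt(2 / flat)),
                    flat, config$dense_units)
    w$bd1 <- numeric(config$dense_units)
    w$Wd2 <- matrix(rnorm(config$dense_units * config$n_classes,
                          sd = sqrt(2 / config$dense_units)),
                    config$dense_units, config$n_classes)
    w$bd2 <- numeric(config$n_classes)
    w
  })
  structure(list(config = config, summary = smry, weights = weights),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %s, %d classes, %s parameters\n",
              paste(x$config$input_shape, collapse = "x"), x$config$n_classes,
              format(sum(x$summary$n_params), big.mark = ",")))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname build_model
#' @param model a `cnn_model`.
#' @export
n_parameters <- function(model) sum(model$summary$n_params)

# stack a list of gray_images (or matrices) into an (H, W, N) array in [0, 1]
images_to_array <- function(images, input_shape) {
  h <- input_shape[1]; w <- input_shape[2]
  arr <- array(0, c(h, w, length(images)))
  for (i in seq_along(images)) {
    m <- images[[i]]
    if (!is.matrix(m) || nrow(m) != h || ncol(m) != w) {
      abort(sprintf("Image %d is %sx%s; the model expects %dx%d.",
                    i, nrow(m), ncol(m), h, w))
    }
    arr[, , i] <- unclass(m) / 255
  }
  arr
}

#' Train the CNN
#'
#' Minimises categorical cross-entropy with mini-batch Adam. Pixels are
#' scaled to `[0, 1]`; the class order is the sorted species list (or the
#' `labels` argument). Training is deterministic for a fixed seed up to
#' floating-point reordering in the BLAS.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param data image index tibble with columns `image` and `species`
#'   (training partition only).
#' @param labels class label order; defaults to `sort(unique(data$species))`
#'   and must have exactly `n_classes` entries.
#' @param epochs overrides `config$epochs`; 0 returns the model unchanged
#'   with an empty history.
#' @param seed overrides `config$seed` for shuffling and dropout.
#' @param verbose print per-epoch loss/accuracy.
#' @return A `cnn_fit`: the trained model, the label order, and a history
#'   tibble (`epoch`, `loss`, `accuracy`).
#' @export
cnn_train <- function(model, data, labels = NULL, epochs = NULL, seed = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  if (!all(c("image", "species") %in% names(data)) || nrow(data) == 0) {
    abort("`data` must be a non-empty image index with `image` and `species` columns.")
  }
  labels <- labels %||% sort(unique(as.character(data$species)))
  if (length(labels) != cfg$n_classes) {
    abort(sprintf("Found %d label(s) but the model has %d output units.",
                  length(labels), cfg$n_classes))
  }
  bad <- setdiff(unique(as.character(data$species)), labels)
  if (length(bad)) abort(sprintf("Label(s) outside the label set: %s.", paste(bad, collapse = ", ")))
  epochs <- as.integer(epochs %||% cfg$epochs)
  seed <- as.integer(seed %||% cfg$seed)

  history <- tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
  if (epochs > 0) {
    X <- images_to_array(data$image, cfg$input_shape)
    y <- match(as.character(data$species), labels) - 1L
    res <- cnn_train_cpp(X, y, model$weights, cfg$n_classes, cfg$kernel_size,
                         cfg$pool_size, cfg$pool_stride, cfg$dropout_conv,
                         cfg$dropout_dense, epochs, cfg$batch_size,
                         cfg$learning_rate, seed, verbose)
    if (isTRUE(res$diverged)) {
      abort(sprintf(paste0("Training diverged (non-finite loss). Last finite losses: %s. ",
                           "Consider lowering learning_rate (current %g)."),
                    paste(signif(utils::tail(res$loss[is.finite(res$loss)], 3), 4),
                          collapse = ", "),
                    cfg$learning_rate))
    }
    model$weights <- res$weights
    history <- tibble(epoch = seq_len(epochs),
                      loss = as.numeric(res$loss),
                      accuracy = as.numeric(res$accuracy))
  }
  structure(list(model = model, labels = labels, history = history,
                 seed = seed, epochs = epochs),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit> %d classes, %d epoch(s)", length(x$labels), x$epochs))
  if (nrow(x$history)) {
    cat(sprintf("; final loss %.4f, accuracy %.4f",
                x$history$loss[nrow(x$history)], x$history$accuracy[nrow(x$history)]))
  }
  cat("\n")
  invisible(x)
}

#' @rdname cnn_train
#' @param x a `cnn_fit`.
#' @param ... unused.
#' @export
tidy.cnn_fit <- function(x, ...) x$history

#' @rdname cnn_train
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble(
    epochs = x$epochs,
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_,
    final_accuracy = if (nrow(x$history)) x$history$accuracy[nrow(x$history)] else NA_real_,
    n_parameters = n_parameters(x$model),
    seed = x$seed
  )
}

#' @rdname cnn_train
#' @param object a `cnn_fit`.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    theme_minimal()
}

predict_probs <- function(model, images, labels) {
  cfg <- model$config
  X <- images_to_array(images, cfg$input_shape)
  p <- cnn_predict_cpp(X, model$weights, cfg$n_classes, cfg$kernel_size,
                       cfg$pool_size, cfg$pool_stride)
  colnames(p) <- labels
  p
}

#' Predict species probabilities for images
#'
#' Returns one softmax probability vector per image (non-negative, summing
#' to 1) and the hard label (`.pred`) as the class with the highest
#' probability, ties broken by the lowest class index.
#'
#' @param object a `cnn_fit` (or a `cnn_model` with explicit `labels`).
#' @param newdata image index tibble with an `image` column, or a list of
#'   [gray_image()]s.
#' @param ... unused.
#' @return Tibble with any `tree_id`/`species` columns of `newdata` carried
#'   through (`species` renamed to `truth`), the predicted `.pred`, and one
#'   probability column per class.
#' @export
predict.cnn_fit <- function(object, newdata, ...) {
  predict_images(object$model, newdata, object$labels)
}

#' @rdname predict.cnn_fit
#' @param labels class label order for the output units.
#' @export
predict.cnn_model <- function(object, newdata, labels = NULL, ...) {
  labels <- labels %||% paste0("class_", seq_len(object$config$n_classes))
  predict_images(object, newdata, labels)
}

predict_images <- function(model, newdata, labels) {
  if (is.data.frame(newdata)) {
    images <- newdata$image
    meta <- tibble(
      tree_id = if ("tree_id" %in% names(newdata)) newdata$tree_id else NA_character_,
      truth = if ("species" %in% names(newdata)) as.character(newdata$species) else NA_character_
    )
  } else {
    images <- newdata
    meta <- tibble(tree_id = vapply(images, function(i) {
      attr(i, "tree_id") %||% NA_character_
    }, ""), truth = NA_character_)
  }
  p <- predict_probs(model, images, labels)
  dplyr::bind_cols(meta,
                   tibble(.pred = argmax_label(p, labels)),
                   as_tibble(as.data.frame(p)))
}
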