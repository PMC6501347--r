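#' Configuration of the convolutional surrogate
#'
#' The reference architecture: three convolutional blocks, each a
#' stride-1, size-preserving convolution with 32 learnable 5x5 kernels
#' followed by ReLU and 2x2 average pooling (spatial sizes 100 -> 50 -> 25
#' -> 12, floor on the odd size); then flatten, and dense layers of 512 and
#' 128 ReLU units with dropout (rate 0.25) before, between and after them;
#' a linear layer with 10 outputs ends the stack (one unit per eigenvalue).
#' Training minimises the mean absolute percentage error with adagrad at
#' learning rate 0.008, batch size 400, at most 100 epochs.  The activation,
#' padding and initialisation are not pinned down by the reference protocol
#' and are package choices (ReLU, same padding, Glorot-uniform).
#'
#' @param input_size side of the square descriptor (default 100).
#' @param n_conv_blocks,kernels_per_block,kernel_size conv stack shape.
#' @param dense_units integer vector of hidden dense layer widths.
#' @param n_outputs number of regressed eigenvalues.
#' @param dropout_rate dropout rate in `[0, 1)` for the three dropout layers.
#' @param learning_rate adagrad learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch bound (no early stopping; final-epoch weights are
#'   kept).
#' @param seed integer seed driving weight initialisation, batch shuffling
#'   and dropout; identical seeds and data give identical training runs.
#' @return an object of class `surrogate_config`.
#' @export
surrogate_config <- function(input_size = 100L, n_conv_blocks = 3L,
                             kernels_per_block = 32L, kernel_size = 5L,
                             dense_units = c(512L, 128L), n_outputs = 10L,
                             dropout_rate = 0.25, learning_rate = 0.008,
                             batch_size = 400L, max_epochs = 100L,
                             seed = 1L) {
  stopifnot(input_size >= 2L, n_conv_blocks >= 1L, kernels_per_block >= 1L,
            kernel_size %% 2L == 1L, length(dense_units) >= 1L,
            n_outputs >= 1L, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1L, max_epochs >= 1L)
  sizes <- input_size
  for (b in seq_len(n_conv_blocks)) {
    sizes <- c(sizes, sizes[length(sizes)] %/% 2L)
    if (sizes[length(sizes)] < 1L)
      stop("input of size ", input_size, " cannot pass ", n_conv_blocks,
           " pooling layers")
  }
  structure(list(input_size = as.integer(input_size),
                 n_conv_blocks = as.integer(n_conv_blocks),
                 kernels_per_block = as.integer(kernels_per_block),
                 kernel_size = as.integer(kernel_size),
                 dense_units = as.integer(dense_units),
                 n_outputs = as.integer(n_outputs),
                 dropout_rate = dropout_rate,
                 optimizer = "adagrad",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 activation = "relu",
                 spatial_sizes = as.integer(sizes),
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

#' @export
print.surrogate_config <- function(x, ...) {
  cat(sprintf(paste0("<surrogate_config> %dx%d input, %d conv blocks ",
                     "(%d kernels %dx%d), dense %s -> %d outputs\n"),
              x$input_size, x$input_size, x$n_conv_blocks,
              x$kernels_per_block, x$kernel_size, x$kernel_size,
              paste(x$dense_units, collapse = "/"), x$n_outputs))
  invisible(x)
}

flatten_dim <- function(config) {
  s <- config$spatial_sizes[length(config$spatial_sizes)]
  s * s * config$kernels_per_block
}

#' Instantiate an untrained surrogate model
#'
#' Initialises all weights (Glorot-uniform, zero biases) from
#' `config$seed` and reports the total parameter count.
#'
#' @param config a [surrogate_config()].
#' @return an object of class `trained_surrogate` with empty history.
#' @export
build_surrogate <- function(config = surrogate_config()) {
  stopifnot(inherits(config, "surrogate_config"))
  weights <- cpp_cnn_init(config, config$seed)
  structure(list(config = config, weights = weights,
                 history = data.frame(epoch = integer(0),
                                      train_mape = numeric(0),
                                      eval_mape = numeric(0)),
                 trained = FALSE),
            class = "trained_surrogate")
}

#' @export
print.trained_surrogate <- function(x, ...) {
  cat(sprintf("<trained_surrogate> %s, %s parameters, %d epochs trained\n",
              if (x$trained) "trained" else "untrained",
              format(n_parameters(x), big.mark = ","), nrow(x$history)))
  invisible(x)
}

#' Number of learnable parameters of a surrogate
#'
#' @param model a `trained_surrogate`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(unlist(model$weights, recursive = FALSE),
             function(layer) length(layer$W) + length(layer$b), numeric(1)))
}

as_input_cube <- function(x, input_size) {
  if (is.list(x) && !is.array(x))
    x <- simplify2array(lapply(x, unclass))        # N x N x samples
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("inputs must be a matrix, array or list")
  # accept samples-first arrays (from build_dataset) or samples-last cubes
  d <- dim(x)
  if (d[2] == input_size && d[3] == input_size && d[1] != input_size)
    x <- aperm(x, c(2, 3, 1))
  else if (d[1] == input_size && d[2] == input_size) x
  else stop("descriptor size ", paste(d, collapse = "x"),
            " does not match the surrogate input size ", input_size,
            "x", input_size,
            " (the surrogate has a fixed input size; prune longer chains)")
  x
}

#' Mean absolute percentage error between spectra
#'
#' `100 * mean over samples of mean over eigenvalues of
#' |predicted - true| / |true|` -- the training loss and the headline
#' evaluation score.  The denominator is always the true eigenvalue.
#'
#' @param true matrix of true eigenvalues (samples x modes), a
#'   `spectrum_target`, or a vector.
#' @param predicted matrix (or vector) of predictions, same shape.
#' @return scalar MAPE in percent.
#' @export
mape <- function(true, predicted) {
  if (inherits(true, "spectrum_target")) true <- true$eigenvalues
  true <- c(as.matrix(true))
  predicted <- c(as.matrix(predicted))
  if (length(true) != length(predicted))
    stop("true and predicted shapes disagree")
  if (any(true == 0)) stop("zero true eigenvalue: MAPE undefined")
  100 * mean(abs(predicted - true) / abs(true))
}

per_sample_mape <- function(true, predicted) {
  100 * rowMeans(abs(predicted - true) / abs(true))
}

#' Train the surrogate on descriptor/spectrum pairs
#'
#' Runs seeded minibatch adagrad on the MAPE loss.  The output bias of the
#' linear layer is initialised to the elementwise mean of the training
#' targets (a standard regression initialisation: the network starts at the
#' non-informative baseline and learns deviations), unless
#' `init_output_bias = "zero"`.  Training and evaluation losses are recorded
#' per epoch; the training value is the running average over the epoch's
#' minibatches (dropout active), the evaluation value a full deterministic
#' pass at epoch end.
#'
#' @param model a `trained_surrogate` from [build_surrogate()].
#' @param x training descriptors: array (samples x N x N), cube
#'   (N x N x samples) or list of matrices.
#' @param y training targets, matrix (samples x n_outputs) of strictly
#'   positive eigenvalues.
#' @param eval_x,eval_y optional held-out set scored once per epoch.
#' @param epochs number of epochs (default `config$max_epochs`).
#' @param batch_size minibatch size (default `config$batch_size`, capped at
#'   the sample count).
#' @param init_output_bias `"target_mean"` (default) or `"zero"`.
#' @param verbose print per-epoch losses?
#' @return the model with updated weights, `history` and `trained = TRUE`.
#' @export
train_surrogate <- function(model, x, y, eval_x = NULL, eval_y = NULL,
                            epochs = NULL, batch_size = NULL,
                            init_output_bias = c("target_mean", "zero"),
                            verbose = FALSE) {
  stopifnot(inherits(model, "trained_surrogate"))
  init_output_bias <- match.arg(init_output_bias)
  cfg <- model$config
  xc <- as_input_cube(x, cfg$input_size)
  y <- as.matrix(y)
  if (nrow(y) != dim(xc)[3]) y <- t(y)
  if (nrow(y) != dim(xc)[3] || ncol(y) != cfg$n_outputs)
    stop("targets must be n_samples x ", cfg$n_outputs)
  if (any(y <= 0)) stop("all training targets must be strictly positive")
  if (is.null(epochs)) epochs <- cfg$max_epochs
  if (is.null(batch_size)) batch_size <- min(cfg$batch_size, dim(xc)[3])
  ec <- NULL; ey <- NULL
  if (!is.null(eval_x)) {
    ec <- as_input_cube(eval_x, cfg$input_size)
    ey <- as.matrix(eval_y)
    if (nrow(ey) != dim(ec)[3]) ey <- t(ey)
    ey <- t(ey)
  }
  if (!model$trained && init_output_bias == "target_mean") {
    nd <- length(model$weights$dense)
    model$weights$dense[[nd]]$b <- colMeans(y)
  }
  fit <- cpp_cnn_train(model$weights, xc, t(y), ec, ey, cfg,
                       as.integer(epochs), as.integer(batch_size),
                       cfg$learning_rate, cfg$dropout_rate,
                       cfg$seed, verbose)
  prev <- nrow(model$history)
  model$weights <- fit$weights
  model$history <- rbind(model$history,
                         data.frame(epoch = prev + seq_len(epochs),
                                    train_mape = as.numeric(fit$train_mape),
                                    eval_mape = as.numeric(fit$eval_mape)))
  model$trained <- TRUE
  model
}

#' Predict eigenvalues from Coulomb matrices
#'
#' Deterministic forward pass with dropout off.  Inputs must match the
#' surrogate's fixed input size -- longer chains must be pruned first (see
#' [prune_chain()]).
#'
#' @param object a `trained_surrogate`.
#' @param newdata descriptors in any form accepted by [train_surrogate()].
#' @param ... unused.
#' @return matrix (samples x n_outputs) of predicted eigenvalues.
#' @export
predict.trained_surrogate <- function(object, newdata, ...) {
  xc <- as_input_cube(newdata, object$config$input_size)
  cpp_cnn_predict(object$weights, xc, object$config)
}

#' Write / read a trained surrogate as plain text
#'
#' The config goes to `config.json`, the training history to `history.tsv`
#' and every weight tensor to its own TSV file.
#'
#' @param model a `trained_surrogate`.
#' @param dir directory to create/read.
#' @return `write_surrogate` returns `dir` invisibly; `read_surrogate` the
#'   model.
#' @export
write_surrogate <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(model$history, file.path(dir, "history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  wtab <- function(m, path)
    utils::write.table(format(m, digits = 17, trim = TRUE), path,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  for (i in seq_along(model$weights$conv)) {
    wtab(model$weights$conv[[i]]$W, file.path(dir, sprintf("conv%d_W.tsv", i)))
    wtab(model$weights$conv[[i]]$b, file.path(dir, sprintf("conv%d_b.tsv", i)))
  }
  for (i in seq_along(model$weights$dense)) {
    wtab(model$weights$dense[[i]]$W,
         file.path(dir, sprintf("dense%d_W.tsv", i)))
    wtab(model$weights$dense[[i]]$b,
         file.path(dir, sprintf("dense%d_b.tsv", i)))
  }
  invisible(dir)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- surrogate_config(input_size = cfg$input_size,
                             n_conv_blocks = cfg$n_conv_blocks,
                             kernels_per_block = cfg$kernels_per_block,
                             kernel_size = cfg$kernel_size,
                             dense_units = cfg$dense_units,
                             n_outputs = cfg$n_outputs,
                             dropout_rate = cfg$dropout_rate,
                             learning_rate = cfg$learning_rate,
                             batch_size = cfg$batch_size,
                             max_epochs = cfg$max_epochs,
                             seed = cfg$seed)
  rtab <- function(path)
    as.matrix(utils::read.delim(path, header = FALSE))
  nconv <- length(list.files(dir, pattern = "^conv[0-9]+_W\\.tsv$"))
  ndense <- length(list.files(dir, pattern = "^dense[0-9]+_W\\.tsv$"))
  weights <- list(
    conv = lapply(seq_len(nconv), function(i)
      list(W = unname(rtab(file.path(dir, sprintf("conv%d_W.tsv", i)))),
           b = as.numeric(rtab(file.path(dir, sprintf("conv%d_b.tsv", i)))))),
    dense = lapply(seq_len(ndense), function(i)
      list(W = unname(rtab(file.path(dir, sprintf("dense%d_W.tsv", i)))),
           b = as.numeric(rtab(file.path(dir,
                                         sprintf("dense%d_b.tsv", i)))))))
  history <- utils::read.delim(file.path(dir, "history.tsv"))
  structure(list(config = config, weights = weights, history = history,
                 trained = nrow(history) > 0),
            class = "trained_surrogate")
}
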