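#' Training configuration for the back-propagation perceptron
#'
#' Hyperparameters for online (per-pattern) back-propagation of squared error
#' with momentum. None of these are dictated by the classification problem
#' itself; the defaults are standard for small bounded tabular inputs.
#'
#' @param learning_rate Step size (> 0).
#' @param momentum Momentum coefficient in \[0, 1).
#' @param max_epochs Maximum training epochs (>= 1).
#' @param shuffle Reshuffle pattern order every epoch?
#' @param seed Seed for weight initialization and shuffling.
#' @param early_stop_tol Stop when the epoch-mean squared error falls below
#'   this value (0 disables early stopping).
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, momentum = 0.9,
                         max_epochs = 500L, shuffle = TRUE, seed = 42L,
                         early_stop_tol = 0) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), shuffle = shuffle,
                 seed = as.integer(seed), early_stop_tol = early_stop_tol),
            class = "train_config")
}

#' Train a single-hidden-layer back-propagation perceptron
#'
#' Logistic sigmoid activations on both layers, squared-error loss, online
#' weight updates with momentum, uniform(-0.5, 0.5) seeded initialization.
#' Four hidden units by default. Training is bit-reproducible for identical
#' `(X, y, cfg, hidden)`.
#'
#' @param X Numeric matrix with entries in \[0, 1\] (one row per pattern).
#' @param y Binary target vector; both classes must be present.
#' @param cfg A [train_config()].
#' @param hidden Number of hidden units (>= 1).
#' @return An `mlp_model` with weight matrices `W1` (hidden x input), `b1`,
#'   `W2`, `b2` and the per-epoch mean squared error trace.
#' @export
train_mlp <- function(X, y, cfg = train_config(), hidden = 4L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(hidden >= 1L, nrow(X) == length(y))
  if (any(!is.finite(X)) || any(X < 0) || any(X > 1))
    stop("X entries must lie in [0, 1]")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary (0/1)")
  if (length(unique(y)) < 2L)
    stop("training targets contain a single class")
  fit <- cpp_train_mlp(X, y, as.integer(hidden), cfg$learning_rate,
                       cfg$momentum, cfg$max_epochs, isTRUE(cfg$shuffle),
                       cfg$seed, cfg$early_stop_tol)
  structure(list(W1 = fit$W1, b1 = fit$b1, W2 = fit$W2, b2 = fit$b2,
                 epoch_mse = fit$epoch_mse, hidden = as.integer(hidden),
                 n_inputs = ncol(X), feature_names = colnames(X), cfg = cfg),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> ", x$n_inputs, " inputs -> ", x$hidden,
      " hidden -> 1 output; ", length(x$epoch_mse),
      " epochs, final MSE ", signif(utils::tail(x$epoch_mse, 1), 4), "\n",
      sep = "")
  invisible(x)
}

#' Network output scores
#'
#' Deterministic forward pass; sigmoid outputs lie strictly in (0, 1).
#'
#' @param model An [train_mlp()] model.
#' @param X Matrix whose column count matches the training width.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_inputs)
    stop("input width ", ncol(X), " does not match training width ",
         model$n_inputs)
  as.numeric(cpp_mlp_scores(X, model$W1, model$b1, model$W2, model$b2))
}

#' Serialize / restore an MLP as a plain-text weight file
#'
#' @param model An `mlp_model`.
#' @param path Output file.
#' @return `path` (write) or the restored `mlp_model` (read).
#' @export
write_mlp <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("twistmap-mlp v1",
               paste(model$n_inputs, model$hidden, sep = " ")), con)
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  writeLines(c(fmt(t(model$W1)), fmt(model$b1), fmt(model$W2),
               fmt(model$b2)), con)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "twistmap-mlp v1") stop("unrecognized weight-file header")
  dims <- as.integer(strsplit(lines[2], " ")[[1]])
  num <- function(s) as.numeric(strsplit(s, " ")[[1]])
  structure(list(W1 = matrix(num(lines[3]), dims[2], dims[1], byrow = TRUE),
                 b1 = num(lines[4]), W2 = num(lines[5]), b2 = num(lines[6]),
                 epoch_mse = numeric(0), hidden = dims[2],
                 n_inputs = dims[1], feature_names = NULL,
                 cfg = NULL),
            class = "mlp_model")
}
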