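#' Bipolar logistic activation
#'
#' The squashing function used by every unit of the network:
#' `2 / (1 + exp(-x)) - 1`, which maps the reals onto (-1, 1) and is
#' algebraically identical to `tanh(x / 2)` (the form used internally for
#' numerical stability). Strictly increasing and odd.
#'
#' @param x Numeric vector.
#' @return Values in (-1, 1).
#' @export
bipolar_logistic <- function(x) tanh(x / 2)

#' Training configuration for the age-classification network
#'
#' Full-batch gradient descent on the summed squared error between the
#' network output and the bipolar target coding (-1 for younger adults,
#' +1 for older adults). Training stops when the per-epoch change in total
#' squared error falls below `convergence_tol` or after `max_epochs`.
#'
#' @param seed Integer seed for weight initialization.
#' @param init_range Half-width of the uniform initialization interval for
#'   all weights and biases (default 0.005, i.e. values in
#'   \[-0.005, 0.005)).
#' @param learning_rate Fixed step size (default 0.05).
#' @param max_epochs Epoch cap (default 20000).
#' @param convergence_tol Stop when the absolute change in total squared
#'   error between consecutive epochs is below this (default 1e-10).
#' @return A list of class `training_config`.
#' @export
training_config <- function(seed = 1L, init_range = 0.005,
                            learning_rate = 0.05, max_epochs = 20000L,
                            convergence_tol = 1e-10) {
  if (init_range <= 0) stop("init_range must be positive")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (max_epochs < 1) stop("max_epochs must be at least 1")
  structure(list(seed = as.integer(seed), init_range = init_range,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 convergence_tol = convergence_tol),
            class = "training_config")
}

#' Initialize network parameters
#'
#' Draws every weight and bias of the p -> h -> 1 network uniformly from
#' \[-init_range, init_range); reproducible under the configuration seed.
#'
#' @param p Number of input units.
#' @param h Number of hidden units (default 2).
#' @param config A [training_config()].
#' @return A list of class `network_params` with elements `W1` (h x p),
#'   `b1` (h), `w2` (h), `b2` (scalar), `p`, `h`.
#' @export
init_network <- function(p, h = 2L, config = training_config()) {
  if (p < 1 || h < 1) stop("p and h must be at least 1")
  set.seed(config$seed)
  r <- config$init_range
  n_par <- h * p + h + h + 1L
  draws <- stats::runif(n_par, -r, r)
  new_network_params(
    W1 = matrix(draws[seq_len(h * p)], nrow = h, ncol = p),
    b1 = draws[h * p + seq_len(h)],
    w2 = draws[h * p + h + seq_len(h)],
    b2 = draws[n_par])
}

new_network_params <- function(W1, b1, w2, b2) {
  W1 <- as.matrix(W1)
  stopifnot(nrow(W1) == length(b1), nrow(W1) == length(w2),
            length(b2) == 1L, all(is.finite(W1)), all(is.finite(b1)),
            all(is.finite(w2)), is.finite(b2))
  structure(list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2), p = ncol(W1), h = nrow(W1)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("network_params: ", x$p, " -> ", x$h, " -> 1 bipolar-logistic MLP\n",
      sep = "")
  invisible(x)
}

#' Bipolar target coding of age groups
#'
#' @param age_group Character vector of `"young"` / `"old"`.
#' @return Numeric vector: -1 for young, +1 for old.
#' @export
encode_targets <- function(age_group) {
  if (!all(age_group %in% age_levels())) stop("unknown age_group value")
  ifelse(age_group == "old", 1, -1)
}

#' Forward pass through the network
#'
#' @param params A `network_params` object.
#' @param x A length-p input vector or an n x p matrix of inputs.
#' @return A list with `hidden` (n x h matrix of hidden activations) and
#'   `output` (length-n vector); all activations lie in (-1, 1).
#' @export
nn_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- unclass(x)
  if (ncol(x) != params$p) {
    stop("input has ", ncol(x), " columns; network expects ", params$p)
  }
  hidden <- bipolar_logistic(sweep(x %*% t(params$W1), 2L, params$b1, "+"))
  output <- bipolar_logistic(drop(hidden %*% params$w2) + params$b2)
  list(hidden = hidden, output = output)
}

#' Train the network by full-batch error-correction backpropagation
#'
#' Minimizes the total squared error between outputs and the bipolar
#' targets by gradient descent with a fixed learning rate. The per-epoch
#' error history is recorded; under full-batch updates it is non-increasing
#' (up to floating-point slack) for a sufficiently small learning rate.
#'
#' @param features A z-scored `feature_matrix` (n x p).
#' @param targets Length-n vector of bipolar targets (+1 old, -1 young),
#'   e.g. from [encode_targets()].
#' @param config A [training_config()]; its seed drives initialization.
#' @param params Optional starting `network_params` (default: fresh
#'   [init_network()] with `h = hidden`).
#' @param hidden Number of hidden units for the fresh initialization.
#' @return A list with `params` (trained `network_params`) and `history`
#'   (list with per-epoch `errors`, `epochs`, `converged`).
#' @export
nn_train <- function(features, targets, config = training_config(),
                     params = NULL, hidden = 2L) {
  x <- unclass(features)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(targets) != nrow(x)) {
    stop("length(targets) must equal nrow(features)")
  }
  if (!all(targets %in% c(-1, 1))) stop("targets must be coded -1 / +1")
  if (is.null(params)) params <- init_network(ncol(x), hidden, config)
  fit <- .cpp_nn_train(x, as.numeric(targets), params$W1, params$b1,
                       params$w2, params$b2, config$learning_rate,
                       config$max_epochs, config$convergence_tol)
  list(params = new_network_params(fit$W1, fit$b1, fit$w2, fit$b2),
       history = list(errors = fit$errors, epochs = fit$epochs,
                      converged = fit$converged))
}

#' Gradient of the total squared error
#'
#' Analytic backpropagation gradient of `sum((targets - output)^2)` with
#' respect to every weight and bias, used for training and exposed for
#' finite-difference verification.
#'
#' @param params A `network_params` object.
#' @param x n x p input matrix.
#' @param targets Length-n bipolar targets.
#' @return A list with the scalar `error` and gradients `gW1`, `gb1`,
#'   `gw2`, `gb2`.
#' @export
nn_gradient <- function(params, x, targets) {
  x <- unclass(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  .cpp_nn_grad(x, as.numeric(targets), params$W1, params$b1, params$w2,
               params$b2)
}

#' Classify inputs as young or old
#'
#' The decision rule of the trained network: an input is labelled `"old"`
#' when the output activation is strictly positive, `"young"` otherwise
#' (an exact zero, a measure-zero event, resolves to `"young"`).
#'
#' @param params A `network_params` object.
#' @param x Input vector or matrix.
#' @return Character vector of `"young"` / `"old"`.
#' @export
nn_classify <- function(params, x) {
  out <- nn_forward(params, x)$output
  ifelse(out > 0, "old", "young")
}

#' Hidden-unit activations for every participant
#'
#' Probes the trained network's internal representation: the n x h matrix
#' of hidden-layer activations elicited by each participant's input row.
#'
#' @param params A `network_params` object.
#' @param features n x p feature matrix.
#' @return n x h matrix with participant ids as row names when available.
#' @export
hidden_activations <- function(params, features) {
  x <- unclass(features)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) == 0L) {
    return(matrix(numeric(0), 0L, params$h))
  }
  h <- nn_forward(params, x)$hidden
  rownames(h) <- rownames(x)
  colnames(h) <- paste0("hidden", seq_len(params$h))
  h
}
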