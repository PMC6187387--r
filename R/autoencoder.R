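sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for auto-encoders and stacked models
#'
#' @param hidden_size number of hidden units.
#' @param max_epochs full-batch gradient-descent epochs (default 3000).
#' @param learning_rate step size eta (default 0.1, constant).
#' @param l2_weight L2 weight-decay coefficient on all weight matrices
#'   (default 1e-4); biases are not penalised.
#' @param sparsity_weight weight of the KL sparsity penalty on mean hidden
#'   activations (default 0 = off).
#' @param sparsity_target target mean activation rho in (0, 1).
#' @param tolerance early stop when the absolute epoch-to-epoch loss change
#'   falls below this (default 1e-9).
#' @param seed integer seed for weight initialization.
#' @param loss_kind reconstruction loss: `"mse"` (default) or
#'   `"cross_entropy"`.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden_size = 40L, max_epochs = 3000L,
                         learning_rate = 0.1, l2_weight = 1e-4,
                         sparsity_weight = 0, sparsity_target = 0.05,
                         tolerance = 1e-9, seed = 1L,
                         loss_kind = c("mse", "cross_entropy")) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(learning_rate >= 0, l2_weight >= 0, sparsity_weight >= 0,
            tolerance >= 0, max_epochs >= 1)
  if (sparsity_weight > 0)
    stopifnot(sparsity_target > 0, sparsity_target < 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, l2_weight = l2_weight,
                 sparsity_weight = sparsity_weight,
                 sparsity_target = sparsity_target,
                 tolerance = tolerance, seed = as.integer(seed),
                 loss_kind = loss_kind),
            class = "train_config")
}

#' Initialize auto-encoder parameters
#'
#' Weights are drawn uniform(-r, r) with `r = sqrt(6 / (fan_in + fan_out))`;
#' biases start at zero. Deterministic given the seed.
#'
#' @param input_size,hidden_size layer widths.
#' @param seed integer seed.
#' @return An `ae_params` object: encoder `W` (hidden x input), `b`, decoder
#'   `W_dec` (input x hidden), `b_dec`; activation is the logistic sigmoid
#'   throughout.
#' @export
ae_init <- function(input_size, hidden_size, seed = 1L) {
  set.seed(as.integer(seed))
  r <- sqrt(6 / (input_size + hidden_size))
  structure(list(
    W = matrix(stats::runif(hidden_size * input_size, -r, r),
               hidden_size, input_size),
    b = numeric(hidden_size),
    W_dec = matrix(stats::runif(input_size * hidden_size, -r, r),
                   input_size, hidden_size),
    b_dec = numeric(input_size),
    activation = "sigmoid"),
    class = "ae_params")
}

#' @export
print.ae_params <- function(x, ...) {
  cat(sprintf("<ae_params> %d -> %d -> %d (sigmoid)\n",
              ncol(x$W), nrow(x$W), nrow(x$W_dec)))
  invisible(x)
}

#' Encode inputs to hidden activations
#'
#' `z = sigmoid(W x + b)`, row-wise over a batch.
#'
#' @param params an `ae_params`.
#' @param x input vector of length `input_size`, or a batch matrix with one
#'   row per sample.
#' @return Hidden activations, same shape convention as the input.
#' @export
ae_encode <- function(params, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1L) else as.matrix(x)
  if (ncol(X) != ncol(params$W)) stop("input size mismatch")
  Z <- sigmoid(tcrossprod(X, params$W) + rep(params$b, each = nrow(X)))
  if (single) drop(Z) else Z
}

#' Decode hidden activations to reconstructions
#'
#' `x' = sigmoid(W_dec z + b_dec)`.
#'
#' @param params an `ae_params`.
#' @param z hidden vector or batch matrix.
#' @return Reconstruction(s) in (0, 1).
#' @export
ae_decode <- function(params, z) {
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, 1L) else as.matrix(z)
  if (ncol(Z) != ncol(params$W_dec)) stop("hidden size mismatch")
  Xh <- sigmoid(tcrossprod(Z, params$W_dec) + rep(params$b_dec, each = nrow(Z)))
  if (single) drop(Xh) else Xh
}

#' Reconstruction loss
#'
#' `"mse"` is the squared error `||x - x'||^2`; `"cross_entropy"` is
#' `-sum_k [x_k log x'_k + (1 - x_k) log(1 - x'_k)]` with reconstructions
#' clipped to `[1e-12, 1 - 1e-12]` before the logs. For batches the
#' per-sample losses are averaged.
#'
#' @param x,x_hat targets and reconstructions, equal shape.
#' @param kind `"mse"` or `"cross_entropy"`.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(x, x_hat, kind = c("mse", "cross_entropy")) {
  kind <- match.arg(kind)
  X <- if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  Xh <- if (is.null(dim(x_hat))) matrix(x_hat, 1L) else as.matrix(x_hat)
  stopifnot(identical(dim(X), dim(Xh)))
  if (kind == "mse") {
    sum((X - Xh)^2) / nrow(X)
  } else {
    eps <- 1e-12
    Xc <- pmin(pmax(Xh, eps), 1 - eps)
    -sum(X * log(Xc) + (1 - X) * log(1 - Xc)) / nrow(X)
  }
}

# full objective on a batch: mean reconstruction loss + L2 on both weight
# matrices + optional KL sparsity penalty on mean hidden activations
ae_loss <- function(params, X, config) {
  Z <- ae_encode(params, X)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow(X))
  Xh <- ae_decode(params, Z)
  loss <- reconstruction_loss(X, Xh, config$loss_kind) +
    config$l2_weight * (sum(params$W^2) + sum(params$W_dec^2))
  if (config$sparsity_weight > 0) {
    rho <- config$sparsity_target
    rho_hat <- colMeans(Z)
    loss <- loss + config$sparsity_weight *
      sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
  }
  loss
}

#' Analytic gradients of the auto-encoder objective
#'
#' Exact gradients of the batch objective (mean reconstruction loss plus L2
#' and optional KL-sparsity penalties) for all four parameter blocks. For the
#' squared-error loss the output delta is
#' `2 (x' - x) x' (1 - x') / n`; for cross-entropy the sigmoid cancels to
#' `(x' - x) / n`.
#'
#' @param params an `ae_params`.
#' @param batch samples x input_size matrix (nonempty).
#' @param config a [train_config()].
#' @return List with gradients `W`, `b`, `W_dec`, `b_dec` and the batch
#'   `loss`.
#' @export
ae_gradients <- function(params, batch, config) {
  X <- as.matrix(batch)
  n <- nrow(X)
  stopifnot(n >= 1L)
  Z <- sigmoid(tcrossprod(X, params$W) + rep(params$b, each = n))
  Xh <- sigmoid(tcrossprod(Z, params$W_dec) + rep(params$b_dec, each = n))
  D_out <- if (config$loss_kind == "mse") {
    2 * (Xh - X) * Xh * (1 - Xh) / n
  } else {
    (Xh - X) / n
  }
  gW_dec <- crossprod(D_out, Z) + 2 * config$l2_weight * params$W_dec
  gb_dec <- colSums(D_out)
  D_hid <- D_out %*% params$W_dec
  if (config$sparsity_weight > 0) {
    rho <- config$sparsity_target
    rho_hat <- colMeans(Z)
    kl_grad <- config$sparsity_weight *
      (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n
    D_hid <- D_hid + rep(kl_grad, each = n)
  }
  D_hid <- D_hid * Z * (1 - Z)
  gW <- crossprod(D_hid, X) + 2 * config$l2_weight * params$W
  gb <- colSums(D_hid)
  loss <- reconstruction_loss(X, Xh, config$loss_kind) +
    config$l2_weight * (sum(params$W^2) + sum(params$W_dec^2))
  if (config$sparsity_weight > 0) {
    rho <- config$sparsity_target
    rho_hat <- colMeans(Z)
    loss <- loss + config$sparsity_weight *
      sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
  }
  list(W = gW, b = gb, W_dec = gW_dec, b_dec = gb_dec, loss = loss)
}

#' Train a single auto-encoder
#'
#' Full-batch gradient descent, `new = old - eta * gradient`, for up to
#' `max_epochs` epochs, stopping early when the loss change between epochs
#' drops below `tolerance`. Deterministic given the config seed.
#'
#' @param data samples x input_size matrix; values should lie in `[0, 1]`
#'   when `loss_kind = "cross_entropy"`.
#' @param config a [train_config()].
#' @return List with trained `params` (an `ae_params`) and `trace` (per-epoch
#'   loss values plus `stop_reason`, `"converged"` or `"max_epochs"`).
#' @export
train_ae <- function(data, config = train_config()) {
  X <- as.matrix(data)
  stopifnot(nrow(X) >= 1L)
  params <- ae_init(ncol(X), config$hidden_size, config$seed)
  losses <- numeric(config$max_epochs)
  prev <- Inf
  stop_reason <- "max_epochs"
  n_done <- 0L
  eta <- config$learning_rate
  for (epoch in seq_len(config$max_epochs)) {
    g <- ae_gradients(params, X, config)
    if (!is.finite(g$loss)) stop("training diverged (reduce learning_rate)")
    params$W <- params$W - eta * g$W
    params$b <- params$b - eta * g$b
    params$W_dec <- params$W_dec - eta * g$W_dec
    params$b_dec <- params$b_dec - eta * g$b_dec
    losses[epoch] <- g$loss
    n_done <- epoch
    if (abs(prev - g$loss) < config$tolerance) {
      stop_reason <- "converged"
      break
    }
    prev <- g$loss
  }
  list(params = params,
       trace = list(loss = losses[seq_len(n_done)], stop_reason = stop_reason),
       config = config)
}
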