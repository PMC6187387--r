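#' Numerically stable softmax
#'
#' `f_j = exp(z_j) / sum_k exp(z_k)`, computed shift-invariantly by
#' subtracting the row maximum before exponentiating.
#'
#' @param z logit vector, or a matrix with one logit row per sample.
#' @return Probability vector / matrix; rows sum to 1.
#' @export
softmax <- function(z) {
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, 1L) else as.matrix(z)
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  if (single) drop(P) else P
}

#' Greedy layerwise pretraining of a stack of auto-encoders
#'
#' The first auto-encoder is trained on the feature rows; each subsequent one
#' is trained on the previous layer's hidden codes. Layer seeds are derived
#' deterministically from the config seed.
#'
#' @param features samples x input_size matrix in `[0, 1]`.
#' @param hidden_sizes integer vector of hidden widths, outermost first.
#' @param config a [train_config()]; its `hidden_size` is overridden per
#'   layer.
#' @return List of trained `ae_params`, one per layer.
#' @export
sae_pretrain <- function(features, hidden_sizes, config = train_config()) {
  stopifnot(length(hidden_sizes) >= 1L)
  X <- as.matrix(features)
  layers <- vector("list", length(hidden_sizes))
  for (k in seq_along(hidden_sizes)) {
    cfg_k <- config
    cfg_k$hidden_size <- as.integer(hidden_sizes[k])
    cfg_k$seed <- derive_seed(config$seed, 100L + k)
    fit <- train_ae(X, cfg_k)
    layers[[k]] <- fit$params
    X <- ae_encode(fit$params, X)
    if (is.null(dim(X))) X <- matrix(X, 1L)
  }
  layers
}

#' Assemble a stacked auto-encoder classifier
#'
#' Combines pretrained encoder layers with a softmax head over the gait
#' classes. The head starts at zero, so an untuned model outputs uniform
#' class probabilities. Decoder halves are retained on the layer objects but
#' unused at inference.
#'
#' @param layers list of `ae_params` from [sae_pretrain()].
#' @param class_names ordered class labels.
#' @param config the [train_config()] used for pretraining.
#' @return An `sae_model`.
#' @export
sae_model <- function(layers, class_names, config = train_config()) {
  stopifnot(length(layers) >= 1L, length(class_names) >= 2L)
  for (k in seq_along(layers)[-1L]) {
    if (ncol(layers[[k]]$W) != nrow(layers[[k - 1L]]$W))
      stop("layer ", k, " input size does not match layer ", k - 1L, " hidden size")
  }
  top <- nrow(layers[[length(layers)]]$W)
  head <- list(weights = matrix(0, length(class_names), top),
               biases = numeric(length(class_names)),
               class_names = as.character(class_names))
  structure(list(layers = layers, head = head,
                 hidden_sizes = vapply(layers, function(l) nrow(l$W), integer(1)),
                 fine_tuned = FALSE, config = config),
            class = "sae_model")
}

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf("<sae_model> %d -> %s -> %d classes%s\n",
              ncol(x$layers[[1L]]$W),
              paste(x$hidden_sizes, collapse = " -> "),
              length(x$head$class_names),
              if (x$fine_tuned) " (fine-tuned)" else " (not fine-tuned)"))
  invisible(x)
}

# forward pass through the encoder stack; returns all layer activations
.sae_forward <- function(model, X) {
  acts <- vector("list", length(model$layers) + 1L)
  acts[[1L]] <- X
  for (k in seq_along(model$layers)) {
    acts[[k + 1L]] <- ae_encode(model$layers[[k]], acts[[k]])
    if (is.null(dim(acts[[k + 1L]]))) acts[[k + 1L]] <- matrix(acts[[k + 1L]], nrow(X))
  }
  acts
}

# cross-entropy objective of the full stacked classifier (+ L2 on encoder and
# head weights)
sae_loss <- function(model, X, Y, l2_weight) {
  acts <- .sae_forward(model, as.matrix(X))
  top <- acts[[length(acts)]]
  P <- softmax(tcrossprod(top, model$head$weights) +
                 rep(model$head$biases, each = nrow(top)))
  if (is.null(dim(P))) P <- matrix(P, nrow(top))
  eps <- 1e-12
  ce <- -sum(Y * log(pmax(P, eps))) / nrow(top)
  l2 <- sum(vapply(model$layers, function(l) sum(l$W^2), numeric(1))) +
    sum(model$head$weights^2)
  ce + l2_weight * l2
}

# gradients of sae_loss for every encoder W/b and the head
sae_gradients <- function(model, X, Y, l2_weight) {
  X <- as.matrix(X)
  n <- nrow(X)
  acts <- .sae_forward(model, X)
  top <- acts[[length(acts)]]
  P <- softmax(tcrossprod(top, model$head$weights) +
                 rep(model$head$biases, each = n))
  if (is.null(dim(P))) P <- matrix(P, n)
  D <- (P - Y) / n
  gH <- crossprod(D, top) + 2 * l2_weight * model$head$weights
  gc <- colSums(D)
  gW <- vector("list", length(model$layers))
  gb <- vector("list", length(model$layers))
  D <- D %*% model$head$weights
  for (k in rev(seq_along(model$layers))) {
    Zk <- acts[[k + 1L]]
    D <- D * Zk * (1 - Zk)
    gW[[k]] <- crossprod(D, acts[[k]]) + 2 * l2_weight * model$layers[[k]]$W
    gb[[k]] <- colSums(D)
    if (k > 1L) D <- D %*% model$layers[[k]]$W
  }
  eps <- 1e-12
  ce <- -sum(Y * log(pmax(P, eps))) / n
  l2 <- sum(vapply(model$layers, function(l) sum(l$W^2), numeric(1))) +
    sum(model$head$weights^2)
  list(head_weights = gH, head_biases = gc, W = gW, b = gb,
       loss = ce + l2_weight * l2)
}

.one_hot <- function(labels, class_names) {
  idx <- match(labels, class_names)
  if (anyNA(idx)) stop("unknown label: ", paste(unique(labels[is.na(idx)]), collapse = ", "))
  Y <- matrix(0, length(labels), length(class_names))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Supervised fine-tuning of a stacked auto-encoder
#'
#' End-to-end full-batch gradient descent on the softmax cross-entropy over
#' all encoder weights and the head (with L2 decay), i.e. standard
#' backpropagation through the stacked network with one-hot gait targets.
#' Stops early when the loss change falls below the config tolerance.
#'
#' @param model an [sae_model()].
#' @param features samples x input_size matrix.
#' @param labels character labels covering at least two classes.
#' @param config a [train_config()]; `max_epochs`, `learning_rate`,
#'   `l2_weight` and `tolerance` are used.
#' @return The fine-tuned `sae_model` with a training `trace` attached.
#' @export
sae_fine_tune <- function(model, features, labels, config = model$config) {
  stopifnot(inherits(model, "sae_model"))
  X <- as.matrix(features)
  if (length(unique(labels)) < 2L) stop("need at least two classes")
  Y <- .one_hot(labels, model$head$class_names)
  eta <- config$learning_rate
  losses <- numeric(config$max_epochs)
  prev <- Inf
  stop_reason <- "max_epochs"
  n_done <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    g <- sae_gradients(model, X, Y, config$l2_weight)
    if (!is.finite(g$loss)) stop("training diverged (reduce learning_rate)")
    model$head$weights <- model$head$weights - eta * g$head_weights
    model$head$biases <- model$head$biases - eta * g$head_biases
    for (k in seq_along(model$layers)) {
      model$layers[[k]]$W <- model$layers[[k]]$W - eta * g$W[[k]]
      model$layers[[k]]$b <- model$layers[[k]]$b - eta * g$b[[k]]
    }
    losses[epoch] <- g$loss
    n_done <- epoch
    if (abs(prev - g$loss) < config$tolerance) {
      stop_reason <- "converged"
      break
    }
    prev <- g$loss
  }
  model$fine_tuned <- TRUE
  model$trace <- list(loss = losses[seq_len(n_done)], stop_reason = stop_reason)
  model
}

#' Train a stacked auto-encoder classifier end to end
#'
#' [sae_pretrain()] followed by [sae_fine_tune()].
#'
#' @param features samples x input_size matrix in `[0, 1]`.
#' @param labels per-row class labels.
#' @param hidden_sizes hidden widths, outermost first.
#' @param config a [train_config()].
#' @param class_names ordered class labels (defaults to sorted unique
#'   labels, or [gait_classes()] when the labels are exactly the four gaits).
#' @return A fine-tuned `sae_model`.
#' @export
train_sae <- function(features, labels, hidden_sizes = 40L,
                      config = train_config(), class_names = NULL) {
  if (is.null(class_names)) {
    u <- unique(labels)
    class_names <- if (setequal(u, gait_classes())) gait_classes() else sort(u)
  }
  layers <- sae_pretrain(features, hidden_sizes, config)
  model <- sae_model(layers, class_names, config)
  sae_fine_tune(model, features, labels, config)
}

#' Class probabilities from a stacked auto-encoder
#'
#' Encodes the rows through every layer and applies the softmax head.
#'
#' @param model an `sae_model`.
#' @param features samples x input_size matrix.
#' @return n_rows x n_classes matrix of probabilities; rows sum to 1.
#' @export
sae_predict_proba <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != ncol(model$layers[[1L]]$W)) stop("feature width mismatch")
  acts <- .sae_forward(model, X)
  top <- acts[[length(acts)]]
  P <- softmax(tcrossprod(top, model$head$weights) +
                 rep(model$head$biases, each = nrow(top)))
  if (is.null(dim(P))) P <- matrix(P, nrow(top))
  colnames(P) <- model$head$class_names
  P
}

#' Save / load a trained model
#'
#' Versioned single-file serialization of any package model (`sae_model` or
#' `esae_model`), including all weight blocks, config and training trace.
#' The round trip is bit-exact.
#'
#' @param model the model object.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "ridergait-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ridergait-model"))
    stop("not a ridergait model file")
  obj$model
}
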