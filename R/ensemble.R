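#' Sum-rule fusion of member probabilities
#'
#' Elementwise arithmetic mean of the members' softmax outputs,
#' `sum_i f_j^{(i)}(z) / N`; the result is again a probability vector.
#'
#' @param probas list of N probability vectors (or matrices with one row per
#'   sample, all the same shape).
#' @return Fused probabilities, same shape as one member.
#' @export
fuse_sum <- function(probas) {
  if (length(probas) == 0L) stop("empty member list")
  Reduce(`+`, probas) / length(probas)
}

#' Product-rule fusion of member probabilities
#'
#' Elementwise product of the members' softmax outputs, renormalized to sum
#' to 1 per sample (the raw product no longer lies on the simplex; the
#' argmax decision is unaffected by the renormalization). Computed in log
#' space for stability.
#'
#' @param probas list of N probability vectors / matrices.
#' @return Fused, renormalized probabilities.
#' @export
fuse_product <- function(probas) {
  if (length(probas) == 0L) stop("empty member list")
  eps <- 1e-300
  logs <- Reduce(`+`, lapply(probas, function(p) log(pmax(p, eps))))
  single <- is.null(dim(logs))
  L <- if (single) matrix(logs, 1L) else logs
  if (any(apply(L, 1L, max) <= log(eps)))
    stop("degenerate product: zero probability in every class")
  P <- softmax(L)  # exp + renormalize, shift-invariant
  if (single) drop(P) else P
}

#' Train an ensemble of stacked auto-encoders
#'
#' Trains N members independently on the same training data; members differ
#' only in their hidden-layer widths and in seeds derived deterministically
#' from the config seed (no bagging). The published configurations are three
#' members with hidden sizes 30, 20, 10 and two members with 46 and 15.
#'
#' @param features samples x input_size matrix in `[0, 1]`.
#' @param labels per-row class labels.
#' @param member_hidden_sizes list of integer vectors, one per member, e.g.
#'   `list(46, 15)` or `list(30, 20, 10)`.
#' @param config a [train_config()].
#' @param fusion `"sum"` or `"product"`.
#' @param class_names ordered class labels (see [train_sae()]).
#' @return An `esae_model` with fields `members`, `fusion`,
#'   `member_hidden_sizes`.
#' @export
train_ensemble <- function(features, labels, member_hidden_sizes = list(46L, 15L),
                           config = train_config(), fusion = c("sum", "product"),
                           class_names = NULL) {
  fusion <- match.arg(fusion)
  if (length(member_hidden_sizes) < 2L) stop("ensemble needs >= 2 members")
  if (is.null(class_names)) {
    u <- unique(labels)
    class_names <- if (setequal(u, gait_classes())) gait_classes() else sort(u)
  }
  members <- vector("list", length(member_hidden_sizes))
  for (i in seq_along(member_hidden_sizes)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, 1000L + i)
    members[[i]] <- train_sae(features, labels,
                              hidden_sizes = member_hidden_sizes[[i]],
                              config = cfg_i, class_names = class_names)
  }
  structure(list(members = members, fusion = fusion,
                 member_hidden_sizes = member_hidden_sizes),
            class = "esae_model")
}

#' @export
print.esae_model <- function(x, ...) {
  sizes <- vapply(x$member_hidden_sizes,
                  function(s) paste(s, collapse = "-"), character(1))
  cat(sprintf("<esae_model> %d members (hidden %s), %s rule\n",
              length(x$members), paste(sizes, collapse = ", "), x$fusion))
  invisible(x)
}

#' Fused class probabilities of an ensemble
#'
#' @param model an `esae_model`.
#' @param features samples x input_size matrix.
#' @param fusion override of the model's fusion rule.
#' @return n_rows x n_classes fused probability matrix.
#' @export
esae_predict_proba <- function(model, features, fusion = model$fusion) {
  stopifnot(inherits(model, "esae_model"))
  probas <- lapply(model$members, sae_predict_proba, features = features)
  P <- if (fusion == "sum") fuse_sum(probas) else fuse_product(probas)
  colnames(P) <- model$members[[1L]]$head$class_names
  P
}

#' Class decisions from a trained model
#'
#' Argmax over the (fused) class probabilities; ties are broken toward the
#' lowest class index.
#'
#' @param model an `sae_model` or `esae_model`.
#' @param features samples x input_size matrix.
#' @param fusion fusion rule override for ensembles.
#' @return Character vector of predicted gait labels.
#' @export
classify <- function(model, features, fusion = NULL) {
  P <- if (inherits(model, "esae_model")) {
    esae_predict_proba(model, features,
                       fusion = if (is.null(fusion)) model$fusion else fusion)
  } else {
    sae_predict_proba(model, features)
  }
  colnames(P)[max.col(P, ties.method = "first")]
}
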