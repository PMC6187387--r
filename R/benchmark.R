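#' Study-scale synthetic gait-classification benchmark
#'
#' Runs the full pipeline at the study's problem size — 48,000 raw frames
#' per gait compressed to 12,000, a 2400 x 40 feature table split 50:50 —
#' once per seed, and scores on the held-out half: the two-member ensemble
#' (hidden sizes 46 and 15) under both fusion rules, each individual member,
#' and a single stacked auto-encoder with hidden size 40.
#'
#' @param seeds integer vector of master seeds; results are averaged over
#'   them.
#' @param n_frames_per_gait raw frames per gait (default 48,000).
#' @param max_epochs training epochs (default 3000).
#' @param member_hidden_sizes ensemble member widths (default `list(46, 15)`).
#' @param single_hidden_sizes hidden widths of the reference single SAE
#'   (default 40).
#' @return List with per-seed accuracy vectors `ensemble_sum`,
#'   `ensemble_product`, `single_sae`, `members` (a matrix seeds x members),
#'   their means, and `n_test`.
#' @export
gait_benchmark <- function(seeds = 1:5, n_frames_per_gait = 48000L,
                           max_epochs = 3000L,
                           member_hidden_sizes = list(46L, 15L),
                           single_hidden_sizes = 40L) {
  n_seeds <- length(seeds)
  acc_sum <- acc_prod <- acc_single <- numeric(n_seeds)
  acc_members <- matrix(NA_real_, n_seeds, length(member_hidden_sizes))
  n_test <- NA_integer_
  for (s in seq_len(n_seeds)) {
    seed <- as.integer(seeds[s])
    recordings <- generate_dataset(default_gait_specs(), n_frames_per_gait,
                                   seed = derive_seed(seed, 1L))
    features <- featurize_dataset(recordings)
    split <- split_5050(features, seed = derive_seed(seed, 2L))
    scaled <- scale_features(split$train, split$test)
    n_test <- nrow(scaled$test$values)
    tc <- train_config(max_epochs = max_epochs, seed = derive_seed(seed, 3L))
    ens <- train_ensemble(scaled$train$values, scaled$train$labels,
                          member_hidden_sizes = member_hidden_sizes,
                          config = tc, class_names = gait_classes())
    truth <- scaled$test$labels
    acc_sum[s] <- mean(classify(ens, scaled$test$values, fusion = "sum") == truth)
    acc_prod[s] <- mean(classify(ens, scaled$test$values, fusion = "product") == truth)
    for (m in seq_along(ens$members)) {
      acc_members[s, m] <-
        mean(classify(ens$members[[m]], scaled$test$values) == truth)
    }
    single <- train_sae(scaled$train$values, scaled$train$labels,
                        hidden_sizes = single_hidden_sizes, config = tc,
                        class_names = gait_classes())
    acc_single[s] <- mean(classify(single, scaled$test$values) == truth)
  }
  list(ensemble_sum = acc_sum, ensemble_product = acc_prod,
       single_sae = acc_single, members = acc_members,
       mean_ensemble_sum = mean(acc_sum),
       mean_ensemble_product = mean(acc_prod),
       mean_single_sae = mean(acc_single),
       n_test = n_test, seeds = as.integer(seeds))
}
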