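# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: explicit loops and direct formula
# evaluation only.

# periodized filter-and-downsample by brute-force modular indexing
oracle_periodized_downsample <- function(x, f) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(f)
  out <- numeric(n / 2L)
  for (m0 in 0:(n / 2L - 1L)) {
    acc <- 0
    for (k0 in 0:(L - 1L)) {
      idx0 <- (2L * m0 + k0 + 1L - L %/% 2L) %% n
      acc <- acc + f[k0 + 1L] * x[idx0 + 1L]
    }
    out[m0 + 1L] <- acc
  }
  out
}

# full packet tree by recursive brute-force splitting; returns nodes keyed
# "level.index" in natural order
oracle_packet_tree <- function(x, filters, levels) {
  nodes <- list("0.0" = as.numeric(x))
  for (lev in seq_len(levels)) {
    for (idx in 0:(2^(lev - 1L) - 1L)) {
      parent <- nodes[[paste(lev - 1L, idx, sep = ".")]]
      nodes[[paste(lev, 2L * idx, sep = ".")]] <-
        oracle_periodized_downsample(parent, filters$h)
      nodes[[paste(lev, 2L * idx + 1L, sep = ".")]] <-
        oracle_periodized_downsample(parent, filters$g)
    }
  }
  nodes
}

# central-difference numerical gradient of fn over every entry of the numeric
# blocks named in `blocks` inside list `params`
numeric_gradient <- function(fn, params, blocks, h = 1e-6) {
  out <- list()
  for (blk in blocks) {
    g <- params[[blk]]
    g[] <- NA_real_
    for (i in seq_along(params[[blk]])) {
      p1 <- params; p2 <- params
      p1[[blk]][i] <- p1[[blk]][i] + h
      p2[[blk]][i] <- p2[[blk]][i] - h
      g[i] <- (fn(p1) - fn(p2)) / (2 * h)
    }
    out[[blk]] <- g
  }
  out
}

max_rel_err <- function(analytic, numeric, floor = 1e-4) {
  max(abs(analytic - numeric) / pmax(floor, abs(numeric)))
}

# small, quickly separable labeled feature set (two Gaussian blobs in 40-d)
make_blob_features <- function(n_per_class = 50L, d = 40L, gap = 0.4, seed = 1L) {
  set.seed(seed)
  centres <- matrix(runif(2L * d, 0.3, 0.7), 2L, d)
  centres[2L, ] <- centres[2L, ] + gap * rep_len(c(1, -1), d) * 0.5
  X <- rbind(
    matrix(rnorm(n_per_class * d, sd = 0.03), n_per_class, d) +
      rep(centres[1L, ], each = n_per_class),
    matrix(rnorm(n_per_class * d, sd = 0.03), n_per_class, d) +
      rep(centres[2L, ], each = n_per_class))
  X <- pmin(pmax(X, 0), 1)
  list(X = X, labels = rep(c("a", "b"), each = n_per_class))
}

# reduced-size pipeline used by property tests: fewer frames and epochs than
# the study-scale defaults, same structure
small_pipeline_config <- function(seed, frames = 4800L, epochs = 300L,
                                  members = list(15L)) {
  pipeline_config(n_frames_per_gait = frames, max_epochs = epochs,
                  member_hidden_sizes = members, seed = seed)
}
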