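#' Five summary statistics of one window
#'
#' The per-window feature quintet: mean, maximum, minimum, variance and
#' standard deviation. The variance is the population variance (divide by n),
#' and the standard deviation is its square root.
#'
#' @param window nonempty numeric vector.
#' @return Named numeric vector `(mean, max, min, variance, std)`.
#' @export
window_stats <- function(window) {
  if (length(window) == 0L) stop("empty window")
  m <- mean(window)
  v <- mean((window - m)^2)
  c(mean = m, max = max(window), min = min(window), variance = v, std = sqrt(v))
}

.stat_names <- c("mean", "max", "min", "variance", "std")

#' Windowed statistical featurization of a recording
#'
#' Partitions the frames into consecutive non-overlapping windows of
#' `window_size` (a trailing remainder shorter than one window is dropped)
#' and computes [window_stats()] per channel and window. Columns are
#' channel-major with stat order (mean, max, min, variance, std), named
#' `"channel.stat"` — 8 channels x 5 stats = 40 columns.
#'
#' @param values frames x 8 numeric matrix (typically wavelet-compressed), or
#'   a `motion_recording`.
#' @param label gait label attached to every row; defaults to the recording's
#'   label when a `motion_recording` is given.
#' @param window_size frames per window (default 20).
#' @return A `feature_matrix`: list with `values` (n_windows x 40), ordered
#'   `column_names`, per-row `labels`, and `window_size`.
#' @export
featurize <- function(values, label = NULL, window_size = 20L) {
  if (inherits(values, "motion_recording")) {
    if (is.null(label)) label <- values$gait_label
    values <- values$values
  }
  values <- as.matrix(values)
  window_size <- as.integer(window_size)
  stopifnot(window_size >= 1L, ncol(values) == 8L)
  if (nrow(values) < window_size) stop("recording shorter than window")
  if (is.null(label)) label <- NA_character_
  n_win <- nrow(values) %/% window_size
  channels <- colnames(values)
  if (is.null(channels)) channels <- gait_channels()
  cols <- as.vector(t(outer(channels, .stat_names, paste, sep = ".")))
  out <- matrix(NA_real_, n_win, 40L, dimnames = list(NULL, cols))
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * window_size + 1L):(w * window_size)
    for (ch in seq_len(8L)) {
      out[w, ((ch - 1L) * 5L + 1L):(ch * 5L)] <- window_stats(values[rows, ch])
    }
  }
  structure(list(values = out, column_names = cols,
                 labels = rep(as.character(label), n_win),
                 window_size = window_size),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (window %d)\n",
              nrow(x$values), ncol(x$values), x$window_size))
  if (!all(is.na(x$labels))) {
    tab <- table(x$labels)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stack feature matrices row-wise
#'
#' @param ... `feature_matrix` objects with identical columns, or a single
#'   list of them.
#' @return One combined `feature_matrix`.
#' @export
bind_features <- function(...) {
  fms <- list(...)
  if (length(fms) == 1L && !inherits(fms[[1L]], "feature_matrix")) fms <- fms[[1L]]
  stopifnot(length(fms) >= 1L)
  cols <- fms[[1L]]$column_names
  for (fm in fms) {
    stopifnot(inherits(fm, "feature_matrix"), identical(fm$column_names, cols))
  }
  structure(list(values = do.call(rbind, lapply(fms, `[[`, "values")),
                 column_names = cols,
                 labels = unlist(lapply(fms, `[[`, "labels"), use.names = FALSE),
                 window_size = fms[[1L]]$window_size),
            class = "feature_matrix")
}

#' Featurize a whole multi-gait dataset
#'
#' Convenience wrapper: wavelet-compress each recording, featurize it and
#' stack the results. With the default 48,000-frame recordings, level-2
#' compression yields 12,000 frames per gait and 600 windows per gait, i.e.
#' a 2400 x 40 labeled feature table over the four gaits.
#'
#' @param recordings list of `motion_recording` (see [generate_dataset()]).
#' @param filters,level passed to [compress_recording()]; `level = 0` skips
#'   compression and featurizes raw frames.
#' @param window_size passed to [featurize()].
#' @return A labeled `feature_matrix`.
#' @export
featurize_dataset <- function(recordings, filters = wavelet_filters("db2"),
                              level = 2L, window_size = 20L) {
  fms <- lapply(recordings, function(rec) {
    compressed <- compress_recording(rec, filters, level)
    featurize(compressed, label = rec$gait_label, window_size = window_size)
  })
  bind_features(fms)
}

#' Min-max feature scaling fitted on training data
#'
#' Scales every column to `[0, 1]` using the training minima and maxima only
#' (sigmoid reconstruction targets must be bounded); a constant training
#' column maps to 0 everywhere. Test values may fall slightly outside
#' `[0, 1]`; they are left unclipped.
#'
#' @param train,test `feature_matrix` objects with identical columns
#'   (`test` may be `NULL`).
#' @return List with scaled `train`, scaled `test` (or `NULL`) and the
#'   `scaler` (column mins and ranges).
#' @export
scale_features <- function(train, test = NULL) {
  stopifnot(inherits(train, "feature_matrix"))
  mins <- apply(train$values, 2L, min)
  maxs <- apply(train$values, 2L, max)
  range <- maxs - mins
  scaler <- structure(list(mins = mins, range = range,
                           column_names = train$column_names),
                      class = "feature_scaler")
  list(train = apply_scaler(scaler, train),
       test = if (!is.null(test)) apply_scaler(scaler, test),
       scaler = scaler)
}

#' @rdname scale_features
#' @param scaler a fitted `feature_scaler`.
#' @param fm a `feature_matrix` to transform.
#' @export
apply_scaler <- function(scaler, fm) {
  stopifnot(inherits(scaler, "feature_scaler"), inherits(fm, "feature_matrix"))
  stopifnot(identical(scaler$column_names, fm$column_names))
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  scaled <- sweep(sweep(fm$values, 2L, scaler$mins, `-`), 2L, rng, `/`)
  scaled[, scaler$range == 0] <- 0
  fm$values <- scaled
  fm
}

#' @rdname scale_features
#' @export
unscale_features <- function(scaler, fm) {
  stopifnot(inherits(scaler, "feature_scaler"), inherits(fm, "feature_matrix"))
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  fm$values <- sweep(sweep(fm$values, 2L, rng, `*`), 2L, scaler$mins, `+`)
  fm
}

#' Write / read a feature table as CSV
#'
#' Plain CSV with the 40 `"channel.stat"` columns plus a trailing `label`
#' column.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV file path.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @param window_size window size recorded on the returned object.
#' @export
read_features <- function(path, window_size = 20L) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("label" %in% colnames(df))
  labels <- as.character(df$label)
  values <- as.matrix(df[, setdiff(colnames(df), "label"), drop = FALSE])
  structure(list(values = values, column_names = colnames(values),
                 labels = labels, window_size = as.integer(window_size)),
            class = "feature_matrix")
}
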