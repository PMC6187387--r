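#' Orthogonal wavelet filter pairs
#'
#' Returns the analysis filter pair (h low-pass, g high-pass) of an
#' orthogonal wavelet. The scaling filter h is stored in standard order with
#' `sum(h) = sqrt(2)`; the wavelet filter is derived by the quadrature-mirror
#' relation `g[k] = (-1)^k h[2N - 1 - k]`.
#'
#' @param name `"haar"` or `"db2"` (Daubechies 2, the default filter of the
#'   compression pipeline).
#' @return An object of class `wavelet_filters` with fields `h`, `g`, `name`.
#' @export
wavelet_filters <- function(name = c("db2", "haar")) {
  name <- match.arg(name)
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)
  structure(list(h = h, g = g, name = name), class = "wavelet_filters")
}

#' @export
print.wavelet_filters <- function(x, ...) {
  cat(sprintf("<wavelet_filters> %s (length %d)\n", x$name, length(x$h)))
  invisible(x)
}

# Periodized filter-and-downsample. With filter f of even length L and input
# x of even length n, out[m] = sum_k f[k] x[(2m + k + 1 - L/2) mod n]
# (0-based); this phase convention matches the standard periodization mode of
# reference wavelet implementations. Odd-length inputs are extended by
# repeating the last sample, so the output length is ceil(n/2).
.periodized_downsample <- function(x, f) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(f)
  m <- seq.int(0L, n / 2L - 1L)
  out <- numeric(n / 2L)
  for (k in seq_len(L)) {
    idx <- (2L * m + (k - 1L) + 1L - L %/% 2L) %% n  # 0-based
    out <- out + f[k] * x[idx + 1L]
  }
  out
}

#' One wavelet-packet analysis step
#'
#' Splits a coefficient sequence into its low-pass (approximation) and
#' high-pass (detail) halves by periodized convolution with the orthogonal
#' filter pair followed by dyadic downsampling — the discrete analogue of
#' `W_{2n}(x) = sqrt(2) sum_k h(k) W_n(2x - k)` and its `g` counterpart.
#' Orthogonality makes the step energy preserving:
#' `||approx||^2 + ||detail||^2 = ||input||^2`.
#'
#' @param coefficients numeric vector, length >= 2.
#' @param filters a [wavelet_filters()] pair.
#' @return List with `approx` and `detail`, each of length
#'   `ceiling(length(coefficients) / 2)`.
#' @export
packet_step <- function(coefficients, filters = wavelet_filters("db2")) {
  if (length(coefficients) == 0L) stop("empty signal")
  if (length(coefficients) < 2L) stop("signal must have length >= 2")
  stopifnot(inherits(filters, "wavelet_filters"))
  list(approx = .periodized_downsample(coefficients, filters$h),
       detail = .periodized_downsample(coefficients, filters$g))
}

#' Full wavelet-packet decomposition
#'
#' Builds the full binary packet tree to the requested depth by recursive
#' [packet_step()]: node (L, 2n) is the low-pass split of node (L-1, n) and
#' (L, 2n+1) its high-pass split, so node (L, 0) is the L-fold approximation
#' path ("A-L").
#'
#' @param signal numeric vector with `length(signal) >= 2^levels`.
#' @param filters a [wavelet_filters()] pair.
#' @param levels decomposition depth, >= 1.
#' @return A `wp_tree`: list with `root_length`, `levels`, `filter_name` and
#'   `nodes`, a list keyed `"L.n"` of lists `(level, index, coefficients)`;
#'   the root `"0.0"` holds the original signal.
#' @export
wp_decompose <- function(signal, filters = wavelet_filters("db2"), levels = 2L) {
  if (length(signal) == 0L) stop("empty signal")
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (length(signal) < 2^levels)
    stop("too many levels for this signal length")
  nodes <- list()
  nodes[["0.0"]] <- list(level = 0L, index = 0L, coefficients = as.numeric(signal))
  for (lev in seq_len(levels)) {
    for (parent_idx in seq.int(0L, 2L^(lev - 1L) - 1L)) {
      parent <- nodes[[paste(lev - 1L, parent_idx, sep = ".")]]
      split <- packet_step(parent$coefficients, filters)
      nodes[[paste(lev, 2L * parent_idx, sep = ".")]] <-
        list(level = lev, index = 2L * parent_idx, coefficients = split$approx)
      nodes[[paste(lev, 2L * parent_idx + 1L, sep = ".")]] <-
        list(level = lev, index = 2L * parent_idx + 1L, coefficients = split$detail)
    }
  }
  structure(list(root_length = length(signal), levels = levels,
                 nodes = nodes, filter_name = filters$name),
            class = "wp_tree")
}

#' @export
print.wp_tree <- function(x, ...) {
  cat(sprintf("<wp_tree> %s, %d levels, root length %d (%d nodes)\n",
              x$filter_name, x$levels, x$root_length, length(x$nodes)))
  invisible(x)
}

#' Extract one packet node's coefficients
#'
#' @param tree a [wp_decompose()] result.
#' @param level,index node coordinates; the pipeline's compressed signal is
#'   the level-2 approximation, node (2, 0).
#' @return Numeric coefficient vector of node `W_{level,index}`.
#' @export
wp_node <- function(tree, level = 2L, index = 0L) {
  stopifnot(inherits(tree, "wp_tree"))
  key <- paste(as.integer(level), as.integer(index), sep = ".")
  node <- tree$nodes[[key]]
  if (is.null(node)) stop(sprintf("node (%d, %d) not in tree", level, index))
  node$coefficients
}

#' Wavelet-packet compression of an 8-channel recording
#'
#' Decomposes every channel independently and keeps only the repeated
#' low-pass (approximation) node at the requested level: the high-frequency
#' packets are discarded as uninformative for gait classification. At level
#' `L` the output has `ceiling(n / 2^L)` rows; e.g. a 49,000-frame channel at
#' level 2 compresses to 12,250 coefficients.
#'
#' @param recording a `motion_recording` (or any frames x 8 numeric matrix).
#' @param filters a [wavelet_filters()] pair.
#' @param level approximation level; 0 returns the input unchanged.
#' @return Matrix of compressed coefficients with the 8 channel columns.
#' @export
compress_recording <- function(recording, filters = wavelet_filters("db2"),
                               level = 2L) {
  values <- if (inherits(recording, "motion_recording")) recording$values
            else as.matrix(recording)
  level <- as.integer(level)
  if (level == 0L) return(values)
  out <- vapply(seq_len(ncol(values)), function(ch) {
    tree <- wp_decompose(values[, ch], filters, levels = level)
    wp_node(tree, level, 0L)
  }, numeric(ceiling(nrow(values) / 2^level)))
  colnames(out) <- colnames(values)
  out
}

# Inverse of one packet step for even-length outputs (used for
# perfect-reconstruction checks): transpose of the orthogonal analysis map.
.packet_step_inverse <- function(approx, detail, filters) {
  n <- 2L * length(approx)
  L <- length(filters$h)
  x <- numeric(n)
  for (m in seq_along(approx)) {
    for (k in seq_len(L)) {
      idx <- (2L * (m - 1L) + (k - 1L) + 1L - L %/% 2L) %% n + 1L
      x[idx] <- x[idx] + filters$h[k] * approx[m] + filters$g[k] * detail[m]
    }
  }
  x
}
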