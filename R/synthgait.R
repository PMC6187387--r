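#' @keywords internal
"_PACKAGE"

#' Fixed channel names of a rider-motion recording
#'
#' The eight channels, in the fixed column order used throughout the package:
#' the vertical (y) coordinate of the rider's hip, the backbone angle, the
#' right and left elbow angles, the right and left knee angles, and the
#' elbow-to-elbow and knee-to-knee distances. Coordinates and distances are in
#' centimetres, angles in degrees.
#'
#' @return Character vector of length 8.
#' @export
gait_channels <- function() {
  c("hip_y", "backbone_angle", "right_elbow_angle", "left_elbow_angle",
    "right_knee_angle", "left_knee_angle", "elbow_distance", "knee_distance")
}

#' The four gait class names, in canonical order
#'
#' @return Character vector: walk, sitting_trot, rising_trot, canter.
#' @export
gait_classes <- function() {
  c("walk", "sitting_trot", "rising_trot", "canter")
}

# Per-channel phase offsets (radians), fixed so channels are not all in phase.
.channel_phases <- c(0, 0.4, 0.9, 1.4, 1.9, 2.4, 2.9, 3.4)

#' Construct a gait specification
#'
#' A `gait_spec` bundles everything the generator needs to synthesise one
#' gait: the fundamental cycle length, per-channel amplitude bounds, the
#' harmonic content of the waveform, per-channel noise levels and phase
#' offsets.
#'
#' @param gait_name one of [gait_classes()].
#' @param period_frames positive integer, fundamental cycle length in frames.
#' @param channel_bounds 8 x 2 numeric matrix (rows named as
#'   [gait_channels()]) of per-channel (min, max) in native units.
#' @param harmonic_weights nonnegative weights of the fundamental and its
#'   overtones; the waveform is their weighted sine sum, renormalised so the
#'   envelope stays inside the bounds.
#' @param noise_std per-channel standard deviation of additive Gaussian
#'   noise, length 8 (recycled from length 1).
#' @param phase_offsets per-channel phase in `[0, 2*pi)`, length 8.
#' @return An object of class `gait_spec`.
#' @export
gait_spec <- function(gait_name, period_frames, channel_bounds,
                      harmonic_weights = c(1, 0.3, 0.1),
                      noise_std = 0,
                      phase_offsets = .channel_phases) {
  stopifnot(is.character(gait_name), length(gait_name) == 1L)
  period_frames <- as.integer(period_frames)
  stopifnot(period_frames >= 1L)
  channel_bounds <- as.matrix(channel_bounds)
  if (nrow(channel_bounds) != 8L || ncol(channel_bounds) != 2L)
    stop("channel_bounds must be an 8 x 2 (min, max) matrix")
  if (is.null(rownames(channel_bounds))) rownames(channel_bounds) <- gait_channels()
  if (any(channel_bounds[, 1] >= channel_bounds[, 2]))
    stop("every channel must have min < max")
  stopifnot(all(harmonic_weights >= 0), sum(harmonic_weights) > 0)
  noise_std <- rep_len(as.numeric(noise_std), 8L)
  stopifnot(all(noise_std >= 0))
  phase_offsets <- rep_len(as.numeric(phase_offsets), 8L)
  structure(
    list(gait_name = gait_name, period_frames = period_frames,
         channel_bounds = channel_bounds,
         harmonic_weights = as.numeric(harmonic_weights),
         noise_std = noise_std, phase_offsets = phase_offsets),
    class = "gait_spec")
}

#' @export
print.gait_spec <- function(x, ...) {
  cat(sprintf("<gait_spec> %s: period %d frames, %d harmonics\n",
              x$gait_name, x$period_frames, length(x$harmonic_weights)))
  invisible(x)
}

# Published amplitude bounds for rising trot and canter (cm / degrees).
# Left/right elbow and knee share the printed per-joint row. The canter
# elbow-distance pair is printed inverted in the source table and is stored
# here in (min, max) order.
.rising_trot_bounds <- function() {
  m <- rbind(
    hip_y             = c(32.08, 38.79),
    backbone_angle    = c(171.39, 176.47),
    right_elbow_angle = c(127.59, 151.82),
    left_elbow_angle  = c(127.59, 151.82),
    right_knee_angle  = c(123.92, 172.20),
    left_knee_angle   = c(123.92, 172.20),
    elbow_distance    = c(23.02, 27.02),
    knee_distance     = c(14.93, 16.42))
  colnames(m) <- c("min", "max")
  m
}

.canter_bounds <- function() {
  m <- rbind(
    hip_y             = c(31.87, 38.31),
    backbone_angle    = c(170.77, 176.34),
    right_elbow_angle = c(124.98, 159.24),
    left_elbow_angle  = c(124.98, 159.24),
    right_knee_angle  = c(119.50, 135.80),
    left_knee_angle   = c(119.50, 135.80),
    elbow_distance    = c(25.78, 25.87),
    knee_distance     = c(15.52, 18.59))
  colnames(m) <- c("min", "max")
  m
}

# Walk and sitting trot have no published bounds; they are fixed variants of
# the rising-trot row: walk keeps 55% of the span with the centre shifted down
# by 5% of the span (smallest movement), sitting trot keeps 80% with the
# centre shifted up by 5%.
.scaled_bounds <- function(base, span_frac, centre_shift_frac) {
  centre <- rowMeans(base)
  span <- base[, 2] - base[, 1]
  c2 <- centre + centre_shift_frac * span
  half <- span_frac * span / 2
  m <- cbind(min = c2 - half, max = c2 + half)
  rownames(m) <- rownames(base)
  m
}

#' Default specifications for the four gaits
#'
#' Canter and rising-trot channel bounds follow the published per-joint
#' min/max ranges; walk and sitting trot are documented scaled variants with
#' walk having the smallest amplitude spans. Cycle lengths encode the
#' qualitative ordering that canter has the shortest cycle and walk the
#' longest: walk 120, sitting trot 70, rising trot 60, canter 45 frames.
#' Default noise is Gaussian with standard deviation 5% of each channel's
#' half-span.
#'
#' @return Named list of four [gait_spec()] objects.
#' @export
#' @examples
#' specs <- default_gait_specs()
#' specs$canter$channel_bounds["hip_y", ]
default_gait_specs <- function() {
  rt <- .rising_trot_bounds()
  bounds <- list(
    walk         = .scaled_bounds(rt, 0.55, -0.05),
    sitting_trot = .scaled_bounds(rt, 0.80, 0.05),
    rising_trot  = rt,
    canter       = .canter_bounds())
  periods <- c(walk = 120L, sitting_trot = 70L, rising_trot = 60L, canter = 45L)
  out <- lapply(gait_classes(), function(g) {
    b <- bounds[[g]]
    gait_spec(g, periods[[g]], b, noise_std = 0.05 * (b[, 2] - b[, 1]) / 2)
  })
  names(out) <- gait_classes()
  out
}

#' Generate one synthetic rider-motion recording
#'
#' Each channel is a bounded sum of harmonics of the gait's fundamental
#' cycle plus additive Gaussian noise: with midpoint m and half-span s of the
#' channel's bounds, `c(t) = m + s * sum_k w_k sin(2*pi*(k+1)*t/period + phi) /
#' sum_k w_k + N(0, noise_std^2)`. Identical `(spec, n_frames, seed)` give
#' bit-identical output.
#'
#' @param spec a [gait_spec()].
#' @param n_frames number of frames; must be at least two full cycles.
#' @param seed integer seed for the noise.
#' @return A `motion_recording`: list with `values` (n_frames x 8 matrix),
#'   `channel_names`, `gait_label`, `seed`, `n_frames`.
#' @export
generate_recording <- function(spec, n_frames, seed = 1L) {
  stopifnot(inherits(spec, "gait_spec"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L * spec$period_frames)
    stop("recording too short for one full cycle (need >= 2 * period_frames)")
  w <- spec$harmonic_weights
  t_idx <- seq_len(n_frames) - 1L
  # weighted harmonic sum, renormalised to [-1, 1] envelope
  base <- matrix(0, n_frames, 8L)
  set.seed(as.integer(seed))
  for (ch in seq_len(8L)) {
    s <- numeric(n_frames)
    for (k in seq_along(w)) {
      s <- s + w[k] * sin(2 * pi * k * t_idx / spec$period_frames +
                            spec$phase_offsets[ch])
    }
    s <- s / sum(w)
    mid <- mean(spec$channel_bounds[ch, ])
    half <- diff(spec$channel_bounds[ch, ]) / 2
    base[, ch] <- mid + half * s
  }
  noise <- matrix(stats::rnorm(n_frames * 8L), n_frames, 8L)
  values <- base + sweep(noise, 2L, spec$noise_std, `*`)
  colnames(values) <- gait_channels()
  structure(
    list(values = values, channel_names = gait_channels(),
         gait_label = spec$gait_name, seed = as.integer(seed),
         n_frames = n_frames),
    class = "motion_recording")
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf("<motion_recording> %s: %d frames x 8 channels (seed %d)\n",
              x$gait_label, x$n_frames, x$seed))
  invisible(x)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 9973) %% 2147483587) + 1L
}

#' Generate a labeled multi-gait dataset
#'
#' One recording per gait specification, with per-recording seeds derived
#' deterministically from the master seed.
#'
#' @param specs named list of [gait_spec()], e.g. [default_gait_specs()].
#' @param n_frames_per_gait frames per recording; at least twice the longest
#'   period.
#' @param seed master seed.
#' @return List of `motion_recording`, one per spec, in spec order.
#' @export
generate_dataset <- function(specs = default_gait_specs(),
                             n_frames_per_gait = 48000L, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  max_period <- max(vapply(specs, function(s) s$period_frames, integer(1)))
  if (n_frames_per_gait < 2L * max_period)
    stop("recording too short for one full cycle of the slowest gait")
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    out[[i]] <- generate_recording(specs[[i]], n_frames_per_gait,
                                   seed = derive_seed(seed, i))
  }
  names(out) <- vapply(specs, function(s) s$gait_name, character(1))
  out
}

#' Write / read a recording as delimited text
#'
#' The on-disk format is a plain CSV with the 8 fixed channel names as the
#' header and one frame per row; the gait label, seed and frame count travel
#' in a JSON sidecar `<path>.meta.json`.
#'
#' @param rec a `motion_recording`.
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `motion_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "motion_recording"))
  utils::write.csv(as.data.frame(rec$values), path, row.names = FALSE)
  meta <- list(gait_label = rec$gait_label, seed = rec$seed,
               n_frames = rec$n_frames)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @param path CSV file path previously written by [write_recording()].
#' @export
read_recording <- function(path) {
  values <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (!identical(colnames(values), gait_channels()))
    stop("recording file does not have the 8 expected channel columns")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(gait_label = NA_character_, seed = NA_integer_)
  structure(
    list(values = values, channel_names = gait_channels(),
         gait_label = meta$gait_label, seed = as.integer(meta$seed),
         n_frames = nrow(values)),
    class = "motion_recording")
}
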