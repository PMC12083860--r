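#' Z-score normalize a recording
#'
#' Normalizes all samples of all sweeps jointly: \eqn{(x - \bar x)/s}. Joint
#' (rather than per-sweep) normalization preserves the relative amplitudes
#' across sweeps, which encode the voltage dependence of the channels. A
#' recording with zero variance normalizes to all zeros.
#'
#' @param rec A \code{\link{recording}}.
#' @return Numeric matrix of the same shape as \code{rec$traces}, with joint
#'   mean 0 and s.d. 1 (when non-constant).
#' @export
zscore <- function(rec) {
  x <- rec$traces
  s <- stats::sd(as.vector(x))
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Three-phase segmentation of a sweep
#'
#' Splits the post-onset samples of a sweep into rising
#' \code{[onset, onset + r_ms)}, sustaining \code{[onset + r_ms, offset)} and
#' falling \code{[offset, end)} phases. Pre-stimulus samples are excluded.
#' Together the phases cover \code{[onset, end)} exactly once.
#'
#' @param protocol A \code{\link{voltage_protocol}}.
#' @param r_ms Duration of the rising phase, ms (default 30); must be smaller
#'   than the stimulus duration.
#' @return An object of class \code{phase_segments}: a list of three 1-based
#'   sample-index vectors \code{rising}, \code{sustaining}, \code{falling}.
#' @examples
#' segment_phases(default_protocol())  # rising samples 501..800, etc.
#' @export
segment_phases <- function(protocol, r_ms = 30) {
  if (r_ms >= protocol$offset - protocol$onset)
    stop(sprintf("r_ms (%g) must be smaller than the stimulus duration (%g ms)",
                 r_ms, protocol$offset - protocol$onset))
  if (r_ms <= 0) stop("r_ms must be > 0")
  n <- n_samples(protocol)
  onset_s <- as.integer(round(protocol$onset * protocol$rate))
  offset_s <- as.integer(round(protocol$offset * protocol$rate))
  r_s <- as.integer(round(r_ms * protocol$rate))
  structure(list(rising = (onset_s + 1L):(onset_s + r_s),
                 sustaining = (onset_s + r_s + 1L):offset_s,
                 falling = (offset_s + 1L):n),
            class = "phase_segments", r_ms = r_ms)
}

#' @export
print.phase_segments <- function(x, ...) {
  for (ph in c("rising", "sustaining", "falling"))
    cat(sprintf("  %-10s samples %d..%d (%d)\n", ph, min(x[[ph]]), max(x[[ph]]),
                length(x[[ph]])))
  invisible(x)
}

#' Cut normalized traces into per-phase window tensors
#'
#' Each phase is cut into non-overlapping windows of equal length (trailing
#' remainder samples dropped). Within a window, the feature vector at each
#' time step is the tuple of all sweeps' currents at that sample, with sweeps
#' ordered by ascending step potential, so one window is a
#' \code{window_len x n_sweeps} multivariate slice.
#'
#' @param norm Normalized trace matrix from \code{\link{zscore}}
#'   (n_sweeps x n_samples).
#' @param segments A \code{\link{segment_phases}} result.
#' @param protocol The recording's \code{\link{voltage_protocol}}.
#' @param window_ms Window length, ms (default 10). The window must fit in
#'   the shortest phase.
#' @param label Optional label attached to every window of every tensor.
#' @return Named list (\code{rising}, \code{sustaining}, \code{falling}) of
#'   arrays \code{[n_windows, window_len, n_sweeps]} with attributes
#'   \code{phase} and \code{label}.
#' @export
windowize <- function(norm, segments, protocol, window_ms = 10,
                      label = "unknown") {
  wl <- as.integer(round(window_ms * protocol$rate))
  if (wl < 1L) stop("window length must be at least 1 sample")
  shortest <- min(lengths(segments[c("rising", "sustaining", "falling")]))
  if (wl > shortest)
    stop(sprintf("window of %d samples is longer than the shortest phase (%d samples)",
                 wl, shortest))
  sweep_order <- order(protocol$steps)
  out <- list()
  for (ph in c("rising", "sustaining", "falling")) {
    idx <- segments[[ph]]
    nw <- length(idx) %/% wl
    arr <- array(0, dim = c(nw, wl, nrow(norm)))
    for (w in seq_len(nw)) {
      cols <- idx[((w - 1L) * wl + 1L):(w * wl)]
      arr[w, , ] <- t(norm[sweep_order, cols, drop = FALSE])
    }
    attr(arr, "phase") <- ph
    attr(arr, "label") <- label
    out[[ph]] <- arr
  }
  out
}

#' Full preprocessing pipeline for one recording
#'
#' \code{\link{zscore}} then \code{\link{segment_phases}} then
#' \code{\link{windowize}}; deterministic and label-preserving, and invariant
#' to affine rescaling of the raw currents.
#'
#' @param rec A \code{\link{recording}}.
#' @param r_ms Rising-phase duration, ms (default 30).
#' @param window_ms Window length, ms (default 10).
#' @return Named list of three window tensors (see \code{\link{windowize}}).
#' @export
preprocess_recording <- function(rec, r_ms = 30, window_ms = 10) {
  segs <- segment_phases(rec$protocol, r_ms)
  windowize(zscore(rec), segs, rec$protocol, window_ms, label = rec$label)
}
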