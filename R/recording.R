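#' Label vocabulary
#'
#' Closed label vocabularies: six normal kinetic categories, four anomaly
#' types, plus \code{"unknown"} for inference-time data.
#'
#' Categories: I typical multi-channel activity; II unsustainable outward
#' (non-inactivation failure); III slow-rising current (fast-inactivation
#' failure); IV slow gating; V disordered overlapping currents; VI
#' hyperpolarization-activated (HCN) activity. Anomalies: I aberrant
#' transients; II no current-voltage correlation; III low SNR; IV erratic
#' depolarizing tail.
#'
#' @format Character vectors.
#' @name labels
NULL

#' @rdname labels
#' @export
NORMAL_CATEGORIES <- paste0("category_", c("I", "II", "III", "IV", "V", "VI"))

#' @rdname labels
#' @export
ANOMALY_TYPES <- paste0("anomaly_", c("I", "II", "III", "IV"))

#' @rdname labels
#' @export
ALL_LABELS <- c(NORMAL_CATEGORIES, ANOMALY_TYPES, "unknown")

#' Whole-cell voltage-clamp recording
#'
#' The atom every analysis stage consumes: a sweeps-by-samples current matrix
#' (pA) with its protocol, membrane capacitance (pF), an optional label from
#' the closed vocabulary, and free-form metadata.
#'
#' @param traces Numeric matrix, \code{n_sweeps x n_samples}, current in pA.
#' @param protocol A \code{\link{voltage_protocol}}; its step count must equal
#'   \code{nrow(traces)}.
#' @param capacitance Membrane capacitance, pF (> 0).
#' @param label One of \code{\link{ALL_LABELS}} (default \code{"unknown"}).
#' @param meta Named list of free-form annotations (group, seed, cell id ...).
#' @return An object of class \code{recording}.
#' @export
recording <- function(traces, protocol, capacitance, label = "unknown",
                      meta = list()) {
  if (!inherits(protocol, "voltage_protocol"))
    stop("protocol must be a voltage_protocol")
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  if (nrow(traces) != length(protocol$steps))
    stop(sprintf(
      "recording invariant violated: n_sweeps (%d) != number of step potentials (%d)",
      nrow(traces), length(protocol$steps)))
  if (ncol(traces) != n_samples(protocol))
    stop(sprintf(
      "recording invariant violated: n_samples (%d) != protocol samples (%d)",
      ncol(traces), n_samples(protocol)))
  if (!all(is.finite(traces)))
    stop("recording invariant violated: all trace values must be finite")
  if (!(is.numeric(capacitance) && length(capacitance) == 1L && capacitance > 0))
    stop("recording invariant violated: capacitance must be > 0")
  label <- as.character(label)
  if (!(label %in% ALL_LABELS))
    stop(sprintf("unknown label '%s'; must be one of: %s", label,
                 paste(ALL_LABELS, collapse = ", ")))
  structure(
    list(traces = traces, protocol = protocol,
         capacitance = as.numeric(capacitance), label = label, meta = meta),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Whole-cell recording: %d sweeps x %d samples, Cm %.3g pF, label '%s'\n",
              nrow(x$traces), ncol(x$traces), x$capacitance, x$label))
  invisible(x)
}

#' Collection of recordings sharing one protocol family
#'
#' All member recordings must have compatible protocols: identical sampling
#' rate, stimulus timing, sweep duration and sweep count. Step potentials may
#' differ between recordings (e.g. depolarizing vs hyperpolarizing families),
#' since segmentation and tensor shapes depend only on the shared timing.
#'
#' @param recordings List of \code{\link{recording}} objects.
#' @param split Optional character vector (one of \code{"train"},
#'   \code{"val"}, \code{"test"} per recording) partitioning the set.
#' @return An object of class \code{recording_set}.
#' @export
recording_set <- function(recordings, split = NULL) {
  if (!is.list(recordings)) stop("recordings must be a list")
  for (r in recordings)
    if (!inherits(r, "recording")) stop("all elements must be recording objects")
  if (length(recordings) > 1L) {
    p0 <- recordings[[1L]]$protocol
    for (i in seq_along(recordings))
      if (!protocol_compatible(p0, recordings[[i]]$protocol))
        stop(sprintf("recording %d has an incompatible protocol (mixed-protocol sets are rejected)", i))
  }
  if (!is.null(split)) {
    if (length(split) != length(recordings))
      stop("split must assign every recording")
    if (!all(split %in% c("train", "val", "test")))
      stop("split values must be train/val/test")
  }
  structure(list(recordings = recordings, split = split),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("Recording set: %d recordings\n", length(x$recordings)))
  if (length(x$recordings)) {
    tab <- table(vapply(x$recordings, function(r) r$label, character(1)))
    for (nm in names(tab)) cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' @export
length.recording_set <- function(x) length(x$recordings)

#' Labels of a recording set
#' @param set A \code{recording_set}.
#' @return Character vector of per-recording labels.
#' @export
set_labels <- function(set) {
  vapply(set$recordings, function(r) r$label, character(1))
}

#' Binary normal/abnormal labels of a recording set
#' @param set A \code{recording_set}.
#' @return Factor with levels \code{normal}, \code{abnormal}.
#' @export
binary_labels <- function(set) {
  lab <- set_labels(set)
  factor(ifelse(lab %in% ANOMALY_TYPES, "abnormal", "normal"),
         levels = c("normal", "abnormal"))
}
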