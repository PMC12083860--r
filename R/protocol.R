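#' Voltage-step protocol
#'
#' Describes the family of command-voltage steps used to evoke a multi-sweep
#' whole-cell recording: the cell is held at \code{holding} mV, stepped to one
#' of \code{steps} mV at \code{onset} ms, and returned to holding at
#' \code{offset} ms. One sweep is acquired per step potential.
#'
#' Units are fixed package-wide: time in ms, voltage in mV, current in pA,
#' capacitance in pF (so current density lands directly in pA/pF). Samples are
#' left-aligned: sample \code{i} (0-based) represents time \code{i / rate} ms.
#'
#' @param holding Holding potential, mV.
#' @param steps Numeric vector of step potentials, mV; strictly monotone.
#' @param onset,offset Stimulus onset and offset, ms; \code{0 <= onset < offset
#'   < duration}.
#' @param duration Sweep duration, ms.
#' @param rate Sampling rate, samples per ms (10 = 10 kHz).
#' @return An object of class \code{voltage_protocol}.
#' @examples
#' p <- voltage_protocol(-80, c(-40, -20, 0, 20, 40), 50, 350, 500, 10)
#' n_samples(p)
#' @export
voltage_protocol <- function(holding, steps, onset, offset, duration, rate) {
  stopifnot(is.numeric(holding), length(holding) == 1L)
  if (length(steps) < 1L || anyNA(steps))
    stop("protocol invariant violated: at least 1 step potential required")
  if (length(steps) > 1L) {
    d <- diff(steps)
    if (!(all(d > 0) || all(d < 0)))
      stop("protocol invariant violated: step potentials must be strictly monotone")
  }
  if (!(onset >= 0 && onset < offset && offset < duration))
    stop("protocol invariant violated: need 0 <= onset < offset < duration")
  if (!(rate > 0))
    stop("protocol invariant violated: sampling rate must be > 0")
  structure(
    list(holding = as.numeric(holding), steps = as.numeric(steps),
         onset = as.numeric(onset), offset = as.numeric(offset),
         duration = as.numeric(duration), rate = as.numeric(rate)),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("Voltage-step protocol: hold %g mV, %d steps (%g..%g mV)\n",
              x$holding, length(x$steps), min(x$steps), max(x$steps)))
  cat(sprintf("  stimulus %g-%g ms of %g ms sweep, %g samples/ms (%d samples)\n",
              x$onset, x$offset, x$duration, x$rate, n_samples(x)))
  invisible(x)
}

#' Number of samples per sweep
#' @param protocol A \code{voltage_protocol}.
#' @return Integer sample count, \code{round(duration * rate)}.
#' @export
n_samples <- function(protocol) {
  as.integer(round(protocol$duration * protocol$rate))
}

#' Time axis of a sweep
#' @param protocol A \code{voltage_protocol}.
#' @return Numeric vector of sample times in ms (left-aligned, starting at 0).
#' @export
time_axis <- function(protocol) {
  (seq_len(n_samples(protocol)) - 1L) / protocol$rate
}

# command voltage of one sweep, per sample
command_voltage <- function(protocol, step_index) {
  t <- time_axis(protocol)
  v <- rep(protocol$holding, length(t))
  v[t >= protocol$onset & t < protocol$offset] <- protocol$steps[step_index]
  v
}

#' Default depolarizing step protocol
#'
#' Holding -80 mV, steps -40..+40 mV in 20 mV increments (five sweeps),
#' stimulus 50-350 ms of a 500 ms sweep.
#'
#' @param rate Sampling rate in samples per ms (default 10, i.e. 10 kHz).
#' @return A \code{voltage_protocol}.
#' @export
default_protocol <- function(rate = 10) {
  voltage_protocol(-80, c(-40, -20, 0, 20, 40), 50, 350, 500, rate)
}

#' Hyperpolarizing step protocol (for HCN-dominated cells)
#'
#' Same timing as \code{\link{default_protocol}} but steps -120..-40 mV, the
#' family used for hyperpolarization-activated (HCN) recordings.
#'
#' @inheritParams default_protocol
#' @return A \code{voltage_protocol}.
#' @export
hyperpol_protocol <- function(rate = 10) {
  voltage_protocol(-80, c(-120, -100, -80, -60, -40), 50, 350, 500, rate)
}

# protocols are "compatible" when timing, rate and sweep count agree; step
# potentials may differ (depolarizing vs hyperpolarizing families share one
# segmentation and tensor shape)
protocol_compatible <- function(a, b) {
  isTRUE(all.equal(a$onset, b$onset)) &&
    isTRUE(all.equal(a$offset, b$offset)) &&
    isTRUE(all.equal(a$duration, b$duration)) &&
    isTRUE(all.equal(a$rate, b$rate)) &&
    length(a$steps) == length(b$steps)
}
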