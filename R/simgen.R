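#' Conductance-based ion-channel model
#'
#' A Hodgkin-Huxley style channel: current \eqn{I = g_{max} m^p h^q (V -
#' E_{rev})} with first-order gating \eqn{dm/dt = (m_\infty(V) - m)/\tau_m},
#' \eqn{m_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/s})} (and likewise for the
#' inactivation gate h, whose slope is negative). Time constants are
#' voltage-independent.
#'
#' @param name Identifier.
#' @param g_max Maximal conductance, nS (>= 0).
#' @param E_rev Reversal potential, mV.
#' @param p Activation exponent (integer >= 0).
#' @param q Inactivation exponent (0 or 1).
#' @param m_vhalf,m_slope Activation midpoint (mV) and slope (mV, != 0;
#'   negative slope gives hyperpolarization-activated gating as in HCN).
#' @param tau_m Activation time constant, ms (> 0).
#' @param h_vhalf,h_slope Inactivation midpoint and slope (slope < 0); only
#'   used when \code{q > 0}.
#' @param tau_h Inactivation time constant, ms (> 0 when \code{q > 0}).
#' @param g_decay_tau Optional time constant (ms) of an artificial
#'   mono-exponential rundown of \code{g_max} from stimulus onset; models
#'   unsustainable conductances (\code{NULL} = none).
#' @return An object of class \code{channel_model}.
#' @export
channel_model <- function(name, g_max, E_rev, p = 1, q = 0,
                          m_vhalf = -10, m_slope = 10, tau_m = 5,
                          h_vhalf = -60, h_slope = -7, tau_h = 10,
                          g_decay_tau = NULL) {
  if (g_max < 0) stop("channel invariant violated: g_max must be >= 0")
  if (tau_m <= 0) stop("channel invariant violated: tau_m must be > 0")
  if (q > 0 && tau_h <= 0) stop("channel invariant violated: tau_h must be > 0 when q > 0")
  if (m_slope == 0 || (q > 0 && h_slope == 0))
    stop("channel invariant violated: slopes must be non-zero")
  structure(list(name = name, g_max = g_max, E_rev = E_rev, p = as.integer(p),
                 q = as.integer(q), m_vhalf = m_vhalf, m_slope = m_slope,
                 tau_m = tau_m, h_vhalf = h_vhalf, h_slope = h_slope,
                 tau_h = tau_h, g_decay_tau = g_decay_tau),
            class = "channel_model")
}

#' Simulated-cell specification
#'
#' @param channels List of \code{\link{channel_model}} objects.
#' @param g_leak Leak conductance, nS (>= 0).
#' @param E_leak Leak reversal potential, mV.
#' @param capacitance Membrane capacitance, pF (> 0).
#' @param noise_sd Gaussian recording-noise s.d. per sample, pA (>= 0).
#' @param cap_transient_amp Capacitive-transient amplitude at each voltage
#'   edge, pA.
#' @param cap_transient_tau Capacitive-transient decay constant, ms (> 0).
#' @return An object of class \code{cell_spec}.
#' @export
cell_spec <- function(channels = list(), g_leak = 1, E_leak = -80,
                      capacitance = 20, noise_sd = 5,
                      cap_transient_amp = 150, cap_transient_tau = 1) {
  if (g_leak < 0) stop("cell invariant violated: g_leak must be >= 0")
  if (capacitance <= 0) stop("cell invariant violated: capacitance must be > 0")
  if (noise_sd < 0) stop("cell invariant violated: noise_sd must be >= 0")
  if (cap_transient_tau <= 0) stop("cell invariant violated: cap_transient_tau must be > 0")
  structure(list(channels = channels, g_leak = g_leak, E_leak = E_leak,
                 capacitance = capacitance, noise_sd = noise_sd,
                 cap_transient_amp = cap_transient_amp,
                 cap_transient_tau = cap_transient_tau),
            class = "cell_spec")
}

boltzmann <- function(v, vhalf, slope) 1 / (1 + exp(-(v - vhalf) / slope))

# Analytic gating trajectory on the three-segment command waveform
# (holding -> step -> holding). Voltage is piecewise constant under ideal
# voltage clamp and tau is voltage-independent, so on each segment
# x(t) = xinf + (x0 - xinf) exp(-(t - t0)/tau) exactly; the per-sample
# exponential-Euler update coincides with this closed form.
gate_trajectory <- function(protocol, v_step, vhalf, slope, tau) {
  t <- time_axis(protocol)
  n <- length(t)
  out <- numeric(n)
  segs <- list(c(0, protocol$onset, protocol$holding),
               c(protocol$onset, protocol$offset, v_step),
               c(protocol$offset, protocol$duration, protocol$holding))
  x0 <- boltzmann(protocol$holding, vhalf, slope)  # steady state at holding
  for (s in segs) {
    idx <- which(t >= s[1] & t < s[2])
    xinf <- boltzmann(s[3], vhalf, slope)
    if (length(idx))
      out[idx] <- xinf + (x0 - xinf) * exp(-(t[idx] - s[1]) / tau)
    x0 <- xinf + (x0 - xinf) * exp(-(s[2] - s[1]) / tau)  # value at boundary
  }
  out
}

#' Simulate one voltage-clamp sweep
#'
#' Integrates every channel's gating variables on the command waveform
#' (holding to \code{steps[step_index]} at onset, back at offset) by
#' exponential Euler, which is exact here because the clamp voltage is
#' piecewise constant and gating time constants are voltage-independent.
#' Total current is the sum of channel currents, leak, a phenomenological
#' capacitive transient at each voltage edge, and i.i.d. Gaussian noise
#' (drawn from the current RNG state).
#'
#' @param cell A \code{\link{cell_spec}}.
#' @param protocol A \code{\link{voltage_protocol}}.
#' @param step_index Which step potential (1-based).
#' @param noise Logical; add Gaussian noise (default \code{TRUE}).
#' @return Numeric vector of current in pA, one value per sample.
#' @export
simulate_sweep <- function(cell, protocol, step_index, noise = TRUE) {
  if (step_index < 1L || step_index > length(protocol$steps))
    stop("step_index out of range")
  t <- time_axis(protocol)
  n <- length(t)
  v_step <- protocol$steps[step_index]
  v <- command_voltage(protocol, step_index)
  i_total <- cell$g_leak * (v - cell$E_leak)
  for (ch in cell$channels) {
    m <- gate_trajectory(protocol, v_step, ch$m_vhalf, ch$m_slope, ch$tau_m)
    g <- ch$g_max * m^ch$p
    if (ch$q > 0) {
      h <- gate_trajectory(protocol, v_step, ch$h_vhalf, ch$h_slope, ch$tau_h)
      g <- g * h^ch$q
    }
    if (!is.null(ch$g_decay_tau)) {
      decay <- rep(1, n)
      on <- t >= protocol$onset
      decay[on] <- exp(-(t[on] - protocol$onset) / ch$g_decay_tau)
      g <- g * decay
    }
    i_total <- i_total + g * (v - ch$E_rev)
  }
  if (cell$cap_transient_amp != 0) {
    # transient charge scales with the voltage jump; amp is calibrated per
    # 100 mV of step
    for (edge in list(c(protocol$onset, v_step - protocol$holding),
                      c(protocol$offset, protocol$holding - v_step))) {
      idx <- t >= edge[1]
      i_total[idx] <- i_total[idx] +
        (edge[2] / 100) * cell$cap_transient_amp *
        exp(-(t[idx] - edge[1]) / cell$cap_transient_tau)
    }
  }
  if (noise && cell$noise_sd > 0)
    i_total <- i_total + stats::rnorm(n, 0, cell$noise_sd)
  i_total
}

# ---- phenotype presets ------------------------------------------------------

# base channel definitions; jitter is applied multiplicatively (log-normal)
# to g_max, V_half and tau parameters per cell
base_channels <- function() {
  list(
    na = channel_model("Na", g_max = 40, E_rev = 60, p = 3, q = 1,
                       m_vhalf = -25, m_slope = 6, tau_m = 0.8,
                       h_vhalf = -60, h_slope = -7, tau_h = 6),
    ka = channel_model("KA", g_max = 25, E_rev = -90, p = 1, q = 1,
                       m_vhalf = 5, m_slope = 8, tau_m = 2,
                       h_vhalf = -35, h_slope = -6, tau_h = 20),
    kdr = channel_model("KDR", g_max = 12, E_rev = -90, p = 1, q = 0,
                        m_vhalf = -10, m_slope = 12, tau_m = 8),
    hcn = channel_model("HCN", g_max = 8, E_rev = -30, p = 1, q = 0,
                        m_vhalf = -90, m_slope = -8, tau_m = 50))
}

jitter_channel <- function(ch, jitter) {
  if (jitter <= 0) return(ch)
  jf <- function(x) x * exp(stats::rnorm(1, 0, jitter))
  ch$g_max <- jf(ch$g_max)
  ch$m_vhalf <- jf(ch$m_vhalf); ch$tau_m <- jf(ch$tau_m)
  if (ch$q > 0) { ch$h_vhalf <- jf(ch$h_vhalf); ch$tau_h <- jf(ch$tau_h) }
  ch
}

scale_tau <- function(ch, f_m, f_h = f_m) {
  ch$tau_m <- ch$tau_m * f_m
  if (ch$q > 0) ch$tau_h <- ch$tau_h * f_h
  ch
}

# cell for one normal category; draws jitter from the current RNG state
category_cell <- function(label, jitter) {
  b <- base_channels()
  chans <- switch(label,
    category_I = b[c("na", "ka", "kdr")],
    category_II = {
      kdr <- b$kdr; kdr$g_decay_tau <- 100  # unsustainable outward current
      list(b$na, b$ka, kdr)
    },
    category_III = {
      kdr <- b$kdr; kdr$tau_m <- kdr$tau_m * 10  # slow rise, no fast inact.
      list(b$na, kdr)
    },
    category_IV = lapply(b[c("na", "ka", "kdr")], scale_tau, f_m = 5),
    category_V = b[c("na", "ka", "kdr")],  # extra per-sweep K added later
    category_VI = b["hcn"],
    stop(sprintf("unknown label '%s'", label)))
  chans <- lapply(chans, jitter_channel, jitter = jitter)
  cap <- 20 * exp(stats::rnorm(1, 0, jitter))
  cell_spec(channels = chans, capacitance = cap)
}

#' Generate one labelled synthetic recording
#'
#' Builds a label-specific cell (with per-cell multiplicative log-normal
#' parameter jitter), simulates all sweeps of the protocol, and applies the
#' label's anomaly transformation where applicable. Category VI is simulated
#' under the hyperpolarizing step family (same timing and rate as
#' \code{protocol}).
#'
#' @param label One of the six categories or four anomaly types (see
#'   \code{\link{ALL_LABELS}}).
#' @param protocol A \code{\link{voltage_protocol}} (default
#'   \code{\link{default_protocol}()}).
#' @param seed Integer seed making the recording fully reproducible.
#' @param jitter Fractional s.d. of multiplicative parameter jitter
#'   (default 0.1).
#' @return A \code{\link{recording}} carrying the label and a meta seed.
#' @export
generate_recording <- function(label, protocol = default_protocol(),
                               seed = 1L, jitter = 0.1) {
  if (!(label %in% c(NORMAL_CATEGORIES, ANOMALY_TYPES)))
    stop(sprintf("unknown label '%s'", label))
  set.seed(as.integer(seed))
  if (label == "category_VI")
    protocol <- voltage_protocol(protocol$holding, c(-120, -100, -80, -60, -40),
                                 protocol$onset, protocol$offset,
                                 protocol$duration, protocol$rate)
  ns <- length(protocol$steps)
  nsamp <- n_samples(protocol)
  t <- time_axis(protocol)
  stim <- t >= protocol$onset & t < protocol$offset
  tail_idx <- t >= protocol$offset
  base_idx <- t < protocol$onset

  sim_all <- function(cell, noise = TRUE) {
    tr <- matrix(0, ns, nsamp)
    for (i in seq_len(ns)) tr[i, ] <- simulate_sweep(cell, protocol, i, noise)
    tr
  }

  if (label %in% NORMAL_CATEGORIES) {
    cell <- category_cell(label, jitter)
    if (label == "category_V") {
      # disordered: extra K population with per-sweep randomized midpoint
      tr <- matrix(0, ns, nsamp)
      for (i in seq_len(ns)) {
        extra <- channel_model("Kx", g_max = 15 * exp(stats::rnorm(1, 0, jitter)),
                               E_rev = -90, p = 1, q = 0,
                               m_vhalf = -10 + stats::runif(1, -25, 25),
                               m_slope = 12, tau_m = 15)
        cs <- cell; cs$channels <- c(cs$channels, list(extra))
        tr[i, ] <- simulate_sweep(cs, protocol, i)
      }
    } else {
      tr <- sim_all(cell)
    }
  } else if (label == "anomaly_I") {
    # aberrant transients: each sweep drawn from a *different* category's
    # cell, with per-sweep amplitude scatter and a random shift of every
    # gating midpoint, so channels appear at low stimuli and vanish at high
    # ones - voltage dependence is broken across the sweep family
    cell <- category_cell("category_I", jitter)
    tr <- matrix(0, ns, nsamp)
    cats <- sample(NORMAL_CATEGORIES[1:5])  # depolarizing presets, permuted
    for (i in seq_len(ns)) {
      cs <- category_cell(cats[((i - 1L) %% 5L) + 1L], jitter)
      amp <- exp(stats::rnorm(1, 0, 0.5))
      vshift <- stats::runif(1, -60, 20)
      cs$channels <- lapply(cs$channels, function(ch) {
        ch$g_max <- ch$g_max * amp
        ch$m_vhalf <- ch$m_vhalf + vshift
        ch
      })
      cs$capacitance <- cell$capacitance
      tr[i, ] <- simulate_sweep(cs, protocol, i)
    }
  } else if (label == "anomaly_II") {
    # stimulated region replaced by amplitude-matched filtered noise,
    # uncorrelated with the command voltage
    cell <- category_cell("category_I", jitter)
    tr <- sim_all(cell)
    k <- max(1L, as.integer(round(5 * protocol$rate)))  # ~5 ms smoothing
    for (i in seq_len(ns)) {
      amp <- stats::sd(tr[i, stim])
      raw <- stats::rnorm(sum(stim) + k)
      sm <- stats::filter(raw, rep(1 / k, k), sides = 1)[-seq_len(k)]
      sm <- sm / stats::sd(sm) * amp
      tr[i, stim] <- mean(tr[i, base_idx]) + sm
    }
  } else if (label == "anomaly_III") {
    # low SNR: noise floor raised above half the largest evoked deflection
    cell <- category_cell("category_I", jitter)
    clean <- sim_all(cell, noise = FALSE)
    peaks <- apply(clean, 1L, function(x) max(abs(x[stim] - mean(x[base_idx]))))
    cell$noise_sd <- 0.8 * max(peaks)
    tr <- sim_all(cell)
  } else if (label == "anomaly_IV") {
    # erratic depolarizing bursts supersede the quiescent tail
    cell <- category_cell("category_I", jitter)
    tr <- sim_all(cell)
    nt <- sum(tail_idx)
    for (i in seq_len(ns)) {
      evoked_peak <- max(abs(tr[i, stim] - mean(tr[i, base_idx])))
      burst_amp <- max(stats::runif(1, 0.1, 0.3) * evoked_peak,
                       6 * cell$noise_sd)
      rw <- pmax(cumsum(stats::rnorm(nt)), 0)
      if (max(rw) > 0) rw <- rw / max(rw) * burst_amp
      tr[i, tail_idx] <- mean(tr[i, base_idx]) + rw +
        stats::rnorm(nt, 0, cell$noise_sd)
    }
  }
  recording(tr, protocol, cell$capacitance, label = label,
            meta = list(seed = as.integer(seed), jitter = jitter))
}

# deterministic per-recording seed derived from the dataset seed
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 100003 + counter * 7919) %% 2147483629)
}

#' Generate a labelled synthetic dataset
#'
#' @param counts Named integer vector or list mapping label to the number of
#'   recordings to generate (all counts >= 0).
#' @param protocol A \code{\link{voltage_protocol}} shared by the set
#'   (Category VI substitutes the hyperpolarizing step family with the same
#'   timing).
#' @param jitter Fractional parameter jitter (default 0.1, \code{[0, 1)}).
#' @param seed Dataset seed; every recording's seed is derived from it, so the
#'   whole set is reproducible.
#' @return A \code{\link{recording_set}}.
#' @export
generate_dataset <- function(counts, protocol = default_protocol(),
                             jitter = 0.1, seed = 1L) {
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (jitter < 0 || jitter >= 1) stop("jitter must be in [0, 1)")
  recs <- list()
  counter <- 0L
  for (lab in names(counts)) {
    for (j in seq_len(counts[[lab]])) {
      counter <- counter + 1L
      r <- generate_recording(lab, protocol,
                              seed = derive_seed(seed, counter), jitter = jitter)
      r$meta$cell_id <- sprintf("%s_%03d", lab, j)
      recs[[counter]] <- r
    }
  }
  recording_set(recs)
}

#' Anomaly-detection corpus preset
#'
#' Train: 120 normal (20 per category) + 120 abnormal (30 per anomaly type);
#' test: 72 normal (12 per category) + 72 abnormal (18 per type).
#'
#' @param seed Dataset seed.
#' @param rate Sampling rate, samples per ms (default 10).
#' @param jitter Parameter jitter (default 0.1).
#' @return List with \code{train} and \code{test} \code{recording_set}s.
#' @export
anomaly_corpus <- function(seed = 1L, rate = 10, jitter = 0.1) {
  proto <- default_protocol(rate)
  tr <- c(stats::setNames(rep(20L, 6), NORMAL_CATEGORIES),
          stats::setNames(rep(30L, 4), ANOMALY_TYPES))
  te <- c(stats::setNames(rep(12L, 6), NORMAL_CATEGORIES),
          stats::setNames(rep(18L, 4), ANOMALY_TYPES))
  list(train = generate_dataset(tr, proto, jitter, seed),
       test = generate_dataset(te, proto, jitter, seed + 500000L))
}

#' Six-category classifier corpus preset
#'
#' Train: 139 recordings (24, 23, 23, 23, 23, 23 over categories I-VI);
#' test: 124 recordings (21, 21, 21, 21, 20, 20).
#'
#' @param seed Dataset seed.
#' @param rate Sampling rate, samples per ms (default 1, i.e. 1 kHz).
#' @param jitter Parameter jitter (default 0.1).
#' @return List with \code{train} and \code{test} \code{recording_set}s.
#' @export
classifier_corpus <- function(seed = 7L, rate = 1, jitter = 0.1) {
  proto <- default_protocol(rate)
  tr <- stats::setNames(c(24L, 23L, 23L, 23L, 23L, 23L), NORMAL_CATEGORIES)
  te <- stats::setNames(c(21L, 21L, 21L, 21L, 20L, 20L), NORMAL_CATEGORIES)
  list(train = generate_dataset(tr, proto, jitter, seed),
       test = generate_dataset(te, proto, jitter, seed + 500000L))
}
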