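# Post-classification kinetics: peak currents, current density, I-V curves,
# activation threshold, reversal potential, group comparisons. Peak windows
# are tied to the same phase segmentation the classifier uses, so both
# analyses share one definition of "rising".

#' Per-sweep peak currents
#'
#' Baseline-subtracted peaks: the baseline is the mean of the 20 ms
#' preceding stimulus onset. The inward peak is the most negative deflection
#' within the rising phase \code{[onset, onset + r_ms)} (where the fast
#' inward sodium current lives); the outward peak is the most positive
#' deflection anywhere in the stimulus window \code{[onset, offset)}. Peaks
#' are clipped at zero toward their own polarity, so a sweep with no
#' negative deflection reports an inward peak of 0.
#'
#' @param rec A \code{\link{recording}}.
#' @param r_ms Rising-phase duration, ms (default 30, matching
#'   \code{\link{segment_phases}}).
#' @return Data frame with one row per sweep: \code{voltage},
#'   \code{peak_inward}, \code{peak_outward} (pA).
#' @export
peak_currents <- function(rec, r_ms = 30) {
  p <- rec$protocol
  t <- time_axis(p)
  base_idx <- t >= (p$onset - 20) & t < p$onset
  rise_idx <- t >= p$onset & t < (p$onset + r_ms)
  stim_idx <- t >= p$onset & t < p$offset
  out <- data.frame(voltage = p$steps, peak_inward = 0, peak_outward = 0)
  for (i in seq_along(p$steps)) {
    x <- rec$traces[i, ]
    b <- mean(x[base_idx])
    out$peak_inward[i] <- min(0, min(x[rise_idx] - b))
    out$peak_outward[i] <- max(0, max(x[stim_idx] - b))
  }
  out
}

#' Current density
#'
#' @param peak Peak current, pA.
#' @param capacitance Membrane capacitance, pF (> 0).
#' @return Current density, pA/pF.
#' @export
current_density <- function(peak, capacitance) {
  if (any(capacitance <= 0)) stop("capacitance must be > 0")
  peak / capacitance
}

#' Current-voltage (I-V) curve of a group of recordings
#'
#' Per step potential, the mean and s.d. across recordings of the chosen
#' measurement's current density. \code{"outward"} and \code{"inward"} use
#' the polarity-clipped peaks of \code{\link{peak_currents}};
#' \code{"steady"} uses the signed mean current over the last 50 ms of the
#' stimulus \emph{without} baseline subtraction (the steady-state I-V, the
#' appropriate measurement for reversal-potential estimation: it keeps the
#' current's sign and absolute level — subtracting the holding current would
#' pin a spurious zero at the holding potential).
#'
#' @param set A \code{\link{recording_set}} sharing one step family.
#' @param polarity \code{"outward"}, \code{"inward"} or \code{"steady"}.
#' @param r_ms Rising-phase duration for the inward peak window.
#' @return An object of class \code{iv_curve}: data frame with
#'   \code{voltage}, \code{mean_density}, \code{sd_density}, \code{n} and a
#'   \code{polarity} attribute.
#' @export
iv_curve <- function(set, polarity = c("outward", "inward", "steady"),
                     r_ms = 30) {
  polarity <- match.arg(polarity)
  if (!length(set$recordings)) stop("empty group")
  volts <- set$recordings[[1]]$protocol$steps
  for (r in set$recordings)
    if (!isTRUE(all.equal(r$protocol$steps, volts)))
      stop("recordings do not share one step family")
  steady_currents <- function(r) {
    p <- r$protocol
    t <- time_axis(p)
    late <- t >= (p$offset - 50) & t < p$offset
    vapply(seq_along(p$steps), function(i)
      mean(r$traces[i, late]), numeric(1))
  }
  dens <- sapply(set$recordings, function(r) {
    v <- if (polarity == "steady") steady_currents(r) else {
      pk <- peak_currents(r, r_ms)
      if (polarity == "outward") pk$peak_outward else pk$peak_inward
    }
    current_density(v, r$capacitance)
  })
  dens <- matrix(dens, nrow = length(volts))
  out <- data.frame(voltage = volts,
                    mean_density = rowMeans(dens),
                    sd_density = apply(dens, 1L, stats::sd),
                    n = ncol(dens))
  if (ncol(dens) == 1L) out$sd_density <- 0
  structure(out, class = c("iv_curve", "data.frame"), polarity = polarity)
}

#' Activation threshold of an I-V curve
#'
#' The smallest step potential at which the absolute mean current density
#' reaches the criterion; \code{NA} if never reached.
#'
#' @param curve An \code{\link{iv_curve}} (or data frame with
#'   \code{voltage} and \code{mean_density}).
#' @param criterion Threshold density, pA/pF (default 2).
#' @return Step potential in mV, or \code{NA}.
#' @export
activation_threshold <- function(curve, criterion = 2) {
  hit <- which(abs(curve$mean_density) >= criterion)
  if (!length(hit)) return(NA_real_)
  curve$voltage[min(hit)]
}

#' Reversal potential from an I-V curve
#'
#' Linear interpolation of the zero crossing of the mean density between the
#' adjacent step potentials where its sign changes; an exact node zero is
#' returned as-is. With multiple crossings the one at the most negative
#' voltage is returned; \code{NA} if the density never changes sign.
#'
#' @param curve An \code{\link{iv_curve}} with at least two points.
#' @return Reversal potential in mV, or \code{NA}.
#' @export
reversal_potential <- function(curve) {
  v <- curve$voltage; d <- curve$mean_density
  if (length(v) < 2L) stop("curve must have at least 2 points")
  zero <- which(d == 0)
  cross <- which(d[-length(d)] * d[-1] < 0)
  cand <- c(v[zero],
            vapply(cross, function(i)
              v[i] - d[i] * (v[i + 1] - v[i]) / (d[i + 1] - d[i]), numeric(1)))
  if (!length(cand)) return(NA_real_)
  min(cand)
}

#' Compare current densities between groups
#'
#' Two groups: two-sided Welch t-test. More than two: one-way ANOVA followed
#' by Tukey HSD. Routine inference is delegated to the standard library
#' (\code{t.test}, \code{aov}, \code{TukeyHSD}).
#'
#' @param ... Two or more numeric vectors of densities (n >= 2 each), or a
#'   single named list of them.
#' @return For two groups: list with \code{method}, \code{statistic},
#'   \code{p_value}, \code{stars}. For more: list with the ANOVA F statistic
#'   and p-value plus the Tukey pairwise table.
#' @export
compare_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]])
    list(method = "Welch two-sample t-test",
         statistic = unname(tt$statistic), p_value = tt$p.value,
         stars = significance_stars(tt$p.value))
  } else {
    df <- data.frame(
      y = unlist(groups),
      g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
    fit <- stats::aov(y ~ g, df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    list(method = "one-way ANOVA + Tukey HSD",
         statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
         stars = significance_stars(an[["Pr(>F)"]][1]),
         tukey = data.frame(comparison = rownames(tk), tk,
                            stars = significance_stars(tk[, "p adj"]),
                            row.names = NULL))
  }
}
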