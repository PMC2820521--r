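#' Normalized alpha-function pulse
#'
#' `alpha(t) = ((t - t0)/tau) * exp(1 - (t - t0)/tau)` for `t >= t0`, zero
#' before onset. The pulse rises from 0, attains its maximum of exactly 1 at
#' `t = t0 + tau`, and decays exponentially.
#'
#' @param t Time(s), s (vectorized).
#' @param tau Time constant, s (> 0).
#' @param t0 Onset time, s.
#' @return Dimensionless pulse value(s) in `[0, 1]`.
#' @examples
#' alpha_pulse(0.5, tau = 0.5)          # 1
#' alpha_pulse(1.0, tau = 0.5)          # 2/e
#' @export
alpha_pulse <- function(t, tau, t0 = 0) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  x <- (t - t0) / tau
  ifelse(x > 0, x * exp(1 - x), 0)
}

#' Calcium input protocol
#'
#' A burst of `n_spikes` presynaptic spikes at inter-spike interval `isi`
#' (the default 8 spikes at 10 ms corresponds to a 100 Hz train), repeated
#' `n_repeats` times every `repeat_interval` seconds. Each spike evokes a
#' calcium transient modeled as an alpha function; transients combine by the
#' pointwise maximum (not temporal summation), so the waveform never exceeds
#' `ca_basal + ca_amp`.
#'
#' @param ca_basal Basal calcium concentration, µM.
#' @param ca_amp Transient amplitude above basal, µM (0 disables input).
#' @param n_spikes Spikes per train.
#' @param isi Inter-spike interval, s.
#' @param n_repeats Number of trains.
#' @param repeat_interval Interval between train onsets, s.
#' @param tau Alpha-function time constant, s.
#' @param t_onset Onset of the first train, s.
#' @return An object of class `"calcium_protocol"`.
#' @export
calcium_protocol <- function(ca_basal = 0.06, ca_amp = 1,
                             n_spikes = 8, isi = 0.01,
                             n_repeats = 6, repeat_interval = 10,
                             tau = 0.3, t_onset = 0) {
  stopifnot(ca_basal >= 0, ca_amp >= 0, n_spikes >= 1, isi > 0,
            n_repeats >= 1, repeat_interval > 0, tau > 0)
  structure(list(ca_basal = ca_basal, ca_amp = ca_amp, n_spikes = n_spikes,
                 isi = isi, n_repeats = n_repeats,
                 repeat_interval = repeat_interval, tau = tau,
                 t_onset = t_onset),
            class = "calcium_protocol")
}

#' Dopamine input protocol
#'
#' One dopamine transient per repeat (a single presynaptic spike), as an
#' alpha function of time constant `tau`, repeated `n_repeats` times.
#' Repeats combine by pointwise maximum, symmetric with
#' [calcium_protocol()]. `offset` shifts every dopamine pulse relative to
#' the corresponding calcium train onset (positive = dopamine later).
#'
#' @param da_basal Basal dopamine concentration, µM.
#' @param da_amp Transient amplitude above basal, µM (0 disables input).
#' @param n_repeats Number of pulses.
#' @param repeat_interval Interval between pulse onsets, s.
#' @param tau Alpha-function time constant, s.
#' @param offset Timing offset relative to calcium train onsets, s.
#' @param t_onset Onset reference of the first repeat, s.
#' @return An object of class `"dopamine_protocol"`.
#' @export
dopamine_protocol <- function(da_basal = 0.003, da_amp = 1,
                              n_repeats = 6, repeat_interval = 10,
                              tau = 0.3, offset = 0, t_onset = 0) {
  stopifnot(da_basal >= 0, da_amp >= 0, n_repeats >= 1,
            repeat_interval > 0, tau > 0)
  structure(list(da_basal = da_basal, da_amp = da_amp,
                 n_repeats = n_repeats, repeat_interval = repeat_interval,
                 tau = tau, offset = offset, t_onset = t_onset),
            class = "dopamine_protocol")
}

.pulse_onsets <- function(p) {
  if (inherits(p, "calcium_protocol")) {
    reps <- p$t_onset + (seq_len(p$n_repeats) - 1L) * p$repeat_interval
    as.vector(outer((seq_len(p$n_spikes) - 1L) * p$isi, reps, `+`))
  } else {
    p$t_onset + p$offset + (seq_len(p$n_repeats) - 1L) * p$repeat_interval
  }
}

#' Calcium input waveform
#'
#' @param t Time(s), s (vectorized).
#' @param p A [calcium_protocol()].
#' @return Calcium concentration(s), µM.
#' @export
calcium_waveform <- function(t, p) {
  stopifnot(inherits(p, "calcium_protocol"))
  if (p$ca_amp == 0) return(rep(p$ca_basal, length(t)))
  on <- .pulse_onsets(p)
  m <- 0
  for (t0 in on) m <- pmax(m, alpha_pulse(t, p$tau, t0))
  p$ca_basal + p$ca_amp * m
}

#' Dopamine input waveform
#'
#' @param t Time(s), s (vectorized).
#' @param p A [dopamine_protocol()].
#' @return Dopamine concentration(s), µM.
#' @export
dopamine_waveform <- function(t, p) {
  stopifnot(inherits(p, "dopamine_protocol"))
  if (p$da_amp == 0) return(rep(p$da_basal, length(t)))
  on <- .pulse_onsets(p)
  m <- 0
  for (t0 in on) m <- pmax(m, alpha_pulse(t, p$tau, t0))
  p$da_basal + p$da_amp * m
}

# time intervals in which the inputs are appreciably above basal
.active_windows <- function(...) {
  ps <- list(...)
  w <- NULL
  for (p in ps) {
    if (is.null(p) || (p$ca_amp %||% p$da_amp) == 0) next
    on <- .pulse_onsets(p)
    w <- rbind(w, cbind(pmin(on, on), on + 10 * p$tau))
  }
  if (is.null(w)) return(NULL)
  w <- w[order(w[, 1]), , drop = FALSE]
  # merge overlaps
  merged <- w[1, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1]) {
    if (w[i, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], w[i, 2])
    else merged <- rbind(merged, w[i, ])
  }
  merged
}
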