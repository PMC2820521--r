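#' Pre-equilibrate a network at basal input levels
#'
#' Integrates the network with constant basal calcium and dopamine until the
#' largest derivative falls below `tol` (µM/s), then polishes the resting
#' point with a damped Newton iteration on the conservation-reduced system.
#' The returned state defines "prior to stimulation" for all experiments.
#'
#' @param net A network from [build_network()] (or any network whose input
#'   species are named in `net$inputs`).
#' @param basal_ca,basal_da Basal input concentrations, µM.
#' @param tol Settling tolerance on `max |dy/dt|` (µM/s).
#' @param t_max Time cap for settling (s).
#' @param y0 Optional starting state (defaults to table initials).
#' @return Named resting-state vector (µM) with attribute `residual`.
#' @export
pre_equilibrate <- function(net, basal_ca = 0.06, basal_da = 0.003,
                            tol = 1e-9, t_max = 40000, y0 = NULL) {
  stopifnot(basal_ca >= 0, basal_da >= 0)
  net <- set_clamp(net, net$inputs[["calcium"]], basal_ca)
  net <- set_clamp(net, net$inputs[["dopamine"]], basal_da)
  rhs <- assemble_rhs(net)
  y <- if (is.null(y0)) initial_state(net) else y0[net$species$name]
  y[net$species$name == net$inputs[["calcium"]]] <- basal_ca
  y[net$species$name == net$inputs[["dopamine"]]] <- basal_da
  t <- 0; chunk <- 500
  repeat {
    tc <- simulate_network(net, c(t, t + chunk), y0 = y)
    y <- unclass(tc)[nrow(tc), ]
    names(y) <- net$species$name
    t <- t + chunk
    res <- max(abs(rhs(t, y, NULL)[[1L]]))
    if (res < 100 * tol || t >= t_max) break
    chunk <- min(2 * chunk, 8000)
  }
  ns <- .newton_polish(net, y, tol = tol)
  if (ns$residual > tol)
    stop("failed to settle: residual ", format(ns$residual),
         " uM/s after ", t, " s")
  structure(ns$y, residual = ns$residual)
}

#' Run a stimulus-driven time course
#'
#' Simulates the pre-equilibrated network under forced calcium and dopamine
#' waveforms. Basal levels of the protocols should match the levels used in
#' [pre_equilibrate()].
#'
#' @param net The network.
#' @param ca_protocol A [calcium_protocol()] (or `NULL` for constant basal).
#' @param da_protocol A [dopamine_protocol()] (or `NULL`).
#' @param y0 Initial state, typically from [pre_equilibrate()].
#' @param t_end End time (s).
#' @param dt Output sampling interval (s).
#' @param times Explicit output grid (overrides `t_end`/`dt`).
#' @param ... Passed to [simulate_network()].
#' @return A `time_course`.
#' @export
run_experiment <- function(net, ca_protocol = NULL, da_protocol = NULL,
                           y0 = NULL, t_end = 600, dt = 1, times = NULL,
                           ...) {
  forcings <- list()
  ca_name <- net$inputs[["calcium"]]; da_name <- net$inputs[["dopamine"]]
  if (!is.null(ca_protocol)) {
    net <- set_clamp(net, ca_name, ca_protocol$ca_basal)
    forcings[[ca_name]] <- function(t) calcium_waveform(t, ca_protocol)
  }
  if (!is.null(da_protocol)) {
    net <- set_clamp(net, da_name, da_protocol$da_basal)
    forcings[[da_name]] <- function(t) dopamine_waveform(t, da_protocol)
  }
  if (is.null(y0)) y0 <- pre_equilibrate(
    net,
    basal_ca = if (is.null(ca_protocol)) 0.06 else ca_protocol$ca_basal,
    basal_da = if (is.null(da_protocol)) 0.003 else da_protocol$da_basal)
  if (is.null(times)) times <- seq(0, t_end, by = dt)
  win <- .active_windows(ca_protocol, da_protocol)
  hmax <- NULL
  if (!is.null(win)) {
    taus <- c(if (!is.null(ca_protocol)) ca_protocol$tau,
              if (!is.null(da_protocol)) da_protocol$tau)
    hmax <- min(taus) / 4
  }
  simulate_network(net, times, y0 = y0, forcings = forcings,
                   active_windows = win, hmax_active = hmax, ...)
}

#' Synaptic-plasticity read-out of a time course
#'
#' Synaptic efficacy is the total AMPA-receptor concentration in the
#' post-synaptic membrane (the anchored pools). Plasticity is the ratio of
#' efficacy at `eval_time` (default 600 s, i.e. 10 min after stimulation
#' onset) to the pre-stimulus value; `> 1` is potentiation (LTP), `< 1`
#' depression (LTD).
#'
#' @param tc A `time_course` from [run_experiment()].
#' @param net The network the time course came from (for the membrane-pool
#'   species list).
#' @param eval_time Evaluation time (s).
#' @return A list of class `"plasticity_result"`: `ratio`, `pre_value`,
#'   `post_value`, `eval_time`.
#' @export
plasticity_ratio <- function(tc, net, eval_time = 600) {
  tt <- tc_times(tc)
  if (max(tt) < eval_time) stop("time course ends before eval_time")
  mem <- trajectory(tc, net$membrane_pool)
  pre <- mem[1L]
  post <- mem[which.min(abs(tt - eval_time))]
  if (pre <= 0) stop("pre-stimulus membrane pool is zero")
  structure(list(ratio = post / pre, pre_value = pre, post_value = post,
                 eval_time = eval_time),
            class = "plasticity_result")
}

#' @export
print.plasticity_result <- function(x, ...) {
  cat(sprintf("plasticity ratio %.3f (%s) at %g s: %.4f -> %.4f uM\n",
              x$ratio, if (x$ratio > 1) "LTP" else "LTD",
              x$eval_time, x$pre_value, x$post_value))
  invisible(x)
}

#' Clamp species at their resting activity ("fixation" experiment)
#'
#' Implements activity-fixation: the listed species are clamped at their
#' value in `state` (typically the pre-equilibrated resting state), so that
#' stimulation can no longer move them. Complexes containing the species
#' still evolve.
#'
#' @param net The network.
#' @param species_to_fix Character vector of species names.
#' @param state Named state vector supplying the fixed values.
#' @return The clamped network.
#' @export
clamp_experiment <- function(net, species_to_fix, state) {
  i <- match(species_to_fix, net$species$name)
  if (anyNA(i)) stop("unknown species: ",
                     paste(species_to_fix[is.na(i)], collapse = ", "))
  set_clamp(net, species_to_fix, value = unname(state[species_to_fix]))
}

#' Plasticity over a grid of calcium and dopamine amplitudes
#'
#' For each `(ca_amp, da_amp)` pair the network is stimulated from the
#' shared resting state and the plasticity ratio evaluated. Solver failures
#' are recorded as `NA` cells rather than aborting the map.
#'
#' @param net The network.
#' @param ca_amps,da_amps Amplitude grids (µM).
#' @param basal_ca,basal_da Basal levels (µM).
#' @param eval_time Evaluation time (s).
#' @param y0 Optional resting state (computed once when `NULL`).
#' @param ... Passed to [run_experiment()].
#' @return A `plasticity_map`: list with `ca_amps`, `da_amps` and matrix
#'   `ratio` (rows = calcium, columns = dopamine).
#' @export
plasticity_map <- function(net, ca_amps, da_amps,
                           basal_ca = 0.06, basal_da = 0.003,
                           eval_time = 600, y0 = NULL, ...) {
  stopifnot(length(ca_amps) >= 1, length(da_amps) >= 1)
  if (is.null(y0)) y0 <- pre_equilibrate(net, basal_ca, basal_da)
  ratio <- matrix(NA_real_, length(ca_amps), length(da_amps),
                  dimnames = list(ca = ca_amps, da = da_amps))
  for (i in seq_along(ca_amps)) for (j in seq_along(da_amps)) {
    cp <- calcium_protocol(ca_basal = basal_ca, ca_amp = ca_amps[i])
    dp <- dopamine_protocol(da_basal = basal_da, da_amp = da_amps[j])
    ratio[i, j] <- tryCatch({
      tc <- run_experiment(net, cp, dp, y0 = y0, t_end = eval_time, ...)
      plasticity_ratio(tc, net, eval_time)$ratio
    }, error = function(e) NA_real_)
  }
  structure(list(ca_amps = ca_amps, da_amps = da_amps, ratio = ratio),
            class = "plasticity_map")
}

#' @export
print.plasticity_map <- function(x, ...) {
  cat("plasticity_map: ", length(x$ca_amps), " x ", length(x$da_amps),
      " (ca x da); ratio range [",
      paste(signif(range(x$ratio, na.rm = TRUE), 3), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Input-timing experiment
#'
#' Runs the stimulation protocol with the dopamine pulses shifted by each
#' offset relative to the calcium train onsets (positive = dopamine later)
#' and evaluates the plasticity ratio, together with AC5/cAMP/PKA traces.
#'
#' @param net The network.
#' @param offsets Offsets (s), e.g. `c(-0.5, 0, 0.5)`.
#' @param ca_amp,da_amp Input amplitudes (µM).
#' @param basal_ca,basal_da Basal levels (µM).
#' @param eval_time Evaluation time (s).
#' @param ... Passed to [run_experiment()].
#' @return A data frame (offset, ratio) with attribute `traces` (a list of
#'   time courses per offset).
#' @export
timing_experiment <- function(net, offsets = c(-0.5, 0, 0.5),
                              ca_amp = 1, da_amp = 1,
                              basal_ca = 0.06, basal_da = 0.003,
                              eval_time = 600, ...) {
  y0 <- pre_equilibrate(net, basal_ca, basal_da)
  traces <- list()
  ratio <- numeric(length(offsets))
  for (k in seq_along(offsets)) {
    cp <- calcium_protocol(ca_basal = basal_ca, ca_amp = ca_amp)
    dp <- dopamine_protocol(da_basal = basal_da, da_amp = da_amp,
                            offset = offsets[k])
    tc <- run_experiment(net, cp, dp, y0 = y0, t_end = eval_time, ...)
    traces[[k]] <- tc
    ratio[k] <- plasticity_ratio(tc, net, eval_time)$ratio
  }
  structure(data.frame(offset = offsets, ratio = ratio), traces = traces)
}
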