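#' Integrate a reaction network
#'
#' Stiff ODE integration with [deSolve::lsoda()]. Brief input transients
#' (the alpha-function calcium/dopamine pulses last tens of milliseconds,
#' separated by seconds of quiet) are easily stepped over by an adaptive
#' solver, so the integration is performed piecewise: inside user-supplied
#' "active windows" the maximum step size is capped, outside it is free.
#'
#' @param net A [reaction_network()].
#' @param times Output time grid (s), increasing, starting at the initial
#'   time.
#' @param y0 Named initial state; defaults to [initial_state()].
#' @param forcings Named list of `function(t)` waveforms for clamped species.
#' @param rtol,atol Solver tolerances (defaults 1e-8 / 1e-12 µM).
#' @param active_windows Optional 2-column matrix (start, end) of time
#'   intervals within which `hmax_active` applies.
#' @param hmax_active Maximum solver step inside active windows (s).
#' @param use_jacobian Supply the analytic Jacobian to the solver.
#' @return A `time_course` object: matrix of concentrations (rows = times)
#'   with attributes `times` and `net`; clamped/forced species columns hold
#'   the imposed values.
#' @export
simulate_network <- function(net, times, y0 = NULL, forcings = list(),
                             rtol = 1e-8, atol = 1e-12,
                             active_windows = NULL, hmax_active = NULL,
                             use_jacobian = TRUE) {
  if (is.null(y0)) y0 <- initial_state(net)
  y0 <- y0[net$species$name]
  if (anyNA(y0)) stop("y0 is missing species")
  rhs <- assemble_rhs(net, forcings)
  jac <- if (use_jacobian) assemble_jacobian(net, forcings) else NULL

  seg_bounds <- sort(unique(c(times[1], times[length(times)],
                              if (!is.null(active_windows))
                                as.vector(active_windows))))
  seg_bounds <- seg_bounds[seg_bounds >= times[1] &
                             seg_bounds <= times[length(times)]]
  in_active <- function(a, b) {
    if (is.null(active_windows)) return(FALSE)
    any(a < active_windows[, 2] & b > active_windows[, 1])
  }

  out <- NULL
  y <- y0
  for (s in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[s]; b <- seg_bounds[s + 1L]
    tt <- sort(unique(c(a, times[times > a & times < b], b)))
    hmax <- if (in_active(a, b) && !is.null(hmax_active)) hmax_active else Inf
    res <- deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol,
                          hmax = if (is.finite(hmax)) hmax else NULL,
                          jacfunc = jac,
                          jactype = if (is.null(jac)) "fullint" else "fullusr",
                          maxsteps = 50000)
    if (attr(res, "istate")[1L] < 0)
      stop("solver failure at t ~ ", utils::tail(res[, 1], 1))
    y <- res[nrow(res), -1L]
    keep <- res[, 1] %in% times
    if (!is.null(out)) keep <- keep & !(res[, 1] %in% out[, 1])
    out <- rbind(out, res[keep, , drop = FALSE])
  }
  tcol <- out[, 1]
  mat <- out[, -1L, drop = FALSE]
  # report imposed values for clamped/forced species
  clamped <- which(net$species$clamped)
  if (length(clamped)) {
    for (j in clamped)
      mat[, j] <- net$species$clamp_value[j]
    for (nm in names(forcings)) {
      j <- match(nm, net$species$name)
      mat[, j] <- vapply(tcol, forcings[[nm]], 0)
    }
  }
  structure(mat, times = tcol, species = net$species$name,
            class = c("time_course", class(mat)))
}

#' @export
print.time_course <- function(x, ...) {
  tt <- attr(x, "times")
  cat("time_course: ", length(tt), " samples over [",
      tt[1], ", ", tt[length(tt)], "] s, ",
      ncol(x), " species\n", sep = "")
  invisible(x)
}

#' Extract a species trajectory from a time course
#'
#' @param tc A `time_course` from [simulate_network()].
#' @param name Species name(s); columns are summed (useful for pooled
#'   read-outs such as total membrane AMPAR).
#' @return Numeric vector along the time grid.
#' @export
trajectory <- function(tc, name) {
  j <- match(name, attr(tc, "species"))
  if (anyNA(j)) stop("unknown species: ",
                     paste(name[is.na(j)], collapse = ", "))
  if (length(j) == 1L) unclass(tc)[, j] else rowSums(unclass(tc)[, j])
}

#' Time grid of a time course
#' @param tc A `time_course`.
#' @return Numeric vector of sample times (s).
#' @export
tc_times <- function(tc) attr(tc, "times")
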