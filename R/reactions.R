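#' Define a molecular species
#'
#' A species is a named molecular state living in the (homogeneous) spine
#' volume. Concentrations are in micromolar throughout; time is in seconds.
#' Clamped species do not evolve: their derivative is zeroed and their value
#' is imposed externally, either as a constant or (at simulation time) as a
#' time-dependent forcing. Clamped species still participate as reactants,
#' which is how constant pools (ATP), housekeeping enzymes and the calcium /
#' dopamine inputs are represented.
#'
#' @param name Species identifier (unique within a network).
#' @param conc Initial concentration (µM), non-negative.
#' @param clamped Logical; if `TRUE` the species is held fixed.
#' @param clamp_value Value imposed while clamped (defaults to `conc`).
#' @return An object of class `"species"`.
#' @examples
#' species("cAMP", 0.1)
#' species("ATP", 2000, clamped = TRUE)
#' @export
species <- function(name, conc = 0, clamped = FALSE, clamp_value = conc) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(conc) || conc < 0)
    stop("initial concentration of '", name, "' must be finite and >= 0")
  structure(list(name = name, conc = as.numeric(conc),
                 clamped = isTRUE(clamped),
                 clamp_value = as.numeric(clamp_value)),
            class = "species")
}

#' Reversible binding reaction A + B <-> AB
#'
#' Mass-action association/dissociation. Rates may be given directly as
#' `kf` (µM^-1 s^-1) and `kb` (s^-1), or via the dissociation constant `kd`
#' (µM) and relaxation time constant `tau` (s), which are converted with
#' [rate_constants_from_kd_tau()]. Explicit `kf`/`kb` take precedence.
#'
#' @param a,b Reactant species names (distinct).
#' @param ab Complex species name.
#' @param kf Forward (association) rate constant, µM^-1 s^-1.
#' @param kb Backward (dissociation) rate constant, s^-1.
#' @param kd Dissociation constant, µM (alternative parameterization).
#' @param tau Relaxation time constant, s (alternative parameterization).
#' @param name Optional reaction label.
#' @param group Optional rate-group label; reactions sharing a group share
#'   one set of rate parameters (used for parameter bookkeeping).
#' @return An object of class `c("binding_reaction", "reaction")`.
#' @examples
#' binding_reaction("A", "B", "AB", kd = 1, tau = 0.5)
#' @export
binding_reaction <- function(a, b, ab, kf = NULL, kb = NULL,
                             kd = NULL, tau = NULL,
                             name = NULL, group = NULL) {
  if (length(unique(c(a, b, ab))) != 3L && a != b)
    stop("binding reaction requires distinct species a, b, ab")
  if (ab %in% c(a, b)) stop("complex must differ from the reactants")
  if (is.null(kf) || is.null(kb)) {
    rk <- rate_constants_from_kd_tau(kd, tau)
    if (is.null(kf)) kf <- rk$kf
    if (is.null(kb)) kb <- rk$kb
  }
  if (!is.finite(kf) || kf <= 0) stop("kf must be > 0")
  if (!is.finite(kb) || kb < 0) stop("kb must be >= 0")
  structure(list(a = a, b = b, ab = ab, kf = kf, kb = kb,
                 name = name %||% paste0(a, "+", b, "<->", ab),
                 group = group),
            class = c("binding_reaction", "reaction"))
}

#' Enzymatic reaction E + S <-> ES -> E + P
#'
#' Integrated as its two elementary mass-action steps; the quasi-steady-state
#' (Michaelis-Menten) shortcut is deliberately not used, so enzyme
#' sequestration in the ES complex is represented explicitly. When only
#' `km` (µM) and `kcat` (s^-1) are known, elementary constants are filled in
#' with [rate_constants_from_km_kcat()] (kb = 4 kcat, kf = 5 kcat / Km).
#' Explicit `kf`/`kb` take precedence.
#'
#' @param enzyme,substrate,product Species names.
#' @param kf Association rate of E and S, µM^-1 s^-1.
#' @param kb Dissociation rate of ES back to E + S, s^-1.
#' @param kcat Catalytic rate ES -> E + P, s^-1.
#' @param km Michaelis constant, µM (alternative parameterization).
#' @param complex Name of the ES complex species (auto-generated when `NULL`;
#'   each enzymatic reaction owns its own complex).
#' @param name Optional reaction label.
#' @inheritParams binding_reaction
#' @return An object of class `c("enzymatic_reaction", "reaction")`.
#' @examples
#' enzymatic_reaction("E", "S", "P", km = 2, kcat = 1)
#' @export
enzymatic_reaction <- function(enzyme, substrate, product,
                               kf = NULL, kb = NULL, kcat = NULL, km = NULL,
                               complex = NULL, name = NULL, group = NULL) {
  if (product %in% c(substrate)) stop("product must differ from substrate")
  if (is.null(kcat) || !is.finite(kcat) || kcat <= 0)
    stop("kcat must be > 0")
  if (is.null(kf) || is.null(kb)) {
    rk <- rate_constants_from_km_kcat(km, kcat)
    if (is.null(kf)) kf <- rk$kf
    if (is.null(kb)) kb <- rk$kb
  }
  if (!is.finite(kf) || kf <= 0) stop("kf must be > 0")
  if (!is.finite(kb) || kb < 0) stop("kb must be >= 0")
  if (is.null(complex))
    complex <- paste0(enzyme, ".", substrate, if (substrate == product) ".c")
  if (complex %in% c(enzyme, substrate, product))
    stop("ES complex name collides with a participant")
  structure(list(enzyme = enzyme, substrate = substrate, product = product,
                 complex = complex, kf = kf, kb = kb, kcat = kcat,
                 name = name %||%
                   paste0(enzyme, ": ", substrate, "->", product),
                 group = group),
            class = c("enzymatic_reaction", "reaction"))
}

#' Convert (Kd, tau) to elementary binding rate constants
#'
#' The convention used throughout the model tables when a binding row is
#' specified thermodynamically: the backward rate is the reciprocal of the
#' relaxation time constant, `kb = 1/tau`, and the forward rate follows from
#' detailed balance, `kf = kb / Kd = 1 / (Kd tau)`, so that `kb/kf = Kd`
#' holds exactly.
#'
#' @param kd Dissociation constant, µM (> 0).
#' @param tau Time constant, s (> 0).
#' @return A list with components `kf` (µM^-1 s^-1) and `kb` (s^-1).
#' @examples
#' rate_constants_from_kd_tau(kd = 2, tau = 0.5) # kf = 1, kb = 2
#' @export
rate_constants_from_kd_tau <- function(kd, tau) {
  if (is.null(kd) || is.null(tau) || !is.finite(kd) || !is.finite(tau) ||
      kd <= 0 || tau <= 0)
    stop("kd and tau must both be finite and > 0")
  kb <- 1 / tau
  list(kf = kb / kd, kb = kb)
}

#' Convert (Km, kcat) to elementary enzymatic rate constants
#'
#' Many kinetic measurements report only the Michaelis constant and turnover
#' number. Elementary constants are recovered with the classical simulator
#' default that the ES dissociation rate is four times the catalytic rate:
#' `kb = 4 kcat` and `kf = (kb + kcat) / Km = 5 kcat / Km`, which makes
#' `Km = (kb + kcat)/kf` hold exactly.
#'
#' @param km Michaelis constant, µM (> 0).
#' @param kcat Catalytic rate constant, s^-1 (> 0).
#' @return A list with components `kf`, `kb`, `kcat`.
#' @examples
#' rate_constants_from_km_kcat(km = 1, kcat = 1) # kf = 5, kb = 4
#' @export
rate_constants_from_km_kcat <- function(km, kcat) {
  if (is.null(km) || is.null(kcat) || !is.finite(km) || !is.finite(kcat) ||
      km <= 0 || kcat <= 0)
    stop("km and kcat must both be finite and > 0")
  kb <- 4 * kcat
  list(kf = (kb + kcat) / km, kb = kb, kcat = kcat)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.reaction <- function(x, ...) {
  cat(class(x)[1L], ": ", x$name, "\n", sep = "")
  invisible(x)
}
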