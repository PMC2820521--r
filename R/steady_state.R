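# Newton solver on the conservation-reduced system, stability
# classification via the reduced Jacobian, hysteresis / bifurcation sweeps.

# internal: damped Newton on the conservation-reduced coordinates.
# The state is parametrized as y_dyn = y0 + N z with N an orthonormal basis
# of the null space of the moiety-law matrix L (the stoichiometric
# subspace); steps stay exactly on the conservation manifold and the
# reduced Jacobian t(N) J N is nonsingular at hyperbolic fixed points.
.newton_core <- function(net, y, max_iter = 60, tol = 1e-11) {
  rhs <- assemble_rhs(net)
  jac <- assemble_jacobian(net)
  dyn <- which(!net$species$clamped)
  laws <- conserved_moieties(net)
  nd <- length(dyn)
  dn <- net$species$name[dyn]
  L <- matrix(0, length(laws), nd)
  for (r in seq_along(laws)) L[r, match(names(laws[[r]]), dn)] <- laws[[r]]
  N <- if (nrow(L)) {
    sv <- svd(L, nu = 0, nv = nd)
    sv$v[, seq(nrow(L) + 1L, nd), drop = FALSE]
  } else diag(nd)
  x <- y[dyn]
  Ffun <- function(x) {
    yy <- y; yy[dyn] <- x
    rhs(0, yy, NULL)[[1L]][dyn]
  }
  f <- Ffun(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    yy <- y; yy[dyn] <- x
    J <- jac(0, yy)[dyn, dyn, drop = FALSE]
    Jr <- crossprod(N, J %*% N)
    step <- tryCatch(drop(N %*% solve(Jr, -crossprod(N, f))),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- tryCatch(Ffun(xn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(f)) || lambda < 1e-6)) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6 && max(abs(fn)) >= max(abs(f))) break
    x <- xn; f <- fn
  }
  y[dyn] <- x
  resid <- max(abs(rhs(0, y, NULL)[[1L]]))
  list(y = y, residual = resid, L = L, dyn = dyn)
}

.newton_polish <- function(net, y, tol = 1e-9) {
  out <- tryCatch(.newton_core(net, y), error = function(e) NULL)
  rhs <- assemble_rhs(net)
  res0 <- max(abs(rhs(0, y, NULL)[[1L]]))
  if (is.null(out) || out$residual > res0 || any(out$y < -1e-8))
    return(list(y = y, residual = res0))
  list(y = out$y, residual = out$residual)
}

#' Classify the stability of a state
#'
#' Eigenvalues are taken from the Jacobian projected onto the tangent space
#' of the conservation laws (the stoichiometric subspace), so the structural
#' zero eigenvalues contributed by moiety conservation never enter the
#' classification.
#'
#' @param net The network.
#' @param y Named state vector.
#' @param marginal_tol States with `max |Re lambda| <` this are "marginal".
#' @return List with `stability` (`"stable"`, `"unstable"`, `"marginal"`)
#'   and `eigenvalues` (of the reduced Jacobian).
#' @export
classify_stability <- function(net, y, marginal_tol = 1e-8) {
  dyn <- which(!net$species$clamped)
  laws <- conserved_moieties(net)
  dn <- net$species$name[dyn]
  L <- matrix(0, length(laws), length(dyn))
  for (r in seq_along(laws)) L[r, match(names(laws[[r]]), dn)] <- laws[[r]]
  J <- assemble_jacobian(net)(0, y)[dyn, dyn, drop = FALSE]
  if (nrow(L)) {
    sv <- svd(L, nu = 0, nv = length(dyn))
    null_idx <- seq(nrow(L) + 1L, length(dyn))
    N <- sv$v[, null_idx, drop = FALSE]
    J <- t(N) %*% J %*% N
  }
  ev <- eigen(J, only.values = TRUE)$values
  mre <- max(Re(ev))
  stability <- if (abs(mre) < marginal_tol) "marginal"
  else if (mre < 0) "stable" else "unstable"
  list(stability = stability, eigenvalues = ev)
}

#' Extract a subsystem with parametric (clamped) inputs
#'
#' Keeps every reaction whose participants all lie within the retained or
#' clamped species sets, drops the rest, and recomputes the derived
#' structure. Clamped species become constant parametric inputs.
#'
#' @param net The full network.
#' @param retain Character vector of retained (dynamic) species.
#' @param clamp Named numeric vector of parametric inputs (species = value).
#' @param state Optional state supplying initial concentrations (defaults
#'   to the network's initials).
#' @return A [reaction_network()] for the subsystem.
#' @export
extract_subsystem <- function(net, retain, clamp = c(), state = NULL) {
  all_names <- net$species$name
  stopifnot(all(retain %in% all_names), all(names(clamp) %in% all_names))
  avail <- c(retain, names(clamp))
  keep_r <- vapply(net$reactions, function(r) {
    p <- if (inherits(r, "binding_reaction")) c(r$a, r$b, r$ab)
    else c(r$enzyme, r$substrate, r$product)
    all(p %in% avail)
  }, TRUE)
  rx <- net$reactions[keep_r]
  if (!length(rx)) warning("subsystem retains no reactions")
  base <- if (is.null(state)) initial_state(net) else state
  sp <- lapply(avail, function(nm)
    species(nm, max(0, unname(base[nm])),
            clamped = nm %in% names(clamp),
            clamp_value = if (nm %in% names(clamp)) clamp[[nm]]
            else unname(base[nm])))
  # inherit ES complex concentrations for kept enzymatic reactions
  sub <- reaction_network(sp, rx)
  es <- intersect(sub$species$name, names(base))
  sub <- set_initial(sub, base[setdiff(es, names(clamp))])
  sub$inputs <- net$inputs[net$inputs %in% sub$species$name]
  sub
}

#' The PKA-PP2A-Thr75 positive-feedback subsystem
#'
#' Convenience wrapper around [extract_subsystem()] retaining the species
#' of the positive feedback loop -- cAMP-driven PKA activation, PKA
#' phosphorylation of PP2A, PP2A dephosphorylation of phospho-Thr75, and
#' sequestration of the PKA catalytic subunit by phospho-Thr75 -- with
#' cAMP, calcium and active Cdk5 as clamped parametric inputs.
#'
#' @param net The full striatal network.
#' @param state State supplying totals (typically pre-equilibrated).
#' @param camp,ca,cdk5 Parametric input levels (µM).
#' @return A subsystem network.
#' @export
feedback_subsystem <- function(net, state = NULL,
                               camp = 0.6, ca = 0.06, cdk5 = 3.6,
                               pp2c = 1.2) {
  retain <- c("PKA", "PKAcAMP", "PKAc",
              "PP2A", "PP2ACa", "PP2Ap", "D000", "D75", "D75PKAc", "PP2C",
              "Cdk5act")
  sub <- extract_subsystem(net, retain,
                           clamp = c(cAMP = camp, Ca = ca),
                           state = state)
  # active Cdk5 has no activation/deactivation reactions inside the
  # subsystem: its conserved total (free + complex) is the parametric
  # input, and the enzyme pool can saturate. Inherited ES complexes of the
  # parametric enzymes are zeroed so the totals equal the parameters.
  zero_es <- function(sub, enzyme) {
    for (r in sub$reactions)
      if (inherits(r, "enzymatic_reaction") && r$enzyme == enzyme)
        sub <- set_initial(sub, stats::setNames(0, r$complex))
    sub
  }
  sub <- set_initial(sub, c(Cdk5act = cdk5))
  sub <- zero_es(sub, "Cdk5act")
  if (!is.null(pp2c)) {
    sub <- set_initial(sub, c(PP2C = pp2c))
    sub <- zero_es(sub, "PP2C")
  }
  sub
}

# apply a parametric-input value: clamped species are re-clamped, dynamic
# parametric pools (conserved enzymes such as Cdk5act) get their free
# concentration reset
.apply_param <- function(sub, name, value) {
  i <- match(name, sub$species$name)
  if (is.na(i)) stop("unknown parametric input: ", name)
  if (sub$species$clamped[i]) set_clamp(sub, name, value)
  else set_initial(sub, stats::setNames(value, name))
}

#' Enumerate steady states of a subsystem
#'
#' Newton iterations started from a deterministic grid of initial states
#' that redistribute each conserved moiety across its member species,
#' augmented by midpoints between distinct converged states (which reliably
#' picks up the unstable saddle between two stable nodes). Converged points
#' are deduplicated at relative max-norm distance `dedup_tol` and
#' classified with [classify_stability()].
#'
#' @param sub A subsystem network (parametric inputs clamped).
#' @param params Optional named vector re-clamping parametric inputs.
#' @param y0 Base state for totals (defaults to subsystem initials).
#' @param resid_tol Acceptance residual (µM/s).
#' @param dedup_tol Relative deduplication tolerance.
#' @return List of `steady_state` objects (`y`, `residual`, `stability`,
#'   `eigenvalues`), ordered by increasing active-PKA (`PKAc`) when present.
#' @export
find_steady_states <- function(sub, params = NULL, y0 = NULL,
                               resid_tol = 1e-10, dedup_tol = 1e-6) {
  if (!is.null(params))
    for (nm in names(params)) sub <- .apply_param(sub, nm, params[[nm]])
  base <- if (is.null(y0)) initial_state(sub) else y0[sub$species$name]
  # all seeds live in the base state's stoichiometric compatibility class:
  # idealized low/high-activity extremes are projected onto the class
  # (through the orthonormal null-space basis of the moiety laws), and
  # interpolations between projections stay inside it
  dyn <- which(!sub$species$clamped)
  laws <- conserved_moieties(sub)
  dn <- sub$species$name[dyn]
  L <- matrix(0, length(laws), length(dyn))
  for (r in seq_along(laws)) L[r, match(names(laws[[r]]), dn)] <- laws[[r]]
  N <- if (nrow(L)) {
    sv <- svd(L, nu = 0, nv = length(dyn))
    sv$v[, seq(nrow(L) + 1L, length(dyn)), drop = FALSE]
  } else diag(length(dyn))
  project <- function(y) {
    z <- y
    z[dyn] <- base[dyn] + drop(N %*% crossprod(N, y[dyn] - base[dyn]))
    z
  }
  lo <- project(tryCatch(.low_activity_state(sub), error = function(e) base))
  hi <- project(tryCatch(.high_activity_state(sub), error = function(e) base))
  seeds <- list(base)
  for (f in c(0, 0.15, 0.3, 0.5, 0.7, 0.85, 1))
    seeds[[length(seeds) + 1L]] <- lo * (1 - f) + hi * f
  # short relaxations from the extremes land inside the stable basins;
  # clip-and-reproject keeps the seed inside the compatibility class
  for (y in list(lo, hi, base)) {
    ys <- project(pmax(project(pmax(y, 0)), 0))
    seeds[[length(seeds) + 1L]] <- tryCatch(
      .settle(sub, ys, t_settle = 400), error = function(e) ys)
  }
  sols <- list()
  push <- function(y) {
    out <- tryCatch(.newton_core(sub, y), error = function(e) NULL)
    if (is.null(out) || out$residual > resid_tol) return(invisible())
    if (any(out$y < -1e-8)) return(invisible())
    for (s in sols) {
      sc <- pmax(abs(s$y), abs(out$y), 1e-6)
      if (max(abs(s$y - out$y) / sc) < dedup_tol) return(invisible())
    }
    cls <- classify_stability(sub, out$y)
    sols[[length(sols) + 1L]] <<- structure(
      list(y = out$y, residual = out$residual,
           stability = cls$stability, eigenvalues = cls$eigenvalues),
      class = "steady_state")
    invisible()
  }
  for (y in seeds) push(y)
  # saddle search between pairs of found states
  if (length(sols) >= 2) {
    pairs <- utils::combn(length(sols), 2)
    for (q in seq_len(ncol(pairs))) {
      a <- sols[[pairs[1, q]]]$y; b <- sols[[pairs[2, q]]]$y
      for (f in c(0.5, 0.25, 0.75)) push(a * (1 - f) + b * f)
    }
  }
  # if two stable basins were found but no saddle, bisect the basin
  # boundary along the connecting segment and start Newton there
  st <- vapply(sols, function(s) s$stability, "")
  if (sum(st == "stable") >= 2 && !any(st == "unstable")) {
    ix <- which(st == "stable")[1:2]
    a <- sols[[ix[1]]]$y; b <- sols[[ix[2]]]$y
    key <- if ("PKAc" %in% names(a)) "PKAc" else names(a)[1]
    basin_of <- function(f) {
      y <- a * (1 - f) + b * f
      ys <- tryCatch(.settle(sub, y, 500), error = function(e) NULL)
      if (is.null(ys)) return(NA)
      abs(ys[[key]] - a[[key]]) < abs(ys[[key]] - b[[key]])
    }
    lo_f <- 0.02; hi_f <- 0.98
    for (it in 1:12) {
      mid <- (lo_f + hi_f) / 2
      ba <- basin_of(mid)
      if (is.na(ba)) break
      if (ba) lo_f <- mid else hi_f <- mid
    }
    # trajectories from the basin boundary flow toward the saddle along
    # its stable manifold: integrate briefly, then Newton
    ymid <- a * (1 - (lo_f + hi_f) / 2) + b * (lo_f + hi_f) / 2
    for (tt in c(50, 150, 400)) {
      ys <- tryCatch({
        tc <- simulate_network(sub, c(0, tt), y0 = ymid)
        z <- unclass(tc)[2, ]; names(z) <- sub$species$name; z
      }, error = function(e) NULL)
      if (!is.null(ys)) push(ys)
    }
    for (f in unique(c(lo_f, hi_f))) push(a * (1 - f) + b * f)
  }
  if ("PKAc" %in% sub$species$name && length(sols) > 1) {
    ord <- order(vapply(sols, function(s) s$y[["PKAc"]], 0))
    sols <- sols[ord]
  }
  sols
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady_state (", x$stability, "), residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

# settle one quasi-static step: integrate then polish
.settle <- function(sub, y, t_settle = 200, tol = 1e-9) {
  tc <- simulate_network(sub, c(0, t_settle), y0 = y)
  y <- unclass(tc)[nrow(tc), ]
  names(y) <- sub$species$name
  .newton_polish(sub, y, tol)$y
}

#' Quasi-static hysteresis sweep
#'
#' Sweeps a clamped parametric input up through `values` and back down,
#' letting the subsystem settle at each step from the previous step's
#' state (integration for `t_settle` seconds plus a Newton polish). In a
#' bistable window the up and down branches disagree.
#'
#' @param sub The subsystem.
#' @param param_name Clamped species swept (e.g. `"cAMP"`).
#' @param values Increasing parameter values.
#' @param readout Species reported (default `"PKAc"`).
#' @param y0 Starting state (defaults to subsystem initials settled at
#'   `values[1]`).
#' @param t_settle Settling time per step (s).
#' @return A data frame (direction, value, readout value) of both branches.
#' @export
hysteresis_sweep <- function(sub, param_name = "cAMP", values,
                             readout = "PKAc", y0 = NULL, t_settle = 200) {
  stopifnot(!is.unsorted(values))
  y <- if (is.null(y0)) initial_state(sub) else y0[sub$species$name]
  i <- match(param_name, sub$species$name)
  clamped_param <- sub$species$clamped[i]
  v_prev <- unname(y[param_name])
  out <- NULL
  for (dir in c("up", "down")) {
    vv <- if (dir == "up") values else rev(values)
    for (v in vv) {
      if (clamped_param) {
        sub <- set_clamp(sub, param_name, v)
        y[param_name] <- v
      } else {
        y[param_name] <- max(0, y[param_name] + (v - v_prev))
      }
      v_prev <- v
      y <- .settle(sub, y, t_settle)
      out <- rbind(out, data.frame(direction = dir, value = v,
                                   readout = unname(y[readout])))
    }
  }
  names(out)[3] <- readout
  out
}

#' Steady-state sheets over a 2-D parameter grid
#'
#' Enumerates steady states at every grid cell of two clamped parameters
#' and summarizes the stable sheets.
#'
#' @param sub The subsystem.
#' @param camp_values,cdk5_values Grids for the two parametric inputs.
#' @param param_names Names of the two swept species.
#' @param readout Species reported.
#' @param ... Passed to [find_steady_states()].
#' @return List with `camp_values`, `cdk5_values`, matrices `n_stable`,
#'   `low`, `high` (stable-readout extremes; equal where monostable) and
#'   `states` (list-matrix of full results).
#' @export
bifurcation_surface <- function(sub, camp_values, cdk5_values,
                                param_names = c("cAMP", "Cdk5act"),
                                readout = "PKAc", ...) {
  n1 <- length(camp_values); n2 <- length(cdk5_values)
  n_stable <- low <- high <- matrix(NA_real_, n1, n2)
  states <- vector("list", n1 * n2); dim(states) <- c(n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    p <- stats::setNames(c(camp_values[i], cdk5_values[j]), param_names)
    ss <- tryCatch(find_steady_states(sub, params = p, ...),
                   error = function(e) list())
    states[[i, j]] <- ss
    st <- vapply(ss, function(s) s$stability, "")
    vals <- vapply(ss, function(s) s$y[[readout]], 0)
    if (any(st == "stable")) {
      n_stable[i, j] <- sum(st == "stable")
      low[i, j] <- min(vals[st == "stable"])
      high[i, j] <- max(vals[st == "stable"])
    }
  }
  list(camp_values = camp_values, cdk5_values = cdk5_values,
       n_stable = n_stable, low = low, high = high, states = states)
}

#' Scale rate constants of a reaction (by label or rate group)
#'
#' @param net The network.
#' @param label Reaction name or `group` label.
#' @param kf,kb,kcat Multiplicative factors.
#' @return The modified network (reindexed).
#' @export
scale_rate <- function(net, label, kf = 1, kb = 1, kcat = 1) {
  hit <- FALSE
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (identical(r$name, label) || identical(r$group, label)) {
      r$kf <- r$kf * kf; r$kb <- r$kb * kb
      if (!is.null(r$kcat)) r$kcat <- r$kcat * kcat
      net$reactions[[j]] <- r
      hit <- TRUE
    }
  }
  if (!hit) stop("no reaction matches label/group: ", label)
  .index_network(net)
}

#' Robustness scan of the positive-feedback threshold
#'
#' For each parameter variant (a loop constant times a fold multiplier) the
#' stationary active-PKA level reached from a low-activity initial state is
#' recorded against the clamped active-Cdk5 level, and the threshold --
#' the Cdk5 level at which PKA activation collapses to the lower branch --
#' is detected as the first grid point where the response falls below the
#' midpoint of its extremes.
#'
#' @param sub The feedback subsystem.
#' @param cdk5_values Increasing grid of active-Cdk5 levels (µM).
#' @param variations Data frame with columns `target` (rate-group label),
#'   `what` (`"kb"` for a dissociation constant scaled via the off-rate,
#'   `"kcat"`), and `fold`.
#' @param y_low Low-activity starting state (defaults to all DARPP-32 of
#'   the subsystem moved into phospho-Thr75 and PKA fully holoenzyme).
#' @param t_settle Settling time per point (s).
#' @return Data frame (target, what, fold, threshold) with attribute
#'   `curves` (list of per-variant data frames cdk5 vs pka).
#' @export
robustness_scan <- function(sub, cdk5_values,
                            variations = default_variations(),
                            y_low = NULL, t_settle = 400) {
  if (is.null(y_low)) y_low <- .low_activity_state(sub)
  curves <- list(); thr <- numeric(nrow(variations))
  for (v in seq_len(nrow(variations))) {
    net_v <- switch(variations$what[v],
                    kb = scale_rate(sub, variations$target[v],
                                    kb = variations$fold[v]),
                    kcat = scale_rate(sub, variations$target[v],
                                      kcat = variations$fold[v]),
                    stop("what must be 'kb' or 'kcat'"))
    pka <- numeric(length(cdk5_values))
    for (k in seq_along(cdk5_values)) {
      net_k <- .apply_param(net_v, "Cdk5act", cdk5_values[k])
      y <- y_low; y["Cdk5act"] <- cdk5_values[k]
      y <- .settle(net_k, y, t_settle)
      pka[k] <- y[["PKAc"]]
    }
    curves[[v]] <- data.frame(cdk5 = cdk5_values, pka = pka)
    mid <- (max(pka) + min(pka)) / 2
    below <- which(pka < mid)
    thr[v] <- if (length(below) && max(pka) > 2 * min(pka))
      cdk5_values[min(below)] else NA_real_
  }
  out <- cbind(variations, threshold = thr)
  attr(out, "curves") <- curves
  out
}

#' Default parameter variations for the robustness scan
#'
#' The three loop constants -- the dissociation constant of the
#' phospho-Thr75:PKA complex, the catalytic constant of PKA acting on PP2A,
#' and the catalytic constant of PP2A acting on phospho-Thr75 -- each at
#' fold changes 10, 5, 2, 1, 0.5, 0.2, 0.1.
#'
#' @return A data frame with columns `target`, `what`, `fold`.
#' @export
default_variations <- function() {
  folds <- c(10, 5, 2, 1, 0.5, 0.2, 0.1)
  rbind(
    data.frame(target = "b.d75_pka", what = "kb", fold = folds),
    data.frame(target = "e.pka_pp2a", what = "kcat", fold = folds),
    data.frame(target = "e.pp2ap_t75", what = "kcat", fold = folds))
}

# Constructed activity extremes of the feedback subsystem. Totals are
# taken from exact structural content vectors (protein_moiety), so the
# extreme states lie in the same stoichiometric compatibility class as the
# current initial state: low = PKA fully holoenzyme with DARPP-32 fully
# phospho-Thr75; high = PKA fully dissociated-active with DARPP-32
# unphosphorylated.
.activity_extremes <- function(sub) {
  y <- initial_state(sub)
  nm <- sub$species$name
  pools <- list(
    c(anchor = "D75", alt = "D000", base = "D000"),
    c(anchor = "PKA", alt = "PKAc", base = "PKA"),
    c(anchor = "PP2A", alt = "PP2Ap", base = "PP2A"),
    c(anchor = "PP2C", alt = "PP2C", base = "PP2C"),
    c(anchor = "Cdk5act", alt = "Cdk5act", base = "Cdk5act"))
  pools <- Filter(function(p) p[["base"]] %in% nm, pools)
  conts <- lapply(pools, function(p) protein_moiety(sub, p[["base"]]))
  tots <- vapply(seq_along(pools), function(i)
    sum(conts[[i]] * y[names(conts[[i]])]), 0)
  lo <- hi <- y
  zero <- unique(unlist(lapply(conts, names)))
  zero <- zero[!sub$species$clamped[match(zero, nm)]]
  lo[zero] <- 0; hi[zero] <- 0
  for (i in seq_along(pools)) {
    p <- pools[[i]]
    if (sub$species$clamped[match(p[["anchor"]], nm)]) next
    lo[p[["anchor"]]] <- tots[i]
    hi[p[["alt"]]] <- tots[i]
  }
  list(lo = lo, hi = hi)
}

.low_activity_state <- function(sub) .activity_extremes(sub)$lo
.high_activity_state <- function(sub) .activity_extremes(sub)$hi
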