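#' Assemble a mass-action reaction network
#'
#' Collects species and reactions into a validated network object. ES
#' complexes of enzymatic reactions that were not declared explicitly are
#' created automatically with zero initial concentration. The network stores
#' the elementary-step decomposition (binding reactions contribute an
#' association and a dissociation step; enzymatic reactions contribute
#' association, dissociation and catalysis), the stoichiometric matrix over
#' elementary steps, and is the object consumed by [simulate_network()],
#' [conserved_moieties()] and the steady-state engine.
#'
#' @param species A list of [species()] objects.
#' @param reactions A list of [binding_reaction()] / [enzymatic_reaction()]
#'   objects.
#' @param volume Spine volume metadata in litres (concentrations remain the
#'   state variables; the volume is carried along for reference only).
#' @return An object of class `"reaction_network"` with elements
#'   `species` (data frame: name, conc, clamped, clamp_value),
#'   `reactions`, `S` (species x elementary-steps stoichiometric matrix),
#'   `steps` (elementary-step table) and `volume`.
#' @examples
#' net <- reaction_network(
#'   list(species("A", 1), species("B", 1), species("AB")),
#'   list(binding_reaction("A", "B", "AB", kf = 1, kb = 1)))
#' net
#' @export
reaction_network <- function(species, reactions, volume = 1e-16) {
  stopifnot(is.list(species), is.list(reactions))
  if (!all(vapply(species, inherits, TRUE, "species")))
    stop("'species' must be a list of species() objects")
  if (!all(vapply(reactions, inherits, TRUE, "reaction")))
    stop("'reactions' must be a list of reaction objects")

  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names))
    stop("duplicate species names: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))

  # auto-create undeclared ES complexes
  for (r in reactions) {
    if (inherits(r, "enzymatic_reaction") && !(r$complex %in% sp_names)) {
      species <- c(species, list(species_obj <- structure(
        list(name = r$complex, conc = 0, clamped = FALSE, clamp_value = 0),
        class = "species")))
      sp_names <- c(sp_names, r$complex)
    }
  }

  refs <- unlist(lapply(reactions, function(r)
    if (inherits(r, "binding_reaction")) c(r$a, r$b, r$ab)
    else c(r$enzyme, r$substrate, r$product, r$complex)))
  missing <- setdiff(refs, sp_names)
  if (length(missing))
    stop("reactions reference undeclared species: ",
         paste(missing, collapse = ", "))

  # ES complexes must be private to their reaction's two elementary steps
  es <- vapply(reactions, function(r)
    if (inherits(r, "enzymatic_reaction")) r$complex else NA_character_, "")
  es <- es[!is.na(es)]
  if (anyDuplicated(es))
    stop("ES complex shared between enzymatic reactions: ",
         paste(unique(es[duplicated(es)]), collapse = ", "))
  other_refs <- unlist(lapply(reactions, function(r)
    if (inherits(r, "binding_reaction")) c(r$a, r$b, r$ab)
    else c(r$enzyme, r$substrate, r$product)))
  bad <- intersect(es, other_refs)
  if (length(bad))
    stop("ES complex used outside its own reaction: ",
         paste(bad, collapse = ", "))

  sp <- data.frame(
    name = sp_names,
    conc = vapply(species, `[[`, 0, "conc"),
    clamped = vapply(species, `[[`, TRUE, "clamped"),
    clamp_value = vapply(species, `[[`, 0, "clamp_value"),
    stringsAsFactors = FALSE)
  rownames(sp) <- NULL

  net <- structure(list(species = sp, reactions = reactions,
                        volume = volume),
                   class = "reaction_network")
  net <- .index_network(net)
  net
}

# build elementary-step table and stoichiometric matrix
.index_network <- function(net) {
  sp_names <- net$species$name
  idx <- function(s) match(s, sp_names)
  n <- length(sp_names)

  k <- numeric(0); i1 <- integer(0); i2 <- integer(0)
  rows <- list()  # stoichiometry increments per step
  lab <- character(0); rxn <- integer(0)
  add_step <- function(kk, a, b, out_minus, out_plus, label, which_rxn) {
    k[[length(k) + 1L]] <<- kk
    i1[[length(i1) + 1L]] <<- idx(a)
    i2[[length(i2) + 1L]] <<- if (is.na(b)) 0L else idx(b)
    col <- numeric(n)
    for (s in out_minus) col[idx(s)] <- col[idx(s)] - 1
    for (s in out_plus)  col[idx(s)] <- col[idx(s)] + 1
    rows[[length(rows) + 1L]] <<- col
    lab[[length(lab) + 1L]] <<- label
    rxn[[length(rxn) + 1L]] <<- which_rxn
  }

  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (inherits(r, "binding_reaction")) {
      add_step(r$kf, r$a, r$b, c(r$a, r$b), r$ab, paste0(r$name, " [f]"), j)
      add_step(r$kb, r$ab, NA, r$ab, c(r$a, r$b), paste0(r$name, " [b]"), j)
    } else {
      add_step(r$kf, r$enzyme, r$substrate, c(r$enzyme, r$substrate),
               r$complex, paste0(r$name, " [on]"), j)
      add_step(r$kb, r$complex, NA, r$complex, c(r$enzyme, r$substrate),
               paste0(r$name, " [off]"), j)
      add_step(r$kcat, r$complex, NA, r$complex, c(r$enzyme, r$product),
               paste0(r$name, " [cat]"), j)
    }
  }
  S <- do.call(cbind, rows)
  dimnames(S) <- list(sp_names, lab)
  net$S <- S
  net$steps <- data.frame(k = k, i1 = i1, i2 = i2, reaction = rxn,
                          label = lab, stringsAsFactors = FALSE)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  nb <- sum(vapply(x$reactions, inherits, TRUE, "binding_reaction"))
  ne <- length(x$reactions) - nb
  cat("reaction_network: ", nrow(x$species), " species, ",
      length(x$reactions), " reactions (", nb, " binding, ", ne,
      " enzymatic), ", sum(x$species$clamped), " clamped\n", sep = "")
  invisible(x)
}

#' Number of reactions and distinct rate parameters
#'
#' Reactions are counted as table rows (one per binding or enzymatic
#' reaction). Parameters are counted per rate group: reactions sharing a
#' `group` label contribute one parameter set (two constants for a binding
#' reaction or a Km/kcat-specified enzymatic reaction).
#'
#' @param net A [reaction_network()].
#' @return A list with `n_reactions` and `n_parameters`.
#' @export
network_counts <- function(net) {
  grp <- vapply(seq_along(net$reactions), function(j) {
    r <- net$reactions[[j]]
    r$group %||% paste0(".r", j)
  }, "")
  first <- !duplicated(grp)
  npar <- sum(vapply(net$reactions[first], function(r) 2L, 1L))
  list(n_reactions = length(net$reactions), n_parameters = npar)
}

#' Assemble the ODE right-hand side of a network
#'
#' Returns a derivative function in the signature expected by
#' [deSolve::lsoda()]. Each elementary step contributes a mass-action flux
#' `k * [X1] * [X2]` (or `k * [X1]` for unimolecular steps) routed through
#' the stoichiometric matrix. Clamped species are overwritten with their
#' imposed value (constant, or the forcing function evaluated at `t`) before
#' fluxes are computed, and their derivatives are zeroed.
#'
#' @param net A [reaction_network()].
#' @param forcings Named list of `function(t)` waveforms for clamped species
#'   (e.g. the calcium and dopamine inputs). Clamped species without a
#'   forcing are held at their `clamp_value`.
#' @return `function(t, y, parms)` returning `list(dy)`.
#' @examples
#' net <- reaction_network(
#'   list(species("A", 1), species("B", 1), species("AB")),
#'   list(binding_reaction("A", "B", "AB", kf = 1, kb = 1)))
#' f <- assemble_rhs(net)
#' f(0, c(A = 1, B = 1, AB = 0), NULL)  # d[AB]/dt = 1
#' @export
assemble_rhs <- function(net, forcings = list()) {
  S <- net$S
  k <- net$steps$k
  i1 <- net$steps$i1 + 1L   # shifted: position 1 holds the constant 1
  i2 <- net$steps$i2 + 1L
  clamped <- which(net$species$clamped)
  clamp_val <- net$species$clamp_value[clamped]
  f_idx <- match(names(forcings), net$species$name)
  if (anyNA(f_idx))
    stop("forcing for unknown species: ",
         paste(names(forcings)[is.na(f_idx)], collapse = ", "))
  if (length(f_idx) && !all(f_idx %in% clamped))
    stop("forcings are only allowed on clamped species")
  forc <- unname(forcings)

  function(t, y, parms) {
    if (length(clamped)) {
      y[clamped] <- clamp_val
      for (q in seq_along(f_idx)) y[f_idx[q]] <- forc[[q]](t)
    }
    y2 <- c(1, y)
    v <- k * y2[i1] * y2[i2]
    dy <- drop(S %*% v)
    if (length(clamped)) dy[clamped] <- 0
    list(dy)
  }
}

#' Analytic Jacobian of the network right-hand side
#'
#' @inheritParams assemble_rhs
#' @return `function(t, y)` returning the dense Jacobian matrix (rows of
#'   clamped species are zero).
#' @export
assemble_jacobian <- function(net, forcings = list()) {
  S <- net$S
  k <- net$steps$k
  i1 <- net$steps$i1
  i2 <- net$steps$i2
  n <- nrow(net$species)
  m <- length(k)
  clamped <- which(net$species$clamped)
  clamp_val <- net$species$clamp_value[clamped]
  f_idx <- match(names(forcings), net$species$name)
  forc <- unname(forcings)
  uni <- i2 == 0L

  function(t, y, ...) {
    if (length(clamped)) {
      y[clamped] <- clamp_val
      for (q in seq_along(f_idx)) y[f_idx[q]] <- forc[[q]](t)
    }
    Dv <- matrix(0, m, n)
    # d(k y1 y2)/dy1 = k y2 ; unimolecular: d(k y1)/dy1 = k
    Dv[cbind(seq_len(m), i1)] <- ifelse(uni, k, k * y[pmax(i2, 1L)])
    bi <- which(!uni)
    # accumulate (handles y1 == y2 autocatalytic steps)
    Dv[cbind(bi, i2[bi])] <- Dv[cbind(bi, i2[bi])] + k[bi] * y[i1[bi]]
    J <- S %*% Dv
    if (length(clamped)) J[clamped, ] <- 0
    J
  }
}

#' Extract conserved moieties of a network
#'
#' Computes a basis of the left null space of the stoichiometric matrix
#' restricted to unclamped species, i.e. weighted sums of concentrations
#' that are invariant along every trajectory. Weights are scaled to small
#' integers where possible. Clamped species are excluded: a clamped
#' reactant acts as a source/sink and breaks the closure of any moiety it
#' participates in.
#'
#' @param net A [reaction_network()].
#' @return A list of named numeric weight vectors (names are species).
#' @examples
#' net <- reaction_network(
#'   list(species("A", 1), species("B", 1), species("AB")),
#'   list(binding_reaction("A", "B", "AB", kf = 1, kb = 1)))
#' conserved_moieties(net)  # {A + AB}, {B + AB}
#' @export
conserved_moieties <- function(net) {
  keep <- !net$species$clamped
  S <- net$S[keep, , drop = FALSE]
  basis <- .left_null_basis(S)
  lapply(basis, function(w) {
    names(w) <- net$species$name[keep]
    w[w != 0]
  })
}

# Left null basis of S via RREF of t(S); integer-rescaled where possible.
.left_null_basis <- function(S, tol = 1e-9) {
  A <- t(S)                       # null(A) = left null of S
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[p, col]) < tol) next
    if (p != row) A[c(p, row), ] <- A[c(row, p), ]
    A[row, ] <- A[row, ] / A[row, col]
    others <- setdiff(seq_len(m), row)
    A[others, ] <- A[others, ] - outer(A[others, col], A[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  basis <- lapply(free, function(fc) {
    v <- numeric(n)
    v[fc] <- 1
    if (length(pivots))
      v[pivots] <- -A[seq_along(pivots), fc]
    v[abs(v) < tol] <- 0
    .integerize(v)
  })
  basis
}

# scale a rational-looking vector to small integers
.integerize <- function(v, max_den = 48L) {
  nz <- v[v != 0]
  if (!length(nz)) return(v)
  for (d in seq_len(max_den)) {
    w <- v * d
    if (all(abs(w - round(w)) < 1e-6)) {
      w <- round(w)
      g <- Reduce(.gcd, abs(w[w != 0]))
      return(w / g)
    }
  }
  v
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Evaluate conservation-law values for a state
#'
#' @param laws Output of [conserved_moieties()].
#' @param y Named state vector (µM).
#' @return Numeric vector of law values.
#' @export
moiety_values <- function(laws, y) {
  vapply(laws, function(w) sum(w * y[names(w)]), 0)
}

#' Find the conservation law spanning a set of species
#'
#' Convenience for locating e.g. the total-DARPP-32 law: returns the first
#' law whose support contains every requested species.
#'
#' @param laws Output of [conserved_moieties()].
#' @param species_names Character vector that must be inside the law.
#' @return A single weight vector, or `NULL` when no law matches.
#' @export
find_moiety <- function(laws, species_names) {
  for (w in laws) if (all(species_names %in% names(w))) return(w)
  NULL
}

#' Protein-content conservation vector
#'
#' Builds the moiety vector of a protein by structural composition
#' propagation: the protein's free states carry content 1, binding
#' complexes sum their parts, ES complexes sum enzyme and substrate, and
#' enzymatic products inherit the substrate's content. The result is
#' verified to lie in the left null space of the stoichiometric matrix,
#' i.e. to be a genuine conservation law.
#'
#' @param net A [reaction_network()].
#' @param base_states Free states of the protein (content 1 each).
#' @return Named content vector over the species with nonzero content.
#' @export
protein_moiety <- function(net, base_states) {
  nm <- net$species$name
  stopifnot(all(base_states %in% nm))
  cont <- stats::setNames(numeric(length(nm)), nm)
  cont[base_states] <- 1
  for (it in 1:8) {
    prev <- cont
    for (r in net$reactions) {
      if (inherits(r, "binding_reaction")) {
        cont[r$ab] <- cont[r$a] + cont[r$b]
      } else {
        cont[r$complex] <- cont[r$enzyme] + cont[r$substrate]
        cont[r$product] <- cont[r$substrate]
      }
    }
    if (identical(prev, cont)) break
  }
  drift <- max(abs(drop(cont %*% net$S[, , drop = FALSE])))
  if (drift > 1e-9)
    stop("composition vector is not conserved (structural inconsistency)")
  cont[cont != 0]
}

#' Initial state vector of a network
#'
#' @param net A [reaction_network()].
#' @return Named numeric vector of initial concentrations (clamped species
#'   at their clamp value).
#' @export
initial_state <- function(net) {
  y <- net$species$conc
  y[net$species$clamped] <- net$species$clamp_value[net$species$clamped]
  names(y) <- net$species$name
  y
}

#' Modify clamping of species
#'
#' @param net A [reaction_network()].
#' @param names Species to modify.
#' @param value Clamp value(s); `NULL` keeps current concentrations.
#' @param clamped Logical, set or release the clamp.
#' @return The modified network.
#' @export
set_clamp <- function(net, names, value = NULL, clamped = TRUE) {
  i <- match(names, net$species$name)
  if (anyNA(i)) stop("unknown species: ",
                     paste(names[is.na(i)], collapse = ", "))
  net$species$clamped[i] <- clamped
  if (!is.null(value)) {
    net$species$clamp_value[i] <- value
    net$species$conc[i] <- value
  } else {
    net$species$clamp_value[i] <- net$species$conc[i]
  }
  net
}

#' Overwrite initial concentrations
#'
#' @param net A [reaction_network()].
#' @param y Named vector of concentrations to set.
#' @return The modified network.
#' @export
set_initial <- function(net, y) {
  i <- match(names(y), net$species$name)
  if (anyNA(i)) stop("unknown species: ",
                     paste(names(y)[is.na(i)], collapse = ", "))
  net$species$conc[i] <- unname(y)
  net
}
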