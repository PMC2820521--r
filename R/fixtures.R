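#' Generate a toy network fixture with a reference solution
#'
#' Deterministic-per-seed toy networks used as test oracles:
#' \describe{
#'   \item{`binding_equilibrium`}{one binding reaction with random totals;
#'     the reference is the closed-form quadratic equilibrium.}
#'   \item{`enzymatic_mm_limit`}{one enzymatic reaction with enzyme far
#'     below substrate; the reference is the Michaelis-Menten initial
#'     velocity `kcat E_tot S / (Km + S)`.}
#'   \item{`bistable_toy`}{a fixed autocatalytic phosphorylation cycle
#'     (the phospho-form is itself the kinase) opposed by a saturable
#'     phosphatase: off and on states coexist under the weak clamped
#'     basal kinase.}
#'   \item{`random_small_network`}{up to 5 random reactions over a small
#'     species pool, for brute-force derivative checks.}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param seed Integer seed; the same seed always yields the same fixture.
#' @return A list with elements `network` and `reference` (kind-specific).
#' @export
generate_fixture <- function(kind = c("binding_equilibrium",
                                      "enzymatic_mm_limit",
                                      "bistable_toy",
                                      "random_small_network"),
                             seed = 1) {
  kind <- match.arg(kind)
  rs <- .with_seed(seed, switch(
    kind,
    binding_equilibrium = .fx_binding(),
    enzymatic_mm_limit = .fx_mm(),
    bistable_toy = .fx_bistable(),
    random_small_network = .fx_random()))
  rs
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

.fx_binding <- function() {
  kf <- stats::runif(1, 0.5, 5); kb <- stats::runif(1, 0.5, 5)
  a0 <- stats::runif(1, 0.5, 3); b0 <- stats::runif(1, 0.5, 3)
  net <- reaction_network(
    list(species("A", a0), species("B", b0), species("AB", 0)),
    list(binding_reaction("A", "B", "AB", kf = kf, kb = kb)))
  kd <- kb / kf
  s <- a0 + b0 + kd
  ab_eq <- (s - sqrt(s^2 - 4 * a0 * b0)) / 2
  list(network = net,
       reference = list(kf = kf, kb = kb, kd = kd,
                        equilibrium = c(A = a0 - ab_eq, B = b0 - ab_eq,
                                        AB = ab_eq)))
}

.fx_mm <- function() {
  km <- stats::runif(1, 1, 10); kcat <- stats::runif(1, 0.5, 5)
  e0 <- 0.01; s0 <- stats::runif(1, 20, 100)
  net <- reaction_network(
    list(species("E", e0), species("S", s0), species("P", 0)),
    list(enzymatic_reaction("E", "S", "P", km = km, kcat = kcat)))
  list(network = net,
       reference = list(km = km, kcat = kcat, e0 = e0, s0 = s0,
                        v0 = kcat * e0 * s0 / (km + s0)))
}

# Weak clamped kinase K seeds X -> Xp; Xp autocatalytically converts the
# remaining X (intersubunit-style); phosphatase F works near saturation.
# The off state (Xp ~ 0) and the on state (Xp ~ pool) coexist.
.fx_bistable <- function() {
  net <- reaction_network(
    list(species("K", 0.002, clamped = TRUE),
         species("X", 10), species("Xp", 0), species("F", 0.3)),
    list(enzymatic_reaction("K", "X", "Xp", km = 2, kcat = 1),
         enzymatic_reaction("Xp", "X", "Xp", km = 2, kcat = 2,
                            complex = "XpX"),
         enzymatic_reaction("F", "Xp", "X", km = 0.1, kcat = 5)))
  list(network = net,
       reference = list(kinase_species = "K",
                        readout = c("Xp", "XpX")))
}

.fx_random <- function() {
  n_sp <- sample(4:6, 1)
  sp_names <- paste0("S", seq_len(n_sp))
  sp <- lapply(sp_names, function(nm)
    species(nm, stats::runif(1, 0.1, 2)))
  n_rx <- sample(2:5, 1)
  rx <- list()
  for (i in seq_len(n_rx)) {
    if (stats::runif(1) < 0.5 && n_sp >= 3) {
      trio <- sample(sp_names, 3)
      rx[[i]] <- binding_reaction(trio[1], trio[2], trio[3],
                                  kf = stats::runif(1, 0.1, 2),
                                  kb = stats::runif(1, 0.1, 2),
                                  name = paste0("bx", i))
    } else {
      trio <- sample(sp_names, 3)
      rx[[i]] <- enzymatic_reaction(trio[1], trio[2], trio[3],
                                    km = stats::runif(1, 0.5, 5),
                                    kcat = stats::runif(1, 0.1, 2),
                                    complex = paste0("ES", i),
                                    name = paste0("ex", i))
      sp <- c(sp, list(species(paste0("ES", i), 0)))
    }
  }
  net <- reaction_network(sp, rx)
  list(network = net, reference = list(n_reactions = n_rx))
}
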