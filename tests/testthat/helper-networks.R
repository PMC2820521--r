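# shared toy networks used across tests

toy_binding <- function(kf = 1, kb = 1, a0 = 1, b0 = 1) {
  reaction_network(
    list(species("A", a0), species("B", b0), species("AB", 0)),
    list(binding_reaction("A", "B", "AB", kf = kf, kb = kb)))
}

toy_enzymatic <- function(km = 2, kcat = 1, e0 = 0.05, s0 = 10) {
  reaction_network(
    list(species("E", e0), species("S", s0), species("P", 0)),
    list(enzymatic_reaction("E", "S", "P", km = km, kcat = kcat)))
}

# analytic equilibrium of A + B <-> AB from total concentrations
binding_equilibrium <- function(kf, kb, a_tot, b_tot) {
  kd <- kb / kf
  s <- a_tot + b_tot + kd
  ab <- (s - sqrt(s^2 - 4 * a_tot * b_tot)) / 2
  c(A = a_tot - ab, B = b_tot - ab, AB = ab)
}
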