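test_that("rate-constant conversions satisfy their defining identities", {
  rk <- rate_constants_from_kd_tau(kd = 1, tau = 1)
  expect_equal(rk$kf, 1)
  expect_equal(rk$kb, 1)
  rk <- rate_constants_from_kd_tau(kd = 2, tau = 0.5)
  expect_equal(rk$kf, 1)
  expect_equal(rk$kb, 2)
  for (kd in c(0.01, 0.5, 3, 40)) for (tau in c(0.02, 1, 15)) {
    rk <- rate_constants_from_kd_tau(kd, tau)
    expect_equal(rk$kb / rk$kf, kd)
    expect_equal(rk$kb, 1 / tau)
  }
  rk <- rate_constants_from_km_kcat(km = 1, kcat = 1)
  expect_equal(rk$kf, 5)
  expect_equal(rk$kb, 4)
  rk <- rate_constants_from_km_kcat(km = 10, kcat = 2)
  expect_equal(rk$kf, 1)
  expect_equal(rk$kb, 8)
  for (km in c(0.1, 2, 30)) for (kcat in c(0.05, 1, 12)) {
    rk <- rate_constants_from_km_kcat(km, kcat)
    expect_equal(rk$kb, 4 * kcat)
    expect_equal((rk$kb + rk$kcat) / rk$kf, km)
  }
  expect_error(rate_constants_from_kd_tau(-1, 1), "finite and > 0")
  expect_error(rate_constants_from_kd_tau(1, 0), "finite and > 0")
  expect_error(rate_constants_from_km_kcat(0, 1), "finite and > 0")
})

test_that("assembled derivatives match direct mass-action evaluation", {
  net <- toy_binding(kf = 1, kb = 1)
  f <- assemble_rhs(net)
  dy <- f(0, c(A = 1, B = 1, AB = 0), NULL)[[1]]
  expect_equal(unname(dy), c(-1, -1, 1))

  # brute-force oracle on random small networks: sum per-elementary-step
  # contributions independently of the vectorized path
  for (seed in 1:5) {
    fx <- generate_fixture("random_small_network", seed = seed)
    net <- fx$network
    f <- assemble_rhs(net)
    y <- initial_state(net)
    y[] <- abs(sin(seq_along(y) + seed)) + 0.1
    dy <- f(0, y, NULL)[[1]]
    brute <- numeric(length(y))
    for (j in seq_len(nrow(net$steps))) {
      v <- net$steps$k[j] * y[net$steps$i1[j]] *
        (if (net$steps$i2[j] > 0) y[net$steps$i2[j]] else 1)
      brute <- brute + net$S[, j] * v
    }
    expect_equal(unname(dy), unname(brute), tolerance = 1e-12)
  }
})

test_that("analytic Jacobian agrees with finite differences", {
  fx <- generate_fixture("random_small_network", seed = 3)
  net <- fx$network
  f <- assemble_rhs(net)
  jac <- assemble_jacobian(net)
  y <- initial_state(net)
  y[] <- abs(cos(seq_along(y))) + 0.2
  J <- jac(0, y)
  h <- 1e-7
  for (j in seq_along(y)) {
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    num <- (f(0, yp, NULL)[[1]] - f(0, ym, NULL)[[1]]) / (2 * h)
    expect_equal(unname(J[, j]), unname(num), tolerance = 1e-5)
  }
})

test_that("conserved moieties are textbook-correct for small motifs", {
  net <- toy_binding()
  expect_length(conserved_moieties(net), 2)
  a_law <- protein_moiety(net, "A")
  expect_setequal(names(a_law), c("A", "AB"))
  b_law <- protein_moiety(net, "B")
  expect_setequal(names(b_law), c("B", "AB"))

  net <- toy_enzymatic()
  expect_length(conserved_moieties(net), 2)
  expect_setequal(names(protein_moiety(net, "E")), c("E", "E.S"))
  expect_setequal(names(protein_moiety(net, "S")), c("S", "E.S", "P"))
})

test_that("binding reaction reaches the closed-form equilibrium", {
  for (seed in 1:3) {
    fx <- generate_fixture("binding_equilibrium", seed = seed)
    tc <- simulate_network(fx$network, c(0, 500))
    y_end <- unclass(tc)[nrow(tc), ]
    names(y_end) <- fx$network$species$name
    ref <- fx$reference$equilibrium
    expect_equal(unname(y_end[names(ref)]), unname(ref), tolerance = 1e-3)
    # mass-action ratio equals Kd within 0.1%
    expect_equal(y_end[["A"]] * y_end[["B"]] / y_end[["AB"]],
                 fx$reference$kd, tolerance = 1e-3)
  }
})

test_that("enzymatic reaction approaches the Michaelis-Menten limit", {
  fx <- generate_fixture("enzymatic_mm_limit", seed = 2)
  ref <- fx$reference
  # measure initial velocity after the brief ES pre-equilibration transient
  tc <- simulate_network(fx$network, seq(0, 2, 0.1))
  p <- trajectory(tc, "P")
  v0 <- (p[21] - p[11]) / 1.0
  expect_equal(v0, ref$v0, tolerance = 0.02)
})

test_that("trajectories conserve moieties and stay non-negative", {
  for (seed in c(1, 4)) {
    fx <- generate_fixture("random_small_network", seed = seed)
    net <- fx$network
    laws <- conserved_moieties(net)
    tc <- simulate_network(net, seq(0, 50, 5))
    y0 <- initial_state(net)
    for (w in laws) {
      v0 <- sum(w * y0[names(w)])
      along <- apply(unclass(tc)[, names(w), drop = FALSE], 1,
                     function(r) sum(w * r))
      if (abs(v0) > 1e-12)
        expect_lt(max(abs(along - v0)) / abs(v0), 1e-6)
    }
    expect_gte(min(unclass(tc)), -1e-11)
  }
})

test_that("clamped species stay fixed but keep driving reactions", {
  net <- reaction_network(
    list(species("E", 0.1, clamped = TRUE), species("S", 5), species("P", 0)),
    list(enzymatic_reaction("E", "S", "P", km = 1, kcat = 1)))
  tc <- simulate_network(net, seq(0, 20, 2))
  expect_true(all(trajectory(tc, "E") == 0.1))
  expect_gt(trajectory(tc, "P")[10], 0.5)
})

test_that("network validation rejects structural errors", {
  expect_error(reaction_network(
    list(species("A", 1), species("B", 1)),
    list(binding_reaction("A", "B", "AB", kf = 1, kb = 1))),
    "undeclared species")
  expect_error(species("A", -1), ">= 0")
  expect_error(binding_reaction("A", "A", "A", kf = 1, kb = 1))
  expect_error(
    reaction_network(
      list(species("A", 1), species("B", 1), species("AB", 0),
           species("A2", 1)),
      list(binding_reaction("A", "B", "AB", kf = 1, kb = 1),
           binding_reaction("A2", "B", "AB", kf = 1, kb = 1))),
    NA)  # sharing a complex between binding reactions is allowed
  expect_error(reaction_network(
    list(species("E", 1), species("S", 1), species("P", 0), species("X", 1),
         species("C", 0)),
    list(enzymatic_reaction("E", "S", "P", km = 1, kcat = 1, complex = "C"),
         enzymatic_reaction("X", "S", "P", km = 1, kcat = 1, complex = "C"))),
    "ES complex")
})
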