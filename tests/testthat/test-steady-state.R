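ss_fix <- local({
  net <- build_network()
  list(net = net, sub = feedback_subsystem(net))
})

test_that("Newton refinement lands on the closed-form toy equilibrium", {
  fx <- generate_fixture("binding_equilibrium", seed = 5)
  net <- fx$network
  out <- spinesim:::.newton_core(net, initial_state(net))
  expect_lt(out$residual, 1e-11)
  ref <- fx$reference$equilibrium
  expect_equal(unname(out$y[names(ref)]), unname(ref), tolerance = 1e-6)
  cls <- classify_stability(net, out$y)
  expect_identical(cls$stability, "stable")
})

test_that("subsystem extraction keeps only interior reactions", {
  net <- ss_fix$net
  sub <- ss_fix$sub
  nm <- vapply(sub$reactions, `[[`, "", "name")
  expect_true("PKAc: PP2A->PP2Ap" %in% nm)
  expect_true("Cdk5act: D000->D75" %in% nm)
  expect_true("D75+PKAc<->D75PKAc" %in% nm)
  expect_false(any(grepl("AMPAR", nm)))
  # retaining everything reproduces the full reaction set
  idty <- extract_subsystem(net, net$species$name)
  expect_identical(length(idty$reactions), length(net$reactions))
  # conservation of the subsystem's DARPP-32 content
  law <- protein_moiety(sub, "D000")
  expect_true(all(c("D000", "D75", "D75PKAc") %in% names(law)))
})

test_that("the feedback subsystem is bistable at intermediate cAMP", {
  sub <- ss_fix$sub
  ss <- find_steady_states(sub)
  st <- vapply(ss, function(s) s$stability, "")
  expect_identical(sum(st == "stable"), 2L)
  expect_identical(sum(st == "unstable"), 1L)
  # fold ordering in the active-PKA coordinate: stable < unstable < stable
  pk <- vapply(ss, function(s) s$y[["PKAc"]], 0)
  expect_identical(st[order(pk)], c("stable", "unstable", "stable"))
  expect_true(all(vapply(ss, function(s) s$residual, 0) < 1e-10))
  # monostable outside the window
  for (camp in c(0.05, 8)) {
    s2 <- find_steady_states(sub, params = c(cAMP = camp))
    expect_identical(sum(vapply(s2, function(s) s$stability, "") ==
                           "stable"), 1L)
  }
})

test_that("stability labels agree with perturbation integration", {
  sub <- ss_fix$sub
  ss <- find_steady_states(sub)
  for (s in ss) {
    # perturb within the stoichiometric class: exchange mass between two
    # members of the DARPP-32 moiety
    d <- 0.02 * max(s$y[["D75"]], 0.05)
    y0 <- s$y
    y0["D75"] <- y0["D75"] + d
    y0["D000"] <- max(y0["D000"] - d, 0)
    tc <- simulate_network(sub, c(0, 2500), y0 = y0)
    yT <- unclass(tc)[2, ]
    names(yT) <- sub$species$name
    dist0 <- abs(y0[["D75"]] - s$y[["D75"]])
    distT <- abs(yT[["D75"]] - s$y[["D75"]])
    if (s$stability == "stable") expect_lt(distT, 0.5 * dist0)
    else expect_gt(distT, 2 * dist0)
  }
})

test_that("quasi-static cAMP sweep shows a hysteresis loop", {
  sub <- ss_fix$sub
  vals <- exp(seq(log(0.05), log(40), length.out = 8))
  hy <- hysteresis_sweep(sub, "cAMP", vals, t_settle = 1200)
  up <- hy[hy$direction == "up", ]
  dn <- hy[hy$direction == "down", ]
  dn <- dn[match(up$value, dn$value), ]
  gap <- abs(up$PKAc - dn$PKAc) / pmax(up$PKAc, dn$PKAc)
  # branches disagree over a nonempty middle interval and agree outside
  expect_gt(sum(gap > 0.3), 0)
  expect_lt(gap[1], 0.05)
  expect_lt(gap[length(gap)], 0.05)
  # the up-branch jumps at a higher parameter value than the down-branch
  jump_up <- up$value[min(which(up$PKAc > 0.5 * max(up$PKAc)))]
  jump_dn <- dn$value[min(which(dn$PKAc > 0.5 * max(dn$PKAc)))]
  expect_gt(jump_up, jump_dn)
  # sweeping a monostable toy gives identical branches
  toy <- generate_fixture("binding_equilibrium", seed = 2)$network
  toy <- set_clamp(toy, "A", 1)
  hy2 <- hysteresis_sweep(toy, "A", c(0.5, 1, 2), readout = "AB",
                          t_settle = 100)
  u2 <- hy2[hy2$direction == "up", ]; d2 <- hy2[hy2$direction == "down", ]
  d2 <- d2[match(u2$value, d2$value), ]
  expect_equal(u2$AB, d2$AB, tolerance = 1e-6)
})

test_that("cAMP activation threshold is non-decreasing in Cdk5", {
  net <- ss_fix$net
  camps <- c(0.2, 0.5, 1.2, 3, 7, 16)
  bf <- bifurcation_surface(feedback_subsystem(net), camps, c(2.5, 3.6, 5))
  # threshold = largest cAMP at which the low sheet (a stable state well
  # below the global high level) still exists
  thr <- vapply(seq_along(bf$cdk5_values), function(j) {
    low_exists <- !is.na(bf$low[, j]) &
      bf$low[, j] < 0.5 * max(bf$high, na.rm = TRUE)
    if (!any(low_exists)) bf$camp_values[1] else
      max(bf$camp_values[low_exists])
  }, 0)
  expect_true(all(diff(thr) >= 0))
})

test_that("threshold behaviour survives ten-fold loop-parameter changes", {
  sub <- ss_fix$sub
  grid <- exp(seq(log(0.3), log(15), length.out = 7))
  vars <- default_variations()
  vars <- vars[vars$fold %in% c(10, 1, 0.1), ]   # desk-scale subset
  rs <- robustness_scan(sub, grid, variations = vars, t_settle = 300)
  expect_true(all(!is.na(rs$threshold)))
  # the control rows of all three families agree
  ctrl <- rs$threshold[rs$fold == 1]
  expect_equal(max(ctrl) / min(ctrl), 1, tolerance = 1e-6)
  # dissociation-constant family: threshold shifts monotonically with fold
  kd <- rs[rs$target == "b.d75_pka", ]
  kd <- kd[order(kd$fold), ]
  expect_true(!is.unsorted(kd$threshold))
})

test_that("rate scaling edits exactly the targeted constants", {
  net <- ss_fix$net
  sc <- scale_rate(net, "e.pka_pp2a", kcat = 2)
  get_r <- function(n, lab) Filter(function(r) identical(r$group, lab),
                                   n$reactions)[[1]]
  expect_equal(get_r(sc, "e.pka_pp2a")$kcat,
               2 * get_r(net, "e.pka_pp2a")$kcat)
  expect_equal(get_r(sc, "e.pp2ap_t75")$kcat,
               get_r(net, "e.pp2ap_t75")$kcat)
  expect_error(scale_rate(net, "no.such.group"), "no reaction matches")
})
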