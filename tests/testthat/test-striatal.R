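nets <- local({
  net <- build_network()
  list(net = net)
})

test_that("model tables load, validate, and reject malformed input", {
  tab <- load_tables()
  expect_s3_class(tab, "model_tables")
  expect_equal(nrow(tab$enzymatic) + nrow(tab$binding), 72)
  bad <- tempfile(fileext = ".csv")
  writeLines("species,conc", bad)
  expect_error(load_tables(concentrations = bad), "empty table")
  writeLines(c("enzyme,substrate,product,km,kcat",
               "Ghost,AMPAR,AMPARp845,1,1"), bad)
  expect_error(load_tables(enzymatic = bad), "Ghost")
  dup <- tempfile(fileext = ".csv")
  s1 <- read.csv(spinesim_table("initial_concentrations.csv"))
  write.csv(rbind(s1, s1[1, ]), dup, row.names = FALSE)
  expect_error(load_tables(concentrations = dup), "duplicate species")
})

test_that("assembled network has the documented structure", {
  net <- nets$net
  counts <- network_counts(net)
  expect_identical(counts$n_reactions, 72L)
  expect_identical(counts$n_parameters, 132L)
  # 8 free phospho-states of DARPP-32
  expect_length(net$proteins$DARPP32, 8L)
  expect_true(all(net$proteins$DARPP32 %in% net$species$name))
  # membrane pools as in the trafficking scheme
  expect_setequal(net$membrane_pool, c("AMPARm", "AMPARp845m", "AMPARppm"))
  # literature / hand-tuned parameter bookkeeping
  prov <- parameter_provenance()
  expect_identical(unname(prov["literature"] + prov["tuned"]), 132L)
  expect_identical(unname(prov["literature"]), 83L)
})

test_that("every protein moiety is closed (no synthesis or degradation)", {
  net <- nets$net
  for (p in names(net$proteins)) {
    law <- protein_moiety(net, net$proteins[[p]])
    expect_gt(length(law), 0)
  }
  # the DARPP-32 law spans free states plus every complex carrying it
  law <- protein_moiety(net, net$proteins$DARPP32)
  expect_true(all(c("D75PKAc", "D34PP1") %in% names(law)))
  # and is found among the null-space conservation laws' span:
  drift <- max(abs(drop(law %*% net$S[names(law), , drop = FALSE])))
  expect_lt(drift, 1e-9)
})

test_that("conservation holds along a stimulated trajectory of the model", {
  net <- nets$net
  rest <- pre_equilibrate(net)
  cp <- calcium_protocol(ca_amp = 1, n_repeats = 2)
  tc <- run_experiment(net, cp, NULL, y0 = rest, t_end = 30, dt = 2)
  for (p in c("DARPP32", "AMPAR", "PP2A", "CaM")) {
    law <- protein_moiety(net, net$proteins[[p]])
    v <- apply(unclass(tc)[, names(law), drop = FALSE], 1,
               function(r) sum(law * r))
    expect_lt(max(abs(v - v[1])) / v[1], 1e-6)
  }
})

test_that("knockout zeroes the protein and removes its influence", {
  net <- nets$net
  ko <- knockout(net, "DARPP32")
  law <- protein_moiety(net, net$proteins$DARPP32)
  i <- match(names(law), ko$species$name)
  expect_true(all(ko$species$clamped[i]))
  expect_true(all(ko$species$clamp_value[i] == 0))
  expect_error(knockout(net, "NotAProtein"), "unknown protein")
  # knocking out a protein with zero initial total changes nothing
  net0 <- set_initial(net, c(I1 = 0))
  ko0 <- knockout(net0, "I1")
  y <- initial_state(net0)
  f0 <- assemble_rhs(net0)(0, y, NULL)[[1]]
  f1 <- assemble_rhs(ko0)(0, initial_state(ko0), NULL)[[1]]
  keep <- setdiff(seq_along(y), match(names(protein_moiety(net0, "I1")),
                                      net0$species$name))
  expect_equal(f0[keep], f1[keep], tolerance = 1e-12)
})

test_that("pathway ablation removes exactly the listed reactions", {
  net <- nets$net
  ab <- ablate_pathway(net, "ck1_cdk5")
  expect_identical(length(ab$reactions), length(net$reactions) - 1L)
  expect_false("CK1: Cdk5->Cdk5act" %in%
                 vapply(ab$reactions, `[[`, "", "name"))
  expect_error(ablate_pathway(net, "no_such_pathway"), "unknown pathway")
  expect_identical(length(ablate_pathway(net, character(0))$reactions),
                   length(net$reactions))
})
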