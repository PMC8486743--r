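test_that("reaction-table loading builds the right network and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# species",
               "A\t1\t0", "B\t1\t0", "C\t0\t0",
               "# reactions",
               "r1\tA + B -> C\t1.0\t."), path)
  net <- load_crn(path)
  expect_equal(nrow(net$species), 3L)
  expect_length(net$reactions, 1L)
  expect_equal(unname(net$S[, "r1"]), c(-1, -1, 1))

  writeLines(c("# species", "A\t1\t0", "# reactions",
               "r1\tA -> D\t1\t."), path)
  expect_error(load_crn(path), "unknown species",
               class = "crnsim_validation_error")
  writeLines(c("# species", "A\t1\t0", "# reactions",
               "r1\tA -> 0\tnot_a_number\t."), path)
  expect_error(load_crn(path), class = "crnsim_parse_error")
  expect_error(load_crn(tempfile()), class = "crnsim_parse_error")
})

test_that("stoichiometric matrix columns are net production counts", {
  fx <- unit_binding()
  S <- stoichiometric_matrix(fx$crn)
  expect_equal(unname(S[, "bind"]), c(-1, -1, 1))
  expect_equal(unname(S[, "unbind"]), c(1, 1, -1))
  iso <- isomerization()
  expect_equal(unname(stoichiometric_matrix(iso)), cbind(c(-1, 1), c(1, -1)))
  dimer <- crn(data.frame(id = c("A", "B"), x0 = c(4, 0)),
               list(list(id = "dim", reactants = c(A = 2L),
                         products = c(B = 1L), k = 0.5)))
  expect_equal(unname(stoichiometric_matrix(dimer)[, 1]), c(-2, 1))
})

test_that("mass-action fluxes follow the power law and stay nonnegative", {
  fx <- unit_binding()
  net <- crn(fx$crn$species,
             list(list(id = "bind", reactants = c(A = 1L, B = 1L),
                       products = c(C = 1L), k = 1)))
  expect_equal(unname(mass_action_flux(net, c(2, 3, 0))), 6)
  dimer <- crn(data.frame(id = c("A", "B"), x0 = c(4, 0)),
               list(list(id = "dim", reactants = c(A = 2L),
                         products = c(B = 1L), k = 0.5)))
  expect_equal(unname(mass_action_flux(dimer, c(4, 0))), 8)  # 0.5 * 4^2
  expect_equal(unname(mass_action_flux(net, c(0, 3, 0))), 0)
  expect_error(mass_action_flux(net, c(-1, 3, 0)), "negative")
  # property: fluxes nonnegative for random states
  for (s in 1:20) {
    set.seed(s)
    x <- stats::runif(3, 0, 10)
    expect_true(all(mass_action_flux(fx$crn, x) >= 0))
  }
})

test_that("the ODE right-hand side is S v and vanishes on constant pools", {
  fx <- unit_binding()
  expect_equal(unname(crn_rhs(fx$crn, c(1, 1, 0))), c(-1, -1, 1))
  expect_lt(max(abs(crn_rhs(fx$crn, fx$x_eq_expected))), 1e-12)
  gen <- generator_fed()
  dx <- crn_rhs(gen, c(2, 0))
  expect_identical(dx[["G"]], 0)     # exactly zero, not just small
  expect_gt(dx[["P"]], 0)
})

test_that("rhs is consistent with finite differences of the trajectory", {
  fx <- unit_binding()
  h <- 1e-4
  tr <- trajectory(fx$crn, t_grid = c(0.5 - h, 0.5, 0.5 + h))
  fd <- (tr$X[, 3] - tr$X[, 1]) / (2 * h)
  an <- crn_rhs(fx$crn, tr$X[, 2])
  expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-4)
})

test_that("the reaction-table writer round-trips S and k bit-exactly", {
  for (fx in list(unit_binding(), phospho_cycle(),
                  random_crn(3, 2, seed = 11))) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_reaction_table(fx$crn, path)
    back <- read_reaction_table(path)
    expect_identical(back$S, fx$crn$S)
    expect_identical(back$k, fx$crn$k)
    expect_identical(back$species$x0, fx$crn$species$x0)
  }
})

test_that("SBML models load with reversible splitting and pool flags", {
  path <- withr::local_tempfile(fileext = ".xml")
  synthetic_sbml(path)
  net <- load_crn(path)
  expect_equal(nrow(net$species), 4L)
  expect_length(net$reactions, 3L)   # reversible pair + irreversible feed
  expect_equal(net$k[["bindAB"]], 1.5)
  expect_equal(net$k[["bindAB_rev"]], 0.25)
  expect_identical(net$reactions[[1]]$reverse_of, "bindAB_rev")
  expect_identical(net$reactions[[2]]$reverse_of, "bindAB")
  expect_true(net$species$constant[net$species$id == "G"])
  expect_true(all(net$S["G", ] == 0))

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml", bad)
  expect_error(load_crn(bad), class = "crnsim_parse_error")
})

test_that("constant pools and pseudo synthesis reactions give the same dynamics", {
  gen <- generator_fed(g0 = 2, k_syn = 0.5, k_deg = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(gen, path)
  alt <- load_crn(path, pools_as_synthesis = TRUE)
  expect_false("G" %in% alt$species$id)
  expect_equal(alt$k[["syn"]], 0.5 * 2)   # pool folded into the constant
  eq1 <- find_equilibrium(gen)
  eq2 <- find_equilibrium(alt)
  expect_equal(eq1$x_eq[["P"]], eq2$x_eq[["P"]], tolerance = 1e-8)
  expect_equal(eq1$x_eq[["P"]], 10, tolerance = 1e-6)  # k_syn g0 / k_deg
})
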