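test_that("LoF projects the supports of the containing laws", {
  fx <- unit_binding()
  laws <- conservation_laws(fx$crn)
  # complete loss of A empties the A + C law
  x1 <- apply_lof(fx$crn, spec = lof("A"), laws = laws)
  expect_equal(unname(x1), c(0, 1, 0))
  # partial degree scales the support, leaves the rest untouched
  x2 <- apply_lof(fx$crn, c(A = 0.6, B = 0.9, C = 0.4), lof("A", 0.5),
                  laws = laws)
  expect_equal(unname(x2), c(0.3, 0.9, 0.2))
})

test_that("LoF of a synthesis-fed protein scales its generator pool", {
  gen <- generator_fed(g0 = 2, k_syn = 0.5, k_deg = 0.1)
  laws <- conservation_laws(gen)
  expect_error(apply_lof(gen, spec = lof("P"), laws = laws), "generator")
  x1 <- apply_lof(gen, spec = lof("P", generator = "G"), laws = laws)
  expect_equal(x1[["G"]], 0)
  eq <- find_equilibrium(gen, x1)
  expect_lt(eq$x_eq[["P"]], 1e-9)      # production stopped, P decays away
  x2 <- apply_lof(gen, spec = lof("P", 0.5, generator = "G"), laws = laws)
  expect_equal(x2[["G"]], 1)
  expect_error(apply_lof(gen, spec = lof("P", generator = "Q"), laws = laws),
               "not in network")
})

test_that("complete LoF keeps the emptied moiety at zero after equilibration", {
  pc <- phospho_cycle()
  laws <- conservation_laws(pc$crn)
  x0 <- apply_lof(pc$crn, spec = lof("S1"), laws = laws)
  eq <- find_equilibrium(pc$crn, x0, laws = laws)
  support <- c("S1", "pS1", "S1_K0", "pS1_P1")
  expect_lt(max(eq$x_eq[support]), 1e-9)
  # species outside the law keep their pools
  expect_gt(eq$x_eq[["K0"]], 0.9)
})

test_that("GoF scales or removes deactivation reactions and preserves the laws", {
  pc <- phospho_cycle()
  half <- apply_gof(pc$crn, gof("S1", pc$gof_reactions, degree = 0.5))
  expect_equal(unname(half$k[pc$gof_reactions]),
               unname(pc$crn$k[pc$gof_reactions]) / 2)
  expect_identical(half$S, pc$crn$S)

  full <- apply_gof(pc$crn, gof("S1", pc$gof_reactions))
  expect_true(all(full$S[, pc$gof_reactions] == 0))
  expect_true(all(full$k[pc$gof_reactions] == 0))
  # exact left-null row spaces before and after are equal
  B0 <- law_matrix(conservation_laws(pc$crn))
  B1 <- law_matrix(conservation_laws(full))
  expect_true(crnsim:::rat_rowspace_equal(B0, B1))
  # locked-active: all substrate ends up phosphorylated or in complexes
  eq <- find_equilibrium(full)
  expect_lt(eq$x_eq[["S1"]], 1e-6)
  expect_gt(eq$x_eq[["pS1"]], 9)
  expect_error(apply_gof(pc$crn, gof("S1", "nope")), "unknown reactions")
})

test_that("removals that change the conservation structure are hard errors", {
  fx <- unit_binding()
  expect_error(apply_gof(fx$crn, gof("A", c("bind", "unbind"))),
               "conservation-law structure")
  chain <- crn(data.frame(id = c("A", "B"), x0 = c(1, 0)),
               list(list(id = "conv", reactants = c(A = 1L),
                         products = c(B = 1L), k = 1)))
  expect_error(apply_gof(chain, gof("A", "conv")),
               "conservation-law structure")
  # removing one direction of the pair is fine
  expect_silent(apply_gof(fx$crn, gof("A", "unbind")))
})

test_that("mutation batches compose order-invariantly and reject conflicts", {
  cs <- cascade()
  id <- apply_mutations(cs$crn, specs = list())
  expect_identical(id$crn$k, cs$crn$k)
  expect_identical(id$x0, cs$x0)

  specs <- list(gof("S1", cs$gof_reactions(1)), lof("P2"), lof("S3", 0.5))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ref <- apply_mutations(cs$crn, specs = specs)
  for (p in perms[-1]) {
    alt <- apply_mutations(cs$crn, specs = specs[p])
    expect_identical(alt$crn$k, ref$crn$k)
    expect_identical(alt$crn$S, ref$crn$S)
    expect_identical(alt$x0, ref$x0)
  }
  expect_error(
    apply_mutations(cs$crn,
                    specs = list(lof("S1"), gof("S1", cs$gof_reactions(1)))),
    "conflicting")
})

test_that("a drug is dosed from the target moiety's conserved total", {
  fx <- toy_binding(a0 = 50, b0 = 20)   # law A + C has total 50
  laws <- conservation_laws(fx$crn)
  d <- drug_spec("A", alpha = 0.75)
  out <- add_drug(fx$crn, spec = d, laws = laws)
  expect_equal(out$dose, 37.5)
  expect_equal(out$x0[["Drug"]], 37.5)
  expect_equal(out$x0[["A_Drug"]], 0)
  # exactly one new conservation law: Drug + complex
  laws2 <- conservation_laws(out$crn)
  expect_length(laws2, length(laws) + 1L)
  supports <- lapply(laws2, `[[`, "support")
  expect_true(any(vapply(supports, function(s)
    setequal(s, c("Drug", "A_Drug")), logical(1))))
  # drug total is conserved along trajectories
  c0 <- conservation_totals(laws2, out$x0)
  tr <- trajectory(out$crn, out$x0, t_grid = c(0, 1, 10, 100))
  drift <- apply(tr$X, 2L, function(x) class_distance(laws2, x, c0))
  expect_lt(max(drift), 1e-6)
  # absolute dosing bypasses the law lookup
  out2 <- add_drug(fx$crn, spec = drug_spec("A", dose = 5), laws = laws)
  expect_equal(out2$x0[["Drug"]], 5)
})

test_that("a zero dose leaves an equilibrium state at equilibrium", {
  fx <- unit_binding()
  eq <- find_equilibrium(fx$crn)
  out <- add_drug(fx$crn, eq$x_eq, drug_spec("A", alpha = 0))
  eq2 <- find_equilibrium(out$crn, out$x0)
  expect_lt(max(abs(eq2$x_eq[names(eq$x_eq)] - eq$x_eq)), 1e-7)
})

test_that("washout returns the system to the mutated equilibrium", {
  cs <- cascade()
  laws <- conservation_laws(cs$crn)
  m <- apply_mutations(cs$crn, specs = list(gof("S1", cs$gof_reactions(1))),
                       laws = laws)
  eq_mut <- find_equilibrium(m$crn, m$x0)
  d <- drug_spec("S2", alpha = 0.75)
  dr <- add_drug(m$crn, eq_mut$x_eq, d)
  eq_drug <- find_equilibrium(dr$crn, dr$x0)
  # the drug moved the system away from the mutated equilibrium
  expect_gt(max(abs(eq_drug$x_eq[names(eq_mut$x_eq)] - eq_mut$x_eq)), 0.1)
  post <- washout(dr$crn, d, k_deg = 0.01)
  eq_back <- find_equilibrium(post, eq_drug$x_eq)
  rel <- abs(eq_back$x_eq[names(eq_mut$x_eq)] - eq_mut$x_eq) /
    pmax(eq_mut$x_eq, 1e-6)
  expect_lt(max(rel), 1e-4)
  expect_lt(eq_back$x_eq[["Drug"]], 1e-8)
  expect_warning(washout(dr$crn, d, k_deg = 0), "persists")
  expect_error(washout(cs$crn, d), "not present")
})

test_that("perturbation configs read from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mutations:",
               "  - kind: GoF",
               "    protein: S1",
               "    degree: 1",
               "    reactions: [t1_phos_bind, t1_phos_cat]",
               "  - kind: LoF",
               "    protein: P2",
               "drugs:",
               "  - target: S2",
               "    alpha: 0.75"), yml)
  cfg <- read_perturbations(yml)
  expect_length(cfg$mutations, 2L)
  expect_identical(cfg$mutations[[1]]$kind, "GoF")
  expect_identical(cfg$mutations[[2]]$degree, 1)
  expect_equal(cfg$drugs[[1]]$k1f, 0.5)
  expect_equal(cfg$drugs[[1]]$k1r, 0.005)
  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"mutations": [{"kind": "LoF", "protein": "A", "degree": 0.5}]}',
             jsn)
  cfg2 <- read_perturbations(jsn)
  expect_equal(cfg2$mutations[[1]]$degree, 0.5)
  expect_length(cfg2$drugs, 0L)
})
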