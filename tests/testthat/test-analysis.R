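test_that("delta profiles quantify relative change with exact edge cases", {
  x <- c(a = 1, b = 2, c = 0.5)
  p0 <- delta_profile(x, x)
  expect_true(all(p0$delta == 0))
  expect_false(any(p0$significant))

  # a low-abundance species amplifies into a huge relative change
  p1 <- delta_profile(c(91.09), c(0.017))
  expect_equal(p1$delta, (91.09 - 0.017) / 0.017)
  expect_equal(p1$delta, 5.37e3, tolerance = 0.01)

  # complete shutdown is exactly -1
  p2 <- delta_profile(c(0, 1), c(2, 1))
  expect_identical(p2$delta[1], -1)

  # reference below the floor: undefined and flagged, never silently 0
  p3 <- delta_profile(c(1, 1), c(0, 1))
  expect_true(is.na(p3$delta[1]))
  expect_false(p3$defined[1])
  expect_false(p3$significant[1])
  expect_error(delta_profile(c(1), c(-1)), ">= 0")
})

test_that("affected fraction counts significant species and is monotone in the threshold", {
  x_ref <- c(rep(1, 8), 1e-15, 1)
  x_mut <- c(1.5, 1.02, 0.5, 1, 1, 1, 1, 1, 5, 0.96)
  p <- delta_profile(x_mut, x_ref)
  expect_equal(affected_fraction(p), 100 * 3 / 10)  # undefined not counted
  p_zero <- delta_profile(rep(1, 4), rep(1, 4))
  expect_equal(affected_fraction(p_zero), 0)
  thresholds <- c(0.001, 0.01, 0.03, 0.1, 0.5, 1)
  fr <- vapply(thresholds, function(th)
    affected_fraction(delta_profile(x_mut, x_ref, threshold = th)),
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("flux traces decompose the derivative, with reversible pairs summed", {
  fx <- unit_binding()
  tr <- trajectory(fx$crn, t_grid = seq(0, 5, by = 0.5))
  ft <- flux_traces(fx$crn, tr, "C")
  expect_length(ft, 1L)                       # bind/unbind summed
  expect_setequal(ft[[1]]$reactions, c("bind", "unbind"))
  a <- tr$X["A", ]; b <- tr$X["B", ]; cc <- tr$X["C", ]
  expect_equal(ft[[1]]$value, a * b - cc, tolerance = 1e-10)

  # decomposition identity on every fixture: traces sum to the rhs
  for (fxt in list(unit_binding(), phospho_cycle(), random_crn(3, 2, seed = 2))) {
    trj <- trajectory(fxt$crn, t_grid = c(0, 0.5, 2, 10))
    for (sp in fxt$crn$species$id[1:3]) {
      fts <- flux_traces(fxt$crn, trj, sp)
      if (length(fts) == 0L) next
      rhs <- apply(trj$X, 2L, function(x) crn_rhs(fxt$crn, x)[[sp]])
      expect_lt(max(abs(attr(fts, "total") - rhs)) /
                  max(1, max(abs(rhs))), 1e-6)
    }
  }

  # at a converged equilibrium the signed traces cancel
  eq <- find_equilibrium(fx$crn)
  tr_eq <- trajectory(fx$crn, eq$x_eq, t_grid = c(0, 1))
  ft_eq <- flux_traces(fx$crn, tr_eq, "C")
  expect_lt(max(abs(attr(ft_eq, "total"))), 1e-9)

  # a species with no incident reactions yields an empty decomposition
  gen <- generator_fed()
  trg <- trajectory(gen, t_grid = c(0, 1))
  expect_length(flux_traces(gen, trg, "G"), 0L)
  expect_error(flux_traces(gen, trg, "Z"), "unknown species")
})

test_that("the bi-symmetric log transform is odd, monotone and anchored at 0", {
  expect_identical(bisymlog(0), 0)
  v <- c(-1e4, -3, -0.01, 0.01, 3, 1e4)
  expect_equal(bisymlog(-v), -bisymlog(v))
  expect_true(all(diff(bisymlog(sort(stats::runif(50, -100, 100)))) > 0))
  expect_error(bisymlog(1, C = 0), "positive")
  expect_error(bisymlog(1, C = -2), "positive")
})

test_that("dose titration scores restoration and peaks at an interior alpha", {
  cs <- cascade()
  laws <- conservation_laws(cs$crn)
  eq_phys <- find_equilibrium(cs$crn, laws = laws)
  m <- apply_mutations(cs$crn, specs = list(gof("S1", cs$gof_reactions(1))),
                       laws = laws)
  eq_mut <- find_equilibrium(m$crn, m$x0)
  d <- drug_spec("S2")
  alphas <- seq(0.1, 0.9, by = 0.1)
  tt <- titrate(m$crn, eq_mut$x_eq, eq_phys$x_eq, d, alphas = alphas)
  expect_equal(tt$alpha, alphas)        # sorted by alpha
  best <- attr(tt, "best_alpha")
  expect_gt(best, min(alphas))
  expect_lt(best, max(alphas))
  expect_gt(max(tt$score), 0)
  # unimodal: nondecreasing up to the peak, nonincreasing after
  peak <- which.max(tt$score)
  expect_true(all(diff(tt$score[seq_len(peak)]) >= 0))
  expect_true(all(diff(tt$score[peak:length(tt$score)]) <= 0))
})

test_that("a zero dose reproduces the mutated-versus-physiological profile", {
  pc <- phospho_cycle()
  laws <- conservation_laws(pc$crn)
  eq_phys <- find_equilibrium(pc$crn, laws = laws)
  mut <- apply_gof(pc$crn, gof("S1", pc$gof_reactions))
  eq_mut <- find_equilibrium(mut)
  tt <- titrate(mut, eq_mut$x_eq, eq_phys$x_eq, drug_spec("pS1"),
                alphas = c(0, 0.5))
  prof0 <- attr(tt, "profiles")[["0"]]
  direct <- delta_profile(eq_mut$x_eq, eq_phys$x_eq)
  expect_equal(prof0$delta, direct$delta)
})

test_that("delta and flux reports export as CSV", {
  p <- delta_profile(c(A = 2, B = 1), c(A = 1, B = 1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_delta_csv(p, f1)
  back <- utils::read.csv(f1)
  expect_equal(back$delta, c(1, 0))
  fx <- unit_binding()
  tr <- trajectory(fx$crn, t_grid = c(0, 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(flux_traces(fx$crn, tr, "C"), f2)
  back2 <- utils::read.csv(f2)
  expect_equal(nrow(back2), 2L)
  expect_identical(unique(back2$reactions), "bind+unbind")
})
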