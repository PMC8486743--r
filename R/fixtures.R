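# Programmatically generated toy networks with known conservation laws and
# (where possible) closed-form equilibria; every other module is testable
# against them without any external model file.

new_fixture <- function(crn, laws_expected, x_eq_expected = NULL,
                        provenance = "", extra = list()) {
  b <- c(list(crn = crn, x0 = initial_state(crn),
              laws_expected = laws_expected,
              x_eq_expected = x_eq_expected,
              provenance = provenance), extra)
  class(b) <- "crn_fixture"
  b
}

#' @export
print.crn_fixture <- function(x, ...) {
  print(x$crn)
  cat("Fixture: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Reversible binding toy network
#'
#' `A + B <-> C` with binding constant `kf` ((nM s)^-1) and unbinding
#' constant `kr` (s^-1).  Its two moiety laws are `A + C` and `B + C` with
#' totals `c1 = a0`, `c2 = b0`, and the equilibrium complex concentration
#' is the closed-form root of `kf (c1 - x)(c2 - x) = kr x` in
#' `[0, min(c1, c2)]`; for unit constants and unit totals this is
#' `(3 - sqrt(5)) / 2`.
#'
#' @param kf,kr rate constants (> 0).
#' @param a0,b0 initial free concentrations (nM, >= 0); the complex starts
#'   at 0.
#' @return a `crn_fixture` with fields `crn`, `x0`, `laws_expected`,
#'   `x_eq_expected`, `provenance`.
#' @export
toy_binding <- function(kf = 1, kr = 1, a0 = 1, b0 = 1) {
  stopifnot(kf > 0, kr > 0, a0 >= 0, b0 >= 0)
  net <- crn(
    species = data.frame(id = c("A", "B", "C"), x0 = c(a0, b0, 0)),
    reactions = list(
      list(id = "bind", reactants = c(A = 1L, B = 1L), products = c(C = 1L),
           k = kf, reverse_of = "unbind"),
      list(id = "unbind", reactants = c(C = 1L), products = c(A = 1L, B = 1L),
           k = kr, reverse_of = "bind")))
  c1 <- a0; c2 <- b0
  # kf x^2 - (kf (c1 + c2) + kr) x + kf c1 c2 = 0, smaller root
  bq <- kf * (c1 + c2) + kr
  xC <- (bq - sqrt(bq^2 - 4 * kf^2 * c1 * c2)) / (2 * kf)
  x_eq <- c(A = c1 - xC, B = c2 - xC, C = xC)
  laws <- list(c(A = 1, B = 0, C = 1), c(A = 0, B = 1, C = 1))
  new_fixture(net, laws, x_eq,
              "A+B<->C; equilibrium from the quadratic kf(c1-x)(c2-x)=kr*x")
}

# One enzymatic phosphorylation-dephosphorylation tier; shared builder for
# phospho_cycle() and cascade().  `kin` may be an existing species id.
add_tier <- function(species, reactions, tier, kin, kf, kr, kcat,
                     s_tot, p_tot, kin_tot = NULL) {
  s <- paste0("S", tier); ps <- paste0("pS", tier)
  ph <- paste0("P", tier)
  ck <- paste0(s, "_", kin); cp <- paste0(ps, "_", ph)
  species <- rbind(species, data.frame(
    id = c(s, ps, ck, ph, cp),
    x0 = c(s_tot, 0, 0, p_tot, 0),
    constant = FALSE))
  if (!is.null(kin_tot))
    species <- rbind(species,
                     data.frame(id = kin, x0 = kin_tot, constant = FALSE))
  pre <- paste0("t", tier, "_")
  reactions <- c(reactions, list(
    list(id = paste0(pre, "kin_bind"),
         reactants = stats::setNames(c(1L, 1L), c(s, kin)),
         products = stats::setNames(1L, ck),
         k = kf, reverse_of = paste0(pre, "kin_unbind")),
    list(id = paste0(pre, "kin_unbind"),
         reactants = stats::setNames(1L, ck),
         products = stats::setNames(c(1L, 1L), c(s, kin)),
         k = kr, reverse_of = paste0(pre, "kin_bind")),
    list(id = paste0(pre, "kin_cat"),
         reactants = stats::setNames(1L, ck),
         products = stats::setNames(c(1L, 1L), c(ps, kin)),
         k = kcat, reverse_of = NA_character_),
    list(id = paste0(pre, "phos_bind"),
         reactants = stats::setNames(c(1L, 1L), c(ps, ph)),
         products = stats::setNames(1L, cp),
         k = kf, reverse_of = paste0(pre, "phos_unbind")),
    list(id = paste0(pre, "phos_unbind"),
         reactants = stats::setNames(1L, cp),
         products = stats::setNames(c(1L, 1L), c(ps, ph)),
         k = kr, reverse_of = paste0(pre, "phos_bind")),
    list(id = paste0(pre, "phos_cat"),
         reactants = stats::setNames(1L, cp),
         products = stats::setNames(c(1L, 1L), c(s, ph)),
         k = kcat, reverse_of = NA_character_)))
  list(species = species, reactions = reactions)
}

#' Phosphorylation-dephosphorylation cycle fixture
#'
#' One substrate cycled by a kinase and a phosphatase through
#' enzyme-substrate complexes, mirroring the canonical deactivation scheme
#' `pS + P <-> pS_P -> S + P`: species `S1`, `pS1`, kinase `K0`,
#' phosphatase `P1` and the two complexes.  Moiety laws: the substrate
#' pool, the kinase pool and the phosphatase pool.  A gain-of-function of
#' the substrate removes the forward reactions `t1_phos_bind` and
#' `t1_phos_cat` (returned in field `gof_reactions`).
#'
#' @param kf binding constant for both enzymes, (nM s)^-1.
#' @param kr unbinding constant, s^-1.
#' @param kcat catalytic constant, s^-1.
#' @param totals named vector with entries `S` (substrate), `K` (kinase)
#'   and `P` (phosphatase) total concentrations (nM).
#' @return a `crn_fixture`; no closed-form equilibrium is attached.
#' @export
phospho_cycle <- function(kf = 1, kr = 0.1, kcat = 1,
                          totals = c(S = 10, K = 1, P = 5)) {
  stopifnot(kf > 0, kr > 0, kcat > 0, all(totals >= 0))
  built <- add_tier(data.frame(id = character(0), x0 = numeric(0),
                               constant = logical(0)),
                    list(), tier = 1L, kin = "K0",
                    kf = kf, kr = kr, kcat = kcat,
                    s_tot = totals[["S"]], p_tot = totals[["P"]],
                    kin_tot = totals[["K"]])
  net <- crn(built$species, built$reactions)
  ids <- net$species$id
  law <- function(members) {
    g <- stats::setNames(rep(0, length(ids)), ids)
    g[members] <- 1
    g
  }
  laws <- list(law(c("S1", "pS1", "S1_K0", "pS1_P1")),
               law(c("K0", "S1_K0")),
               law(c("P1", "pS1_P1")))
  new_fixture(net, laws, NULL,
              "kinase/phosphatase futile cycle with explicit complexes",
              extra = list(gof_reactions = c("t1_phos_bind", "t1_phos_cat")))
}

#' Kinase cascade fixture
#'
#' `n_tiers` chained phosphorylation cycles in which tier t's
#' phosphorylated substrate is the kinase of tier t+1 (the
#' Ras-Raf-MEK-ERK shape at `n_tiers = 4`); a constitutively active root
#' kinase `K0` drives tier 1 and each tier has its own phosphatase.
#' Moiety laws: one per substrate (including its downstream kinase
#' complex), one per phosphatase, and one for `K0` -- `2 n_tiers + 1` in
#' total.  Field `gof_reactions(t)` lists the dephosphorylation forwards
#' of tier t, the removal set for that tier's gain of function.
#'
#' @param n_tiers number of tiers, >= 2.
#' @param kf,kr,kcat enzyme kinetics shared by all tiers ((nM s)^-1, s^-1,
#'   s^-1).
#' @param substrate_total,phosphatase_total per-tier totals (nM).
#' @param k0_total concentration of the root kinase (nM); kept small so
#'   the cascade amplifies.
#' @return a `crn_fixture`.
#' @export
cascade <- function(n_tiers = 4, kf = 1, kr = 0.1, kcat = 1,
                    substrate_total = 10, phosphatase_total = 5,
                    k0_total = 1) {
  stopifnot(n_tiers >= 2)
  species <- data.frame(id = character(0), x0 = numeric(0),
                        constant = logical(0))
  reactions <- list()
  for (t in seq_len(n_tiers)) {
    kin <- if (t == 1L) "K0" else paste0("pS", t - 1L)
    built <- add_tier(species, reactions, tier = t, kin = kin,
                      kf = kf, kr = kr, kcat = kcat,
                      s_tot = substrate_total, p_tot = phosphatase_total,
                      kin_tot = if (t == 1L) k0_total else NULL)
    species <- built$species
    reactions <- built$reactions
  }
  net <- crn(species, reactions)
  ids <- net$species$id
  law <- function(members) {
    g <- stats::setNames(rep(0, length(ids)), ids)
    g[members] <- 1
    g
  }
  laws <- list(law(c("K0", "S1_K0")))
  for (t in seq_len(n_tiers)) {
    members <- c(paste0("S", t), paste0("pS", t),
                 paste0("S", t, "_", if (t == 1L) "K0" else paste0("pS", t - 1L)),
                 paste0("pS", t, "_P", t))
    if (t < n_tiers)
      members <- c(members, paste0("S", t + 1L, "_pS", t))
    laws <- c(laws, list(law(members)))
    laws <- c(laws, list(law(c(paste0("P", t), paste0("pS", t, "_P", t)))))
  }
  new_fixture(net, laws, NULL,
              paste0(n_tiers, "-tier kinase cascade driven by K0"),
              extra = list(
                gof_reactions = function(t)
                  paste0("t", t, c("_phos_bind", "_phos_cat"))))
}

#' Reproducible random network with prescribed conservation laws
#'
#' Composes motifs whose moiety structure is known by construction: each
#' moiety i contributes an inactive/active pair `X_i <-> aX_i`, and random
#' pairs of active forms are joined by reversible binding
#' `aX_i + aX_j <-> C_i_j`.  The prescribed law for moiety i puts
#' coefficient 1 on `X_i`, `aX_i` and every complex containing i, so a
#' nontrivial left null space is guaranteed rather than hoped for.  Rate
#' constants and totals are drawn from the seeded RNG; the same seed gives
#' a bit-identical fixture.
#'
#' @param n_moieties number of moieties (>= 1).
#' @param reactions_per_moiety controls how many binding motifs are added
#'   (default 2).
#' @param seed RNG seed.
#' @return a `crn_fixture` with `laws_expected` = the prescribed laws.
#' @export
random_crn <- function(n_moieties, reactions_per_moiety = 2, seed = 1) {
  stopifnot(n_moieties >= 1, reactions_per_moiety >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- n_moieties
  species <- data.frame(id = c(paste0("X", seq_len(n)),
                               paste0("aX", seq_len(n))),
                        x0 = c(round(stats::runif(n, 5, 15), 3), rep(0, n)),
                        constant = FALSE)
  reactions <- list()
  rk <- function() signif(10 ^ stats::runif(1, -1, 1), 6)
  for (i in seq_len(n)) {
    reactions <- c(reactions, list(
      list(id = paste0("act", i),
           reactants = stats::setNames(1L, paste0("X", i)),
           products = stats::setNames(1L, paste0("aX", i)),
           k = rk(), reverse_of = paste0("deact", i)),
      list(id = paste0("deact", i),
           reactants = stats::setNames(1L, paste0("aX", i)),
           products = stats::setNames(1L, paste0("X", i)),
           k = rk(), reverse_of = paste0("act", i))))
  }
  complexes <- character(0)
  members <- lapply(seq_len(n), function(i)
    c(paste0("X", i), paste0("aX", i)))
  if (n >= 2) {
    all_pairs <- utils::combn(n, 2)
    n_pairs <- min(ncol(all_pairs),
                   max(1L, round(reactions_per_moiety * n / 2)))
    pick <- sample.int(ncol(all_pairs), n_pairs)
    for (p in pick) {
      i <- all_pairs[1L, p]; j <- all_pairs[2L, p]
      cx <- paste0("C", i, "_", j)
      complexes <- c(complexes, cx)
      species <- rbind(species, data.frame(id = cx, x0 = 0, constant = FALSE))
      reactions <- c(reactions, list(
        list(id = paste0("bind", i, "_", j),
             reactants = stats::setNames(c(1L, 1L),
                                         c(paste0("aX", i), paste0("aX", j))),
             products = stats::setNames(1L, cx),
             k = rk(), reverse_of = paste0("unbind", i, "_", j)),
        list(id = paste0("unbind", i, "_", j),
             reactants = stats::setNames(1L, cx),
             products = stats::setNames(c(1L, 1L),
                                        c(paste0("aX", i), paste0("aX", j))),
             k = rk(), reverse_of = paste0("bind", i, "_", j))))
      members[[i]] <- c(members[[i]], cx)
      members[[j]] <- c(members[[j]], cx)
    }
  }
  net <- crn(species, reactions)
  ids <- net$species$id
  laws <- lapply(members, function(m) {
    g <- stats::setNames(rep(0, length(ids)), ids)
    g[m] <- 1
    g
  })
  new_fixture(net, laws, NULL,
              sprintf("random motif composition (%d moieties, seed %d)",
                      n, seed))
}
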