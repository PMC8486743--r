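---
title: "Simulating mutations and targeted drugs in mass-action signalling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mutations and targeted drugs in mass-action signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnsim)
```

# The model

A signalling network is a set of `n` well-mixed species with
concentrations `x` (nM) coupled by `r` irreversible mass-action reactions,

$$\dot{x} = S\,v(x, k), \qquad
  v_j = k_j \prod_i x_i^{\,r_{ij}},$$

with `S` the integer stoichiometric matrix and `k` the rate constants
(s⁻¹ for first-order, (nM·s)⁻¹ for second-order steps; the package fixes
units to nM and seconds and offers no conversion layer).  Two structural
conventions matter throughout:

* **Reversible reactions are stored as two irreversible reactions** linked
  by a `reverse_of` field.  Each direction carries its own constant, which
  is what both the flux evaluation and gain-of-function removal need: a
  "remove the deactivation step" operation deletes individual columns of
  `S`, and that only makes sense when forward and reverse live in separate
  columns.
* **Constant generator pools** (species modelling an inexhaustible
  synthesis supply) are implemented by zeroing their row of `S`: they
  drive fluxes but never change.  The alternative convention — a pseudo
  reaction from the null complex with the pool folded into the rate
  constant — is exactly equivalent and exposed as the loader option
  `pools_as_synthesis = TRUE`; the zero-row form was preferred because it
  keeps the pool visible as a species one can scale in loss-of-function
  experiments.

# Conservation laws

Moiety conservation laws are nonnegative integer vectors
$\gamma \ne 0$ with $\gamma^{\mathsf T} S = 0$, so $\gamma^{\mathsf T}x(t)$
is constant and trajectories are confined to the stoichiometric
compatibility class $SC(c)$.  Their computation is deliberately exact:

1. the rank of `S` (and hence the null-space dimension `n − rank S`) is
   obtained by Gauss–Jordan elimination over the rationals, with
   numerators/denominators held as exact integers and reduced by gcd at
   every step — a floating-point rank decision could silently create or
   destroy a law;
2. nonnegative generators are built by the tableau (double-description)
   scheme: starting from `[I | S]`, each column of the `S`-part is
   processed by keeping rows with a zero entry and adding every positive
   pairwise combination of rows with opposite signs, pruning rows whose
   support strictly contains another's.  The surviving rows are the
   support-minimal nonnegative left-null vectors;
3. a reproducible generating subset of the right size is selected greedily
   (smallest support first, ties by species order), each generator reduced
   to gcd 1.

If the tableau blows up combinatorially or no nonnegative generating set
of full dimension exists, the signed rational basis is returned with a
warning and a `nonnegative = FALSE` flag — never a silent failure.
Constant pools would each contribute a trivial singleton law (their `S`
rows are zero); those are suppressed and reported separately, and
`uncovered_species()` consequently lists the non-constant species outside
every law — in practice the species that are degraded or exchange matter
with the environment.

# Equilibria

Stable states are computed by integrating the stiff system with `deSolve`
(`lsoda`, a variable-order stiff multistep family) at `rtol = 1e-8`,
`atol = 1e-12` nM.  "Asymptotic value" is made operational as: integrate
on geometrically growing horizons (1e5 s, then doubling) until both

* the scaled residual `‖S v(x,k)‖∞ / max(1, ‖x‖∞) ≤ 1e-9`, and
* the componentwise relative change between successive horizons `≤ 1e-8`,

capped at 1e9 s; a result that has not met both criteria is returned with
`converged = FALSE`.  Small negative undershoots from the integrator are
clipped to zero and accumulated; more than `n × 1e-9` nM of total clipping
triggers a warning.  Every result also carries the drift of the conserved
totals (`class_distance`), which on the test fixtures stays far below the
1e-6 bound the package's checks impose.  Uniqueness of the equilibrium
within a compatibility class is not a theorem the package relies on but a
property it verifies numerically on its fixtures (five random states per
class agreeing to 1e-6).

# Perturbations

**Loss of function.**  For a protein covered by conservation laws, every
species in the support of each containing law is multiplied by
`1 − degree`; at degree 1 this is the projection that zeroes the protein
and all its compounds, and because the network is unchanged the emptied
moiety can never refill (verified post-equilibration in the tests).  A
protein covered by several laws has all of them emptied, with a warning —
the biologically exercised cases involve single-law proteins, and emptying
a strict subset would leave the state outside any consistent class.  For
synthesis-fed proteins (no law), the generator pool's constant
concentration is scaled instead.  Partial degrees interpolate linearly on
totals; no other dose–response shape is offered.

**Gain of function.**  The deactivation reactions are explicit user input
(for a phosphoprotein: the forward phosphatase binding and the catalytic
step) — inferring "deactivation" from topology is ambiguous, so the
package refuses to guess.  Rate constants are scaled by `1 − degree`; at
degree 1 the `S` columns are zeroed and the package proves, via the exact
rank, that the left null space is unchanged.  Including a reverse partner
in the removal list is the classic mistake that does change the
conservation structure, and it is a hard error naming the reactions.

**Composition.**  `apply_mutations()` applies all GoF removals to the
network and all LoF projections to the state.  Specs are canonically
sorted before application, so permuted input lists give bit-identical
results (floating-point multiplication chains would otherwise differ in
the last ulp).  LoF supports are taken from the input network's laws,
which GoF removals provably preserve, so the two kinds commute by
construction.  A LoF and a GoF on the same protein is rejected as
contradictory.

**Drugs.**  A competitive inhibitor binds the free target only —
`target + Drug ⇌ complex`, defaults `k1f = 0.5 (nM s)⁻¹`,
`k1r = 0.005 s⁻¹` (binding fast relative to unbinding) — and is dosed as
`α` times the conserved total of the target's law, evaluated at the state
being drugged; an absolute dose is available as an alternative.  The
drugged network gains exactly one new law, `Drug + complex`.  Washout
zeroes the binding constant and adds `Drug → ∅` with rate `k_deg`
(default 0.01 s⁻¹); `k_deg = 0` leaves free drug in the system and is
flagged.

# Read-outs

The central index is the per-species relative difference
$\delta_i = (\tilde{x}_i^e - x_i^e)/x_i^e$ between perturbed and reference
equilibria; $|\delta_i| > 0.03$ marks a species as significantly affected,
and $\delta_i = -1$ (exact, by construction when $\tilde{x}^e_i = 0$)
means complete shutdown.  Reference concentrations below a floor of
1e-12 nM make δ undefined — flagged, never reported as zero — because the
ratio is numerically meaningless there; undefined entries count as not
significant in `affected_fraction()`.  For display across orders of
magnitude the bi-symmetric log transform
`sign(v)·log10(1 + |v|/C)` is provided, with `C = 1/ln 10` so the slope at
zero is one in base-10 units.

`flux_traces()` decomposes one species' derivative into signed per-reaction
contributions, with the two directions of a reversible pair summed into a
single net trace; the traces add up to the ODE right-hand side at every
sampled time, which the tests enforce to 1e-6.

`titrate()` sweeps dose fractions and scores each dose by the number of
species restored to within the significance threshold of the physiological
equilibrium (drug and complex excluded).  The score's *ranking* across
doses is the contract — it operationalises "which dose works best" — not
its absolute value, which depends on the threshold.

# Fixtures: what they emulate, what they do not

All tests run on networks generated in code:

* `toy_binding()` — `A + B ⇌ C`, closed-form equilibrium from a quadratic;
  anchors the solver against analytics.
* `phospho_cycle()` — substrate/kinase/phosphatase futile cycle with
  explicit complexes; the canonical deactivation motif that GoF removal
  targets.  Defaults (kf = 1 (nM s)⁻¹, kr = 0.1 s⁻¹, kcat = 1 s⁻¹, totals
  S:K:P = 10:1:5) put the physiological state in the responsive regime:
  phosphatase in excess, so deactivation removal produces a large swing.
* `cascade(n_tiers)` — chained cycles where tier t's phosphorylated form
  is tier t+1's kinase (the Ras→Raf→MEK→ERK shape at 4 tiers), driven by a
  small constitutive kinase pool; the substrate GoF plus
  downstream-inhibitor titration experiments run here.
* `random_crn()` — seeded composition of activation and binding motifs
  whose conservation matrix holds by construction, for property tests; it
  never samples raw stoichiometries, so a nontrivial left null space is
  guaranteed rather than hoped for.

These fixtures reproduce the *structural* features large signalling models
rely on — bimolecular binding, phosphorylation cycles, generator pools,
degradation breaking conservation coverage — but not their scale (hundreds
of species), their calibrated rate-constant spread, or multistability.
Passing tests therefore certify the machinery (exact conservation
analysis, convergence criteria, perturbation semantics), not the biology
of any particular large model, whose rate constants and removal lists
must come from its own distribution files.  Problem sizes in the test
suite and acceptance script are 3–37 species per network, for which the
whole suite runs in seconds; the same code paths apply unchanged to
SBML-loaded models of hundreds of species, where a single equilibration
is minutes of stiff integration.

# Known limitations

* Mass action only: no Michaelis–Menten aggregation, compartments, SBML
  events or assignment rules.
* No multistability or bifurcation analysis; the equilibrium search
  reports what the integrator converges to from the given state.
* The tableau step for nonnegative generators is exponential in the worst
  case; it is capped, with the signed rational basis as the flagged
  fallback.
* Drug binding targets the free protein only; complexes containing the
  target are not inhibited, and no pharmacokinetics beyond the washout
  toggle is modelled.
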