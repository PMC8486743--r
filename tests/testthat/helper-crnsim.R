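# Shared fixture builders for the test suite; everything is generated in
# code, no data files.

# A + B <-> C with defaults; most tests want the unit-parameter instance.
unit_binding <- function() toy_binding(kf = 1, kr = 1, a0 = 1, b0 = 1)

# Two-state isomerization A <-> B.
isomerization <- function(kf = 1, kr = 1, a0 = 2, b0 = 0) {
  crn(data.frame(id = c("A", "B"), x0 = c(a0, b0)),
      list(list(id = "f", reactants = c(A = 1L), products = c(B = 1L),
                k = kf, reverse_of = "b"),
           list(id = "b", reactants = c(B = 1L), products = c(A = 1L),
                k = kr, reverse_of = "f")))
}

# Constant generator pool G feeding P, with degradation of P: the
# synthesis-fed protein motif (P is covered by no conservation law).
generator_fed <- function(g0 = 2, k_syn = 0.5, k_deg = 0.1) {
  crn(data.frame(id = c("G", "P"), x0 = c(g0, 0),
                 constant = c(TRUE, FALSE)),
      list(list(id = "syn", reactants = c(G = 1L), products = c(G = 1L, P = 1L),
                k = k_syn, reverse_of = NA),
           list(id = "deg", reactants = c(P = 1L), products = integer(0),
                k = k_deg, reverse_of = NA)))
}

law_matrix <- function(laws) do.call(rbind, lapply(laws, `[[`, "gamma"))

# Minimal synthetic SBML document (level 2) exercising the reader:
# a reversible binding with kf/kr, an irreversible step, and a
# boundary-condition generator pool.
synthetic_sbml <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="toy">
    <listOfSpecies>
      <species id="A" initialConcentration="1" boundaryCondition="false"/>
      <species id="B" initialConcentration="1"/>
      <species id="C" initialConcentration="0"/>
      <species id="G" initialConcentration="2" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="bindAB" reversible="true">
        <listOfReactants>
          <speciesReference species="A"/>
          <speciesReference species="B"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="kf" value="1.5"/>
            <parameter id="kr" value="0.25"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="feedA" reversible="false">
        <listOfReactants>
          <speciesReference species="G"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="G"/>
          <speciesReference species="A"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="k" value="0.01"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  path
}
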