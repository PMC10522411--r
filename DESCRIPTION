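Package: cgram
Title: Coarse-Grained Resource Allocation Models of Microbial Carbon and
    Nitrogen Metabolism
Version: 0.1.0
Authors@R:
    person("cgram", "maintainers", email = "cgram@example.org",
           role = c("aut", "cre"))
Description: Simulates a coarse-grained resource allocation model (C-GRAM)
    of carbon and nitrogen metabolism in unicellular microbes.  The cell is
    described by twelve biomass mass fractions (four metabolites, seven
    catalytic protein sectors and one housekeeping sector) whose dynamics
    follow Michaelis-Menten kinetics coupled through a mass-balanced
    stoichiometry; balanced growth is the steady state of the resulting
    stiff ODE system.  Translational allocation fractions are chosen by a
    derivative-free simplex optimizer that maximizes the steady-state
    growth rate under the allocation constraint.  Experiment drivers sweep
    nutrient-quality parameters (uptake efficiencies, nitrogen-source
    carbon content) to reproduce the Monod and ribosomal growth laws,
    respiration/fermentation switching, and ketoacid recycling/excretion
    phase diagrams.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
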