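## shared fixtures and small helpers for the test suite

## linear chain: b1 imports A, r1 converts A -> B, b2 exports B; biomass = b2
chainNetwork <- function() {
  S <- matrix(0, 2, 3, dimnames = list(c("A", "B"), c("b1", "r1", "b2")))
  S["A", "b1"] <- -1
  S["A", "r1"] <- -1; S["B", "r1"] <- 1
  S["B", "b2"] <- -1
  MetabolicNetwork(S, c(-10, 0, 0), c(10, 10, 10), biomassId = "b2")
}

## deterministic batch of small random networks (m <= 8, n <= 12)
randomBatch <- function(nNets, seedOffset = 0) {
  lapply(seq_len(nNets), function(k) {
    seed <- k + seedOffset
    rec <- networkRecipe(metabolites = 3 + seed %% 4,
                         internalReactions = 3 + seed %% 5,
                         boundaryMetabolites = 2 + seed %% 2,
                         reversibleProb = 0.3,
                         seed = seed)
    randomNetwork(rec)
  })
}

supportKeys <- function(supports) {
  vapply(supports, paste, character(1), collapse = ",")
}

## supports of the standardized rays of an EfmSet
efmSupportKeys <- function(efms) {
  supportKeys(lapply(seq_len(nrow(efms@raysStd)),
                     function(i) which(efms@raysStd[i, ] != 0)))
}

## is v a nonnegative combination of the rows of R? (LP feasibility)
inConicHull <- function(v, R) {
  if (all(v == 0)) return(TRUE)
  if (!nrow(R)) return(FALSE)
  solveLp(numeric(nrow(R)), t(R), rep("==", ncol(R)), v,
          lb = 0)$status == "optimal"
}

## support-minimal members of a pattern list
supportMinimal <- function(pats) {
  keep <- vapply(seq_along(pats), function(i) {
    !any(vapply(seq_along(pats), function(j) {
      j != i && length(pats[[j]]) < length(pats[[i]]) &&
        all(pats[[j]] %in% pats[[i]])
    }, logical(1)))
  }, logical(1))
  pats[keep]
}

ecoliModelPath <- function() {
  system.file("extdata", "e_coli_core.json", package = "exopath")
}

## a minimal SBML Level 3 + fbc document for the chain network
chainSbml <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="chain">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="B" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="lb_0" value="0" constant="true"/>
      <parameter id="ub_10" value="10" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="b1" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_10">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="r1" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_10">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="growth_b2" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_10">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}
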