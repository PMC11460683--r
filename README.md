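# exopath

Unbiased pathway analysis of **metabolite exchanges** in constraint-based
metabolic models.

Constraint-based models describe metabolism by a stoichiometric matrix `N`
with steady-state mass balances `N r = 0` and flux bounds `lb ≤ r ≤ ub`.
Many biological questions concern only how a cell (or a microbial
community) exchanges metabolites with its environment and its neighbours —
the *boundary subnetwork* — rather than the internal flux routing. Several
formal pathway definitions target exactly this subnetwork, and `exopath`
implements all of them, for modellers who want to enumerate, compare, and
sample growth-supporting metabolite exchanges:

* **EFMs** — elementary flux modes, the extreme rays of the flux cone
  `C = {x ≥ 0 : N_std x = 0}` (double description method, exact integer
  arithmetic);
* **ECMs** — elementary conversion modes, the extreme rays of the
  projection of `C` onto the exchange subnetwork (exact Fourier–Motzkin
  elimination with LP redundancy removal, then double description);
* **EFPs** — elementary flux patterns, the exchange sign patterns that
  cannot be built from other patterns without cancellation (union-closure
  extraction from EFM or ECM patterns);
* **MPs** — minimal pathways, the support-minimal sets of exchanges that
  must carry flux for growth above a floor (LP-guided exclusion search).

Compared as flux patterns on the same subnetwork, these definitions form a
hierarchy

```
P_MP ⊆ P_EFP ⊆ P_ECM ⊆ P_EFM
```

which the package verifies on every analysis (`verifyHierarchy()`), along
with metabolite exchange frequencies, pairwise and producer–consumer
interaction frequencies for community models, community-model construction
with a shared exchange compartment and balanced growth, and uniform
hit-and-run flux sampling validated against flux variability analysis —
including sampling restricted to a single pathway, which reaches flux
regions of vanishing volume that global sampling misses.

Every enumerative stage ships with an independent brute-force oracle
(exhaustive supports via nullspace tests, exhaustive subset LPs, exhaustive
union closure) and generators for random mass-balanced networks and a
three-member cross-feeding community, so the algorithms are testable
end-to-end without any external data.

## Worked example

```r
library(exopath)

net <- loadModel(system.file("extdata", "e_coli_core.json", package = "exopath"))
net
#> MetabolicNetwork: 72 metabolites, 95 reactions ( 20 boundary, 46 reversible )
#>   biomass: Biomass_Ecoli_core

res <- runPipeline(net, definitions = c("ecm", "efp", "mp"))
res$counts
#>   definition raw uniquePatterns growthPatterns
#> 1        ECM 689            419            346
#> 2        EFP 118            118             63
#> 3         MP  34             34             34
res$hierarchy$holds
#> [1] TRUE
```

Reading: the E. coli core model admits 689 elementary conversion modes,
corresponding to 419 unique exchange patterns of which 346 support growth;
118 of the patterns are elementary flux patterns (63 growth-supporting);
and 34 minimal pathways — support-minimal exchange sets — suffice to
summarize all growth-supporting behaviour. Every growth-supporting EFP
contains exactly one MP:

```r
cmp <- res$comparison
all(cmp$subsetCounts$MP_in_EFP == 1)
#> [1] TRUE
```

Exchange frequencies (the fraction of pathways using each metabolite in
each direction) and their differences between definitions:

```r
head(res$frequencies$MP, 3)
#>               entity direction count frequency
#> 1 Biomass_Ecoli_core    export    34 1.0000000
#> 2               ac_e    export     8 0.2352941
#> 3            acald_e    export     6 0.1764706
```

Biomass export has frequency one by construction (all MPs support growth);
acetate secretion, for example, appears in 8 of the 34 minimal pathways.

For a community model, build members with `MetabolicNetwork()`, join them
with `mergeCommunity()` (shared compartment, equal-shares community
biomass), and analyse intermicrobial transfers with
`subnetworkMode = "boundary_plus_intermicrobial"`; `interactionFrequency()`
then tallies producer–consumer–metabolite triples. See the methods
vignette (`vignettes/exopath-methods.Rmd`) for the model, the algorithms,
and all numerical design choices.

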