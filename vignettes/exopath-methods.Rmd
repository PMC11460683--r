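---
title: "Pathway definitions for metabolite exchanges: models, algorithms and design choices"
author: "exopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway definitions for metabolite exchanges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exopath)
```

## The model

A constraint-based metabolic model describes a network of `m` metabolites and
`n` reactions by a stoichiometric matrix `N`. Under the quasi-steady-state
assumption the mass balances read `N r = 0`, where `r` is the vector of
reaction fluxes, and lower/upper flux bounds `lb <= r <= ub` encode
reaction directionality and, optionally, uptake capacities. When only the
homogeneous part of these constraints is kept (directionality, no bound
magnitudes) and every reaction is re-encoded to be irreversible with
nonnegative flux, the feasible set is the *flux cone*

```
C = { x >= 0 : N_std x = 0 }.
```

`standardize()` performs this re-encoding: irreversible reactions admitting
only negative flux are direction-flipped, every reversible reaction is split
into a forward and a backward part, and each stoichiometric row is scaled to
integers (mass balances are invariant to row scaling) so that all later cone
computations are exact. For a boundary (exchange) reaction the two split
parts are the *export* and *import* of its single metabolite; these
(entity, direction) pairs are the **items** of the analysis subnetwork. The
biomass reaction is always appended to the subnetwork so growth support is
part of every pattern.

## Four pathway definitions, one currency

All four definitions are compared as *flux patterns*: the set of subnetwork
items with nonzero flux.

* **EFMs** (elementary flux modes) are the extreme rays of `C`, computed
  here with the double description method. The restriction of the EFMs to
  the subnetwork generates the projected cone.
* **ECMs** (elementary conversion modes) are the extreme rays of the
  projection of `C` onto the subnetwork, i.e. the elementary net metabolite
  conversions. They are computed *without* enumerating EFMs: the internal
  coordinates are eliminated exactly and the projection's rays are
  enumerated directly, which is what lets ECMs scale beyond EFMs.
* **EFPs** (elementary flux patterns) are the patterns that cannot be
  written as a cancellation-free union of other patterns. Following the
  union-closure characterization, a pattern is elementary iff the union of
  its proper sub-patterns (within the complete unique pattern family of the
  EFMs or ECMs) differs from the pattern itself. Because the subnetwork is
  all-irreversible, unions cannot cancel, and the extraction gives the same
  result from EFM patterns and from ECM patterns (asserted on every test
  network).
* **MPs** (minimal pathways) are the support-minimal item sets that permit a
  feasible flux with biomass at least a growth floor (default `1e-4` 1/h).

These collections are nested,

```
P_MP  ⊆  P_EFP  ⊆  P_ECM  ⊆  P_EFM,
```

and `verifyHierarchy()` checks the chain (with witnesses on violation) for
any combination of tiers, including the equality case in which every
pattern is support-minimal.

## Algorithms and numerical choices

**Exact arithmetic.** Pattern extraction is a sign computation, so the cone
pipeline must not round. There is no arbitrary-precision integer package in
the runtime, so all cone computations run on integer-valued doubles (rays
and constraint rows are reduced by their gcd), the double description core
stores rays as 64-bit integers and combines them in 128-bit intermediates,
and any overflow aborts loudly rather than degrading to floating point.
Stoichiometries are rationalized by continued fractions (tolerance `1e-9`)
before enumeration.

**Double description.** Constraints are processed against the nonnegative
orthant in a deterministic order (equalities sorted by increasing nonzero
count, then inequalities). Ray adjacency is decided by the combinatorial
test on tight-constraint sets, which is exact for pointed cones when the
ray list is maintained as the exact extreme-ray set - our cones are always
pointed because they live inside the orthant. A cardinality pre-filter
using the rank of the current ray span keeps the pair loop fast. Output
rays are canonicalized (gcd-reduced, exported with first nonzero scaled to
1) and sorted lexicographically, so results are invariant to input row
order. A configurable ray ceiling (default 2e6) aborts with a progress
report instead of truncating silently.

**Projection.** `projectCone()` eliminates internal coordinates by Gaussian
substitution where an equality allows it and by Fourier-Motzkin combination
otherwise (eliminating the variable with the smallest positive-negative
product first). After each elimination, redundant inequalities are removed
with a Farkas-certificate LP: a row is dropped iff it is a nonnegative
combination of the remaining inequality rows plus a linear combination of
the equalities. This keeps the intermediate descriptions small enough that
the method handles genome-scale boundary subnetworks in seconds.

**Futile two-cycles.** Splitting a reversible exchange creates a
forward/backward pair whose simultaneous use is a zero-conversion cycle.
These appear as extreme rays of both the full and the projected cone; they
are removed from EFM and ECM sets (elementary objects never contain both
directions of one exchange), and the tests assert that property on every
collection.

**EFM orientation.** A fully reversible mode appears as a mirror pair of
standardized rays and is counted once (canonical orientation, first nonzero
positive); a mode using any irreversible reaction has a unique feasible
orientation, which is kept. Pattern extraction uses the full standardized
ray set, so both orientations of reversible modes contribute patterns.

**Minimal pathways.** MPs are enumerated by alternating feasibility LPs
with a systematic exclusion search: a feasibility witness is shrunk to a
minimal item set by greedy single-item removal with LP re-checks (activity
threshold `1e-6`; a final verification LP enforces a floor of `1e-8` on
every remaining item simultaneously), and the search branches on excluding
each item of every minimal set found. Completeness follows because any
other MP misses at least one item of each found MP and therefore survives
along some branch; visited exclusion sets are memoized.

**Bound handling for MPs.** The hierarchy is a statement about pathways
enumerated under *equivalent constraints*. EFMs, ECMs and EFPs are
cone-based and see only reaction directionality, so `enumerateMps()`
defaults to the same homogeneous constraints (bound magnitudes relaxed to
direction-only, plus the growth floor). This matters in practice: with the
distributed E. coli core bounds, the ATP-maintenance floor (`ATPM >= 8.39`)
makes exactly one of the 34 support-minimal growth patterns (an anaerobic
succinate/formate route) infeasible, and MP enumeration under full bounds
returns 33 rather than 34 pathways, breaking the equality between MPs and
support-minimal EFPs. `homogeneousBounds = FALSE` restores the
full-constraint behaviour for users who want inhomogeneous MPs.

**Linear programming.** The runtime provides no LP solver, so the package
carries a dense two-phase primal simplex (Dantzig pricing, Bland
anti-cycling fallback on stall, compiled core with a pure-R reference
implementation used for cross-checking in the tests). All LPs here are
small and dense; feasibility tolerances are `1e-9` (pivoting) and `1e-7`
(phase-1 infeasibility).

**Flux sampling.** `sampleFluxes()` implements artificial-centering
hit-and-run on `{S v = 0, lb <= v <= ub, v_bio >= floor}` (sampling floor
default 0.1 1/h). Warm-up points are the flux-variability vertices;
directions are differences of stored points projected onto the null space
of the stoichiometry each step, so numerical drift cannot accumulate;
pinned coordinates (`lb = ub`) are held fixed by treating them as equality
rows. The default thinning of 100 steps suits production runs; the tests
use smaller thinning to keep runtimes short. Samples are validated against
flux-variability ranges and a split-chain potential-scale-reduction
diagnostic (pass threshold 1.05) is attached; non-convergence is a warning,
never a silent failure. `samplePerPathway()` restricts the polytope to one
pattern by zero-fixing all other subnetwork items and giving the pattern's
items an activity floor of `1e-6` - with the effect that regions of
vanishing volume, invisible to global sampling, are sampled directly.

## Community models

`mergeCommunity()` joins member models through a shared compartment: member
boundary reactions for shared metabolites are rewired into internal
transfer reactions (member metabolite to shared metabolite), environmental
exchange reactions are created only for designated metabolites, and a
community biomass pseudo-metabolite assembled from member biomasses in
fixed shares (default equal) enforces balanced growth - no member biomass
can leave except through the community biomass reaction. With
`subnetworkMode = "boundary_plus_intermicrobial"` the analysis subnetwork
contains both environmental exchanges and the member-qualified transfer
items (`"member:metabolite"`), from which `interactionFrequency()` tallies
producer-consumer-metabolite triples.

## What the synthetic data emulate

`makeToyNetwork()` is a five-metabolite network (A-D plus biomass) with
five internal and three boundary reactions in which two units of A are
needed per unit of the intermediate C. Its ground truth is fully known:
three elementary conversions (`2A -> BM`, `2A -> B`, `2A + B -> 2BM`),
three EFPs identical to the ECM patterns, and exactly one MP (import A,
export biomass), because B alone supports no growth. `randomNetwork()`
draws small mass-balanced integer networks (rejection-sampled until growth
of at least `1e-3` is LP-certified), sized so that the brute-force oracles
- exhaustive support tests via SVD nullspaces, exhaustive subset LPs,
exhaustive union closure, none of which share code with the enumerators -
remain exact references. `makeToyCommunity()` builds a stylized
phototrophic-mat community (a phototroph secreting organics and oxygen, a
photoheterotroph, and a reducer exchanging H2/CO2) whose growth requires
every member.

These generators emulate the structural properties the analysis relies on
(mass balance, directionality, single-metabolite exchanges, a feasible
biomass) but not the biochemical realism of curated models: coefficients
are small integers, there are no cofactor or proton balances, and network
sizes are far below genome scale. Passing the property suite therefore
demonstrates algorithmic correctness, not biological fidelity; the bundled
E. coli core model provides the realistic benchmark.

## Problem sizes and known limitations

The test-suite and acceptance runs use the toy fixtures, 100 random
networks (at most 8 metabolites and 12 reactions), the E. coli core model
(95 reactions; ECM, EFP and MP tiers), and samplers at 10,000 samples.
Full-network EFM enumeration is exponential and is exercised only on small
networks where the support oracle can confirm it; the E. coli core EFM tier
(about 1e5 modes) and genome-scale ECM enumeration are outside the default
runs. Exact Fourier-Motzkin elimination can overflow the 64-bit integer
range on ill-conditioned stoichiometries (notably biomass rows with many
four-decimal coefficients combined repeatedly); the computation then aborts
explicitly. The MP search assumes LP feasibility is decided correctly at
tolerance `1e-7`; degenerate models with meaningful fluxes below `1e-8`
would need tighter settings.

## A worked example

```{r example}
net <- makeToyNetwork()
res <- runPipeline(net, definitions = c("efm", "ecm", "efp", "mp"))
res$counts
res$hierarchy$holds
subnetworkItems(standardize(net))[res$collections$MP@patterns[[1]], 1:2]
```
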