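---
title: "Dynamic FBA co-cultures and diversity graphs: methods and design"
author: "CrossFeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic FBA co-cultures and diversity graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrossFeed)
```

# The problem

When a clonal bacterial population grows on a single limiting carbon
source, its metabolism routinely leaks organic by-products (acetate,
formate, glycolate, ...) into the medium. Genetically different strains
leak *different* by-products, and a strain that can consume what
another secretes gains a second resource. CrossFeed asks, for a pool of
single-gene-knockout strains of a constraint-based metabolic model:
which strains differ enough in by-production to feed each other, and do
mixtures of such strains actually outgrow their monocultures in a
closed batch culture?

The package answers this with two devices: a **multi-competitor dynamic
FBA model** that grows several independent strains against one shared,
depleting substrate pool, and a **diversity graph** that turns pairwise
differences in by-product secretion into edge weights so that candidate
communities appear as cliques.

# The growth model

## Per-step optimization

Each strain is a stoichiometric model: metabolites \(\times\) reactions
matrix \(S\), flux bounds \(v_{min} \le v \le v_{max}\), a biomass
reaction whose flux is the specific growth rate \(\mu\) (1/h), and
boolean gene-protein-reaction (GPR) rules. At every time step each
strain solves the canonical FBA program

\[\max \mu \quad \text{s.t.} \quad S v = 0,\; v_{min} \le v \le v_{max},\]

followed by a secondary program that minimizes the total enzymatic cost
\(\sum_j |v_j|\) while holding \(\mu\) at its optimum (within relative
slack \(\varepsilon = 10^{-9}\)). The second stage matters here more
than in ordinary FBA studies: the by-product *secretion fluxes* are the
scientific readout, and the L1 objective collapses most of the
alternate-optima freedom that growth maximization leaves behind.
Remaining ties are broken deterministically by the solver, so identical
inputs give bit-identical solutions; across different LP backends,
though, tied solutions may differ, which is why downstream comparisons
of simulated concentrations use tolerances.

Exchange reactions carry the fixed sign convention *positive =
secretion, negative = uptake*. An uptake-bound map passed to the solver
defines the environment completely: exchanges without an entry are
closed for uptake. Bounds supplied per step can only tighten the
model's own bounds, so knocked-out reactions stay closed.

## Batch dynamics

Time is divided into intervals \(\delta t\) with intracellular
quasi-steady state inside each interval. With biomass \(b_i\) growing
exponentially at the rate \(\mu_i\) found by the LP, the updates over
one interval are

\[b_i(t + \delta t) = b_i(t)\, e^{\mu_i \delta t},\qquad
C_s(t + \delta t) = C_s(t) + \sum_i v_{ex,i}^s\, b_i(t)\,
\frac{e^{\mu_i \delta t} - 1}{\mu_i},\]

the exact integral of exchange at rate \(v^s_{ex,i}\) per gram dry
weight over exponentially growing biomass. As \(\mu_i \to 0\) the
medium term is the 0/0 limit \(v_{ex,i}^s b_i \delta t\), implemented
in closed form below \(\mu < 10^{-9}\): a non-growing strain may still
exchange at steady state, and the explicit limit avoids numerical
blow-up.

The uptake bound of a tracked metabolite at concentration \(C_s\) is

\[v_{min}^{ex,s} = -\min\!\left(\frac{C_s}{\delta t \sum_i b_i},\;
\text{cap}_s\right),\]

i.e. the pool divided by the *total* population biomass — every
competitor receives the same per-gDW bound, the model's fairness
assumption, with no per-strain partitioning of the pool. The
per-metabolite cap is applied at every step (the scheme only pins the
initial bounds; capping throughout is this package's choice).
In-excess metabolites (oxygen and inorganics, in genome-scale settings)
are bounded by their cap only and never tracked.

Because growth within the step is exponential while the bound is
computed linearly, the final step over an emptying pool can overdraw it
by at most the factor \((e^{\mu\delta t}-1)/(\mu\delta t)\).
Concentrations are clamped at zero and the clamped mass is logged on
the trajectory rather than hidden; on the shipped fixtures it stays
below 0.01% of the initial carbon at \(\delta t = 0.1\) h. We chose
clamping over adaptive sub-stepping to keep the fixed-\(\delta t\)
scheme exactly reproducible.

Newly secreted metabolites join the tracked pool at their produced
concentration and become consumable by every strain from the next step
on — this is the mechanism that lets cross-feeding emerge without being
modeled explicitly. Strains are solved independently; nothing optimizes
a collective objective.

Termination: when no strain grows faster than `muTol` (default
\(10^{-6}\) 1/h, an engineering choice) the run stops as `stalled`,
otherwise at `maxTime` (default 100 h) as `max-time`, with the reason
recorded. Growth rates between 0 and `muTol` are treated as zero so
that vanishing residual growth cannot stall termination indefinitely. A
strain seeded with zero biomass is skipped entirely: it has no mass to
exchange, and letting its (massless) positive growth rate veto
termination would run every simulation to the horizon.

A co-culture of \(k\) identical strains is mathematically identical to
the monoculture of their summed biomass (same bounds, same LP, additive
medium terms); the test suite verifies the reduction to \(10^{-9}\).

# The diversity graph

For each viable strain \(i\) the batch monoculture yields a by-product
blueprint: the maximum concentration \(Cmax_i^s\) each secreted
metabolite \(s\) reaches in the medium. The primal source is excluded,
and an exclusion list keeps non-informative species (CO2, water,
protons in genome-scale models) out; the fixtures secrete only organic
by-products, so their list is empty. The edge weight between strains
\(i\) and \(j\) is

\[w_{ij} = \max_s \frac{|Cmax_i^s - Cmax_j^s|}{\max(Cmax_i^s, Cmax_j^s)}
\in [0, 1],\]

with metabolites secreted by neither strain contributing 0 (a 0/0 ratio
means the strains are indistinguishable on that metabolite, not
different). \(w = 0\) means identical by-production; \(w = 1\) means at
least one strain secretes something the other does not.

Because the weights are ratios, the graph does not depend on the
initial source concentration, and an equivalent graph can be estimated
from a *single* flux-minimized FBA solve per strain by replacing
\(Cmax^s\) with the by-production efficiency — secretion flux over
primal carbon uptake rate. Both constructions are implemented
(`buildDiversityGraph`, `fastGraphFromFBA`) and agree on the fixtures.
Two caveats are documented rather than engineered away: strains that
*re-consume* their own by-product give the ratio identity only
approximately across different initial concentrations (floating-point
accumulation over different step counts), and node viability is
decided by `muTol` at the first step.

Binarization keeps edges with \(w \ge\) threshold; the conventional
threshold is 0.6 and the comparison is inclusive (a choice this package
documents since either convention is defensible). Structural
compression merges nodes with identical binary neighborhoods —
necessarily mutually non-adjacent — into supernodes; quotient cliques
correspond exactly to original cliques with one representative per
supernode, which both accelerates the search and makes the graph
readable.

Graph statistics follow the standard definitions, isolated behind one
formula layer so they are easy to swap: strength centrality is the sum
of incident weights normalized by \(n - 1\); network centralization is
the Freeman form \(\sum_i (c_{max} - c_i)/(n - 2)\); local clustering
is the Watts-Strogatz coefficient (degree < 2 contributing 0);
attribute assortativity is the Pearson correlation of a node attribute
over edge endpoints, each edge counted in both orientations, with edge
weights as multiplicities in the weighted variant and a distinct signal
(NA + warning) when the attribute variance vanishes. The conservation
density summarizes an ordered strain list in non-overlapping windows of
10 as the percentage of strains whose attribute exceeds 0.7, reporting
a trailing partial window at its actual size.

# Communities and growth benefit

A community is a set of pairwise different strains — a clique of the
binary graph. The maximum clique size bounds the metabolic diversity a
condition can support. The search is exact: the graphs here are small
or heavily compressible, so exact algorithms (igraph's branch-and-bound
and pivoted enumeration) are tractable, and the suite checks them
against exhaustive subset enumeration on hundreds of random graphs.
Representative choice during decompression is deterministic
(lexicographically smallest member); since supernode members are
by-production-identical the choice cannot affect simulations, but it is
still recorded for reproducibility.

Community growth is scored by the endpoint biomass \(g\) of one
co-culture simulation against reference monoculture endpoints \(m_i\):

\[\text{benefit} = \frac{g - \max_i m_i}{\max_i m_i},\]

*relative* when \(i\) ranges over the members, *absolute* over all
strains of the graph. Endpoint means biomass at termination; runs cut
off by `maxTime` are flagged non-comparable instead of being scored
silently. Interactions are read from the exchange-flux time profiles:
producer flux above \(10^{-6}\) mmol/gDW/h (the LP-noise floor) and
consumer flux below \(-10^{-6}\), with production required to start no
later than consumption ends — consumption may trail production, as in
sequential re-use after source exhaustion. Ratio scans hold the total
initial biomass fixed (0.003 gDW/L) and vary only the split, on a
default grid of ninths.

The pair-mean predictor estimates a community's endpoint as the mean of
its constituent pairs' endpoints, valid when every pair interacts; the
implementation flags communities violating the precondition and the
correlation utility excludes them.

# The synthetic fixtures

`makeCrossfeedModel` builds small stoichiometric networks from a
parameter object: source exchange and transport, gene-gated catabolic
routes `source -> yield * biomass-precursor (+ coef * by-product)`,
per-by-product uptake and catabolism, and a biomass sink. Defaults (in
`toyCrossfeedSpec`): efficient route at yield 0.1 gDW/mmol secreting
0.5 mmol by-product per mmol source, clean alternative route at 0.05,
by-product catabolism at 0.1 behind the two-subunit rule
`cat1a and cat1b`, and a catabolic flux capacity of 2 mmol/gDW/h — the
overflow-metabolism abstraction: without it, FBA recycles the
by-product internally within a step and nothing reaches the medium.
Yields are round numbers chosen so every endpoint has a closed form
\(b_0 + Y \cdot C_0\); the growth condition defaults (0.003 gDW/L,
10 mmol/L, \(\delta t = 0.1\) h, uptake cap 10 mmol/gDW/h) are the
package's standard batch setting.

Knockouts of this one model generate the phenomena the package is
about: either `cat` subunit gives a pure provider (altruist), `srcA`
gives a slower but by-product-consuming strain, the wild-type shows
two-phase (diauxic-like) growth with a secretion peak and full
re-consumption. `toyTripletSpec` adds a catabolic reaction that needs
*two* by-products in 1:1 proportion, producing the indirect-benefit
triplet — two non-interacting producers and a scavenger, every pair
non-beneficial, the triplet beneficial. `toyBidirectionalSpec` gives
complementary double knockouts that exchange in both directions.
`makeRandomGraph` (seeded Erdos-Renyi with planted cliques, global RNG
state restored) and `makeFigure1Graph` (the four-node worked example)
cover the graph algorithms.

What the fixtures deliberately do not emulate: realistic pathway
topology, redox/energy bookkeeping, oxygen limitation, regulation, or
the size of a genome-scale network. Passing tests therefore demonstrate
the *correctness of the machinery* — LP optima, integrals, graph
constructions, clique exactness, benefit arithmetic — on networks where
every expected value has an analytic derivation; they do not validate
biological predictions of any particular genome-scale reconstruction.

# Numerical choices

* **LP backend.** A dense two-phase primal simplex with Bland's
  anti-cycling rule, written for the small, highly degenerate programs
  that L1 flux minimization produces, behind a single internal entry
  point so another backend can be swapped in. Tolerance \(10^{-9}\) on
  reduced costs and pivots; infinite bounds truncated at \(10^{6}\)
  (model conventions use \(\pm 1000\)). Deterministic by construction.
* **Flux minimization at every dynamic step** (switchable off), so
  secretion profiles are reproducible; \(\mu\) is re-fixed with
  relative slack \(10^{-9}\), and the minimized solution sits at the
  bottom of that slack band.
* **Problem sizes.** The shipped analyses run fixtures of 5-13
  reactions for tens to hundreds of time steps, 200 random graphs of up
  to 15 nodes for the clique-exactness check (the exhaustive oracle
  enumerates all \(2^n\) subsets), and sweeps of a 5-gene universe;
  these sizes keep every expected value independently computable while
  exercising the same code paths a genome-scale model would take.
* **Caching.** Monoculture sweeps are content-addressed on (model,
  knockout set, condition, settings); a warm cache re-runs with zero LP
  solves, which the suite asserts via the package's solve counter.

# Known limitations

Alternate optima can survive flux minimization; integer-valued
structure (cliques, supernode counts) is robust to this, simulated
concentrations are compared with tolerances. The fixed-step scheme
overdraws an emptying pool by a bounded, logged amount; halving
\(\delta t\) moves fixture endpoints by well under 1%. The fast graph
construction assumes secretion efficiency is concentration-independent,
which holds for the LP but not necessarily for regulation-aware
extensions. Evolutionary stability of communities (invasion by
non-secreting cheaters) is out of scope.
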