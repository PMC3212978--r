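# CrossFeed

Dynamic flux balance analysis of batch co-cultures, and diversity-graph
discovery of growth-efficient cross-feeding strain communities.

## What it is for

Bacteria growing on a single limiting carbon source secrete organic
by-products into the medium, and strains that differ metabolically can
feed on each other's leftovers. CrossFeed is for researchers working
with constraint-based (stoichiometric) metabolic models who want to

* simulate **batch monocultures and multi-strain batch co-cultures** in
  which independent competitors share one depleting substrate pool,
* map pairwise differences in by-product secretion onto a weighted
  **diversity graph** whose cliques are candidate cross-feeding
  communities, and
* quantify whether a simulated community actually **outgrows its
  monocultures**, and which metabolites its members exchange.

## The model

Each strain solves, at every time step \(\delta t\), the FBA program
max &mu; s.t. *S v* = 0, *v*<sub>min</sub> &le; *v* &le;
*v*<sub>max</sub>, followed by minimization of the total flux
&Sigma;|v<sub>j</sub>| at the optimal growth rate (so secretion fluxes
are reproducible). Biomass and medium then advance by

* *b<sub>i</sub>(t+&delta;t) = b<sub>i</sub>(t) e<sup>&mu;<sub>i</sub>&delta;t</sup>*
* *C<sub>s</sub>(t+&delta;t) = C<sub>s</sub>(t) + &Sigma;<sub>i</sub>
  v<sup>s</sup><sub>ex,i</sub> b<sub>i</sub>(t)
  (e<sup>&mu;<sub>i</sub>&delta;t</sup> &minus; 1)/&mu;<sub>i</sub>*

with uptake bounds
*&minus;min(C<sub>s</sub>/(&delta;t &Sigma;<sub>i</sub> b<sub>i</sub>), cap<sub>s</sub>)*
shared by all competitors. Secreted metabolites join the common pool
and become consumable, which is how cross-feeding emerges.

Strain pairs are scored by the diversity-graph weight

&nbsp;&nbsp;*w<sub>ij</sub> = max<sub>s</sub>
|Cmax<sup>s</sup><sub>i</sub> &minus; Cmax<sup>s</sup><sub>j</sub>| /
max(Cmax<sup>s</sup><sub>i</sub>, Cmax<sup>s</sup><sub>j</sub>)* &isin; [0, 1],

where *Cmax<sup>s</sup><sub>i</sub>* is the peak concentration of
by-product *s* in strain *i*'s monoculture (0 = identical
by-production, 1 = a novel by-product). Communities are cliques of the
graph thresholded at 0.6, found exactly on the structurally compressed
graph, and their benefit is
*(g &minus; max<sub>i</sub> m<sub>i</sub>)/max<sub>i</sub> m<sub>i</sub>*
with *g* the co-culture endpoint biomass and *m<sub>i</sub>* the
monoculture endpoints (members only: *relative*; all strains:
*absolute*).

## Worked example

The built-in fixture is a small cross-feeding network: an efficient
catabolic route that obligately secretes a by-product, a clean slower
route, and gene-gated by-product catabolism. Knocking out a catabolism
subunit gives a *provider* (secretes, cannot re-consume); knocking out
the efficient route gives a *consumer*.

```r
library(CrossFeed)

toy <- makeCrossfeedModel(toyCrossfeedSpec())
toy
#> StoichiometricModel 'toy_crossfeed'
#>   5 metabolites, 8 reactions, 4 genes
#>   biomass: BIOMASS; exchanges: 2

cond <- growthCondition("src_e")   # 10 mmol/L source, 0.003 gDW/L, dt 0.1 h
provider <- applyKnockout(toy, strainSpec("prov", "cat1a"))
consumer <- applyKnockout(toy, strainSpec("cons", "srcA"))

trajP <- simulateMonoculture(provider, cond, "prov")
trajP
#> BatchTrajectory (1 strain(s), 60 time points, stalled)
#>   endpoint biomass: prov = 1.003 gDW/L
```

The provider converts all 10 mmol/L source at yield 0.1 gDW/mmol:
endpoint 0.003 + 1.0 gDW/L, the closed-form mass balance. Its secreted
by-product (5 mmol/L) is lost — unless the consumer is present:

```r
trajC <- simulateMonoculture(consumer, cond, "cons")
monos <- c(prov = growthPerformance(trajP),
           cons = growthPerformance(trajC))
res <- communityBenefit(c("prov", "cons"),
                        list(prov = provider, cons = consumer),
                        cond, monoEndpoints = monos)
res
#> CommunityResult {prov, cons}
#>   group endpoint: 1.33065 gDW/L
#>   relative benefit: 0.3266
#>   interactions: 1
```

The 50/50 co-culture ends 33% above the best monoculture, and the
interaction record shows the by-product flowing provider &rarr;
consumer. The two strains are maximally different in by-production:

```r
edgeWeight(byproductProfile(trajP), byproductProfile(trajC))
#> [1] 1
```

`sweepKnockouts` + `buildDiversityGraph` + `cliquesViaCompression`
(or `fullPipeline`) chain these steps over a whole knockout universe;
`inst/scripts/crossfeed` exposes the same workflow as shell
subcommands (`simulate-mono`, `simulate-co`, `build-graph`,
`find-communities`, `benefit`, `scan-ratios`, `sweep`, `pipeline`,
`make-fixtures`).

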