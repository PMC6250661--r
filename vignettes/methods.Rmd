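---
title: "Allele-resolution pleiotropy in constraint-based metabolic models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolution pleiotropy in constraint-based metabolic models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioflux)
```

# The scientific question

Pleiotropy — one gene affecting several phenotypic traits — is usually
measured at the coarse resolution of full gene knockouts. This package
quantifies pleiotropy at *allele* resolution in constraint-based models of
metabolism: each trait is the ability to synthesize one biomass component,
and an allele of a gene is modeled as a fractional capacity of the
reactions that require that gene's product. Sweeping the capacity from
100% down to 0% reveals whether a gene's effects on different traits
appear all at once or sequentially, which full-knockout studies cannot
distinguish.

# Model and procedure

## Flux balance analysis and the wildtype state

A metabolic network with stoichiometric matrix $S$ is assumed at steady
state, $S v = 0$, with flux bounds $lb \le v \le ub$. Flux balance
analysis (FBA) maximizes the flux through the biomass pseudo-reaction. The
*wildtype* flux distribution $v^{WT}$ is obtained by parsimonious FBA
(pFBA): maximize biomass, then, holding biomass at its optimum (within a
relative band of $10^{-9}$), minimize the total absolute flux
$\sum_i |v_i|$ via the standard forward/reverse flux splitting. pFBA
approximates efficient enzyme usage and removes futile cycles. Alternate
pFBA optima are not further tie-broken; quantities that depend on the
wildtype flux can therefore vary slightly across LP solvers. The package's
tests compare the engine to an independently coded brute-force oracle with
its own pFBA implementation, which keeps this variation visible.

## Wildtype flux caps and allele restriction

From $v^{WT}$ every reaction receives a sign-respecting cap
(`wildtype_caps()`):

$$
v_i^{WT} \ge 0 \Rightarrow v_i \in [0,\, v_i^{WT}], \qquad
v_i^{WT} < 0 \Rightarrow v_i \in [v_i^{WT},\, 0],
$$

so reactions may only shrink in magnitude, never reroute. An allele of
gene $g$ with remaining capacity $f \in [0, 1]$ additionally caps every
reaction that *requires* $g$ at $f \cdot |v^{WT}|$ (`restrict_gene()`). A
reaction requires $g$ when $g$ is boolean-essential for its
gene-protein-reaction (GPR) rule: the rule evaluates to false with $g$
absent and all other genes present. A gene listed only as one of several
isoenzymes (an `or` alternative) therefore constrains nothing. Caps are
always intersected with the native bounds and never widen them.

## Counting affected traits

Each biomass substrate (minus a user-supplied exclusion list of
uninformative species such as water and inorganic ions) is one trait. The
reference (`build_reference()`) appends one free secretion exchange per
component and records each component's maximal production rate under the
wildtype caps. For an allele, a component counts as affected when its
maximal production falls below $(1 - 10^{-4})$ times its wildtype maximum
— a *relative* threshold of 0.01%, with components whose wildtype maximum
is below an absolute floor of $10^{-9}$ treated as unscorable. The
pleiotropy of the allele is the number of affected components.

`sweep_gene()` evaluates the count on a grid of capacity fractions from 1
to 0 in steps of 0.005 (201 points) and reports the number of *steps*:
grid transitions at which the count strictly increases. Because caps only
shrink as $f$ decreases, each component's affected status flips exactly
once along the grid; the default `method = "bisect"` finds each flip by
binary search and is exactly equivalent to evaluating all 201 points
(`method = "grid"`), which the tests verify.

## Essentiality

`essentiality_count()` answers a different question: after the mutation,
the network may *reroute freely* within its native bounds; only the gene's
own reactions are capped at $f \cdot |v^{WT}|$. The baseline is the same
computation at $f = 1$, so an unrestricted allele is never counted. This
choice resolves an ambiguity in the usual verbal definition ("compare
against the wildtype"): comparing a restricted-but-free mutant against the
fully capped wildtype state would count rerouting as damage. With the
baseline at $f = 1$, a gene whose flux can be taken over by an isoenzyme
scores 0, matching the biological notion of dispensability.

## Type-II decomposition

For genes catalyzing two or more reactions, `type2_share()` compares the
full-knockout pleiotropy against the maximum pleiotropy of blocking each
reaction alone. A ratio near 1 means the pleiotropy emerges from a single
molecular function (type II); a low ratio means it aggregates several
functions (type I).

## Currency-metabolite mediation

Genes can be pleiotropic merely because they regenerate a shared cofactor
(ATP, NAD(P)H, ...). `add_free_cofactor()` adds a reversible, unbounded
interconversion between the charged and discharged form (plus free
exchanges for any balancing pseudo-species), making regeneration
limitless. `currency_reduction_analysis()` rebuilds the entire reference
on the modified model — the wildtype itself changes when a cofactor is
free — and reports, per cofactor, the fraction of previously pleiotropic
genes (baseline knockout count $\ge 2$) whose count strictly decreased,
plus the union over cofactors and an all-cofactors-free run.

## Gene-trait network modularity

Full-knockout affected sets define a bipartite gene-trait network.
Its modular structure is scored by Barber's bipartite modularity

$$
Q = \frac{1}{m} \sum_{g, t \text{ in same module}}
\left( A_{gt} - \frac{k_g d_t}{m} \right),
$$

maximized by LP&BRIM: label propagation seeds the module assignment, BRIM
alternately reassigns gene-side and trait-side labels to the adjacent
module maximizing $Q$ (with retreat to fresh singleton modules when every
module has negative score). Each restart also refines the deterministic
all-singletons start, which avoids the $Q = 0$ plateau that label
propagation reaches on connected networks. Significance comes from
degree-preserving double-edge-swap nulls ($10m$ attempted swaps per null):
`scaled_modularity()` reports $z = (Q_{obs} - \bar Q_{null}) / sd(Q_{null})$
over `n_null = 10000` rewired networks and the empirical p-value
$(1 + \#\{Q_{null} \ge Q_{obs}\}) / (1 + n_{null})$.

## Steps vs knockout pleiotropy

A gene's knockout pleiotropy bounds its step count from above. The
randomization test (`step_randomization_test()`) asks whether the observed
Spearman correlation between the two exceeds what the bound alone
produces: under the null, each gene's step count is uniform on
$\{0, \dots, \text{max pleiotropy}\}$. The test draws $10^6$ such datasets
(vectorized, with ranks computed in closed form) and reports the empirical
p-value with resolution floor $1/(10^6 + 1)$. Genes with zero maximal
pleiotropy force ties at zero in both variables and are excluded by
default (`include_zero = FALSE` restores them). Null draws with zero step
variance have undefined correlation and count as not exceeding.

# Synthetic data and the brute-force oracle

Since genome-scale reconstructions cannot be bundled, the package
generates seeded random networks (`make_random_network()`) with three
topologies: independent linear pathways, pathways sharing a precursor
trunk, and pathways consuming a cofactor charged by a shared generator
reaction. GPR rules include isoenzymes (`or`) and complexes (`and`);
stoichiometric coefficients stay small integers so results remain
hand-checkable. Two fixed fixtures, `make_toy1()` (two independent
pathways; biomass optimum 5) and `make_toy2()` (currency-coupled; biomass
optimum 3, generator gene pleiotropic with one step at fraction 0.5),
have fully hand-derived expected values.

Ground truth comes from `oracle_profile()`/`oracle_ko_table()`: a
deliberately naive reimplementation that re-evaluates GPR strings as raw
boolean expressions, rebuilds every LP from scratch (one per component per
grid point, no caching, no bisection) and shares no code path with the
engine. The test suite requires exact agreement on the toys and on 50
seeded networks per topology.

```{r toy2, eval = FALSE}
m <- make_toy2()
ref <- build_reference(m)
sweep_gene(ref, "gE")
#> <pleiotropy_profile gE: knockout pleiotropy 2, 1 steps over 201 grid points>
```

# Numerical and design choices

- **LP solver.** No linear-programming package is available in the target
  environment (`boot::simplex` fails beyond toy sizes and
  `pracma::linprog`'s bounded path mis-handles `lb`/`ub`), so the package
  ships a dense bounded-variable two-phase primal simplex in C++
  (RcppArmadillo), with Dantzig pricing, a Bland fallback against cycling,
  bound flips, and periodic refactorization. It is intended for the
  hundreds-of-variables LPs of the synthetic networks, not for
  genome-scale models, where a commercial or COIN solver should replace it.
  Where `pracma` is available, the test suite cross-checks the solver
  against `pracma::linprog`'s (reliable) inequality/equality path on random
  LPs.
- **SBML I/O** is a hand-written reader/writer over `xml2`: SBML L3V1 with
  the fbc-v2 extension (parameter-referenced bounds written at `%.17g`, so
  numeric round-trips are exact; `geneProductAssociation` trees), plus a
  fallback for legacy COBRA files (kinetic-law `LOWER_BOUND`/`UPPER_BOUND`,
  `GENE_ASSOCIATION` notes, `boundaryCondition` species).
- **Thresholds.** Production reduction threshold $10^{-4}$ (relative),
  wildtype-maximum floor $10^{-9}$, grid step 0.005, pFBA band $10^{-9}$
  relative.
- **Seeds.** All stochastic stages take seeds derived from one master
  seed (`run_pipeline(seed = ...)`); results are reproducible bit-for-bit,
  including the modularity nulls and the randomization test.

# Problem sizes and limitations

The bundled tests and the acceptance script run on networks of roughly
10–40 reactions and up to ~15 genes each; the brute-force oracle
comparison covers 152 networks in about a minute. Published genome-scale
analyses of this kind (e.g. *E. coli* iJO1366, yeast 7.6: mean knockout
pleiotropy ≈ 10.0/12.1 over ~299/222 fitness-contributing genes, bipartite
modularity Q ≈ 0.235 with scaled modularity ≈ 9.1, Spearman ρ ≈
0.926/0.986 between knockout pleiotropy and steps, and currency-mediated
reductions for 55.3%/87.4% of pleiotropic genes) require downloading those
reconstructions and hours of LP solves; they are documented here as
full-scale targets and are deliberately not part of the test suite. The
dense simplex and dense modularity matrices are the main scalability
limits; both are isolated behind small interfaces (`solve_lp()`,
`barber_q()`) and can be swapped for sparse/industrial implementations.
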