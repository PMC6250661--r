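# pleioflux

Allele-resolution pleiotropy analysis in constraint-based metabolic
models.

## The problem

Pleiotropy — one gene affecting many traits — is usually assessed with
full gene knockouts. In metabolism the traits can be made precise: each
biomass component (amino acids, nucleotides, lipids, cofactors) is one
trait, and a gene's pleiotropy is the number of components whose maximal
production its loss impairs. This package goes one step further and
resolves *alleles*: the reactions requiring a gene are capped at a
fraction *f* of their wildtype flux, and the count of affected traits is
traced as *f* sweeps from 1 to 0. Genes whose effects appear in several
*steps* along this sweep hit different traits at different severities —
structure that is invisible to knockout screens.

## Model and algorithms

Given a stoichiometric matrix *S* with bounds *lb ≤ v ≤ ub*:

1. **Wildtype**: parsimonious FBA — maximize biomass flux subject to
   *S v = 0*, then minimize Σ|vᵢ| holding the optimum (±1e-9 relative).
2. **Caps**: every reaction is capped at its wildtype flux,
   sign-respecting: v<sub>i</sub><sup>WT</sup> ≥ 0 ⇒ [0, v<sub>i</sub><sup>WT</sup>],
   else [v<sub>i</sub><sup>WT</sup>, 0] (no rerouting).
3. **Allele f of gene g**: reactions for which *g* is boolean-essential in
   the GPR rule are further capped at f·|v<sup>WT</sup>|. A component
   counts as affected when its maximal production (via a free secretion
   exchange) drops below (1 − 10⁻⁴) of its wildtype maximum.
4. **Sweep**: fractions 1, 0.995, …, 0 (201 points); *steps* = strict
   increases of the count. **Essentiality** variant: free flux
   redistribution within native bounds, only the gene's reactions capped,
   baseline at f = 1.
5. **Currency mediation**: re-run everything with a cofactor pair
   (charged ⇌ discharged) interconvertible by a free reversible reaction;
   report which genes lose pleiotropy.
6. **Modularity**: bipartite gene-trait network from knockout affected
   sets; Barber's Q maximized by LP&BRIM; significance from 10,000
   degree-preserving double-edge-swap nulls (scaled modularity z).
7. **Steps vs pleiotropy**: Spearman correlation against 10⁶ null
   datasets with steps uniform on {0, …, max pleiotropy} per gene.

All LPs are solved by a bundled dense bounded-variable two-phase primal
simplex (RcppArmadillo) — adequate for the synthetic and toy networks the
package ships; swap in an industrial solver behind `solve_lp()` for
genome-scale work. SBML I/O (L3V1 + fbc-v2, plus legacy COBRA fallback) is
included. See `vignette("methods")` for every formula, default and design
decision.

## Worked example

```r
library(pleioflux)

m <- make_toy2()          # currency-coupled toy: generator gene gE charges
print(m)                  # cofactor Xa consumed by both biomass pathways
#> <metabolic_model 'TOY2': 6 reactions, 6 metabolites, 3 genes; biomass = BIOMASS>

ref <- build_reference(m)
#> <wildtype_reference: 2 biomass components, biomass max 3, 2 scorable (wildtype max > 0)>

sweep_gene(ref, "gE")     # both traits lost at once, below fraction 0.5
#> <pleiotropy_profile gE: knockout pleiotropy 2, 1 steps over 201 grid points>

essentiality_count(ref, "gE", 0)
#> $count
#> [1] 2
#> $affected
#> [1] "B1" "B2"

# gE's pleiotropy is entirely currency-mediated:
currency_reduction_analysis(m, attr(m, "currency"))$per_metabolite
#>   name n_reduced fraction_reduced
#> 1    X         1                1

bundle <- run_pipeline(m, n_null = 1000, n_rand = 10000, seed = 1)
bundle$summary
#>   gene ko_pleiotropy essentiality steps fitness_contributing          class
#> 1   g1             1            1     1                 TRUE   pleiotropy_1
#> 2   g2             1            1     1                 TRUE   pleiotropy_1
#> 3   gE             2            2     1                 TRUE all_components
```

Seeded random networks with brute-force ground truth:

```r
rn <- make_random_network(synthetic_spec(topology = "currency", seed = 7))
head(rn$truth)            # gene, ko_pleiotropy, essentiality (oracle-derived)
```

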