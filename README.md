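# agediv

Tools for testing whether the **stem age of higher taxa predicts their
extant species richness** — and whether among-clade variation in
diversification rates could explain an observed *lack* of such a
relationship.

The package is aimed at comparative biologists working with backbone
timetrees (tips = families, orders, or other named clades; branch lengths
in millions of years) paired with per-clade species counts. It provides:

* **Birth-death closed forms.** For a lineage evolving for time *t* at
  speciation rate λ and extinction rate μ (*r* = λ − μ), the progeny count
  has the geometric-tail law *P(N=0) = a_t*,
  *P(N=n) = (1−a_t)(1−b_t)b_t^(n−1)*. Survival-conditioned expectations —
  *e^{rt}/(1−a_t)*, reducing to *N(t) = 1 + λt* for the balanced process
  μ = λ — plus exact samplers and constant-rate ML fitting, with μ > λ
  supported throughout.
* **PGLS and phylogenetic signal.** GLS regression of log-richness on stem
  age under Brownian-motion, Pagel's-Λ or identity covariance; ML
  estimation of Λ; an independent-contrasts variance test; subtree scans
  and age-truncation subsets.
* **A stepwise AICc rate-shift model** for backbone trees with tip
  richness (threshold ΔAICc = A(N−B)^C + D), with extinction allowed to
  exceed speciation.
* **A two-state higher-taxon simulator**: lineages speciate, die, convert
  irreversibly into higher taxa at rate Φ (= current λ by default) and
  shift rate class at rate α; it generates Spearman null distributions for
  the observed age-richness correlation.
* **A hierarchical lognormal relaxed-rate model** (MCMC) with
  posterior-predictive standardized effect sizes,
  SES = (β_obs − mean β_sim)/sd β_sim.
* **Robustness studies**: type-I error of OLS vs PGLS when richness
  carries phylogenetic signal but no age effect, and degradation of a true
  age-richness correlation under clade-age error.
* **Synthetic data generators** with recorded ground truth for all of the
  above.

## Worked example

The package ships a small synthetic higher-taxon compilation (120 clades,
~260,000 species, strong right skew; `inst/extdata/`, labelled synthetic).
Reconcile it with its timetree and ask whether stem age predicts richness:

```r
library(agediv)

tree    <- read_timetree(system.file("extdata", "synthetic_timetree.nwk",
                                     package = "agediv"))
records <- load_richness(system.file("extdata", "synthetic_richness.tsv",
                                     package = "agediv"))
missing <- load_richness(system.file("extdata", "synthetic_missing.tsv",
                                     package = "agediv"))
ds <- reconcile(tree, records, missing = missing, tie_break = "first")$dataset

ds
#> clade dataset: 117 clades, 259,596 species, stem ages 0.351-218 My

pgls_fit(ds)
#> PGLS[BM] regression of log(richness) on stem age (log base 2.718)
#>   beta = 0.0320028 (SE 0.00717), t = 4.462, df = 115, p = 1.904e-05

estimate_lambda(ds)
#> Pagel's lambda ML = 0.9483 (delta AIC vs lambda = 0: 15.28)
```

Here the slope β is the change in natural-log richness per My: about
0.032, i.e. richness grows by roughly e^3.2 ≈ 25× per 100 My of extra
stem age in this synthetic dataset — a clear positive coupling, together
with strong phylogenetic signal in clade size (Λ ≈ 0.95), so an OLS
analysis of these data would not be trustworthy. (This dataset was
*generated* with clade rates independent of the tree, so the detected
slope reflects the age-dependence built into survival-conditioned
growth.) `run_pipeline()`
chains the full analysis — reconciliation, regression and signal tests,
rate-shift fitting, the simulator null, relaxed-rate SES and both
robustness studies — into per-stage TSV/JSON outputs from one config and
one seed.

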