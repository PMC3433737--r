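---
title: "Models and methods for testing age-richness decoupling in higher taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for testing age-richness decoupling in higher taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agediv)
```

# The question

Under any diversification process in which clades tend to grow, older clades
should hold more species. `agediv` implements the comparative machinery for
asking whether that expectation holds across named higher taxa (families,
orders) on an ultrametric timetree: a phylogenetic regression of
log-richness on stem clade age, and two generative models of among-clade
rate variation that serve as nulls for what the age-richness relationship
*should* look like if diversification rates vary among clades in plausible
ways. A decoupling of age and richness that survives both nulls is evidence
against unbounded time-dependent diversity growth.

The data model is deliberately minimal: a rooted, binary, ultrametric tree
whose tips are higher taxa (branch lengths in My), and one extant species
count per tip. The stem age of a tip is defined as the age of its parent
node — equivalently its pendant branch length — because a higher taxon's
crown age is usually unknowable from a backbone tree while its stem age is
determined by the backbone itself.

# Constant-rate birth-death building blocks

Everything downstream rests on the constant-rate birth-death progeny
distribution. For one lineage evolving for time $t$ at speciation rate
$\lambda$ and extinction rate $\mu$ (net rate $r = \lambda - \mu$), the
number of extant descendants $N(t)$ has the classical geometric-tail form

$$P(N = 0) = a_t, \qquad P(N = n) = (1 - a_t)(1 - b_t)\, b_t^{\,n-1},$$

with
$a_t = \mu(e^{rt} - 1)/(\lambda e^{rt} - \mu)$ and
$b_t = \lambda(e^{rt} - 1)/(\lambda e^{rt} - \mu)$. Conditioning on
survival ($N \ge 1$) leaves a geometric distribution with parameter $b_t$,
so the conditioned expectation is $e^{rt}/(1 - a_t)$ and, in the balanced
case $\mu = \lambda$, reduces to $N(t) = 1 + \lambda t$: even a clade whose
diversity performs a fair random walk is expected to grow linearly in age
once we only look at surviving clades. The package's closed forms are
validated against a truncated matrix-exponential of the birth-death
generator, and the sampler is an exact $O(1)$ inverse-CDF draw using the
geometric structure.

Numerical choices: the formulas are evaluated via `expm1`, which removes
the $r \to 0$ cancellation; the exact balanced expressions take over when
$|r|t < 10^{-8}$; $e^{rt}$ overflow switches to the asymptotic forms of
$(a_t, b_t)$; and sampler draws are capped at $10^{15}$, beyond which the
geometric parameter is not representable in doubles (all downstream use is
on the log scale). $\mu > \lambda$ is supported throughout — declining
clades are part of the scientific question, not an error state.

# Phylogenetic regression and signal

`pgls_fit()` regresses $\log N$ on stem age by generalized least squares
with residual covariance proportional to shared path lengths on the
timetree (Brownian motion), a Pagel's-$\Lambda$ transform of it, or the
identity (OLS). The natural log is the default; the base only rescales the
slope, and every result records the base used. Slopes are tested with a
two-tailed $t$ on $n - 2$ df. `estimate_lambda()` profiles the
Brownian-motion root state and rate and maximises over $\Lambda \in [0,1]$,
reporting the AIC difference to the $\Lambda = 0$ model; it is
cross-checked in the test suite against an independent implementation
(`phytools::phylosig`). `contrasts_signal_test()` compares the variance of
standardized independent contrasts to its tip-permutation distribution;
the analytic mode fits a normal to the permuted log-variances so that
extreme signal can be quantified beyond the $1/(B+1)$ floor of the
permutation p-value.

Why the phylogeny matters here is itself demonstrated by simulation
(`type1_error_study()`): when log-richness carries phylogenetic signal but
is independent of age by construction, OLS rejects the true null far above
its nominal level while PGLS does not. The inflation is driven by the
*alignment of stem ages with clade membership*: on a homogeneous Yule
backbone the effect is modest, but on backbones whose clades radiated at
different tempos — young dense radiations beside old depauperate lineages,
the signature of real higher-level timetrees — OLS rejection rates reach
0.4-0.7 at $\Lambda \approx 0.72$. The `yule_shift` backbone generator
exists precisely to reproduce this regime; PGLS with the generating
$\Lambda = 1$ covariance stays within binomial error of the nominal level,
and under $\Lambda = 0.724$ generation PGLS(BM) is conservative (the safe
direction of miscalibration).

# The stepwise rate-shift model

`stepwise_fit()` re-implements forward stepwise AICc selection of
diversification rate shifts on a backbone tree with tip richness. The
likelihood is an exact pruning density of the observed data: a pendant
edge contributes the probability of the tip's richness — the
survival-conditioned progeny probability times the clade's survival
probability over the stem branch — and an internal edge contributes the
probability that the lineage leaves exactly one descendant with observed
progeny while its other descendants die out, times the speciation density
at the child node. Keeping the per-tip survival factors on the stem edges
(rather than dividing every tip term by survival and leaving the backbone
terms untouched) is essential: the conditioned-only hybrid is not a proper
density and degenerates toward infinite balanced rates.

Each candidate shift paints a node's stem branch and subtree until any
nested shift overrides it. A candidate's score refits the new class *and*
every class that loses edges; the accepted shift is then followed by a
full class-by-class refit (the classes partition the edges, so the joint
ML factorises). Rates are optimised in $(\log\lambda, \log\mu)$, which
allows $\mu > \lambda$ smoothly and avoids the coordinate singularity of a
relative-extinction parameterisation at $\varepsilon = 1$. Ties in AICc
break toward the lowest postorder node index, making reruns deterministic.
The stopping threshold is the sample-size-dependent curve
$\Delta\mathrm{AICc} = A(N - B)^C + D$ with the GEIGER coefficients
($A=-35.94105$, $B=6.73726$, $C=-0.10062$, $D=27.51668$); $N$ defaults to
the number of tips and is configurable, since the appropriate sample size
for backbone-plus-richness data is genuinely ambiguous. Parameter count is
$np = 3 \cdot \mathrm{shifts} + 2$ (two rates per class plus one location
per shift).

# The two-state higher-taxon simulator

To ask what age-richness relationship a fitted shift model *predicts*, the
package simulates the joint origin of backbone trees and higher taxa.
Units are individual lineages and higher taxa; lineages speciate
($\lambda$), die ($\mu$), irreversibly convert into higher taxa ($\Phi$)
and shift rate class ($\alpha$, resampling with replacement from the
fitted pool). Waiting times are exponential with total rate
$\beta = \lambda + \mu + \Phi + \alpha$ per lineage and event identities
are sampled proportional to rates — a Gillespie engine over the lineage
set, with no time discretisation. A taxon formed at $T_1$ inherits its
parent's rates and draws its present-day richness from the unconditioned
progeny distribution over $T_c - T_1$, so taxa can die. $\Phi$ tracks the
current $\lambda$ by default: a reconstructed backbone over $N$ taxa
contains $N - 1$ speciation events, so the two rates must be roughly
balanced for the simulated trees to resemble observed ones. Lineages that
reach the present unconverted are kept as richness-1 terminals by default
(`drop_unconverted` inverts this); their stem ages, like every terminal's,
are read from the pruned surviving-terminals tree, since true formation
times are unobservable. Simulations start from two lineages at the crown
age, require at least one surviving terminal pair, and are rejected when
the terminal count leaves the 50-150% band around the observed count.

Each accepted dataset yields a Spearman correlation between reconstructed
stem age and richness; the observed correlation is scored against this
null with a one-tailed lower p-value (pseudocount +1). Under constant-rate
pools the null mean correlation is strongly positive and grows with the
terminal count. Whether rate heterogeneity lowers the null mean is
regime-dependent: with pools matched in overall tempo, heterogeneity
dilutes the correlation as expected, but pools that also deepen the
stem-age spread can raise it — the property test uses the matched
comparison.

# The relaxed-rate hierarchical model

As a phylogeny-free alternative, `run_mcmc()` fits clade net rates
$r_i \sim \mathrm{LogNormal}(m, s)$ with the survival-conditioned richness
likelihood at fixed relative extinction $\varepsilon$ (0 and 0.99 mirror
the low- and high-turnover readings of the same data). Priors, unstated in
the source analyses and therefore chosen here, are weakly informative:
$m \sim N(0, 10^2)$ and $s \sim \mathrm{halfCauchy}(1)$; both are
configurable. The sampler is Metropolis-within-Gibbs: a conjugate normal
update for $m$, log-scale random walks for $s$ and the $r_i$ (the latter
vectorised, since the $r_i$ are conditionally independent), with proposal
scales adapted during burn-in and frozen afterward so the retained chain
is Markovian. Convergence is monitored with split-$\hat R$ and
autocorrelation ESS on the hyperparameters.

`posterior_predictive()` draws fresh clade rates from the
hyperdistribution of a sampled posterior state (a flag switches to the
fitted per-clade rates) and simulates richness at the observed stem ages
on the fixed tree. `standardized_effect_size()` then scores the observed
PGLS slope as $\mathrm{SES} = (\beta_{obs} - \bar\beta_{sim})/
\sigma_{sim}$, reporting both the empirical tail probability and its
normal approximation, because with a few hundred predictive draws the
empirical tail saturates at $1/n_{sim}$ while the normal version can
express more extreme displacement. Since the model couples age and
richness, predictive slopes are positive whenever $s$ is not enormous; a
negative SES on real data therefore says the observed coupling is weaker
than any lognormal-rates explanation allows.

# Robustness studies

Two simulation studies probe the inference itself. The signal study
(above) quantifies type-I error of OLS versus PGLS on signal-only data.
The age-error study holds a fixed age vector, draws richness from a
survival-conditioned constant-rate process (defaults
$\lambda = 0.71, \mu = 0.64$, rates of the scale estimated for large
angiosperm radiations), perturbs each age with
$N(0, (\delta T)^2)$ noise resampled until positive — resampling, not
clipping, which deliberately skews perturbed ages upward for large
$\delta$ — and correlates log-richness with the perturbed ages across
$\delta \in \{0.1, \ldots, 0.6\}$ (Pearson by default, Spearman
available). At $\delta = 0.6$ a 100-My clade has a nominal 95% age
interval of $(0, 217.6)$ My, yet the correlation distribution remains
predominantly positive: even severe dating error does not manufacture
age-richness decoupling.

# Synthetic data and what passing tests mean

`generator_spec()`/`generate_clade_dataset()` produce backbone trees
(forward-simulated Yule with exact exponential order statistics;
reconstructed birth-death via `ape::rphylo`; `yule_shift` for
rate-heterogeneous backbones) and richness under four models:
`constant_rate` (age predicts richness), `lognormal_relaxed`,
`bm_signal_only` (signal without any age effect; regression studies use
the unrounded log values, pipeline stages the rounded integer counts),
and the delegated `higher_taxon_process`. Ground truth (rates, signal
parameters, seeds) is recorded so every generated value replays exactly.
The packaged example compilation (120 clades, ~260k species, one
dominant clade) was generated once from the `lognormal_relaxed` model at
$m = -3.4$, $s = 0.55$, $\varepsilon = 0.3$ on a 350-My Yule backbone —
values chosen to reproduce the strong right skew and 1-to-$10^5$ richness
range of real higher-taxon compilations — and is labelled synthetic in its
filenames.

The generators emulate the statistical structure the analyses assume:
ultrametric backbones, right-skewed richness, lognormal rate spread,
tunable signal. They do not emulate taxonomic name structure, incomplete
or uneven sampling of the timetree, dating error correlated across related
clades, or the non-random way systematists delimit higher taxa. Passing
tests therefore certify the machinery — estimators recover known truth,
nulls are calibrated under self-simulation, type-I error behaves as the
theory says — not that any empirical dataset will show a particular
result.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the targeted effects are
unambiguous: 80-tip trees with 15-30-tip planted clades for shift
recovery (50 replicates), 150 clades for hyperparameter recovery (50
replicates, 4,000 MCMC iterations), 300-tip backbones and 400-500
datasets for the type-I study, and nulls of 60-150 accepted simulations
for calibration checks. Defaults on the user-facing functions are larger
(e.g. 4 chains of 50,000 MCMC states, 5,000-simulation nulls) and are the
settings a full analysis would use. All randomness flows from explicit
seeds; the pipeline derives per-stage child seeds from one global seed and
records them in every output file.

# Known limitations

* The backbone likelihood treats each rate class's extinction-to-present
  probability under its own class even where descendants are governed by a
  nested shift; this mirrors the local-likelihood structure of the
  original stepwise method and keeps candidate scoring separable.
* Stem ages of pruned or truncated datasets are clade properties inherited
  from the full tree, so re-derived covariances after pruning are exact
  but pendant "ages" shown by the pruned tree alone would differ.
* The relaxed-rate model deliberately has no phylogenetic correlation in
  rates; the simulator and shift model carry all phylogenetic structure.
* No time-varying or diversity-dependent likelihoods are fitted; they are
  part of the interpretation space, not of this package's scope.
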