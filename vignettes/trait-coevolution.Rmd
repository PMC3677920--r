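---
title: "Modelling correlated evolution of discrete reproductive traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling correlated evolution of discrete reproductive traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevotraits)
```

## The scientific problem

Leiobunine harvestmen ("daddy long-legs") of eastern North America divide
into species in which males carry paired penile sacs that deliver a
nuptial gift during courtship (S+) and species that lack them (S-), while
females either have an unarmed genital operculum (B-) or a sclerotized
pregenital barrier (B+) that impedes forced intromission.  Male pedipalps
are likewise either simple (P-) or enhanced for clasping (P+).  The
comparative questions are: in which direction and how often did these
traits change; do sac loss and barrier gain evolve together; and does
change in one sex tend to precede change in the other?

`coevotraits` implements the full analysis chain for questions of this
kind: constrained continuous-time Markov (Mk-type) models of discrete
characters evaluated over a posterior sample of trees, Bayesian model
comparison through marginal likelihoods, hierarchical ancestral-state
reconstruction, stochastic character mapping with dwell-time association
statistics, and asymmetric parsimony.  A synthetic-data module generates
trees and characters with the statistical structure the analysis assumes,
so every stage is testable without molecular data.

## Trait models

A character with $k$ states evolves along each branch as a
continuous-time Markov chain with generator $Q$; off-diagonal entries
$q_{ij} \ge 0$ are per-unit-length transition rates and rows sum to zero.
A `rate_model_spec` is a $k \times k$ template whose off-diagonal cells
are either structural zeros or parameter slots; shared slot indices
impose equality constraints.  Five model structures ship as constants:

* `male_6rate()` — three male states (S+P-, S-P-, S-P+), all six directed
  transitions free ("no precedence"); optionally with the root fixed in
  the sacculate state.
* `male_2rate()` — only sac loss followed by pedipalp enhancement
  ("penis precedence").
* `indep_4rate()` — four joint penis/barrier states; penis rates shared
  across barrier states and vice versa (independent evolution).
* `dep_8rate()` — all eight single-step transitions free (dependent,
  "precedence possible").
* `dep_7rate_noprec()` — as `dep_8rate()` but barrier gain and sac loss
  out of the ancestral S+B- state share one rate.

Transitions that would change both characters at once are structural
zeros in all joint models, and the joint state order is
(S+B-, S+B+, S-B+, S-B-).  `joint_embedding()` builds the independent
4-state model from two binary models; its likelihood factorizes exactly
into the two marginal likelihoods, which the tests verify to 1e-10.

The likelihood on a rooted tree is computed by Felsenstein pruning with
per-branch transition probabilities $P(t) = e^{Qt}$.  Matrix exponentials
use an eigendecomposition when $Q$ is numerically diagonalizable
(verified once per generator against a scaling-and-squaring exponential
at the longest branch, tolerance 1e-9) and fall back to
`Matrix::expm()` otherwise.  Missing tips contribute all-ones partial
likelihoods.  Root states are weighted uniformly, fixed to one state, or
by observed tip frequencies (`root_policy()`).

```{r models}
Q <- build_generator(dep_8rate(), c(0.3, 0.3, 1.5, 1.5, 0.3, 0.3, 1.5, 1.5))
round(Q, 2)
```

## Rate inference and model comparison

`run_mcmc()` samples the free rates by Metropolis–Hastings: per
iteration one rate (chosen uniformly) receives a sliding-window
perturbation of half-width `rate_deviation`, reflected at the uniform
prior bounds, and the tree is independently resampled uniformly from the
tree sample; the joint proposal is accepted by likelihood ratio.
Resampling the tree every iteration is a valid sampler for the posterior
averaged over the fixed tree sample.  `tune_rate_deviation()` doubles or
halves the proposal width until the realized acceptance rate falls in
the 20–40% window, clamped to [0.001, 2].

Marginal likelihoods are approximated by the stabilized harmonic mean of
Newton and Raftery applied to the post-burn-in log-likelihood trace, with
stabilization weight $\delta = 0.01$ (the plain harmonic mean, recovered
at $\delta = 0$, has infinite variance).  The standard error comes from
bootstrap resampling of the trace (1000 replicates by default).  Models
are compared by the Bayes factor $K = |\Delta \log m|$ or, for nested
pairs, by $\chi^2 = 2\,\Delta \log m$ referred to a chi-square
distribution with the difference in free-parameter counts as degrees of
freedom.  Forming a likelihood-ratio statistic from *marginal* rather
than maximized likelihoods mirrors the BayesTraits-era workflow this
package replicates; it is statistically unorthodox, and the p-values
should be read as heuristic model-choice summaries, not frequentist
error rates.  Pooling independent runs uses the mean of run means and
the mean of run SEs, the convention of the replication target's summary
table.

Default chain lengths are desk-scale ($5 \times 10^5$ iterations,
thinning 100, 30% burn-in); production-scale runs in the $10^8$–$10^9$
range are reachable through `mcmc_config()`.

### Priors and identifiability

The default rate prior is uniform on (0, 100], per unit of tree length.
A single categorical character on a few dozen taxa carries limited
information about eight rates: beyond a few expected changes per unit
height the likelihood flattens onto a saturation plateau, and under a
very diffuse uniform prior the plateau's sheer prior volume can dominate
the posterior.  The packaged parameter-recovery experiment therefore
bounds the prior at 3 per unit tree height — comfortably above every
generating rate it uses — and with that prior the true rates fall inside
the 95% credible intervals for at least 7 of 8 rates on average across
seeds.  Users analysing real data should choose the prior bound with the
same consideration in mind.

## Hierarchical ancestral states and stochastic mapping

For a binary character the generator is parameterized by an overall rate
$r$ and a stationary bias $b$ (equilibrium frequency of the derived
state): $q_{01} = rb$, $q_{10} = r(1-b)$.  The bias prior is either
empirical (point mass at the observed tip frequency) or a symmetric
$\mathrm{Beta}(\alpha, \alpha)$; the rate prior is
$\Gamma(\alpha_s, \beta_r)$.  Both are integrated by fixed-grid
discretization — Beta on midpoints, Gamma on equal-probability quantiles,
25 points per dimension by default — rather than nested MCMC; the grids
make every fit deterministic and testable.  `fit_bias_prior()` and
`fit_rate_prior()` maximize the tree-averaged marginal likelihood over
log-spaced hyperparameter grids refined once; the overall-rate anchor for
the bias fit is the profile estimate at $b = 1/2$.  The hyperparameters
fitted in the original harvestman study ship as presets
(`preset_priors()`): Beta shape 5.888/5.906 and Gamma (3.515, 0.038) /
(3.108, 0.036) for the penis and barrier characters.

Note one structural limitation: the symmetric Beta bias prior puts equal
mass on both extreme biases, so a strongly biased character is supported
through small $\alpha$ only when the data can rule out the opposite
extreme; near-invariant characters may instead fit large $\alpha$.

`root_marginal_posterior()` averages, over trees and the prior grid,
the pruning-computed root posterior with stationary root weights.
`stochastic_map()` draws full character histories: node states from
their joint conditional distribution (root first, then each child given
its parent), then branch paths conditioned on their endpoints by
rejection sampling (forward simulation until the endpoint matches, cap
$10^5$ tries) with an exact uniformization sampler as fallback.
Tests verify that endpoint-conditioned change counts match the
uniformization distribution and that map node-state frequencies converge
to enumeration-based posteriors.

The association between two mapped characters is summarized by
$m_{ij} = \mathrm{E}[J_{ij} - p_i q_j]$ — the mean excess of the joint
dwell fraction in state pair $(i,j)$ over the product of the marginal
dwell fractions — and the overall $M = \sum_{ij} |m_{ij}|$.  Significance
comes from predictive sampling: both characters are re-simulated
independently from their priors on the same trees, the statistics
recomputed, and a two-tailed p-value taken as twice the smaller tail
fraction, capped at 1.  Ten maps per tree with ten prior draws is the
default bookkeeping (431 trees give the 43,100 predictive samples of the
replication target).

## Parsimony

`fitch_count()` implements the classic intersection/union pass for
unordered characters on binary trees; `sankoff()` implements the general
dynamic program for arbitrary nonnegative cost matrices, polytomies and
missing tips, and reports the per-node sets of states attainable in some
globally optimal labeling plus one deterministic labeling (ties broken
toward the lower state index, assigned root-down).  "No parallel gains"
of a complex structure is encoded by `dollo_costs()`: loss costs 1,
regain carries a prohibitive finite cost of $10^6$, avoiding infinite
arithmetic while making regains impossible in any minimal
reconstruction.  Transition counts for a directed change are read off
the labeling with `count_transitions()`.

## Synthetic data

`simulate_yule_tree()` grows a pure-birth tree: the root split opens two
lineages at time zero, the wait from $k$ to $k+1$ lineages is
$\mathrm{Exp}(\lambda k)$, the process stops at the birth of the
$n$-th lineage, and all tips extend to that final event time.  The
expected root height is therefore $\sum_{k=2}^{n-1} 1/(\lambda k)$,
which the tests check against 2000 simulated trees.  Tree samples are
independent Yule trees over one label set — with an outgroup clade
attached below the ingroup and padded stems keeping the tree ultrametric
— optionally with lognormal branch-length jitter emulating posterior
spread.  This emulates the *product* of a Bayesian tree inference (a
sample of ultrametric trees with topological variation), not the
inference itself: real posterior samples concentrate around one
topology, whereas these topologies are exchangeable draws, so
backbone-filtering pass rates are lower than for a real posterior.

Characters are simulated on the first tree of the sample under four
regimes with the root fixed in the ancestral courtship state S+B-:
`INDEPENDENT` (two uncoupled binary characters via the joint embedding),
`DEPENDENT` (all eight rates free, transitions *into* the concordant
states S+B- and S-B+ five times faster than into the discordant ones),
`PRECEDENCE` (sac loss out of S+B- much faster than barrier gain), and
`MALE_CHAIN` (the 3-state male character under the 2-rate chain).  The
default base rate is 0.3 per unit height, giving a handful of expected
changes on a 29-taxon Yule tree — enough variation to be informative
without saturating.  The 3-state male character is derived from the S
history plus an independent pedipalp overlay masked so P+ never co-occurs
with S+, matching the empirical absence of that combination.  Simulation
retries (deterministically, at most 40 times) until both binary
characters vary at the tips, mirroring the ascertainment of variable
traits.

`make_paper_like_fixture()` is a hand-built, clearly synthetic 29-taxon
ultrametric tree whose tip states reproduce the published census — two
taxa with both sacs and barrier, one with neither, the rest S+B- or
S-B+ — with the four barrier-bearing clades each sister to a sacculate
clade so the four gains (and five Dollo sac losses) are phylogenetically
independent.  It makes no claim of matching the true phylogeny; it
exists so the parsimony claims have a reproducible, text-only input.

```{r fixture}
fx <- make_paper_like_fixture()
table(state_labels(fx$sb))
sk <- sankoff(fx$tree, fx$s, dollo_costs(fx$s$state_space))
count_transitions(fx$tree, sk$labeling, "S+", "S-", fx$s$state_space)
```

## The pipeline

`run_pipeline()` chains the stages — synthetic simulation or file input,
optional backbone filtering, at least four independent MCMC runs per
model with bootstrap marginal likelihoods, the per-run summary table,
Bayes factors and LRTs with automatic degrees of freedom, hierarchical
root posteriors, stochastic-mapping association with a predictive null,
and Dollo parsimony on the MCC tree — under one master seed from which
every stage derives its own seed, so any stage can be rerun in
isolation and whole reports are byte-reproducible.

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(
  scenario = scenario_config(n_taxa = 29, n_outgroup = 4, n_trees = 50,
    scenario = "DEPENDENT"),
  mcmc = mcmc_config(iterations = 2e4, thin = 10),
  seed = 1
))
print(report)
```

## Numerical choices and limitations

* Pruning partials are rescaled when they fall below 1e-200; path sums
  for the ultrametricity check accumulate root-down with relative
  tolerance 1e-6.
* Clade identity is the set of descendant leaf labels on the rooted
  tree; MCC ties break to the earliest sample index.
* Grid discretization of the hierarchical priors trades smoothness for
  determinism; 25 points per dimension is ample for binary characters,
  and the pipeline's smaller default grids are a speed choice.
* Two-tailed predictive p-values are `2 * min(tail fractions)` capped at
  1; with a finite number of predictive replicates they are discrete.
* The test suite and examples run at desk scale (tens of taxa, chains of
  $10^3$–$10^4$ iterations, tens of replicates); they exercise the same
  code paths as production-scale analyses but their Monte-Carlo
  tolerances are set for those sizes.
* The association test's paired maps must live on identical trees; the
  package does not attempt continuous characters, rate variation across
  branches within one likelihood, hidden-state models, or
  stepping-stone/path-sampling marginal likelihoods.
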