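---
title: "Epoch-stratified CTMC models of trait and biome evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epoch-stratified CTMC models of trait and biome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(perishift)
```

## The scientific problem

Desert plant lineages often carry drought-tolerance traits that appear to
predate the deserts they live in. One way to test whether such traits are
adaptations to aridity or exaptations (preadaptations acquired in older
settings, e.g. on bare rock outcrops inside wetter biomes) is to put
discrete-trait evolution and biome occupancy on a common time-calibrated
phylogeny and ask, with explicit models, (i) which transition rates are
credibly nonzero, (ii) whether two traits evolved dependently, and (iii)
whether biome shifts track the availability of biomes through geological
time. `perishift` implements that toolkit: continuous-time Markov chain
(CTMC) models of discrete characters on chronograms, with rate matrices
that may change at geological epoch boundaries and may be informed by
paleogeographic and paleobiome structure.

## Model components

### Chronograms and epoch stratification

A chronogram is a rooted ultrametric tree with branch lengths in Ma; node
ages are measured back from the present. Ultrametricity is enforced at
construction with a relative tolerance of `1e-6` of the root age, because
divergence-dating software prints rounded branch lengths. Epochs tile time
back from the present; intervals are half-open `[end, start)` looking
backward, and ages older than the oldest epoch's start belong to the
oldest epoch. A branch crossing an epoch boundary is split there, and its
transition probability matrix is the product of per-segment matrix
exponentials ordered from the parent (older) end to the child (younger)
end. The product does not commute, so this orientation is part of the
contract and is tested.

### Likelihoods

`prune_likelihood()` is Felsenstein pruning with per-edge rescaling (so
150+ tip trees do not underflow), implemented in C++ with one spectral
decomposition per epoch per evaluation and a dense scaling-and-squaring
matrix exponential fallback whenever the generator is defective or its
eigenvector matrix is ill-conditioned (reconstruction error above
`1e-9` relative). The root is summed under a root prior; the default is
flat over states because the reference Bayesian implementations do not
document their root treatment, and a stationary-distribution option is
provided. Marginal ancestral states come from the standard
upward/downward pass; reports include the maximum a posteriori (MAP)
state and, whenever its posterior probability falls below 0.9, the
second-ranked state ("split circle" reporting). MAP ties break by
alphabet order, deterministically.

### Stochastic mapping

`stochastic_map()` samples joint node states from the pruning partials
and then branch histories conditional on endpoint states, by forward
rejection sampling with a cap of 1,000 attempts per branch; after the cap
it switches to a uniformization bridge (segment endpoint states are first
drawn from the segment-product bridge, then each homogeneous segment is
bridged exactly). The cap guarantees termination on long branches with
awkward endpoint constraints; both samplers target the same conditional
law, which the tests verify against the closed form
`E[N | equal endpoints] = qt tanh(qt)` for a symmetric binary chain.

### Reversible-jump MCMC over zero/nonzero rates

For a k-state character, each ordered pair (i, j) carries an indicator
`delta_ij`; `delta_ij = 0` pins the rate at zero. Both indicator values
have prior probability 1/2, and active rates have an exponential prior.
The prior mean defaults to `10 / tree length` — ten expected events
across the whole tree, a weakly informative scale that adapts to the
tree; it is configurable because Bayes factors depend on it. Dimension
jumps draw the new rate from its prior, so the acceptance ratio reduces
to the likelihood ratio; this makes prior-only runs an exact check of the
sampler (each indicator must sit at 0.5, active rates at their prior
moments), which the suite performs. Each iteration makes one indicator
move on a random pair and one log-scale multiplier move on a random
active rate. The default chain is 15,000 iterations with 10% burn-in and
node states sampled every 10 iterations, mirroring the scale of a
13,500-sample posterior while staying desk-sized; two chains run by
default and a Gelman-Rubin-style PSRF on the log posterior is logged,
not enforced.

Bayes factors are indicator-count ratios: posterior odds of the nonzero
model, with no prior correction since the prior odds are 1. When no
sample visits the zero model the BF is reported as infinite ("Inf.").
`2logBF` is read on the Kass-Raftery bands: `[0,2)` equivocal, `[2,6)`
strong, `[6,Inf]` decisive. HPD intervals are shortest order-statistic
windows containing `ceiling(0.95 n)` samples. Note that the BF and the
HPD summarise different aspects of the same trace (model visits vs
pooled rate samples including zeros); a transition can be decisively
nonzero by BF while its pooled 95% HPD touches zero.

### Correlated evolution of two binary characters

`fit_independent()`/`fit_dependent()` are maximum-likelihood fits of the
classic dependent (8 free rates) and independent (4 free rates) CTMCs on
the combined 4-state space, with dual transitions fixed at zero.
We chose ML with the statistic `2(logL_dep - logL_ind)` rather than an
MCMC treatment: the quantities of interest are point log-likelihoods and
a decision statistic read on the same bands as 2logBF, and ML is
deterministic, fast, and directly testable (nesting guarantees a
non-negative statistic; simulation calibration checks both error rates).
The optimizer is multistart (default 10 starts) bounded L-BFGS-B on
log-rates with bounds `[-12, 3]`; the first start is an events-per-unit-
length heuristic and the rest are drawn log-uniformly. A chi-squared
(4 df) tail probability is reported as a frequentist reference alongside
the band.

### The paleobiome-informed biome-shift model

Composite states are (area, biome) pairs, flattened area-major. Three
rate graphs are mixed by a simplex `w = (w_u, w_g, w_b)` shared across
event classes (the reference analysis does not state whether weights
were shared; sharing is this package's contract and reproduces the
`w_u/w_g/w_b` decomposition of its weight table):

* dispersal `(a,b) -> (a',b)`: `delta * (w_u + w_g G_k[a,a'] + w_b B_k[a',b])`
* biome shift `(a,b) -> (a,b')`: `beta * (w_u + w_g + w_b B_k[a,b'])`
* simultaneous area and biome change: rate 0 (anagenetic-only; no
  cladogenetic component — subset-sympatry belongs to range-evolution
  models outside this package's scope).

`G_k` (area adjacency, symmetric) and `B_k` (area x biome availability)
take values in `{0, weak, 1}` per epoch; "weak" defaults to 0.1, a
declared convention (the qualitative sources say only "weak
connectivity"), overridable in the config so its sensitivity can be
explored. The bundled `paleo_perityleae()` preset encodes four areas,
four biomes, and four epochs (33.9-23, 23-16, 16-5.3, 5.3-0 Ma), with
South America isolated in every epoch, the Baja California-mainland
connection decaying strong/strong/weak/zero, and desert availability
growing zero/zero/weak/strong. Because `w_u` multiplies an all-ones
graph, zero adjacency never makes a destination unreachable — rare
long-distance dispersal (e.g. into the isolated southern area) stays
representable.

`biome_mcmc()` samples `delta`, `beta` (exponential priors, mean
`10 / tree length`) and the weights (flat Dirichlet prior; proposals are
Dirichlet centred on the current weights with concentration 50 plus a
0.5 offset to avoid sticking at the boundary). An optional
reversible-jump indicator pins `w_b` to 0 with equal prior odds; the
birth move draws the new `w_b` from its conditional prior Beta(1,2), so
— after the simplex-contraction Jacobian `(1 - w_b)` cancels against the
proposal and prior densities — the acceptance ratio is again the bare
likelihood ratio. The default chain is 25,000 iterations with 6%
burn-in. Ancestral composite states are model-averaged by redrawing
joint node states per retained iteration; with full histories enabled,
`count_biome_shifts()` tallies, per history, the branches on which the
biome component enters a target biome, giving a posterior distribution
of independent shift counts.

## The synthetic-data generator

`simulate_chronogram()` produces birth-death trees conditioned on the
tip count (forward simulation with rejection on extinction, via
`ape::rphylo`), then rescales linearly so the crown age is hit exactly;
backward/coalescent-style samplers are unnecessary at the tree sizes
used here (n <= 200). Defaults (n = 73 tips, crown age 15.8033 Ma,
birth 0.25 / death 0.05 per Ma) emulate a medium-sized radiation whose
crown age sits inside a 7.93-23.22 Ma calibration window.
`simulate_character()` draws the root from the model's root prior and
runs a forward Gillespie walk along each branch, re-drawing waiting
times at epoch boundaries (valid by memorylessness), and records the
full event history so recovery tests can compare against truth.

`make_perityleae_like_dataset()` assembles the full study system: the
life-history character evolves from a suffrutescent root with elevated
suffrutescent-to-other rates (generating values 0.0141, 0.0107, 0.0053
events/Ma, plus herbaceous-to-shrub 0.0055, all other rates zero —
mirroring the asymmetric posterior-mean pattern the preset emulates);
the edaphic character evolves dependently on the caudex (bare-rock
gains at 0.06/Ma on caudex-bearing lineages vs 0.002/Ma otherwise, and
losses at 0.10/Ma after caudex loss vs 0.01/Ma with it — a strong,
recoverable dependence); and the composite biome-area character evolves
under the preset with generating weights (0.303, 0.247, 0.45) and base
rates delta = 0.05, beta = 0.08 events/Ma, enough to yield multiple
desert entries after desert biomes become available. What this generator
does **not** emulate: cladogenetic state change, range polymorphism
(each tip holds one composite state), diversification-rate dependence on
states, and phylogenetic error — passing tests demonstrate correctness
of the inference machinery under the model, not robustness of the
biological conclusions to model violations on real data.

## Numerical choices

* Ultrametricity tolerance relative `1e-6`; offending tips are named.
* Generator exponentials: spectral fast path with `expmat` fallback;
  transition matrices are clamped at zero from below; row-sum error is
  property-tested below `1e-10`.
* Partial likelihoods rescaled per edge; log-scale accumulated.
* Pruning validated against exhaustive enumeration to `1e-10` on
  hundreds of random stratified trees; identical-epoch splitting exact
  to `1e-12` over 1,000 random branches.
* MAP ties break by alphabet order; split-state reporting threshold 0.9.
* Optimizer bounds log-rate in `[-12, 3]`; non-finite likelihoods are
  penalised rather than propagated.
* All samplers take explicit integer seeds; identical seeds reproduce
  traces bit-for-bit (tested).

## Validation problem sizes

The test suite exercises: 200 random trees (<= 6 tips, <= 4 states,
<= 3 epochs) against the enumeration oracle; 1,000 random branches for
epoch-splitting exactness; 10,000 prior-only rjMCMC iterations; 20
calibration replicates of 150-tip datasets for indicator Bayes factors;
20,000 stochastic maps on a fixed 4-tip tree; 2 x 20 correlated-evolution
replicates on 200-tip trees; 20 paired biome-shift recovery replicates
(150 tips, 5,000 iterations each); and a 30-tip end-to-end pipeline.
These sizes were chosen to keep each property statistically sharp (3
Monte-Carlo-SE bands, binomial error-rate bounds) while remaining
desk-sized.

## Known limitations

* Anagenetic-only biome model; no cladogenetic events, no polymorphic
  ranges, no diversification feedback.
* The rjMCMC explores zero/nonzero rate configurations, not arbitrary
  rate equality constraints.
* Bayes factors depend on the active-rate prior mean; the default
  (`10 / tree length`) is a documented convention, not an estimate.
* The correlated-evolution test is ML-based; an MCMC variant with
  stepping-stone marginal likelihoods is out of scope.
* Per-event-class weight simplices (rather than one shared simplex) are
  a known variant of the biome-shift model and are not implemented.

## A worked end-to-end run

```{r example}
bundle <- make_perityleae_like_dataset(seed = 42)

lh <- rjmcmc_run(bundle$tree, bundle$life_history,
                 iterations = 15000, seed = 1)
bf_report(lh)

anc <- model_averaged_ancestral(lh, bundle$tree)
head(anc$summary)

xy <- paired_binary_traits(bundle$caudex, bundle$edaphic)
cmp <- compare_models(fit_independent(bundle$tree, xy),
                      fit_dependent(bundle$tree, xy))
cmp

bt <- biome_mcmc(bundle$tree, bundle$biome_area, bundle$paleo,
                 iterations = 25000, seed = 7)
biome_summary(bt)

anc_b <- biome_ancestral(bt, bundle$tree, bundle$biome_area,
                         bundle$paleo, full_history = TRUE)
count_biome_shifts(anc_b$maps, "desert")$distribution
```
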