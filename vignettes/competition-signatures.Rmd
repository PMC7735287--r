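---
title: "Detecting signatures of interspecific competition in trait evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting signatures of interspecific competition in trait evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsig)
```

## The question and the models

Standard models of continuous-trait macroevolution assume lineages evolve
independently once they split. Competition between coexisting relatives
violates that assumption in two characteristic ways: evolutionary rates may
track the number of coexisting competitors (diversity dependence), and
trait values may be actively repelled from the trait values of competitors
(character displacement). `compsig` fits and compares seven models of a
continuous trait $x$ on a time-calibrated, ultrametric phylogeny of depth
$T$, with time $t$ running from 0 at the crown root to $T$ at the present:

* **BM** — Brownian motion with rate $\sigma^2$ and root state $z_0$.
* **OU** — Ornstein–Uhlenbeck with pull $\alpha \ge 0$ towards $z_0$:
  $dx = \alpha(z_0 - x)\,dt + \sigma\,dW$. We use the root-conditioned,
  non-stationary form on ultrametric trees: for tips $i, j$ whose ancestor
  lived at $t_{ij}$,
  $\mathrm{Cov}(x_i, x_j) =
  \frac{\sigma^2}{2\alpha} e^{-2\alpha (T - t_{ij})}
  (1 - e^{-2\alpha t_{ij}})$.
* **TDlin / TDexp** — time-dependent rates
  $\sigma^2(t) = \sigma^2 + b_t\,t$ or $\sigma^2(t) = \sigma^2 e^{r_t t}$
  ($r_t < 0$ is the classical early burst).
* **DDlin / DDexp** — diversity-dependent rates
  $\sigma^2(t) = \sigma^2 + b_n\,n(t)$ or
  $\sigma^2(t) = \sigma^2 e^{r_n n(t)}$, where $n(t)$ is the reconstructed
  lineage-through-time step function.
* **MC** — matching competition: each lineage $i$ alive at $t$ receives
  drift $S\,(\mu_i(t) - x_i)$ with $\mu_i$ the mean trait over lineages in
  $i$'s interaction set and $S \le 0$, so traits are repelled from the
  local mean.

All seven models are Gaussian at the tips, $x \sim N(z_0\mathbf{1},\,
\sigma^2 V_0(\theta))$, with a model-specific unit-rate structure matrix
$V_0$ and at most one shape parameter $\theta$. For BM, OU and the TD
models $V_0$ is an elementwise transform of the shared-time matrix. For the
DD models the covariance of two tips is the integral of the rate along
their shared root path. For MC we propagate the joint covariance of all
alive lineages through time: between events (branching times and regime
changes) the drift matrix $A = S(P - I)$ is constant, where $P$ averages
over each lineage's interaction set including itself. Because $P$ is a
symmetric projection, $e^{Ah} = P + e^{-Sh}(I - P)$, and the Lyapunov
update of the covariance over an interval of length $h$ is available in
closed form — each interval costs one set of grouped matrix products, no
numerical ODE integration. The MC tip mean is identically $z_0$ because
$P$ preserves constant vectors.

## Ecoguilds and structured interactions

Within a real clade not every species competes with every other. Species
carry one dominant diet and one dominant foraging-stratum label (the
package reads single dominant categories, not percentage profiles) and
are reduced to four *ecoguilds* by a PCA (SVD of the column-centered
one-hot indicator matrix, 8 diet + 9 foraging-stratum categories, each row
summing to 2) and the quadrant of each species' first two scores. Axis
signs are fixed by forcing the largest-magnitude loading positive, species
rows are processed in a canonical (sorted) order so the assignment is
deterministic and invariant to input order even when singular values are
tied, and boundary scores within $10^{-12}$ of an axis fall on the
positive side. Only co-membership matters downstream, so the arbitrary
orientation of the axes is harmless.

Guild membership through time is reconstructed with stochastic character
maps under a continuous-time Markov (Mk) model. The default Mk flavour is
equal-rates (ER) with an equal root prior — a deliberate identifiability
choice for 4 states on clades as small as 20 tips; SYM/ARD and a
stationary root prior are available. Rate fitting and map sampling go
through `phytools` (`fitMk`, `make.simmap`), wrapped behind a `regime_map`
representation: per edge, an ordered list of (state, duration) segments.
In structured DD models each lineage's rate at time $u$ uses the count of
lineages sharing its regime state at $u$; in structured MC only same-state
lineages enter the interaction mean. Reconstructions with excessive
back-and-forth transitions are flagged as suspect when the map-mean number
of changes per unit tree depth exceeds a threshold (default 10).

## Fitting, model comparison and the competition flag

Because $\sigma^2$ enters every model's covariance as a pure scale and
$z_0$ only shifts the mean, both are profiled analytically (GLS for $z_0$,
closed-form ML for $\sigma^2$), leaving a one-dimensional optimization
over the shape parameter. The optimizer evaluates five seeded
Latin-hypercube start points within documented bounds
($\log\alpha \in [-10, 7]$; $S \in [-50, 0]$; slope and exponent bounds
chosen so the effective rate stays within $[10^{-8}, 10^6]$ relative to
$\sigma^2$ over the tree) and refines the two best by L-BFGS-B; with the
dimension already reduced to one, full quasi-Newton runs from every start
point would be redundant. Parameter regions whose covariance is
numerically indefinite (extreme $|S|$, where entries grow like
$e^{2|S|t}$) are rejected outright rather than regularized — adding jitter
there hands the optimizer spurious likelihood values. If no start
converges the start set is doubled once and the fit is flagged rather than
thrown.

Models are compared by AICc with $k = 2$ (BM) or $3$ parameters. A clade
$\times$ trait is *flagged for competition* when the best model is DDlin,
DDexp or MC **and** it beats the best independent-evolution model (BM, OU,
TDlin, TDexp) by more than 2 AICc units. Exact ties (within $10^{-8}$)
resolve to fewer parameters, then alphabetical name. When several sampled
regime maps are supplied, each model is fitted per map and the map-mean
AICc and parameters are reported, with per-map fits retained — a symmetric
and reproducible treatment of map uncertainty.

Across clades, `prevalence()` tabulates flags per trait and for "any
trait", and `d_statistic()` measures phylogenetic signal in the binary
flag on a clade-level tree (sister-clade contrast sum, scaled between the
permutation expectation, $D = 1$, and a prevalence-matched
threshold-Brownian expectation, $D = 0$). Collapsing clades to single tips
keeps one representative tip per clade; its pendant edge runs from the
clade's stem attachment to the present.

## Simulation

Gaussian-family models are simulated exactly, branch by branch: OU by its
exact transition recursion towards $z_0$, TD/DD by Gaussian increments
with variance $\int \sigma^2(u)\,du$ over each branch segment (piecewise
closed form). MC is simulated by Euler–Maruyama on a shared global grid
(default $T/2000$, refined automatically so $|S|h \le 0.01$ for stability
of the linear drift), with branch traversal in a fixed preorder so a seed
fully determines the outcome. Simulating BM with `method = "euler"` forces
it onto the same discretized path as MC, which is how the pathwise
$S = 0 \equiv$ BM reduction is tested. During simulation and fitting the
DD lineage count is the reconstructed, extant-only count — the same
quantity the likelihood can see.

## The synthetic-data generator

`make_fixture()` emulates the structure of a multi-clade comparative
dataset: per clade a pure-birth (optionally birth–death) tree conditioned
on its tip count via `ape::rphylo`, a true guild history simulated under a
4-state ER Mk process at 0.5 expected transitions per off-diagonal per
unit tree depth, diet/forage labels derived from a fixed guild-to-category
mapping (optionally noised), and six traits — four "shape PCs", size and
mass — simulated under configurable generating models (default BM with
$\sigma^2 = 0.1$, matching the trait scale of the false-positive design).
Clades have at least 21 tips, the empirical floor for trustworthy fits.
The fixture reproduces the statistical structure the analysis assumes —
Gaussian tip distributions, Mk guild histories, guild-consistent
categories — but not features of real data such as measurement error,
missing species, fossil signal or correlated traits; passing tests on
fixtures therefore validate the machinery, not any biological claim.
Mass is simulated independently of size, so the PGLS "relative size"
residualization is exercised without implying allometry.

## The false-positive study

`run_fp_study()` reproduces the key robustness experiment: traits are
simulated under OU ($\sigma^2 = 0.1$, $z_0 = 0$, $\alpha \in \{1, 5\}$) on
trees standardized to depth 1, the competition models are fitted alongside
OU, and a false positive is recorded when a competition model's AICc beats
OU's by more than 2. Trees default to seeded pure-birth trees of
25/51/112/195 tips — an approximation standing in for empirical trees of
those sizes, configurable to user-supplied Newick. The guild-structured
arm simulates guild states once per tree and samples 10 maps per tree
(scaled down from 50 for routine runs; configurable). Every rate is
reported with a Wilson 95% interval, and scaled-down replicate counts are
compared to reference values only through those intervals.

One design choice deserves emphasis. On an ultrametric tree the
root-conditioned OU covariance is *exactly* an accelerating
exponential-in-time rate model:
$e^{-2\alpha(T - t_{ij})}(1 - e^{-2\alpha t_{ij}}) =
e^{-2\alpha T}(e^{2\alpha t_{ij}} - 1)$, i.e. OU $\equiv$ TDexp with
exponent $2\alpha$ (the package's fits reproduce this equality to
machine precision). A consequence is that when OU's constraint parameter
is allowed to roam freely, the true OU model essentially never loses to a
diversity-dependent competitor by more than 2 AICc units, and
strong-constraint false positives all but vanish. The widely used
comparative-methods toolchain, however, conventionally caps the fitted
$\alpha$ at $e \approx 2.718$ — below a generating $\alpha = 5$ — and it
is model selection *as practiced with that constraint box* whose failure
modes the false-positive experiment characterizes (inflated DDexp
preference in small, strongly constrained clades, alleviated by guild
structure). `fp_config()` therefore fits OU inside the study with
`ou_alpha_max = exp(1)` by default, while the package-wide fitting bounds
stay wide ($\log\alpha \in [-10, 7]$). Setting `ou_alpha_max = Inf`
switches the study to fully unconstrained OU fits and shows the false
positives collapse towards zero.

Problem sizes used by the packaged checks (chosen once as desk-scale
versions of the reference design): the unstructured arms run 200
replicates on the 25- and 51-tip trees; the guild-structured arms run 100
replicates (both sizes) at $\alpha = 1$ and 200 replicates (25 tips,
DD models) at $\alpha = 5$; moment-consistency ensembles use 4000–6000
simulations; parameter recovery uses 100 (BM) and 50 (OU, DDexp, MC)
replicates at 100 tips; D-statistic calibration uses 500 replicates on a
64-tip tree.

## Numerical choices and limitations

* Ultrametricity is enforced within $10^{-6} T$; OU, DD and MC reject
  non-ultrametric trees rather than silently approximating.
* Polytomies are resolved deterministically to binary with zero-length
  edges; zero-length edges contribute zero variance.
* Linear rate models are constrained so the effective rate never falls
  below $10^{-8}$ (relative to $\sigma^2$) anywhere on the tree; parameter
  combinations violating this are outside the model domain.
* The Gaussian likelihood uses a Cholesky factorization; in user-facing
  evaluation a single jitter retry bounded by $10^{-10}\,\mathrm{tr}(V)$
  is allowed, while fitting rejects indefinite regions (see above).
* The MC event mesh merges branching times and regime breakpoints and
  snaps boundaries closer than $10^{-9} T$; within an interval the drift
  matrix is constant and the update exact, so likelihood accuracy does not
  depend on a step size.
* Whether subclade extraction precedes or follows pruning to sampled
  species is data-set specific; both orders are supported by composing
  `extract_midpoint_subclades()` with the pruning flag of
  `read_trait_table()`.
* Known limitations: no measurement error model; the MC likelihood ignores
  extinct lineages (as any reconstructed-tree method must); diversity
  counts come from the reconstructed tree, so slope estimates are
  conservative under extinction; biogeographic (range-based) interaction
  structure is supported only insofar as any discrete regime map can be
  supplied — range inference itself is out of scope.

## A minimal session

```{r example, eval = FALSE}
cfg <- fixture_config(n_clades = 2, n_tips = 25, seed = 42)
bundle <- make_fixture(cfg)
res <- run_pipeline(bundle, n_maps = 10, seed = 1)
res$prevalence

fp <- run_fp_study(fp_config(sizes = 25, alpha = c(1, 5),
                             n_reps = 100, seed = 1))
fp$rates
```
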