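---
title: "The IWE-SSE model: methylation dynamics with island-wide events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IWE-SSE model: methylation dynamics with island-wide events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iwesse)
```

## The model

`iwesse` models the evolution of CpG methylation states along a rooted tree
of cell types (or other taxa). Each CpG site is in one of three states —
unmethylated (`u`), partially methylated (`p`) or methylated (`m`) — and
belongs to a CpG island. Islands evolve independently; within an island,
two kinds of events act:

* **Single-site events (SSEs).** At rate $R$ per site, an event resamples
  the site's state from the island's current equilibrium triple
  $\pi = (\pi_u, \pi_p, \pi_m)$. The new state may equal the old one; such
  *silent* events still count in the time scaling. This is an F81-style
  three-state substitution process: the rate matrix has off-diagonal
  entries $R\,\pi_j$ and the transition probabilities over a duration $t$
  have the closed form $(1 - e^{-Rt})\pi_j$ off the diagonal and
  $\pi_i + (1 - \pi_i)e^{-Rt}$ on it (`sse_transition_matrix()`).

* **Island-wide events (IWEs).** At rate $\mu$ per island per time unit, a
  compound-Poisson event redraws the island's equilibrium triple from a
  uniform (Dirichlet(1,1,1)) distribution and simultaneously moves every
  site by a minimal-motion stochastic matrix $M$ chosen so that the
  expected state frequencies match the new triple immediately
  (`iwe_transition_matrix()`). When exactly one frequency grows, each
  shrinking state keeps its state with probability $\pi'_s/\pi_s$ and
  otherwise jumps to the growing state; when exactly one frequency
  shrinks, that state feeds each growing state proportionally to its
  gain. In both cases $\pi M = \pi'$ holds exactly. If a frequency is
  unchanged, its state keeps its state — the two case formulas coincide
  there, and the choice is continuous in the triples.

Per-site rate factors follow an invariant+gamma mixture: $R = 0$ with
probability $r$ (an invariant site), and otherwise one of three
discretized-gamma categories with shape $\alpha$ and mean one, each with
conditional probability $1/3$. The discretization uses the *means* of
three equal-probability slices, renormalized so the category mean is
exactly one; means rather than medians because the construction is meant
to preserve the unit expectation exactly, which medians do not. With this
scaling, one unit of branch length equals one expected SSE per CpG site,
so a branch of length $l$ carries on average $l$ SSEs per site and
$\mu l$ IWEs per island. Equivalently, for an island set with $n$ islands
of $n_1, \dots, n_n$ sites,
$l = \mathbb{E}[S + W] / (n\mu + \sum_i n_i)$ where $S$ and $W$ count
SSEs (including silent ones) and IWEs on the branch; the event-mode
simulator checks this identity directly.

Because an SSE resamples the state from $\pi$, a fraction
$\pi_u^2 + \pi_p^2 + \pi_m^2 \ge 1/3$ of SSEs is silent, minimized at the
simplex center. Branch lengths in SSE units are therefore not directly
comparable to "expected state changes per site" scales used elsewhere.

## Likelihood

Conditional on an island's IWE configuration $W_i$ (event positions and
triples) and a site's rate factor, sites evolve independently, so the
island likelihood is a product over sites and the total likelihood a
product over islands. For one site the likelihood is computed by
Felsenstein pruning with the IWE matrices interleaved on branches: a
branch with $h$ events contributes the operator
$P_0 \prod_{k=1}^h M_k P_k$, where $P_k$ is the SSE transition matrix of
the $k$-th inter-event interval under the triple in force there
(`branch_partial()`, `compose_interval_transition()`). The triple in
force at any point is the most recent event triple on the path from the
root, or the island's root triple. Partial likelihood vectors carry a
separate log-scale factor and are rescaled at every node so that products
over many branches cannot underflow.

Observed nodes (in the intended applications, *all* nodes, including
internal ones) pin the partial vector to an indicator of the observed
state; missing values at observed nodes contribute an all-ones vector,
the standard ambiguity convention. With tips-only data the root term sums
over root states weighted by the island's root triple. The per-site rate
factor is shared across the whole tree for that site, so the four-term
mixture over $R$ (probability $r$ for $R = 0$ and $(1-r)/3$ per gamma
category) is applied once per site, outside the tree recursion.

Two engines implement the same recursion: a reference implementation in R
(`engine = "R"`), written operation by operation, and a compiled C++
engine used by default and inside the sampler. The test suite requires
both to agree with each other and with a brute-force enumeration over all
hidden states on small instances, to $10^{-9}$.

## Priors, proposals and the sampler

The posterior is explored with a reversible-jump Metropolis–Hastings
sampler (`run_mcmc()`). Priors: log branch lengths are normal$(-2, 2)$;
$\log\alpha$ is normal$(0,1)$; $r$ is uniform on $[0,1]$; $\log\mu$ is
normal$(0,2)$; island root triples and IWE triples are Dirichlet(1,1,1);
IWE positions form a Poisson process of intensity $\mu$ per island. These
are weakly informative defaults centered on plausible scales (a typical
branch of $e^{-2} \approx 0.14$ expected SSEs per site) and are all
configurable via `default_priors()`.

One sweep performs, per island, one IWE birth/death attempt and one
frequency update, then one update per branch length and one per global
parameter ($r$, $\alpha$, $\mu$); burn-in is counted in sweeps. Moves:

* **Birth/death.** A branch is chosen uniformly; a birth draws the
  position uniformly on the branch and the triple from its Dirichlet
  prior, so proposal and prior terms cancel and the acceptance
  probability reduces to
  $\min\{1, \mathrm{LR}\cdot\mu l/(n+1)\}$ for a branch with $n$ of the
  island's events; the death move uses the reciprocal
  (`iwe_birth_acceptance()`, `iwe_death_acceptance()`). This is the one
  proposal under which the ratio takes this closed form.
* **Branch lengths.** Proposals are symmetric on the log scale, from a
  two-component Gaussian mixture (scales 0.1 and 1.0, weights 0.9/0.1) —
  small steps for local mixing, occasional large jumps to cross between
  prior and posterior scales. Acceptance is
  $\min\{1, \mathrm{LR}\,(l'/l)^n e^{-\mu N(l'-l)}\,p(\ell')/p(\ell)\}$
  with $n$ the branch's total IWE count over all $N$ islands. Existing
  event offsets rescale proportionally; internally events store
  *relative* positions, which makes the rescaling exact and shows that
  $(l'/l)^n$ is precisely the density ratio of the rescaled Poisson
  process.
* **Frequencies.** The island's root triple, or the triple of one
  existing event (chosen uniformly among the $1+h$ candidates), is
  redrawn from the Dirichlet prior; the Hastings ratio is then just the
  likelihood ratio.
* **Globals.** $r$ uses a reflected uniform walk on $[0,1]$;
  $\log\alpha$ and $\log\mu$ use Gaussian walks with an occasional
  five-fold larger step (same small/large rationale as for lengths).
  The $\mu$ update involves no data likelihood, only the
  Poisson-process factor $\mu^{n_{\rm tot}}e^{-\mu N L_{\rm tot}}$ over
  the current configuration and the prior.
* **Tree rescaling.** One move per sweep multiplies every branch length
  by a common factor $c$ and divides $\mu$ by $c$. The product
  $\mu L_{\rm tot}$ — and with it the whole Poisson-process factor and
  the event-position densities — is invariant under this map, so the
  acceptance ratio reduces to likelihood times the normal priors. The
  move travels along the ridge where island-wide events and single-site
  events trade off in explaining the same data, which the
  one-parameter walks cross only very slowly.
* **Extend/truncate.** For single branches there is a second kind of
  length proposal: lengthening a branch keeps its existing events at
  their absolute offsets and populates the new segment with events drawn
  from the Poisson-process prior (count, positions and triples);
  shortening truncates the events beyond the new length. Prior and
  proposal cancel exactly, so the acceptance ratio again carries no
  event terms. This matters because under the proportional-rescaling
  move a branch carrying $n$ events can only change its log length in
  steps of order $1/\sqrt{n}$ (the $(l'/l)^n e^{-\mu N(l'-l)}$ factor is
  that sharply peaked), which effectively freezes long, event-rich
  branches. A symmetric guard skips proposals whose expected event count
  would be astronomical, identically in both directions, leaving
  detailed balance intact. Each branch attempts this move with
  probability 1/2 per sweep to bound its cost.

`run_mcmc()` can also repeat the per-island and per-branch move blocks
several times per sweep (`island_reps`, `length_reps`) when faster joint
mixing of counts and lengths is worth the extra likelihood evaluations.

The **null model** (`mode = "null"`) fixes $\mu = 0$ and disables IWE
moves; islands keep distinct but time-constant equilibrium triples, and
the branch-length acceptance reduces to
$\min\{1, \mathrm{LR}\cdot p(\ell')/p(\ell)\}$.

Chains start without IWEs and with parameters at their prior means (this
avoids long convergence from many misplaced initial events), are
deterministic given a seed, and record every tenth sweep by default. The
sampler caches per-island log-likelihoods and can recompute them from
scratch periodically (`cache_check_every`); the largest deviation is
reported and must stay below $10^{-9}$.

Position-shift moves for existing IWEs are not implemented: birth/death
plus the proportional rescaling under length moves already make positions
irreducible, and a shift move is not required for correctness.

## The simulator

`simulate_dataset()` generates the study conditions end to end: island
sizes uniform on a configurable range, all scalar parameters drawn from
their priors, root triples Dirichlet(1,1,1), per-branch IWE counts
Poisson($\mu N l$) with uniform positions, root states drawn from the
root triples, and states propagated root-to-tips. Two modes exist:
`matrix` draws child states from the composed interval transition
matrices; `event` simulates individual SSEs (exponential waiting times,
each event resampling from the current triple, silent events counted)
and IWE transitions, and logs per-branch event counts. Both sample the
same distribution; the event mode exists to validate the time-scaling
identity above.

The simulator emulates categorical methylation states at every node of a
known topology. It does not emulate read-level noise, read depth,
fraction-to-state categorization error, missing data patterns, linked
islands, or unknown topologies — so passing tests demonstrate
correctness of inference *under the model*, not robustness of the model
on real RRBS data.

## Validation strategy and problem sizes

Three layers of checks, all in the test suite:

1. **Exact algebra.** Closed-form SSE matrices against a truncated-series
   matrix exponential; $\pi M = \pi'$ for the IWE matrices; pruning
   against brute-force enumeration over all hidden states, event-interval
   states and rate categories on trees of up to 4 nodes.
2. **Kernel invariance.** With the likelihood forced to 1, chains started
   from exact prior draws must stay prior-distributed after any number of
   sweeps; Kolmogorov–Smirnov tests on every scalar marginal and a
   chi-square test of per-branch IWE counts against Poisson($\mu N l$)
   with $\mu$ and lengths held fixed. This tests stationarity directly
   and is insensitive to the (genuinely slow) mixing of the joint
   $(\mu, \text{counts}, \text{lengths})$ prior, whose heavy tails put
   hundreds of events on the tree.
3. **Simulation-based calibration.** A from-prior coverage study — 30
   replicates on a balanced 4-tip tree with 20 islands of 10–100 sites,
   inferred with $2\times10^4$ burn-in and $2\times10^4$ recorded sweeps —
   in which 95% credibility intervals must cover the generating values at
   rates statistically consistent with the nominal level, overall and per
   parameter class. These sizes keep the full study in the tens of
   minutes on a single core while leaving the binomial tolerances
   meaningful; `scripts/acceptance.R` reruns exactly this study.

A complementary null-model check simulates data without IWEs, fits the
full model, and verifies that it infers (almost) no events, while a
positive control with many true IWEs yields large inferred counts.

## Numerical choices and degenerate inputs

* Equilibrium triples must sum to one within $10^{-12}$; components below
  $10^{-12}$ are rejected wherever a triple is used as a divisor
  (IWE matrices) — Dirichlet draws are almost surely interior, so an
  exact zero signals a caller bug. Dirichlet proposals that land below
  the floor are discarded.
* `dt = 0` and identical triples yield exact identity matrices; a zero
  total site likelihood propagates as $-\infty$ with a warning, and a
  non-finite *initial* likelihood aborts the sampler naming the island.
* Equal-tailed credibility intervals are quantile intervals; per-branch
  IWE-rate intervals of $\log(\text{count}/l)$ are Bonferroni-corrected
  across branches (the multiple-testing rule is a package choice), and a
  branch with zero count throughout the trace is reported on
  $\text{count}+0.5$ and flagged.
* Island-level classification uses strict majorities of non-missing
  sites; methylation fractions map to states with inclusive bounds at
  0.1 and 0.8 (`categorize_site()`), reading "10 to 80%" inclusively.
  The island-mean encoding for the Euclidean baseline distance is
  $u = 0$, $p = 0.5$, $m = 1$, the natural ordinal midpoint scheme.

## A small worked example

```{r example}
set.seed(1)
design <- simulation_design(balanced_tree(4), n_islands = 10,
                            site_range = c(10, 40))
sim <- simulate_dataset(design, seed = 1)
fit <- run_mcmc(sim$tree, sim$data, n_sweeps = 2000, burn_in = 2000,
                thin = 10, seed = 1)
fit
credibility_interval(fit$trace$mu)
sim$truth$theta$mu
```

## Known limitations

* The SSE model draws the new state independently of the old one; general
  reversible three-state rate matrices and neighbor-dependent (Ising)
  models are out of scope, as are topology moves — the tree is fixed.
* The IWE rate $\mu$ is constant across branches a priori; per-branch
  rates are summarized a posteriori via `iwe_rate_intervals()` but not
  modeled.
* The prior-mixing caveat above: on the *prior* (or with very weak data)
  the joint of $\mu$, lengths and event counts decorrelates slowly;
  posterior runs on informative data mix much faster, but short chains
  on nearly-null data should be interpreted with care.
* The reversible-jump posterior can be metastable at small data sizes:
  the same data sometimes admit a few-events/short-branch and a
  many-events/long-branch explanation of nearly equal likelihood,
  separated by a barrier that local moves (even the rescaling and
  extend/truncate moves) cross only rarely. Chains started at either
  mode remain there over tens of thousands of sweeps. In the reduced
  calibration study this depresses the empirical interval coverage a
  few points below the nominal 95% — concentrated in replicates whose
  generating parameters make branch lengths nearly unidentifiable (an
  invariant fraction close to 1, or very high event rates). With more
  islands and sites per island the likelihood separates the modes and
  the effect disappears; the standard remedy at small scale, tempered
  or multi-chain sampling, is deliberately outside this package's
  scope.
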