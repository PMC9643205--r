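---
title: "Comparing amino acid replacement models by Bayesian cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing amino acid replacement models by Bayesian cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

Protein alignments used for deep phylogenetics are strongly heterogeneous
across sites: different columns prefer different subsets of amino acids
(pattern heterogeneity) and evolve at different overall speeds (rate
heterogeneity).  `mixcv` implements a lattice of amino acid replacement
models that switch each of these ingredients on or off, fits each model by
MCMC on a fixed tree topology, and compares models by how well they
predict held-out alignment columns.

Every model is a reversible continuous-time Markov chain on the 20 amino
acids.  Its generator is built from two pieces:

* a **profile** $\pi$, a point on the 20-simplex of amino acid
  frequencies, and
* **exchangeabilities** $\rho_{ab}$, 190 symmetric pairwise rate factors,

with off-diagonal rates $q_{ab} \propto \rho_{ab}\,\pi_b$ normalized so
that one unit of branch length equals one expected replacement per site at
stationarity.  "Poisson" sets all $\rho_{ab}$ equal (the amino acid
analogue of Felsenstein's 1981 model when combined with a single free
profile, printed `F81`); "GTR" treats the 190 values as free parameters
(identified by fixing their mean to one, since their scale is confounded
with branch lengths).

Pattern heterogeneity enters through a mixture over profiles, shared
exchangeabilities across components:

* `single` — one profile (`F81`, `GTR`);
* `empirical` — a fixed published profile set (e.g. C60 or the UDM sets)
  whose **weights are re-inferred** from the data while the profiles stay
  at their published values;
* `free` — a free finite mixture with a fixed component count
  (`CATf=k-...`), profiles and weights both inferred;
* `dp` — a Dirichlet-process (infinite) mixture, the CAT family
  (`CAT-...`), realized by the Chinese-restaurant process so the occupied
  component count is itself a random variable.

Rate heterogeneity (`+G`) uses site rates acting as branch-length
multipliers, drawn from a mean-one gamma law with shape $\alpha$ and
discretized into equally weighted quantile categories.  We use the
*mean-of-bin* discretization (each category rate is the conditional mean
of the gamma density inside its quantile bin) because it keeps the mean
rate exactly one for every $\alpha$; the category count defaults to 4 and
is exposed as `n_cat` (8 is the other common choice).

## Likelihoods

Site likelihoods are computed by Felsenstein pruning, vectorized across
sites in compiled code, averaging over mixture components (by weight) and
gamma categories (equal weight).  Missing data (`-`, `?`, `X`, treated
identically) contribute a partial-likelihood vector of ones, i.e. they are
marginalized.  Numerical choices:

* transition matrices come from the symmetrized eigendecomposition of the
  reversible generator ($D^{1/2} Q D^{-1/2}$ is symmetric), which is
  stable and exact; tiny negative entries from round-off are clamped at
  zero;
* profiles are floored at $10^{-8}$ and renormalized wherever they enter
  (read from files, drawn in proposals), so log-likelihoods stay finite;
* pruning uses per-node column rescaling with log-scale accumulators
  (applied every few tree levels), so alignments with many taxa do not
  underflow;
* identical columns may be collapsed to unique patterns with
  multiplicities; the result is unchanged and this is tested.

A brute-force enumerator over all internal-node states (up to five taxa)
serves as the independent oracle for the pruning code, and the F81 closed
form serves as the oracle for the matrix exponential under Poisson
exchangeabilities.

## MCMC

`run_chain()` samples branch lengths, exchangeabilities, profiles,
weights (finite mixtures) or the site allocation and concentration (DP),
and the gamma shape from their posterior, with the topology fixed (user-
or simulator-supplied).  Fixing the topology isolates the replacement-
model question and keeps the artifact desk-scale; it is the package's
main structural limitation.

Priors: exponential(mean 0.1) per branch length, uniform Dirichlet on
profiles, normalized exchangeabilities and weights, exponential(mean 1)
on the gamma shape and on the DP concentration.  These are reasonable
defaults rather than canonical choices; no exact numerical agreement with
any other implementation is claimed.

A *cycle* is one sweep touching every parameter block once:

1. **Branch lengths** — a depth-first pass over the tree that gives every
   branch one multiplicative Metropolis-Hastings update, using cached
   upward/downward partial likelihoods so the whole sweep costs a small
   constant number of tree passes rather than one full pruning pass per
   branch.
2. **Exchangeabilities** (GTR modes) — Dirichlet random-walk MH on the
   normalized 190-vector, two proposals per cycle at coarse and fine
   concentrations.
3. **Profiles** — per component, Dirichlet random-walk MH (again at two
   scales), with an occasional independence draw from the prior to escape
   simplex corners.  Empirical mixtures skip this block: their profiles
   are data, only the weights move.  DP components are updated against
   their allocated sites only.
4. **Weights** (finite mixtures) — Dirichlet MH; free-finite components
   may shrink toward zero weight but are never deleted, keeping the
   dimension fixed.
5. **DP allocation** — one Chinese-restaurant Gibbs sweep with
   `dp_new_m = 10` auxiliary components carrying fresh base-distribution
   profile draws (the auxiliary-component realization of the CRP
   predictive): each site is removed (empty components are deleted,
   their profile serving as an auxiliary for that site only) and
   reseated among occupied components with probability
   $\propto n_j L_j(i)$ or at auxiliary $m$ with probability
   $\propto (\alpha/M) L_m(i)$; a chosen auxiliary becomes a real
   component and is replaced by a fresh base draw.  The DP profile
   block pairs its random-walk move with an independence proposal from
   the Dirichlet posterior of the component's pooled column counts
   (proper Hastings ratio), so new components specialize in one step.
   The concentration $\alpha$ is Gibbs-updated by the Escobar-West
   auxiliary-beta scheme (exact under the exponential = Gamma(1, ·)
   prior).
6. **Gamma shape** — multiplicative MH.

DP chains need two further mixing devices, both confined to burn-in (so
the sampling-phase kernel is untouched, exactly as with proposal-width
adaptation).  The site allocation is *initialized* by k-means on the
columns' amino acid compositions (at most 12 clusters), because the
Gibbs sweep sorts a compositionally mixed table only by slow singleton
nucleation and practically never empties a large table — cold starts
otherwise lodge in fragmented, high-component-count metastable states
that carry far less posterior mass than the sorted ones.  Near the end
of burn-in, greedy *merge passes* consolidate redundant components: the
pair whose merge most improves the allocated log-likelihood plus the
CRP partition term is merged repeatedly, with each side scored at the
Dirichlet posterior-mean profile of its pooled column counts so the
comparison is optimized-versus-optimized.

Proposal widths adapt every 10 cycles *during burn-in only* (targeting
acceptance between 0.2 and 0.5) and are frozen afterwards, preserving
detailed balance in the sampling phase.  Initial proposal concentrations
for simplex parameters scale with the number of sites, since posterior
widths shrink like $1/\sqrt{N}$.

Chains start from a data-informed state: free profiles at (jittered)
empirical amino acid frequencies, the DP allocation at its k-means
seating, free exchangeabilities even, everything else from its prior
(`instantiate_model()` draws pure prior states).
Initialization does not affect the stationary distribution; it shortens
burn-in enough that the desk-scale cycle counts below suffice.  The
entire chain is reproducible bit-for-bit from its seed, and
`sample_from_prior()` runs the identical machinery with the likelihood
forced to one, which is how the Geweke-style prior-recovery tests are
implemented.

## Cross-validation

`split_folds()` draws, for each replicate, an independent uniform random
subset of one fifth of the columns as the testing set, the complement
being the learning set.  Replicates are independent resamplings, not a
disjoint partition — the protocol is *repeated random splitting*, with
the term "fivefold" used loosely; a strict disjoint partition is
available behind `partition = TRUE`.

Given a learning-set posterior sample $\theta_1,\dots,\theta_K$, the
score of a test set is

$$\text{cv-score} = \sum_i \ln\Big(\frac1K \sum_{k=1}^K
p(D_i \mid \theta_k)\Big),$$

computed with log-sum-exp per site (per-draw site likelihoods underflow
at realistic taxon counts).  Finite and empirical mixtures score test
columns marginally over their components.  A DP draw has no weights for
unseen data, so test columns are scored by the exact Chinese-restaurant
predictive rule: occupied components weighted $n_j/(n+\alpha)$ plus
$\alpha/(n+\alpha)$ times the prior-predictive term, the latter again a
Monte Carlo average over `m_new` fresh base draws.

`relative_score_table()` reports, per model, the mean and sample standard
deviation (the $n-1$ flavor) across replicates of the per-replicate
difference from a reference model, plus the count of replicates each
model won (exact ties award every tied model a count and are logged).
`run_experiment()` orchestrates the full grid — folds × models — with
per-task seeds derived deterministically from the master seed, per-task
checkpoint/resume, and a manifest of every artifact written.

## The synthetic benchmarks

Real phylogenomic data sets at the scale this methodology is usually
applied to (tens of taxa, tens of thousands of columns) are not bundled;
`make_benchmark_suite()` generates alignments with the same statistical
structure: across-site profile heterogeneity drawn from a mixture,
discrete-gamma site rates acting as branch-length multipliers, and
missing cells.  Trees come from sequential random joins with exponential
branch lengths (mean 0.15 in the fixtures, a moderate divergence for
concatenated protein data).  The fixtures:

* `f81` — single profile, Poisson, no gamma; 8 taxa × 2000 sites;
* `gtr_gamma` — single profile, GTR, $\alpha = 0.5$; 8 taxa × 5000 sites;
* `mix3` — three well-separated profiles (70% of the mass on disjoint
  amino acid triples, guaranteeing identifiability at this scale), equal
  weights, Poisson, no gamma; 10 taxa × 3000 sites;
* `smoke` — 4 taxa × 50 sites with 10% missing cells.

Everything is generator code plus a seed; no data files ship with the
package.  What the simulator does *not* emulate: indels and alignment
uncertainty (gaps are i.i.d. masks, not evolutionary events),
compositional drift across the tree (the process is time-homogeneous),
and correlation between sites.  Passing tests therefore demonstrate
correctness of the machinery and recoverability under the assumed model,
not performance on real data.

## Test and validation scales

The statistical acceptance checks run at sizes chosen to finish on one
CPU in minutes while leaving the conclusions unambiguous: parameter
recovery fits `gtr_gamma` for 1100 cycles (100 burn-in, thinning 2);
ranking recovery runs fivefold CV on `mix3` with models
{`F81`, `F81+G`, `CATf=3-Poisson`} at 200 cycles per chain (75 burn-in,
thinning 3); DP shrinkage runs `CAT-Poisson` on `mix3` for 350 cycles
(150 burn-in); prior-recovery
chains use 10,000 post-burn-in draws with batch-means standard errors.
The default `chain_config()` (2200 cycles, 200 burn-in) reflects common
practice for production runs on real data.

## Known limitations

* Topology is fixed; no tree search.
* Random-walk MH on high-dimensional simplices mixes slowly; the
  two-scale proposals and data-informed starts mitigate but do not remove
  this.  For serious GTR exchangeability estimation expect to need more
  cycles than the defaults.
* The DP sampler is the plain Chinese-restaurant Gibbs sweep (no
  split-merge moves), so traversal between well-separated allocation
  modes is slow.
* Empirical profile sets are consumed as files; none ship with the
  package.
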