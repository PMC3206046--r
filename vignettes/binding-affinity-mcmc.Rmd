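---
title: "Estimating dissociation constants from paired pre-bound/bound sequencing counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dissociation constants from paired pre-bound/bound sequencing counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The experiment and the model

A pool of short double-stranded DNA ligands ("ds-oligos", all of one length
L) is mixed with a transcription factor (TF), allowed to reach binding
equilibrium, and the TF-bound fraction is purified.  Both the pre-bound pool
and the bound pool are sequenced, giving two count tables over the same
ligand set.  Each ligand i binds according to the hyperbolic isotherm

    theta_i = [TF] / ([TF] + Kd_i)

where `[TF]` is the *free* TF concentration at equilibrium (shared by all
ligands) and `Kd_i` is the ligand's dissociation constant (both in nM).
The bound pool is the pre-bound pool reweighted by binding probability:

    B_i = P_i * theta_i / sum_j P_j * theta_j

This is a physical transformation of relative frequencies, not an
application of Bayes' theorem: with `[TF]` treated as a free parameter, the
ligands influence one another only through `[TF]`, and the normalizing sum
may run over any subset of ligands one chooses to compare.

Counts are modeled as multinomial draws: pre-bound counts `C ~
Multinomial(N_C, P)` and bound counts `D ~ Multinomial(N_D, B)`.  The
**basic binding model (BBM)** has free parameters `{P, Kd (non-reference),
[TF]}`; `theta` and `B` are derived.  Its constant-free log-likelihood is
`sum_i C_i log P_i + sum_i D_i log B_i` (multinomial coefficients are
dropped; only differences between states are meaningful, which is all an
MH ratio needs).  Ligands with independently known Kds ("references") keep
those values fixed; they anchor the concentration scale, since the
likelihood is otherwise invariant under jointly rescaling `[TF]` and all
free Kds.

The **generative energy model (GEM)** adds an additive position-specific
energy model.  Energies are dimensionless (units of RT) and relative to the
optimal (consensus) sequence: `E(s) = e0 + sum_k terms[k, s_k]`, with the
optimal nucleotide's term structurally zero at each position and all other
terms non-negative.  Each ligand carries a residual

    eps_i = ln(Kd_i / Kd_opt) - (E(s_i) - e0),    eps_i ~ N(0, sigma^2)

and the GEM log-likelihood is the BBM log-likelihood plus the Gaussian
log-densities of the residuals.  `sigma` is a free parameter: when the
additive model explains the Kds, small `sigma` lets the model share
information across ligands (helping ligands with few counts); when it does
not, `sigma` grows and the fit falls back to the count-based estimates.
Which terms are present is itself sampled: a binary indicator matrix
`delta` is explored by reversible-jump moves, so the posterior reports an
inclusion probability per (position, nucleotide).  Interactive
(pairwise/higher-order) terms are accepted by the data structures as a
scaffold hook but are constrained to zero.

The **generative sequence model (GSM)** is an order-m Markov model of the
synthesis pool: a start-frequency table over the first m-mer (capturing
terminus bias) and next-nucleotide probabilities given the preceding m-mer.
It is used to predict pre-bound frequencies for simulation and smoothing,
never silently substituted into the likelihood.

## Sampling

All inference is Metropolis-Hastings MCMC with flat priors on each block's
sampling scale and symmetric Gaussian proposals, so acceptance reduces to
the likelihood ratio plus the exact Jacobian terms of constrained moves:

* `log Kd_i` and `log [TF]`: one scalar random-walk block each, bounded
  supports (below).
* Frequencies `P`: a sweep of single-coordinate logit-scale moves sharing
  one tuned width.  Perturbing `logit(P_j)` and renormalizing the rest has
  the exact Jacobian `log(y'(1-y')) - log(y(1-y)) + (K-2)(log(1-y') -
  log(1-y))`; with it, the kernel leaves a flat Dirichlet density invariant
  (verified by a Kolmogorov-Smirnov test against Beta(1, K-1) marginals).
  Because each elementary proposal is unidimensional the 0.45 acceptance
  target applies; the 0.234 multidimensional target is kept in the
  configuration but no all-coordinate simplex move is implemented (the
  renormalized joint proposal has no tractable exact Hastings factor).
* A joint **scale move** translates `log [TF]` and all free `log Kd`
  together.  `theta` depends only on `Kd/[TF]`, so this is the
  likelihood's soft direction, constrained only by the references;
  without a dedicated move the chain mixes across it glacially.
* `sigma`: flat prior on sigma itself, proposed on the log scale with the
  `log(sigma'/sigma)` Jacobian, support bounded away from zero (1e-4) to
  avoid degeneracy.
* Energy terms: Gaussian walks reflected into `[0, w_E]` (symmetric).
  Each included term also gets a joint variant translating the term and
  the log Kds of its non-reference carrier sequences together; this leaves
  those residuals invariant, so term moves still travel when `sigma` is
  small and the Gaussian penalty pins terms to the current Kds.  Without
  it, the sampler freezes in locally-consistent but wrong energy models.
* Reversible jumps: a birth draws a new term from `U(0, w_E)` and a death
  collapses one to zero, each in a plain or Kd-shifted variant (chosen
  with probability 1/2 on both sides, so the factor cancels).  The prior
  on an included term is the same `U(0, w_E)` -- a proper prior that makes
  the between-model Bayes factor well-defined -- so the prior density
  cancels the birth density and the jump is accepted with the likelihood
  ratio times the term-selection ratio.  The chain's occupancy ratio
  between two nested models then *equals* their Bayes factor, which the
  tests verify against 1-D quadrature on a one-term toy.

  One deliberate deviation from the "proposal reallocation" recipe that
  refines a proposed jump *before* the accept decision and uses the
  refined state in the ratio: that rule is exact only under the assumption
  that refinement forgets its starting value, and taken literally it
  biases model occupancies.  Here the accept decision uses the initially
  drawn value (exact detailed balance), and the refinement steps -- which
  are ordinary fixed-dimension moves that cannot disturb the stationary
  distribution -- are applied to the freshly born term immediately after
  acceptance, serving the same purpose of settling a new term quickly.
* Proposal widths adapt multiplicatively toward the 0.45 unidimensional
  target every 100 burn-in generations and are frozen at the end of
  burn-in, so the post-burn-in kernel is fixed and the stationary
  distribution untouched.
* Convergence is assessed by running >= 2 chains and computing the
  within/between-chain variance ratio (potential scale reduction) per
  scalar parameter.

Defaults follow the standard practice for this assay: 100,000 generations
with the first 10,000 discarded, thinning 10.  The test suite scales these
down (stated per test) to fit its compute budget.

## Priors, bounds, and two honest pathologies

Flat priors on the log scale are scale-invariant -- the natural
non-informative choice for concentrations -- but they are improper without
bounds, and for this model the bounds matter in two specific ways that we
verified against brute-force posteriors on small systems:

1. **The Kd/TF scale ridge.**  Only the references pin the joint scale of
   `{[TF], Kd}`.  With few or only-strong references the likelihood
   penalty along the ridge is a handful of log units, and a wide prior
   window lets the marginal posterior of `[TF]` drift far above the truth
   purely by volume.  A reference with Kd *above* the working `[TF]`
   blocks this (its saturation is expensive); the simulator therefore
   defaults to one strong and one weak reference, and real designs should
   include a weak binder among the references.  When the total TF added is
   known it can be supplied as `tf_total`, a hard upper bound.
2. **Sub-resolvable strong binders.**  A ligand with `Kd << [TF]` is
   almost fully bound; the data cannot distinguish its Kd from anything
   smaller, and the flat-log prior then spreads a large share of the
   posterior mass over the unresolvable decades down to the lower bound
   (the grid-oracle comparison in the acceptance suite exercises exactly
   this regime).  Point estimates (posterior means) for such ligands are
   prior-driven, which is why the package also reports the categorical
   low/medium/high classification and why credible-interval coverage
   degrades exactly for the strongest binders -- the assay's known blind
   spot, not a sampler defect.

The default supports, `Kd in [1e-3, 1e5]` nM and `[TF] in [1e-3, 1e4]` nM,
span the physically plausible range of protein-DNA affinities (1 pM to 0.1
mM); both are configuration knobs, and the grid-posterior oracle test uses
a window matching its grid so the comparison is exact.

## The synthetic world

`sim_preset()` reproduces the geometry of three published designs with
generated stand-in landscapes (the original Kd sets live in external
publications): 43 ligands around the 10-bp Leu3 palindrome CCGGTACCGG
(equal pre-bound frequencies, TF grid 1/10/50 nM), 46 around the 15-bp
ArcA site GTTACCATTATGTTA (equal frequencies, 1/100/1000 nM), and all 436
ligands within two mismatches of the Zif268 site GCGTGGGCGT (skewed pool:
0.8 observed + 0.2 order-3 GSM mixture, echoing the 0.8/0.2 order-7 recipe
of the original design; TF grid 0.1/1/10/100 nM).  Panels are composed as
a titration study would be: consensus, all single mutants, then double
mutants to fill.  Position terms are drawn U(0, 2.3) RT -- the span of
empirically reported position terms -- and the per-sequence deviation from
additivity defaults to `epsilon_std = 0.3` RT (a moderately good additive
model; set 0 for an exactly additive landscape).  Sequencing is a fixed
read budget per fraction, `Multinomial(K * mean_depth, .)`; the Poisson
"10% std at expectation 100" statement holds marginally.  Replicates share
the landscape and differ only in count noise.  The simulator equilibrates
at the stated realized free TF concentration; `solve_tf_free()` provides
the mass-balance mode.  What a green test on this world does *not*
establish: robustness to purification losses of weak binders, PCR/read
errors, context effects from flanking sequence, or multiple binding sites
per oligo -- none of which are modeled.

## Numerical choices

Likelihood evaluations inside the sampler are incremental (O(1) per scalar
move via cached sufficient sums) with a full recompute every 1000
generations to cancel floating-point drift; an optional debug mode asserts
the drift is below 1e-6.  Degenerate logit proposals that round to 0 or 1
are rejected outright.  `kd_from_freqs()` refuses implied binding
probabilities >= 1 rather than truncating, so inconsistent calibrations
surface; only `initialize_state()` clamps, since its output is merely a
starting point.  Observed zero counts are legal data contributing zero
terms; zero *parametric* frequencies score `-Inf` (a rejected state, never
an exception).  Ties in `categorize_kd` go to "medium" at the exact
minimum.  The GSM pools transition counts across positions by default
(maximizing counts per context; `position_specific = TRUE` conditions on
position) and backs off through lower orders to marginal nucleotide
frequencies on missing contexts unless `strict = TRUE`.

## Known limitations

Reference Kds are fixed constants without uncertainty.  The GEM requires
the optimal sequence to be a member of the analyzed set.  Purification
loss of weak binders is not modeled.  Interactive energy terms are a
scaffold only.  Run configs are JSON rather than YAML.  The CV comparison
and energy tables assume >= 100 posterior draws.
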