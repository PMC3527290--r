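---
title: "Isolation-with-migration coalescent HMMs: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolation-with-migration coalescent HMMs: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcoalhmm)
```

## The inference problem

Two closely related species contribute one haploid genome each to a
pairwise alignment.  Because of recombination, different stretches of the
alignment have different times to their most recent common ancestor
(TMRCA), and the joint pattern of segment lengths and segment divergences
is informative about how the two populations separated.  The model behind
`imcoalhmm` is an isolation-with-migration (IM) demography with three
epochs (backwards in time): isolated demes on `[0, tau1)`, demes coupled
by symmetric migration at rate `M` on `[tau1, tau2)`, and a panmictic
ancestral population beyond `tau2`.  Within demes lineages coalesce at
rate `C` (`C_anc` in the ancestor) and recombine at rate `R` per link.
All quantities are scaled by the substitution rate, so times are expected
substitutions per site.

Exact likelihood under the coalescent with recombination is infeasible
for genome-scale data, so two standard approximations are made:

1. **Markov approximation along the sequence** — the coalescence time of
   a nucleotide pair depends on its left neighbour only;
2. **Time discretization** — coalescence times are binned into
   `n_mig + n_anc` intervals (default 10 + 10).

Both matter below; the second turned out to be the decisive design axis.

## From two-nucleotide CTMCs to HMM transitions

For a *pair* of neighbouring nucleotides the ancestral process is a
finite continuous-time Markov chain.  States are sets of lineages; each
lineage carries the set of samples its left and its right nucleotide are
ancestral to, and a deme label.  The state space is enumerated
generatively from the initial state (both samples doubly linked, one per
deme) under three transition rules — coalescence (same-deme lineages
merge by per-side union when their same-side material is disjoint),
recombination (a doubly linked lineage splits), migration (a lineage
switches deme) — giving 4 isolated-epoch, 94 migration-epoch and 15
ancestral one-deme states.  States where both nucleotides have reached
their MRCA are absorbing.  Rate matrices assign `C`, `R` and `M` to the
corresponding edges; 0/1 injection and projection matrices align the
state spaces at the epoch boundaries (the projection relabels every
lineage into the single ancestral deme).

With equally spaced break points inside each epoch, one matrix
exponential per epoch suffices; interval matrices are composed with the
epoch bridges, and a prefix-accumulator dynamic program sums over all
paths that keep both nucleotides uncoalesced until interval `i`, coalesce
the left one there, keep the right one uncoalesced until interval `j`,
and absorb it there.  The result is the joint interval distribution
`J(i, j)`, numerically symmetric by the left/right exchangeability of the
process; its row conditionals are the HMM transition probabilities and
its marginal is the stationary initial distribution (the chain is then in
detailed balance, which the tests exploit through reversal invariance).
The final, unbounded interval needs no matrix: every surviving lineage
pair eventually coalesces, so its absorption mass is the surviving
probability itself.

Two independent checks pin this machinery down: the row sums of `J` are
reproduced to 1e-8 by a separately coded one-nucleotide chain, and `J`
itself is reproduced within Monte-Carlo error by direct event-driven
(Gillespie) simulation of the two-nucleotide chain.

## Emissions

Conditional on coalescing within interval `i`, the emission probability
of an alignment column uses the Jukes-Cantor mismatch probability at the
interval's *end-conditioned mean* coalescence time `m_i`: the mean of `t`
under the absorption density of the one-nucleotide chain restricted to
the interval.  In the migration epoch this density mixes migration and
coalescence, and the integral `∫ t f(t) dt` is evaluated spectrally
through an eigendecomposition of the (lumped) 5-state rate matrix; the
per-eigenvalue integrals depend only on the shared interval width, so
they are computed once.  The chain is not reversible, so eigenvalues may
be complex; computations stay in complex arithmetic and assert that the
imaginary residue of the (provably real) result is below 1e-9.  Should
the eigenvector matrix be ill-conditioned (condition number above 1e8),
the code falls back to adaptive quadrature of the same integrand and says
so.  Ancestral intervals are truncated exponentials with closed-form
means; the unbounded tail has mean `start + 1/C_anc`.

The hidden time `m_i` is a per-lineage divergence, so the tree connecting
the two sequences has length `2 m_i` and the mismatch probability is
`(3/4)(1 − exp(−(8/3) m_i))`.  Missing data (N, gap, masked, or
soft-masked when requested) emits probability 1 in every state: it
contributes nothing to the likelihood but preserves positional structure,
so the chain carries coalescence-time correlation across assembly gaps.

## The decisive numerical choice: the ancestral discretization span

Equal spacing with the migration-epoch width `delta = (tau2 − tau1) /
n_mig` reused for the ancestral epoch looks natural but is fatal for
inference: with realistic parameters the finite ancestral intervals then
cover only a fraction of `1/C_anc`, leaving roughly 40% of all
coalescences in the single unbounded interval, represented by a single
point emission.  The likelihood rewards parameter combinations that
spread this lump (larger `tau2`, larger `M`, larger `C`), and the bias
*grows* with data — the estimator is inconsistent under that
discretization.  `discretize_time()` therefore spans the finite ancestral
intervals over `3 / C_anc` by default (about 95% of the ancestral
coalescence mass, still equal-width within the epoch); any explicit span
can be passed via `anc_span`.  The comparison isolation (I) model instead
places its break points at exponential coalescent quantiles of the fitted
rate, one-twentieth of the mass per interval, since it has no migration
epoch to anchor a width.

A side effect worth knowing: the resolution of the ancestral tail also
controls how much of the recombination signal is visible.  With a coarse
tail, many coalescence-time changes fall within one interval and are
invisible, which depresses the recombination-rate estimate further.  The
well-documented downward bias of `R` under the Markov approximation (the
full process often recombines and coalesces back to the same ancestor,
so the effective rate of *visible* transitions is lower than `R`) is
therefore discretization-dependent: it shrinks as the tail is resolved
more finely.  `scripts/acceptance.R` recomputes its mean value at the
documented scenario.

## Estimation

`im_fit()` maximizes the forward log-likelihood by Nelder-Mead over
log-transformed parameters; `tau2` is parameterized as
`tau1 + gap` with `gap > 0`, so the split ordering holds by construction
and no penalties are needed.  Starting values come from the mean pairwise
difference: the Jukes-Cantor distance fixes the mean per-lineage
divergence `Tbar`; the start takes `tau2 = Tbar/2`, `tau1 = tau2/2`,
`C = 1.6/Tbar`, `M = 100`, and `R = C/2000` (the genome-average ratio of
recombination to mutation, about 0.8 cM/Mb against 1e-9 per bp per year).
By default two random restarts perturb the start on the log scale
(sd 0.3); the best optimum wins.  Parameter corners where the HMM
degenerates (vanishing interval mass) yield a uniform-row fallback with a
warning inside the model builder and a large penalty in the objective.

The scaled forward recursion is run-length compressed: a run of `k`
identical symbols advances the forward vector through cached binary
powers of the per-symbol update matrix with explicit log-scale
bookkeeping, so each likelihood evaluation costs milliseconds on a 1 Mbp
alignment and the whole fit takes seconds.  Posterior decoding
(`posterior_decode()`) uses the plain scaled forward-backward pass and
maps posteriors to a mean-TMRCA track.

AIC comparison uses `k = 5` (IM) against `k = 3` (I);
`delta = AIC(I) − AIC(IM)` is positive when gene flow is preferred.  At
the clean-split boundary (`tau1 → tau2`, `M → 0`) the two likelihoods
coincide and `delta → −4`, the pure parameter-count penalty — visible in
the clean-split replications, which cluster tightly around that value.

## The simulator and what the validation shows

`simulate_arg()` is an exact event-driven backwards simulation of the
coalescent with recombination and migration over discrete sites: no
sequential-Markov approximation, recombination on every spanned link
including trapped non-ancestral material, migration only during
`[tau1, tau2)`, demes merged at `tau2`.  Per-site cross-deme TMRCAs are
recorded as a piecewise-constant track; sequences evolve by Jukes-Cantor
either from the track (two samples) or through mutation events placed
directly on the graph (needed for two samples per deme, where the
alignment of four sequences feeds the random-phase mosaic experiment).
Mutation-rate heterogeneity (geometric blocks with uniform factors) and
synthetic autocorrelated recombination maps plug into the same engine.
Because the simulator is the full process while the model is its Markov,
discretized approximation, recovery tests are genuine model-misfit tests,
not round trips.

The documented scenarios (see `validation_scenario()`) fix `C = 1250`,
`R = 0.4` — an effective size of 20,000 and 0.8 cM/Mb under a mutation
rate of 1e-9 per bp per year and 20-year generations — with splits on
the 250 kya – 2 Mya scale.  The replays use ten replicates of 1 Mbp;
at that problem size a fit takes seconds, the full validation suite
minutes.  What that scale shows, and does not show:

* `tau2` and `C` are recovered with median errors inside the 15% band the
  validation suite asserts, and `M` within a factor of two.
* `tau1` (the end of gene flow) is only weakly identified at 1 Mbp under
  moderate migration — its median error runs to several tens of percent.
  The information about `tau1` sits in the lower edge of the coalescence-
  time distribution, which carries few sites when migration is limited, so
  scaling the data down by a factor of ten costs `tau1` its
  identifiability before it costs the other parameters theirs.
* `R` is biased downward on average, as expected under the Markov
  approximation, but at 1 Mbp the replicate scatter of the estimate is of
  the same order as the bias itself, so the measured mean bias moves
  substantially between seed sets.
* Model selection distinguishes a *long* migration epoch with limited
  flow from a clean split.  A short epoch with very strong migration is
  effectively panmictic and indistinguishable from a slightly older clean
  split — an identifiability boundary of the demography itself, not an
  implementation artifact.
* Mutation-rate heterogeneity (blocks of mean 500 bp, factors 0.5–1.5)
  depresses the estimated `C` and inflates the estimated `M`: rate
  variation masquerades as extra variance in coalescence times, which the
  model can only explain with more migration and a smaller coalescence
  rate.
* With two samples per deme at a very recent split, collapsing unphased
  genomes into random-allele mosaics inflates the estimated `C`
  moderately (the mosaic switches haplotypes, which looks like extra
  recent coalescence), while leaving it below a 50% overshoot.

Real data differ from the generator in ways the tests deliberately do not
model: non-Jukes-Cantor substitution processes, CpG hypermutability,
alignment and assembly error, selection, and population structure within
each species.  Passing the suite demonstrates internal consistency of the
machinery and robustness to the modelled perturbations, not immunity to
those.

## Degenerate inputs and edge behaviour

* `tau2 = tau1` is a degenerate migration epoch and is rejected for the
  IM model; the I model is the intended description of that history.
* `R = 0` produces a diagonal `J` and an identity HMM transition matrix;
  `M = 0` produces zero coalescence mass before `tau2` and
  truncated-exponential masses after it.  Both limits are asserted
  exactly in the tests.
* All-missing input has likelihood 1 by construction and posterior equal
  to the stationary distribution.
* Hidden-state masses below 1e-300 trigger the uniform-row fallback with
  a warning rather than NaNs.

## Limitations

Only two haploid genomes, two demes and symmetric, time-constant rates
are supported; asymmetric or time-varying migration and more samples
require a larger state space than this two-nucleotide construction
enumerates by default.  The recombination-rate estimate should be read as
a lower bound.  Emission uses a point mass at the interval mean rather
than integrating the Jukes-Cantor curve over the within-interval
coalescence density; with 20 intervals and the adaptive ancestral span
the residual effect is small compared to the Markov approximation.
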