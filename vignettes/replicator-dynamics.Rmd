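---
title: "Replicator dynamics as multiplicative weights in a potential game"
author: "evoGames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics as multiplicative weights in a potential game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoGames)
```

## The models

All dynamics in this package act on probability vectors in discrete
generations and share the replicator schema: multiply each coordinate by
its (marginal) fitness, renormalize. The package's state spaces are the
genotype simplex Δ(Γ) over an abstract multi-locus genotype space Γ (a
`GenotypeSpace` with `m` loci and a fixed allele count per locus,
enumerated row-major with the last locus fastest) and the product of
per-locus simplices Θ (an `AllelicProfile`).

**Asexual (clonal) selection.** `asexualStep()` applies
d⁺_g = d_g w_g / w̄ on Δ(Γ). Point masses are its only fixed points
under generic fitness; zero-fitness genotypes leave the support and
never return. Model assumptions: infinite population, non-overlapping
generations, frequency-independent fitness, no mutation, migration or
drift.

**Haploid sexual selection.** With panmictic mating and free
recombination, each generation of offspring is in linkage equilibrium:
genotype frequencies are the product of per-locus allele frequencies.
The state reduces to Θ and `haploidStep()` applies
q⁺_ij = q_ij w_ij / w̄, where the marginal fitness w_ij of allele j at
locus i is the fitness of the genotypes carrying it, weighted by their
current (product-form) frequencies. `t1Step()` is the same map viewed
on Δ(Γ): project to marginals, update, lift back to the product.

**Genetic linkage.** A partition λ of the loci into blocks models
physical linkage: offspring inherit each block intact. `lambdaStep()`
realizes one generation of λ-type reproduction as "factorize by blocks,
select, re-factorize": the mating pool is the product of the
population's block marginals, selection reweights it by fitness, and the
offspring generation is again the product of the post-selection block
marginals. The coarsest partition (one block) is exactly the asexual
step for every input, and the finest partition is exactly `t1Step()` for
every input — including inputs in linkage disequilibrium, where the
per-locus projection is taken first. This makes the mixture dynamic
`recombinationTupleStep()` (d⁺ = Σ_λ r_λ T_λ(d)) agree with the
classical two-partition form d⁺ = r·T1(d) + (1−r)·T0(d) term by term. A
design note: one could instead define λ-reproduction by selecting on the
*actual* (linkage-disequilibriated) distribution before factorizing;
the two definitions coincide on linkage-equilibrium inputs, and we chose
the projection-first form because it is the one consistent with the
two-partition mixture above. Mixture trajectories leave linkage
equilibrium after one step, so the choice is substantive there.

**Diploid selection.** `diploidSingleStep()` implements
p⁺_i = p_i W_i / W̄ with W_i = (Wp)_i and W̄ = p'Wp for a symmetric
fitness matrix W over unordered allele pairs (random mating,
Hardy–Weinberg pairing, no position effects). Unlike the haploid case,
stable *mixed* equilibria (heterozygote advantage) are possible.
`diploidTwoLocusStep()` tracks two-locus gamete frequencies under random
union of gametes with recombination rate r: with probability 1−r an
offspring gamete is parental (drawn fitness-proportionally), with
probability r it swaps second-locus alleles between the two parental
gametes. The update is not a replicator — the difference
D_g = x_g W_g/W̄ − x⁺_g is the linkage disequilibrium residual, reported
per gamete — and mean fitness can genuinely decrease, which the
diagnostics report rather than forbid. The m-locus (m > 2) diploid
linkage-disequilibrium recursion is out of scope.

**Multiplicative weights and Baum–Eagon.** `mwuPolynomialStep()`
(d⁺_i ∝ d_i(1 + ηℓ_i)) and `mwuExponentialStep()` (d⁺_i ∝ d_i e^{ηℓ_i},
Hedge) are the online-learning forms of the same update; the
parameter-free polynomial mode (η → ∞) is literally the replicator, and
Hedge applied to log fitness reproduces it exactly. `baumEagonStep()` is
the growth transformation q⁺_ij ∝ q_ij ∂U/∂q_ij of a polynomial U with
nonnegative coefficients: it never decreases U, and with U the
multilinear mean-fitness polynomial it *is* the haploid step, with the
quadratic p'Wp it *is* the diploid single-locus step. These identities
are tested as oracle equivalences, not assumed.

## The game-theoretic reading

A fixed landscape induces an identical-interests game
(`gameFromLandscape()`): loci are players, alleles are actions, the
common payoff at a pure profile is the genotype's fitness, and mean
fitness is the game's potential (its multilinear extension is
`potentialValue()`). Pure Nash equilibria — profiles with no improving
unilateral deviation, equivalently local maxima of the potential — are
enumerated exactly (`enumeratePureNash()`, weak-inequality ties kept, so
degenerate landscapes may return plateaus). `findPotential()` decides
whether an arbitrary finite game is an exact potential game by
integrating payoff differences along coordinate paths from a reference
profile and verifying every unilateral edge at tolerance 1e-9; failure
returns `NULL` rather than a least-squares fit, because the downstream
theory needs exactness. Simultaneous best reply (`bestReplyStep()`,
lowest-index tie-break for determinism) illustrates why convergence of
independent MWU updating is not trivial: on the 2×2 coordination game it
cycles between the two miscoordinated profiles forever, while MWU
self-play from any full-support profile reaches the payoff-2
equilibrium.

## Environments and varying fitness

An `EnvironmentProcess` supplies one landscape per generation: fixed,
explicit cycled schedule, i.i.d. draws, a finite-state Markov chain, or
a callback. Realizations are deterministic given the stored seed and
never disturb the caller's RNG stream. For i.i.d. and Markov modes the
average one-step-ahead expected log fitness
ρ̂_t^g = (1/t) Σ_s E[ln w_g(next) | state_s] is computed in closed form
(for Markov environments the conditioning on the whole past reduces to
the current chain state); for arbitrary schedules no conditional law
exists and only the labelled plug-in estimator
`empiricalOneStepAhead()` is offered. Asymptotic superiority is decided
by a finite-horizon surrogate: tail-window min/max in place of
liminf/limsup, with the window defaulting to the last 20% of the
horizon. Where the classical statement of the ergodic-environment result
says "maximal expected fitness", the package deliberately uses maximal
expected *log* fitness: that is the criterion consistent with
multiplicative growth, and the two differ when fitness variance differs
across genotypes.

## Diagnostics and numerical choices

* **Distances** are max-norm on the natural state coordinates; vertex
  proximity and per-locus monomorphism are max-norm statements.
* **Two tolerances** separate fixed-point detection (1e-9, and a much
  tighter 1e-14 early-stop inside `runTrajectory()`) from vertex/ε-Nash
  classification (1e-6): interior saddle passages are slow and would be
  misclassified by a single loose tolerance.
* **Simplex hygiene**: every step renormalizes its output; states are
  validated to sum to one within 1e-12. No log-space representation is
  used — at desk-scale horizons (≤ 10⁶ steps) renormalization each
  generation prevents underflow.
* **Hedge overflow** is guarded by max-subtraction, which is exact
  because the update is invariant to adding constants to payoffs.
* **Regret** is computed in log-growth mode by default
  (ℓ_t(x_t) = ln w̄_t), where the asexual replicator satisfies the exact
  telescoping identity Π_t w̄_t = Σ_g d_g⁰ Π_t w_g^t and hence the bound
  R_n ≤ −ln min_g d_g⁰ under *every* environment realization. The
  best-in-hindsight comparator is searched over vertices only: the
  cumulative payoff is linear in the comparator, so the maximum is
  attained at a vertex anyway.
* **Virtual convergence** is reported as the finite-horizon average-gap;
  per-locus gaps score each locus against its best allele in hindsight
  given the *internal environment* (the other loci's realized
  frequencies), and require `recordEvery = 1`. Whether a joint
  genotype-level comparator with vanishing gap always exists is not
  guaranteed by the theory, so the joint gap is reported but only the
  per-locus gaps are asserted to shrink in tests.
* **Basins** are mapped by sampling flat Dirichlet(1, …, 1) initial
  states with a stored seed, running to convergence and matching the
  limit to a catalogued equilibrium within tolerance; non-converged
  samples are labelled `"none"`, never dropped.
* **Diploid equilibria** are found by support enumeration: on each
  support the marginal-fitness-equalization system is linear; solutions
  in the simplex are classified as stable when no off-support allele
  earns more than the equilibrium payoff and mean fitness is a local
  maximum under directional perturbations of size 1e-4. The step size
  matters: curvature effects scale with its square, and a much smaller
  step would fall below double-precision resolution and miss unstable
  mixed saddles. The enumeration is exponential in the allele count and
  intended for ≤ 10 alleles.
* **Monotonicity violations** under dynamics where mean fitness is
  provably a Lyapunov function are surfaced as warnings with the step
  index, not errors: exact ties can round either way, and the two-locus
  diploid dynamic is genuinely allowed to decrease.

## What the built-in fixtures and generators emulate

The five fixtures (`makeFixture()`) are the worked objects used
throughout the documentation and tests: two 3×3 two-locus fitness
matrices with opposite single peaks ("rainy"/"drought" years), a 2×2
coordination game, a two-genotype periodic environment with fitnesses
e^{1/2}/e^{1/3} swapped every 100 generations, and the heterozygote-
advantage diploid matrix. `randomLandscape()` draws i.i.d. fitness
values (uniform on (0, 1] or lognormal), redrawing on ties so instances
are generic — isolated equilibria, no payoff plateaus. That is what the
property tests rely on, and also what they show: passing them
demonstrates the dynamics' behaviour on generic landscapes under the
stated model assumptions (infinite panmictic populations, fitness known
exactly each generation). It does not demonstrate robustness to the
features real data add — finite-population drift, mutation, estimation
noise in fitness, frequency dependence — all of which are explicitly
outside the model class.

## Problem sizes used in the tests

The shipped test and acceptance runs use two-to-three-locus spaces with
two to four alleles per locus, horizons of 10⁴ generations for
fixed-fitness convergence (early-stopped at the 1e-14 fixed-point
criterion, typically after a few hundred generations), 10⁵ generations
for the Markov parameter-recovery property across 20 seeds, and 50+
seeded random instances for the monotonicity property. These sizes were
chosen because the quantities under test have already equilibrated far
below the asserted tolerances at those horizons; all dynamics scale
linearly in the number of genotypes per step except the partition and
two-locus-diploid steps (quadratic in block-marginal/gamete counts) and
the diploid equilibrium enumeration (exponential in alleles).

## Known limitations

Continuous-time replicator ODEs, mutation–selection balance,
finite-population (Wright–Fisher/Moran) sampling, mixed-Nash enumeration
for general games, analytic basin boundaries and the m > 2 diploid
linkage recursion are deliberately not implemented. Fitness values are
accepted on [0, ∞), not only [0, 1]: the dynamics use only fitness
ratios, and the periodic fixture's e^{1/2} > 1 would otherwise be
inexpressible.
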