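# evoGames

Discrete-time replicator dynamics and potential games for multi-locus
selection models.

## What this package is for

Population geneticists and evolutionary game theorists share one core
update rule: a probability vector reweighted by relative fitness,

    d_g(t+1) = d_g(t) · w_g(t) / w̄(t),        w̄(t) = Σ_g d_g(t) w_g(t).

`evoGames` implements this rule in all of its standard guises on
multi-locus genotype spaces — the asexual (clonal) replicator on the
genotype simplex Δ(Γ); the haploid sexual replicator on the product of
per-locus allele simplices Θ = Δ₁ × … × Δ_m, with genetic linkage
expressed through recombination partitions λ and recombination tuples
{r_λ}; single-locus diploid selection p⁺ = p·W p / p'Wp; the two-locus
diploid gamete recursion with its linkage-disequilibrium residual D_g;
and the multiplicative-weights (polynomial and exponential/Hedge) and
Baum–Eagon updates that unify them.

The unifying observation is game-theoretic: a fixed fitness landscape
makes the loci the players of an identical-interests game whose common
payoff is the genotype fitness and whose potential is mean fitness.
Selection at each locus is then multiplicative-weights updating of a
mixed strategy, so fixed-fitness trajectories climb the potential
(Baum–Eagon) and converge to pure Nash equilibria — the local maxima of
the landscape under single-locus allele swaps — while under arbitrarily
varying environments the same dynamics retain the no-regret guarantee of
multiplicative weights: realized average log growth matches the best
single genotype in hindsight ("virtual convergence") even when the
state never settles.

The package provides the game machinery (exact potential construction
and verification, pure Nash enumeration, best-reply steps, ε-Nash
certificates), seeded environment processes (fixed, scheduled, i.i.d.,
Markov), and the diagnostics that make the theory checkable at desk
scale: monomorphic/polymorphic convergence classification, Lyapunov
monotonicity checks, regret records, virtual-convergence gaps, basin
maps and local exponential rates.

## Worked example

The built-in fixture `table3_rainy` is a two-locus, three-alleles-per-
locus fitness matrix with a unique fitness peak of 0.80 at the allele
pair (1, 3):

```r
library(evoGames)
rainy <- makeFixture("table3_rainy")
enumeratePureNash(gameFromLandscape(rainy))
#>      [,1] [,2]
#> [1,]    1    3

tr <- runTrajectory("haploid", uniformProfile(rainy@space),
                    fixedEnvironment(rainy), 10000)
classifyConvergence(tr)
#> ConvergenceReport: monomorphic after 460 steps
#>   limiting mean fitness: 0.8
#>   limit alleles: ( 1, 3 )
```

The loci-as-players game of the rainy-year matrix has exactly one pure
Nash equilibrium, allele 1 at the first locus with allele 3 at the
second, and the haploid sexual replicator started from uniform allele
frequencies fixes on exactly that genotype: the run stops at a numerical
fixed point after 460 generations with limiting mean fitness 0.80, the
equilibrium genotype's own fitness.

A periodic environment shows the opposite regime. The fixture
`periodic_exp` alternates two single-locus landscapes (fitnesses e^{1/2}
and e^{1/3}, swapped every 100 generations), so neither genotype can
fix:

```r
pe <- makeFixture("periodic_exp")
trp <- runTrajectory("asexual", uniformDistribution(GenotypeSpace(2)),
                     pe, 2000, stopTol = 0)
classifyConvergence(trp)
#> ConvergenceReport: none after 2000 steps
#>   limiting mean fitness: 1.5221668

regretReport(trp)
#> RegretRecord (log-growth): horizon 2000, regret 0 (average 0), best vertex 1
```

The state oscillates forever (`status: none`), yet the regret against
the best genotype in hindsight is zero over whole periods: the
population's realized average log growth equals the 5/12 achieved by
either genotype alone — virtual convergence without convergence.

A command-line wrapper is installed with the package
(`inst/scripts/evogames`); `evogames nash --fixture table3_rainy`,
`evogames simulate --fixture table3_rainy --dynamic haploid --steps
10000 --out run` and friends drive the same functions from a shell.

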