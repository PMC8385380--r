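Package: evoGames
Title: Discrete-Time Replicator Dynamics and Potential Games for
    Multi-Locus Selection Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses discrete-time evolutionary dynamics on
    multi-locus genotype spaces: the asexual replicator, the haploid sexual
    replicator with and without genetic linkage (recombination partitions
    and recombination tuples), single-locus and two-locus diploid selection
    with linkage disequilibrium, multiplicative-weights updating (polynomial
    and exponential/Hedge) and generic Baum-Eagon monotone updates.
    Provides the accompanying game-theoretic machinery (loci-as-players
    identical-interests games, exact potential construction and
    verification, pure Nash enumeration, best-reply dynamics) and
    convergence diagnostics (monomorphic/polymorphic classification,
    Lyapunov monotonicity checks, regret and virtual-convergence metrics,
    basins of attraction, local exponential rates) together with seeded
    environment processes (fixed, scheduled, i.i.d., Markov) for
    temporally varying fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
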