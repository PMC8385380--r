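#' @import methods
NULL

.PROB_TOL <- 1e-12

.isProb <- function(x, tol = .PROB_TOL) {
  is.numeric(x) && length(x) >= 1L && all(is.finite(x)) &&
    all(x >= -tol) && abs(sum(x) - 1) <= max(tol, length(x) * tol)
}

#' GenotypeSpace: a multi-locus allele state space
#'
#' Describes an abstract genotype space with `m` loci and a fixed number of
#' alleles per locus. A genotype is a tuple of allele indices, one per
#' locus; genotypes are enumerated row-major (last locus varies fastest),
#' giving a bijection with `1..numGenotypes`.
#'
#' @slot numLoci integer, number of loci (>= 1).
#' @slot allelesPerLocus integer vector, alleles at each locus (each >= 1).
#' @export
setClass("GenotypeSpace",
  representation(numLoci = "integer", allelesPerLocus = "integer"),
  validity = function(object) {
    if (length(object@numLoci) != 1L || object@numLoci < 1L)
      return("numLoci must be a single integer >= 1")
    if (length(object@allelesPerLocus) != object@numLoci)
      return("allelesPerLocus must have one entry per locus")
    if (any(object@allelesPerLocus < 1L))
      return("every locus needs at least one allele")
    TRUE
  })

#' FitnessLandscape: one fitness value per genotype
#'
#' @slot space a [GenotypeSpace-class].
#' @slot values numeric vector of non-negative fitnesses in row-major
#'   genotype order; at least one value must be positive. Values above 1
#'   are allowed (only fitness ratios enter the dynamics).
#' @slot label optional environment tag.
#' @export
setClass("FitnessLandscape",
  representation(space = "GenotypeSpace", values = "numeric",
                 label = "character"),
  validity = function(object) {
    n <- prod(object@space@allelesPerLocus)
    if (length(object@values) != n)
      return(sprintf("values must have length %d (one per genotype)", n))
    if (!all(is.finite(object@values)) || any(object@values < 0))
      return("fitness values must be finite and >= 0")
    if (!any(object@values > 0))
      return("at least one fitness value must be > 0")
    TRUE
  })

#' GenotypeDistribution: a probability vector over genotypes
#'
#' A point of the genotype simplex: relative proportions of each genotype
#' in an (infinite) population.
#'
#' @slot space a [GenotypeSpace-class].
#' @slot weights probability vector over genotypes (row-major order).
#' @export
setClass("GenotypeDistribution",
  representation(space = "GenotypeSpace", weights = "numeric"),
  validity = function(object) {
    n <- prod(object@space@allelesPerLocus)
    if (length(object@weights) != n)
      return("weights must have one entry per genotype")
    if (!.isProb(object@weights))
      return("weights must be a probability vector (sum 1 within 1e-12)")
    TRUE
  })

#' AllelicProfile: per-locus allele frequency vectors
#'
#' A point of the product of per-locus simplices: one allele-frequency
#' vector per locus. Interpreted game-theoretically as a mixed-strategy
#' profile of the loci-as-players game.
#'
#' @slot space a [GenotypeSpace-class].
#' @slot freqs list of per-locus probability vectors.
#' @export
setClass("AllelicProfile",
  representation(space = "GenotypeSpace", freqs = "list"),
  validity = function(object) {
    k <- object@space@allelesPerLocus
    if (length(object@freqs) != length(k))
      return("freqs must have one vector per locus")
    for (i in seq_along(k)) {
      if (length(object@freqs[[i]]) != k[i])
        return(sprintf("locus %d frequency vector has wrong length", i))
      if (!.isProb(object@freqs[[i]]))
        return(sprintf("locus %d frequencies are not a probability vector", i))
    }
    TRUE
  })

#' DiploidLandscape: symmetric fitness matrix for unordered allele pairs
#'
#' Single-locus diploid fitnesses: entry (i, j) is the fitness of genotype
#' a_i a_j; no position effects, so the matrix is symmetric.
#'
#' @slot numAlleles integer, number of alleles.
#' @slot values symmetric numeric matrix of non-negative fitnesses.
#' @slot label optional tag.
#' @export
setClass("DiploidLandscape",
  representation(numAlleles = "integer", values = "matrix",
                 label = "character"),
  validity = function(object) {
    n <- object@numAlleles
    if (!all(dim(object@values) == c(n, n)))
      return("values must be an numAlleles x numAlleles matrix")
    if (!all(is.finite(object@values)) || any(object@values < 0))
      return("diploid fitnesses must be finite and >= 0")
    if (max(abs(object@values - t(object@values))) > 0)
      return("diploid fitness matrix must be symmetric")
    TRUE
  })

#' GameteState: two-locus diploid gamete frequencies with pair fitnesses
#'
#' Tracks the distribution of gametes (haploid halves of diploid
#' genotypes) on a two-locus space, together with the symmetric fitness of
#' each unordered gamete pairing.
#'
#' @slot space a two-locus [GenotypeSpace-class] (the gamete space).
#' @slot freqs probability vector over gametes.
#' @slot pairFitness symmetric matrix, fitness of each gamete pairing.
#' @export
setClass("GameteState",
  representation(space = "GenotypeSpace", freqs = "numeric",
                 pairFitness = "matrix"),
  validity = function(object) {
    if (object@space@numLoci != 2L)
      return("gamete space must have exactly two loci")
    n <- prod(object@space@allelesPerLocus)
    if (length(object@freqs) != n)
      return("freqs must have one entry per gamete")
    if (!.isProb(object@freqs))
      return("gamete frequencies must be a probability vector")
    if (!all(dim(object@pairFitness) == c(n, n)))
      return("pairFitness must be a square matrix over gametes")
    if (!all(is.finite(object@pairFitness)) || any(object@pairFitness < 0))
      return("pair fitnesses must be finite and >= 0")
    if (max(abs(object@pairFitness - t(object@pairFitness))) > 1e-12)
      return("pairFitness must be symmetric")
    TRUE
  })

#' FiniteGame: a finite normal-form game
#'
#' Payoffs are stored per player as a vector over pure action profiles in
#' row-major profile order (last player's action varies fastest), the same
#' enumeration convention used for genotypes.
#'
#' @slot numPlayers integer.
#' @slot actionCounts integer vector of actions per player.
#' @slot payoffs list (one numeric vector per player) over profiles.
#' @export
setClass("FiniteGame",
  representation(numPlayers = "integer", actionCounts = "integer",
                 payoffs = "list"),
  validity = function(object) {
    if (length(object@actionCounts) != object@numPlayers)
      return("actionCounts must have one entry per player")
    if (any(object@actionCounts < 1L))
      return("every player needs at least one action")
    n <- prod(object@actionCounts)
    if (length(object@payoffs) != object@numPlayers)
      return("payoffs must have one vector per player")
    for (i in seq_len(object@numPlayers)) {
      if (length(object@payoffs[[i]]) != n)
        return(sprintf("player %d payoff vector has wrong length", i))
      if (!all(is.finite(object@payoffs[[i]])))
        return("payoffs must be finite")
    }
    TRUE
  })

#' PotentialGame: a finite game together with an exact potential
#'
#' The potential satisfies, for every player and every unilateral
#' deviation, `Phi(a', a_-i) - Phi(a'', a_-i) = u_i(a', a_-i) -
#' u_i(a'', a_-i)` (within 1e-9). Validity checks this on every edge.
#'
#' @slot game a [FiniteGame-class].
#' @slot potential numeric vector over pure profiles.
#' @export
setClass("PotentialGame",
  representation(game = "FiniteGame", potential = "numeric"),
  validity = function(object) {
    n <- prod(object@game@actionCounts)
    if (length(object@potential) != n)
      return("potential must have one value per profile")
    dev <- .maxPotentialDeviation(object@game, object@potential)
    if (dev > 1e-9)
      return(sprintf(
        "potential mismatch on some unilateral edge (max %.3g)", dev))
    TRUE
  })

#' Partition: a partition of the loci into linkage blocks
#'
#' Blocks of loci inherited intact from one parent during reproduction.
#'
#' @slot numLoci integer, number of loci partitioned.
#' @slot blocks list of disjoint non-empty integer vectors covering
#'   `1..numLoci`.
#' @export
setClass("Partition",
  representation(numLoci = "integer", blocks = "list"),
  validity = function(object) {
    all_loci <- sort(unlist(object@blocks))
    if (any(lengths(object@blocks) == 0L))
      return("blocks must be non-empty")
    if (!identical(as.integer(all_loci), seq_len(object@numLoci)))
      return("blocks must be disjoint and cover all loci exactly once")
    TRUE
  })

#' RecombinationTuple: a probability distribution over linkage partitions
#'
#' Weight `r_lambda` is the probability that an offspring is produced by
#' partition-`lambda` linkage; weights sum to one.
#'
#' @slot partitions list of [Partition-class] objects over one locus set.
#' @slot weights non-negative numeric weights summing to 1.
#' @export
setClass("RecombinationTuple",
  representation(partitions = "list", weights = "numeric"),
  validity = function(object) {
    if (length(object@partitions) != length(object@weights))
      return("one weight per partition required")
    if (length(object@partitions) == 0L)
      return("at least one partition required")
    m <- object@partitions[[1L]]@numLoci
    for (p in object@partitions) {
      if (!is(p, "Partition")) return("partitions must be Partition objects")
      if (p@numLoci != m) return("all partitions must share one locus set")
    }
    if (any(object@weights < 0) ||
        abs(sum(object@weights) - 1) > .PROB_TOL * length(object@weights))
      return("weights must be >= 0 and sum to 1 within 1e-12")
    TRUE
  })

#' EnvironmentProcess: a seeded source of per-generation fitness landscapes
#'
#' Supplies one fitness landscape per generation. Modes: `"fixed"` (one
#' landscape forever), `"schedule"` (a cycled explicit sequence),
#' `"iid"` (independent draws from a probability vector), `"markov"`
#' (a finite-state Markov chain), `"callback"` (a user function
#' `t -> landscape index`). Realizations are deterministic given `seed`.
#'
#' @slot mode one of "fixed", "schedule", "iid", "markov", "callback".
#' @slot landscapes list of landscape objects sharing one state space.
#' @slot labels character labels, one per landscape.
#' @slot schedule integer indices cycled in schedule mode.
#' @slot probs draw probabilities (iid mode).
#' @slot transition row-stochastic transition matrix (markov mode).
#' @slot init initial state distribution (markov mode).
#' @slot callback function of the time index (callback mode).
#' @slot seed integer RNG seed for iid/markov realizations.
#' @export
setClass("EnvironmentProcess",
  representation(mode = "character", landscapes = "list",
                 labels = "character", schedule = "integer",
                 probs = "numeric", transition = "matrix",
                 init = "numeric", callback = "ANY", seed = "integer"),
  validity = function(object) {
    k <- length(object@landscapes)
    if (k < 1L) return("at least one landscape required")
    if (length(object@labels) != k)
      return("one label per landscape required")
    cls <- vapply(object@landscapes, function(x) class(x)[1L], character(1))
    if (length(unique(cls)) != 1L)
      return("all landscapes must have the same class")
    if (object@mode == "schedule") {
      if (length(object@schedule) == 0L) return("schedule must be non-empty")
      if (any(object@schedule < 1L) || any(object@schedule > k))
        return("schedule indices out of range")
    } else if (object@mode == "iid") {
      if (length(object@probs) != k || !.isProb(object@probs))
        return("probs must be a probability vector over landscapes")
    } else if (object@mode == "markov") {
      if (!all(dim(object@transition) == c(k, k)))
        return("transition must be k x k")
      if (any(object@transition < 0) ||
          max(abs(rowSums(object@transition) - 1)) > .PROB_TOL * k)
        return("transition rows must sum to 1 within 1e-12")
      if (length(object@init) != k || !.isProb(object@init))
        return("init must be a probability vector over landscapes")
    } else if (object@mode == "callback") {
      if (!is.function(object@callback))
        return("callback mode requires a function")
    } else if (object@mode != "fixed") {
      return("unknown environment mode")
    }
    TRUE
  })

#' Trajectory: a recorded run of a discrete evolutionary dynamic
#'
#' Holds the per-step mean fitness and environment index for every step,
#' plus state snapshots at recorded times (always including the initial
#' state and the final two consecutive states, so convergence can be
#' classified).
#'
#' @slot dynamic name of the step operator iterated.
#' @slot states list of state objects at the recorded times.
#' @slot recordedAt integer times (0-based) of the recorded states.
#' @slot meanFitness numeric, mean fitness of the pre-update state under
#'   the step-t landscape, for t = 1..steps.
#' @slot envIndex integer landscape index used at each step.
#' @slot env the [EnvironmentProcess-class] that supplied the landscapes.
#' @slot steps number of steps actually taken.
#' @slot stopReason "completed" or "fixed_point".
#' @export
setClass("Trajectory",
  representation(dynamic = "character", states = "list",
                 recordedAt = "integer", meanFitness = "numeric",
                 envIndex = "integer", env = "EnvironmentProcess",
                 steps = "integer", stopReason = "character"),
  validity = function(object) {
    if (length(object@states) != length(object@recordedAt))
      return("one recorded time per recorded state")
    if (length(object@meanFitness) != object@steps ||
        length(object@envIndex) != object@steps)
      return("meanFitness and envIndex must have one entry per step")
    TRUE
  })
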