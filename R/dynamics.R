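# Step operators: asexual and haploid replicators, linkage partitions and
# recombination tuples, diploid selection, multiplicative weights, and the
# generic Baum-Eagon monotone update.

#' Construct a Partition of the loci
#'
#' @param numLoci number of loci.
#' @param blocks list of disjoint integer vectors covering `1..numLoci`.
#' @return a [Partition-class].
#' @examples
#' coarsestPartition(3)  # one block: asexual inheritance
#' finestPartition(3)    # singleton blocks: free recombination
#' @export
Partition <- function(numLoci, blocks) {
  new("Partition", numLoci = as.integer(numLoci),
      blocks = lapply(blocks, as.integer))
}

#' @rdname Partition
#' @export
coarsestPartition <- function(numLoci)
  Partition(numLoci, list(seq_len(numLoci)))

#' @rdname Partition
#' @export
finestPartition <- function(numLoci)
  Partition(numLoci, as.list(seq_len(numLoci)))

setMethod("show", "Partition", function(object) {
  cat("Partition of", object@numLoci, "loci:",
      paste(vapply(object@blocks,
                   function(b) paste0("{", paste(b, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
})

#' Construct a RecombinationTuple
#'
#' A probability distribution over linkage partitions: each offspring is
#' produced under partition `lambda` with probability `r_lambda`. The
#' two-partition tuple `{coarsest: 1 - r, finest: r}` recovers the
#' classical single recombination rate `r`.
#'
#' @param partitions list of [Partition-class] objects.
#' @param weights non-negative weights summing to 1.
#' @return a [RecombinationTuple-class].
#' @export
RecombinationTuple <- function(partitions, weights) {
  new("RecombinationTuple", partitions = partitions,
      weights = as.numeric(weights))
}

#' @rdname RecombinationTuple
#' @param numLoci number of loci.
#' @param r probability of free recombination (finest partition); the
#'   complement is asexual (coarsest-partition) reproduction.
#' @export
recombinationRateTuple <- function(numLoci, r) {
  stopifnot(r >= 0, r <= 1)
  RecombinationTuple(list(coarsestPartition(numLoci),
                          finestPartition(numLoci)),
                     c(1 - r, r))
}

setMethod("show", "RecombinationTuple", function(object) {
  cat("RecombinationTuple over", length(object@partitions),
      "partitions, weights (",
      paste(format(object@weights, digits = 4), collapse = ", "), ")\n")
})

.extinct <- function() {
  stop("extinction error: population mean fitness is zero", call. = FALSE)
}

#' Asexual (clonal) replicator step
#'
#' `d_g^+ = d_g w_g / wbar`. Support can only shrink (zero-fitness
#' genotypes vanish); point masses are fixed points; under a constant
#' landscape every distribution is a fixed point.
#'
#' @param d a [GenotypeDistribution-class].
#' @param w a [FitnessLandscape-class] on the same space.
#' @return the next-generation [GenotypeDistribution-class].
#' @examples
#' sp <- GenotypeSpace(2)
#' d <- GenotypeDistribution(sp, c(0.5, 0.5))
#' w <- FitnessLandscape(sp, c(0.8, 0.4))
#' genotypeWeights(asexualStep(d, w))  # (2/3, 1/3)
#' @export
asexualStep <- function(d, w) {
  .checkSameSpace(d, w, "distribution and landscape")
  v <- d@weights * w@values
  s <- sum(v)
  if (s <= 0) .extinct()
  GenotypeDistribution(d@space, v / s)
}

#' Polynomial multiplicative-weights update
#'
#' `d_i^+ = d_i (1 + eta l_i) / sum_j d_j (1 + eta l_j)`. With
#' `eta = "parameter-free"` (the limit eta -> infinity) the update is
#' `d_i l_i / sum_j d_j l_j`, which is exactly the replicator equation
#' with `l` in the role of fitness; that mode requires strictly positive
#' payoffs on the support.
#'
#' @param d probability vector.
#' @param payoffs numeric payoff per coordinate.
#' @param eta positive step size, or `"parameter-free"` (default).
#' @return the updated probability vector.
#' @export
mwuPolynomialStep <- function(d, payoffs, eta = "parameter-free") {
  stopifnot(length(d) == length(payoffs))
  if (identical(eta, "parameter-free") || is.infinite(eta)) {
    if (any(d > 0 & payoffs <= 0))
      stop("step-size error: parameter-free updating requires strictly ",
           "positive payoffs on the support", call. = FALSE)
    v <- d * payoffs
  } else {
    stopifnot(is.numeric(eta), eta > 0)
    f <- 1 + eta * payoffs
    if (any(d > 0 & f <= 0))
      stop("step-size error: 1 + eta * payoff must stay positive on the ",
           "support", call. = FALSE)
    v <- d * f
  }
  v / sum(v)
}

#' Exponential multiplicative-weights (Hedge) update
#'
#' `d_i^+` proportional to `d_i exp(eta l_i)`. The maximum payoff is
#' subtracted before exponentiation, which guards against overflow and is
#' exact because the update is invariant to adding a constant to the
#' payoffs. With `l_i = ln(f_i) / eta` this reproduces the replicator
#' step on fitnesses `f`.
#'
#' @inheritParams mwuPolynomialStep
#' @param eta positive step size.
#' @return the updated probability vector.
#' @export
mwuExponentialStep <- function(d, payoffs, eta = 1) {
  stopifnot(length(d) == length(payoffs), all(is.finite(payoffs)),
            is.numeric(eta), eta > 0)
  z <- eta * payoffs
  v <- d * exp(z - max(z))
  v / sum(v)
}

#' Haploid sexual replicator step on allele frequencies
#'
#' `q_ij^+ = q_ij w_ij / wbar`, where `w_ij` is the marginal fitness of
#' allele `j` at locus `i` under the linkage-equilibrium lift of `q` and
#' `wbar` the corresponding mean fitness. Free recombination and random
#' mating keep each generation in linkage equilibrium, so the state lives
#' on the product of per-locus simplices.
#'
#' @param q an [AllelicProfile-class].
#' @param w a [FitnessLandscape-class] on the same space.
#' @return the next-generation [AllelicProfile-class].
#' @export
haploidStep <- function(q, w) {
  .checkSameSpace(q, w, "profile and landscape")
  d <- .liftWeights(q)
  sel <- d * w@values
  wbar <- sum(sel)
  if (wbar <= 0) .extinct()
  tup <- genotypeTuples(q@space)
  k <- q@space@allelesPerLocus
  freqs <- lapply(seq_along(k), function(i) {
    num <- numeric(k[i])
    for (j in seq_len(k[i])) num[j] <- sum(sel[tup[, i] == j])
    num / sum(num)
  })
  AllelicProfile(q@space, freqs)
}

# product over partition blocks of the block marginals of `weights`
.blockFactorize <- function(weights, tup, blocks) {
  out <- rep(1, length(weights))
  for (b in blocks) {
    sub <- tup[, b, drop = FALSE]
    key <- sub[, 1L]
    if (length(b) > 1L)
      for (u in 2:length(b)) key <- (key - 1L) * max(sub[, u]) + sub[, u]
    marg <- rowsum(weights, key)
    out <- out * marg[match(key, as.integer(rownames(marg)))]
  }
  as.numeric(out)
}

#' Haploid sexual replicator step on genotype distributions
#'
#' The genotype-simplex form of the haploid dynamic: project to allele
#' frequencies, apply the haploid replicator, lift back to the (linkage
#' equilibrium) product distribution. Equals [asexualStep()] on
#' single-locus spaces, and its output always has zero
#' [linkageDeviation()].
#'
#' @param d a [GenotypeDistribution-class].
#' @param w a [FitnessLandscape-class].
#' @return a [GenotypeDistribution-class] in linkage equilibrium.
#' @export
t1Step <- function(d, w) {
  liftRhoInverse(haploidStep(projectRho(d), w))
}

#' Replicator step under a linkage partition
#'
#' Reproduction in which each offspring inherits every block of the
#' partition intact from one parent, independently across blocks: the
#' population is first replaced by the product of its block marginals
#' (mating randomizes across blocks), selection reweights by fitness, and
#' the offspring generation is again the product of the post-selection
#' block marginals. The coarsest partition gives exactly [asexualStep()];
#' the finest gives exactly [t1Step()].
#'
#' @param d a [GenotypeDistribution-class].
#' @param w a [FitnessLandscape-class].
#' @param partition a [Partition-class] of the loci.
#' @return a [GenotypeDistribution-class].
#' @export
lambdaStep <- function(d, w, partition) {
  .checkSameSpace(d, w, "distribution and landscape")
  stopifnot(is(partition, "Partition"),
            partition@numLoci == d@space@numLoci)
  tup <- genotypeTuples(d@space)
  dl <- .blockFactorize(d@weights, tup, partition@blocks)
  sel <- dl * w@values
  wbar <- sum(sel)
  if (wbar <= 0) .extinct()
  out <- .blockFactorize(sel / wbar, tup, partition@blocks)
  GenotypeDistribution(d@space, out / sum(out))
}

#' Replicator step under a recombination tuple
#'
#' The convex combination `d^+ = sum_lambda r_lambda T_lambda(d)` of the
#' per-partition steps: fraction `r_lambda` of each offspring generation
#' is produced under partition `lambda`. With the two-partition tuple
#' `{coarsest: 1 - r, finest: r}` this is the classical
#' recombination-rate-`r` dynamic `d^+ = r T1(d) + (1 - r) T0(d)`.
#'
#' @param d a [GenotypeDistribution-class].
#' @param w a [FitnessLandscape-class].
#' @param rTuple a [RecombinationTuple-class].
#' @return a [GenotypeDistribution-class].
#' @export
recombinationTupleStep <- function(d, w, rTuple) {
  stopifnot(is(rTuple, "RecombinationTuple"))
  out <- numeric(numGenotypes(d@space))
  for (l in seq_along(rTuple@partitions)) {
    if (rTuple@weights[l] == 0) next
    out <- out + rTuple@weights[l] *
      lambdaStep(d, w, rTuple@partitions[[l]])@weights
  }
  GenotypeDistribution(d@space, out / sum(out))
}

#' Single-locus diploid replicator step
#'
#' `p_i^+ = p_i W_i / Wbar` with marginal fitness `W_i = sum_j p_j W_ij`
#' and mean fitness `Wbar = p' W p`. Random mating (Hardy-Weinberg
#' pairing) precedes selection each generation.
#'
#' @param p allele-frequency vector.
#' @param W a [DiploidLandscape-class].
#' @return the next-generation allele-frequency vector.
#' @examples
#' het <- DiploidLandscape(matrix(c(0, 1, 1, 0), 2, 2))
#' diploidSingleStep(c(0.8, 0.2), het)  # jumps to (0.5, 0.5)
#' @export
diploidSingleStep <- function(p, W) {
  stopifnot(is(W, "DiploidLandscape"), length(p) == W@numAlleles)
  Wi <- as.numeric(W@values %*% p)
  wbar <- sum(p * Wi)
  if (wbar <= 0) .extinct()
  v <- p * Wi / wbar
  v / sum(v)
}

#' Two-locus diploid gamete-frequency step with recombination
#'
#' Random union of gametes with recombination: with probability `1 - r`
#' an offspring gamete is a parental gamete drawn
#' fitness-proportionally, with probability `r` it is a recombinant that
#' swaps the second-locus alleles of the two parental gametes:
#' \deqn{x^+_{(i,j)} \bar W = (1-r) \sum_{(k,l)} x_{(i,j)} x_{(k,l)}
#'   W_{(i,j),(k,l)} + r \sum_{(k,l)} x_{(i,l)} x_{(k,j)}
#'   W_{(i,l),(k,j)}.}
#' The linkage-disequilibrium residual `D_g = x_g W_g / Wbar - x_g^+`
#' (zero for all gametes when `r = 0`) is returned alongside the state
#' when `details = TRUE`. Because of `D_g` this dynamic is not a
#' replicator and mean fitness need not increase.
#'
#' @param x a [GameteState-class].
#' @param r recombination rate in `[0, 1]`.
#' @param details if `TRUE`, return a list with the new state, the
#'   disequilibrium vector `D`, and the pre-step mean fitness.
#' @return a [GameteState-class], or a list when `details = TRUE`.
#' @export
diploidTwoLocusStep <- function(x, r, details = FALSE) {
  stopifnot(is(x, "GameteState"), r >= 0, r <= 1)
  k <- x@space@allelesPerLocus
  tup <- genotypeTuples(x@space)
  n <- nrow(tup)
  W <- x@pairFitness
  f <- x@freqs
  Wg <- as.numeric(W %*% f)      # marginal gamete fitness
  wbar <- sum(f * Wg)
  if (wbar <= 0) .extinct()
  parental <- f * Wg
  recomb <- numeric(n)
  if (r > 0) {
    idx <- function(i, j) (i - 1L) * k[2L] + j
    for (a in seq_len(n)) {
      i <- tup[a, 1L]; j <- tup[a, 2L]
      acc <- 0
      for (b in seq_len(n)) {
        kk <- tup[b, 1L]; ll <- tup[b, 2L]
        g1 <- idx(i, ll); g2 <- idx(kk, j)
        acc <- acc + f[g1] * f[g2] * W[g1, g2]
      }
      recomb[a] <- acc
    }
  }
  xplus <- ((1 - r) * parental + r * recomb) / wbar
  xplus <- pmax(xplus, 0)
  xplus <- xplus / sum(xplus)
  out <- GameteState(x@space, xplus, W)
  if (details)
    list(state = out, D = f * Wg / wbar - xplus, meanFitness = wbar)
  else out
}

# ---- Baum-Eagon polynomials ---------------------------------------------

#' Polynomials with nonnegative coefficients over simplex variables
#'
#' Representation used by [baumEagonStep()]: variables are the allele
#' frequencies `q_ij`, flattened locus by locus; a polynomial is a set of
#' monomials, each with a nonnegative coefficient and an integer exponent
#' per variable.
#'
#' `meanFitnessPolynomial` builds the multilinear mean-fitness polynomial
#' of a fitness landscape (one monomial per genotype);
#' `diploidMeanFitnessPolynomial` builds the quadratic `p' W p` of a
#' diploid landscape on a single simplex.
#'
#' @param counts integer vector: simplex sizes (alleles per locus).
#' @param coef numeric vector of nonnegative monomial coefficients.
#' @param expo integer matrix, one row per monomial, one column per
#'   flattened variable.
#' @return an object of class `"bePolynomial"`.
#' @export
bePolynomial <- function(counts, coef, expo) {
  counts <- as.integer(counts)
  expo <- as.matrix(expo)
  storage.mode(expo) <- "double"
  stopifnot(length(coef) == nrow(expo), ncol(expo) == sum(counts),
            all(coef >= 0), all(expo >= 0))
  structure(list(counts = counts, coef = as.numeric(coef), expo = expo),
            class = "bePolynomial")
}

#' @rdname bePolynomial
#' @param w a [FitnessLandscape-class].
#' @export
meanFitnessPolynomial <- function(w) {
  k <- w@space@allelesPerLocus
  tup <- genotypeTuples(w@space)
  off <- c(0L, cumsum(k))[seq_along(k)]
  expo <- matrix(0, nrow(tup), sum(k))
  for (i in seq_along(k))
    expo[cbind(seq_len(nrow(tup)), off[i] + tup[, i])] <- 1
  bePolynomial(k, w@values, expo)
}

#' @rdname bePolynomial
#' @param W a [DiploidLandscape-class].
#' @export
diploidMeanFitnessPolynomial <- function(W) {
  n <- W@numAlleles
  coefs <- c()
  rows <- list()
  for (i in seq_len(n)) for (j in i:n) {
    e <- numeric(n)
    e[i] <- e[i] + 1
    e[j] <- e[j] + 1
    coefs <- c(coefs, if (i == j) W@values[i, i] else 2 * W@values[i, j])
    rows[[length(rows) + 1L]] <- e
  }
  bePolynomial(n, coefs, do.call(rbind, rows))
}

#' @rdname bePolynomial
#' @param U a `"bePolynomial"`.
#' @param qflat numeric vector of all variables, flattened locus by locus.
#' @export
bePolyValue <- function(U, qflat) {
  stopifnot(length(qflat) == ncol(U$expo))
  vals <- vapply(seq_along(U$coef), function(t)
    U$coef[t] * prod(qflat ^ U$expo[t, ]), numeric(1))
  sum(vals)
}

# gradient of U at qflat (handles variables at 0 exactly)
.bePolyGrad <- function(U, qflat) {
  nv <- ncol(U$expo)
  grad <- numeric(nv)
  for (t in seq_along(U$coef)) {
    e <- U$expo[t, ]
    for (v in which(e > 0)) {
      e2 <- e
      e2[v] <- e2[v] - 1
      grad[v] <- grad[v] + U$coef[t] * e[v] * prod(qflat ^ e2)
    }
  }
  grad
}

#' Baum-Eagon growth-transformation step
#'
#' For a polynomial `U` with nonnegative coefficients over product-simplex
#' variables, the update
#' `q_ij^+ = q_ij (dU/dq_ij) / sum_s q_is (dU/dq_is)` increases `U`
#' strictly unless `q` is a fixed point. With `U` the multilinear
#' mean-fitness polynomial this reproduces [haploidStep()] exactly; with
#' the quadratic `p' W p` of a diploid landscape it reproduces
#' [diploidSingleStep()]; with a linear `U` it is the asexual replicator.
#'
#' @param q an [AllelicProfile-class] (use a one-locus profile for a
#'   single simplex).
#' @param U a `"bePolynomial"` over matching variables.
#' @return the updated [AllelicProfile-class].
#' @export
baumEagonStep <- function(q, U) {
  stopifnot(is(q, "AllelicProfile"), inherits(U, "bePolynomial"),
            identical(as.integer(q@space@allelesPerLocus), U$counts))
  qflat <- unlist(q@freqs, use.names = FALSE)
  grad <- .bePolyGrad(U, qflat)
  k <- U$counts
  off <- c(0L, cumsum(k))
  freqs <- vector("list", length(k))
  for (i in seq_along(k)) {
    idx <- (off[i] + 1L):off[i + 1L]
    num <- qflat[idx] * grad[idx]
    den <- sum(num)
    if (den <= 0)
      stop("degenerate-state error: zero Baum-Eagon denominator at locus ",
           i, call. = FALSE)
    freqs[[i]] <- num / den
  }
  AllelicProfile(q@space, freqs)
}
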