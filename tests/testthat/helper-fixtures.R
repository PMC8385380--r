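# Shared helpers: seeded random states, an independent brute-force Nash
# oracle, and a self-play MWU loop for games.

rdirichlet1 <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}

randDistribution <- function(space) {
  GenotypeDistribution(space, rdirichlet1(numGenotypes(space)))
}

randProfile <- function(space) {
  AllelicProfile(space, lapply(allelesPerLocus(space), rdirichlet1))
}

# Brute-force pure Nash scan, independent of the package's enumeration:
# walks every profile/player/deviation through its own expand.grid
# indexing of the payoff arrays.
bruteForceNash <- function(actionCounts, payoffList) {
  m <- length(actionCounts)
  grid <- as.matrix(rev(expand.grid(rev(lapply(actionCounts, seq_len)))))
  colnames(grid) <- NULL
  flat <- function(a) {
    idx <- 0
    for (i in seq_len(m)) idx <- idx * actionCounts[i] + (a[i] - 1)
    idx + 1
  }
  nash <- list()
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    ok <- TRUE
    for (i in seq_len(m)) {
      ua <- payoffList[[i]][flat(a)]
      for (alt in seq_len(actionCounts[i])) {
        b <- a
        b[i] <- alt
        if (payoffList[[i]][flat(b)] > ua) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) nash[[length(nash) + 1L]] <- a
  }
  if (length(nash)) do.call(rbind, nash) else
    matrix(integer(0), 0, m)
}

# every player simultaneously applies parameter-free polynomial MWU to its
# own mixed strategy against the others'; returns the final profile
mwuSelfPlay <- function(game, x, maxSteps = 50000, gapTol = 1e-6,
                        checkEvery = 50) {
  np <- length(actionCounts(game))
  for (t in seq_len(maxSteps)) {
    x <- lapply(seq_len(np), function(i) {
      pay <- vapply(seq_len(actionCounts(game)[i]), function(a)
        expectedPayoff(game, x, i, a), numeric(1))
      mwuPolynomialStep(x[[i]], pay)
    })
    if (t %% checkEvery == 0L && epsilonNashGap(game, x) <= gapTol)
      break
  }
  x
}

table3RainyValues <- c(0.40, 0.60, 0.80,
                       0.48, 0.55, 0.75,
                       0.20, 0.51, 0.70)
table3DroughtValues <- c(0.40, 0.48, 0.20,
                         0.60, 0.55, 0.51,
                         0.80, 0.75, 0.70)

# two-locus gamete-pair fitness with strong coupling epistasis: the
# coupling gametes (1,1) and (2,2) pair well, everything else is poor
epistaticPairFitness <- function() {
  W <- matrix(0.2, 4, 4)
  W[1, 1] <- W[4, 4] <- W[1, 4] <- W[4, 1] <- 1
  W
}
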