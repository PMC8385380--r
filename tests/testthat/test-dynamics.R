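test_that("the asexual replicator reweights by relative fitness", {
  sp <- GenotypeSpace(2)
  d <- GenotypeDistribution(sp, c(0.5, 0.5))
  w <- FitnessLandscape(sp, c(0.8, 0.4))
  expect_equal(genotypeWeights(asexualStep(d, w)), c(2 / 3, 1 / 3),
               tolerance = 1e-15)
  # constant fitness: every distribution is a fixed point
  wc <- FitnessLandscape(sp, c(0.3, 0.3))
  expect_equal(genotypeWeights(asexualStep(d, wc)), c(0.5, 0.5))
  # point masses are fixed points; zero-fitness support vanishes
  expect_equal(genotypeWeights(asexualStep(pointMass(sp, 2), w)),
               c(0, 1))
  w0 <- FitnessLandscape(sp, c(1, 0))
  expect_equal(genotypeWeights(asexualStep(d, w0)), c(1, 0))
  expect_error(asexualStep(pointMass(sp, 2), w0), "extinction")
})

test_that("polynomial MWU interpolates between identity and the replicator", {
  # parameter-free mode with fitness payoffs is exactly the replicator
  set.seed(31)
  for (rep in 1:5) {
    sp <- GenotypeSpace(4)
    w <- randomLandscape(sp, seed = 400 + rep)
    d <- rdirichlet1(4)
    expect_equal(mwuPolynomialStep(d, fitnessValues(w)),
                 genotypeWeights(asexualStep(GenotypeDistribution(sp, d),
                                             w)),
                 tolerance = 1e-14)
  }
  expect_equal(mwuPolynomialStep(c(0.5, 0.5), c(1, 0), eta = 1),
               c(2 / 3, 1 / 3))
  # small eta barely moves the state
  d <- c(0.3, 0.7)
  out <- mwuPolynomialStep(d, c(1, -1), eta = 1e-8)
  expect_equal(out, d, tolerance = 1e-7)
  expect_error(mwuPolynomialStep(c(0.5, 0.5), c(1, -2), eta = 1),
               "step-size")
  expect_error(mwuPolynomialStep(c(0.5, 0.5), c(1, 0)), "step-size")
})

test_that("Hedge with log payoffs is the replicator and is shift-invariant", {
  sp <- GenotypeSpace(3)
  w <- randomLandscape(sp, seed = 77)
  d <- c(0.2, 0.5, 0.3)
  eta <- 0.7
  expect_equal(mwuExponentialStep(d, log(fitnessValues(w)) / eta, eta),
               genotypeWeights(asexualStep(GenotypeDistribution(sp, d),
                                           w)),
               tolerance = 1e-14)
  expect_equal(mwuExponentialStep(d, c(2, 2, 2), 1), d)
  expect_equal(mwuExponentialStep(d, c(1, 3, -2), 1),
               mwuExponentialStep(d, c(1, 3, -2) + 57, 1),
               tolerance = 1e-14)
})

test_that("the haploid replicator updates each locus by marginal fitness", {
  rainy <- makeFixture("table3_rainy")
  q1 <- haploidStep(uniformProfile(rainy@space), rainy)
  wbar <- 4.99 / 9
  rowMeans3 <- c(0.60, (0.48 + 0.55 + 0.75) / 3, (0.20 + 0.51 + 0.70) / 3)
  expect_equal(alleleFreqs(q1)[[1]], (rowMeans3 / 3) / wbar,
               tolerance = 1e-12)
  # point-mass profiles are fixed points
  qp <- AllelicProfile(rainy@space, list(c(0, 1, 0), c(1, 0, 0)))
  expect_equal(alleleFreqs(haploidStep(qp, rainy)), alleleFreqs(qp))
  # on one locus the haploid and asexual replicators coincide
  sp1 <- GenotypeSpace(4)
  w1 <- randomLandscape(sp1, seed = 3)
  set.seed(12)
  d0 <- rdirichlet1(4)
  expect_equal(alleleFreqs(haploidStep(AllelicProfile(sp1, list(d0)),
                                       w1))[[1]],
               genotypeWeights(asexualStep(GenotypeDistribution(sp1, d0),
                                           w1)),
               tolerance = 1e-14)
})

test_that("the genotype-simplex haploid step projects, selects and lifts", {
  rainy <- makeFixture("table3_rainy")
  set.seed(14)
  d <- randDistribution(rainy@space)
  out <- t1Step(d, rainy)
  expect_equal(linkageDeviation(out), 0, tolerance = 1e-12)
  expect_equal(genotypeWeights(out),
               genotypeWeights(liftRhoInverse(haploidStep(projectRho(d),
                                                          rainy))))
  # composition of the projected haploid example
  u <- t1Step(uniformDistribution(rainy@space), rainy)
  qh <- haploidStep(uniformProfile(rainy@space), rainy)
  expect_equal(genotypeWeights(u),
               genotypeWeights(liftRhoInverse(qh)))
})

test_that("partition steps bracket the asexual and free-recombination dynamics", {
  set.seed(15)
  for (rep in 1:6) {
    sp <- GenotypeSpace(c(2, 3, 2))
    w <- randomLandscape(sp, seed = 500 + rep)
    d <- randDistribution(sp)
    expect_equal(genotypeWeights(lambdaStep(d, w, coarsestPartition(3))),
                 genotypeWeights(asexualStep(d, w)), tolerance = 1e-14)
    expect_equal(genotypeWeights(lambdaStep(d, w, finestPartition(3))),
                 genotypeWeights(t1Step(d, w)), tolerance = 1e-14)
    # from linkage equilibrium, one-step allelic marginals do not depend
    # on the partition structure
    dle <- liftRhoInverse(randProfile(sp))
    lams <- list(coarsestPartition(3), finestPartition(3),
                 Partition(3, list(c(1, 2), 3)),
                 Partition(3, list(c(1, 3), 2)))
    qs <- lapply(lams, function(lam)
      unlist(alleleFreqs(projectRho(lambdaStep(dle, w, lam)))))
    for (i in 2:4) expect_equal(qs[[i]], qs[[1]], tolerance = 1e-12)
  }
})

test_that("recombination tuples mix partition dynamics convexly", {
  sp <- GenotypeSpace(c(2, 2))
  w <- randomLandscape(sp, seed = 6)
  set.seed(16)
  d <- randDistribution(sp)
  # degenerate tuple on the finest partition is the free-recombination step
  expect_equal(
    genotypeWeights(recombinationTupleStep(d, w,
      RecombinationTuple(list(finestPartition(2)), 1))),
    genotypeWeights(t1Step(d, w)))
  # two-partition tuple reproduces r*T1 + (1-r)*T0
  for (r in c(0, 0.25, 0.8, 1)) {
    got <- recombinationTupleStep(d, w, recombinationRateTuple(2, r))
    want <- r * genotypeWeights(t1Step(d, w)) +
      (1 - r) * genotypeWeights(asexualStep(d, w))
    expect_equal(genotypeWeights(got), want, tolerance = 1e-14)
  }
  # neutral fitness, half recombination, maximal linkage disequilibrium
  wc <- FitnessLandscape(sp, rep(1, 4))
  dld <- GenotypeDistribution(sp, c(0.5, 0, 0, 0.5))
  expect_equal(
    genotypeWeights(recombinationTupleStep(dld, wc,
                                           recombinationRateTuple(2, 0.5))),
    c(0.375, 0.125, 0.125, 0.375))
})

test_that("single-locus diploid selection follows marginal allele fitness", {
  het <- makeFixture("hetero_advantage")
  expect_equal(diploidSingleStep(c(0.8, 0.2), het), c(0.5, 0.5),
               tolerance = 1e-15)
  # constant fitness: identity
  Wc <- DiploidLandscape(matrix(1, 3, 3))
  p <- c(0.2, 0.3, 0.5)
  expect_equal(diploidSingleStep(p, Wc), p)
  # symmetric homozygote-advantage matrix holds its unstable midpoint
  Wi <- DiploidLandscape(diag(2))
  expect_equal(diploidSingleStep(c(0.5, 0.5), Wi), c(0.5, 0.5))
})

test_that("two-locus diploid recursion reduces to a replicator when r = 0", {
  sp <- GenotypeSpace(c(2, 2))
  set.seed(17)
  for (rep in 1:4) {
    W <- matrix(runif(16, 0.2, 1), 4, 4)
    W <- (W + t(W)) / 2
    x <- GameteState(sp, rdirichlet1(4), W)
    res <- diploidTwoLocusStep(x, r = 0, details = TRUE)
    Wg <- as.numeric(W %*% gameteFreqs(x))
    wbar <- sum(gameteFreqs(x) * Wg)
    expect_equal(gameteFreqs(res$state),
                 gameteFreqs(x) * Wg / wbar, tolerance = 1e-12)
    expect_equal(res$D, rep(0, 4), tolerance = 1e-12)
  }
  # neutral fitness and linkage equilibrium: fixed for any r
  Wc <- matrix(1, 4, 4)
  xle <- GameteState(sp, c(0.12, 0.18, 0.28, 0.42), Wc)
  for (r in c(0, 0.3, 1))
    expect_equal(gameteFreqs(diploidTwoLocusStep(xle, r)),
                 c(0.12, 0.18, 0.28, 0.42), tolerance = 1e-12)
  # full recombination factorizes a coupling population in one step
  xld <- GameteState(sp, c(0.5, 0, 0, 0.5), Wc)
  res <- diploidTwoLocusStep(xld, r = 1, details = TRUE)
  expect_equal(gameteFreqs(res$state), rep(0.25, 4))
  expect_equal(res$D[1], 0.25)
})

test_that("linkage disequilibrium decays geometrically under neutral fitness", {
  sp <- GenotypeSpace(c(2, 2))
  Wc <- matrix(1, 4, 4)
  x <- GameteState(sp, c(0.5, 0, 0, 0.5), Wc)
  for (r in c(0.2, 0.5)) {
    tr <- runTrajectory("diploid_two_locus", x, fixedEnvironment(Wc),
                        6, r = r, stopTol = 0)
    ld <- vapply(tr@states, function(s)
      linkageDeviation(GenotypeDistribution(sp, gameteFreqs(s))),
      numeric(1))
    ratios <- ld[-1] / ld[-length(ld)]
    expect_equal(ratios, rep(1 - r, length(ratios)), tolerance = 1e-10)
  }
})

test_that("Baum-Eagon updating specializes to the named replicators", {
  rainy <- makeFixture("table3_rainy")
  U <- meanFitnessPolynomial(rainy)
  set.seed(18)
  for (rep in 1:5) {
    q <- randProfile(rainy@space)
    expect_equal(unlist(alleleFreqs(baumEagonStep(q, U))),
                 unlist(alleleFreqs(haploidStep(q, rainy))),
                 tolerance = 1e-12)
  }
  # quadratic diploid mean fitness reproduces the diploid step
  set.seed(19)
  W <- matrix(runif(9, 0.1, 1), 3, 3)
  W <- (W + t(W)) / 2
  dl <- DiploidLandscape(W)
  Ud <- diploidMeanFitnessPolynomial(dl)
  for (rep in 1:5) {
    p <- rdirichlet1(3)
    expect_equal(alleleFreqs(baumEagonStep(
      AllelicProfile(GenotypeSpace(3), list(p)), Ud))[[1]],
      diploidSingleStep(p, dl), tolerance = 1e-12)
  }
  # linear polynomial on one simplex is the asexual replicator
  sp1 <- GenotypeSpace(4)
  w1 <- randomLandscape(sp1, seed = 23)
  Ul <- bePolynomial(4, fitnessValues(w1), diag(4))
  p <- rdirichlet1(4)
  expect_equal(alleleFreqs(baumEagonStep(AllelicProfile(sp1, list(p)),
                                         Ul))[[1]],
               genotypeWeights(asexualStep(GenotypeDistribution(sp1, p),
                                           w1)),
               tolerance = 1e-14)
  # the defining inequality: U never decreases along the update
  set.seed(20)
  for (rep in 1:5) {
    q <- randProfile(rainy@space)
    expect_gte(bePolyValue(U, unlist(alleleFreqs(baumEagonStep(q, U)))),
               bePolyValue(U, unlist(alleleFreqs(q))) - 1e-12)
  }
})

test_that("trajectories are consistent with direct stepping and conserve mass", {
  rainy <- makeFixture("table3_rainy")
  env <- fixedEnvironment(rainy)
  d0 <- uniformDistribution(rainy@space)
  tr1 <- runTrajectory("asexual", d0, env, 1)
  expect_equal(genotypeWeights(finalState(tr1)),
               genotypeWeights(asexualStep(d0, rainy)))
  # simplex conservation along a longer run
  tr <- runTrajectory("t1", randDistribution(rainy@space), env, 50,
                      stopTol = 0)
  for (s in tr@states) {
    expect_equal(sum(genotypeWeights(s)), 1, tolerance = 1e-12)
    expect_true(all(genotypeWeights(s) >= 0))
  }
  # fixed environment: mean fitness never decreases
  expect_true(monotonicityCheck(tr)$ok)
})

test_that("random interior starts reach point-mass Nash profiles under fixed fitness", {
  # haploid and tuple dynamics on generic landscapes
  set.seed(24)
  for (rep in 1:4) {
    sp <- GenotypeSpace(c(3, 3))
    w <- randomLandscape(sp, seed = 600 + rep)
    nash <- enumeratePureNash(gameFromLandscape(w))
    trh <- runTrajectory("haploid", randProfile(sp), fixedEnvironment(w),
                         30000)
    rh <- classifyConvergence(trh, tolVertex = 1e-4)
    expect_equal(rh$status, "monomorphic")
    expect_true(any(apply(nash, 1, function(a)
      all(a == rh$limitAlleles))))
    trt <- runTrajectory("tuple", liftRhoInverse(randProfile(sp)),
                         fixedEnvironment(w), 30000,
                         rTuple = recombinationRateTuple(2, 0.5))
    rt <- classifyConvergence(trt, tolVertex = 1e-4)
    expect_equal(rt$status, "monomorphic")
    expect_true(any(apply(nash, 1, function(a)
      all(a == rt$limitAlleles))))
  }
})

test_that("MWU self-play converges to Nash on random potential games", {
  set.seed(25)
  for (rep in 1:20) {
    np <- sample(2:3, 1)
    ac <- sample(2:4, np, replace = TRUE)
    w <- runif(prod(ac), 0.5, 1.5)
    if (anyDuplicated(w)) w <- w + seq_along(w) * 1e-9
    pg <- findPotential(FiniteGame(ac, w))
    x0 <- lapply(ac, rdirichlet1)
    x <- mwuSelfPlay(pg, x0, maxSteps = 100000)
    expect_lte(epsilonNashGap(pg, x), 1e-6)
  }
})
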