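test_that("convergence classification separates vertex, mixed and none", {
  rainy <- makeFixture("table3_rainy")
  tr <- runTrajectory("asexual", uniformDistribution(rainy@space),
                      fixedEnvironment(rainy), 1e4)
  rep_ <- classifyConvergence(tr)
  expect_equal(rep_$status, "monomorphic")
  expect_equal(rep_$limitAlleles, c(1L, 3L))
  expect_equal(rep_$limitMeanFitness, 0.80, tolerance = 1e-6)
  # heterozygote advantage: interior fixed point, polymorphic
  het <- makeFixture("hetero_advantage")
  trh <- runTrajectory("diploid_single", c(0.8, 0.2),
                       fixedEnvironment(het), 100)
  reph <- classifyConvergence(trh)
  expect_equal(reph$status, "polymorphic")
  expect_equal(stateCoords(reph$limitState), c(0.5, 0.5))
  # periodic schedule: no convergence of any kind
  pe <- makeFixture("periodic_exp")
  trp <- runTrajectory("asexual",
                       uniformDistribution(GenotypeSpace(2)), pe, 2000)
  expect_equal(classifyConvergence(trp)$status, "none")
})

test_that("Lyapunov monotonicity holds where guaranteed and fails for two-locus diploids", {
  rainy <- makeFixture("table3_rainy")
  set.seed(41)
  for (dyn in c("asexual", "haploid", "t1")) {
    init <- if (dyn == "haploid") randProfile(rainy@space) else
      randDistribution(rainy@space)
    tr <- runTrajectory(dyn, init, fixedEnvironment(rainy), 500)
    expect_true(monotonicityCheck(tr)$ok)
  }
  # constant landscape: constant mean fitness is (weakly) monotone
  wc <- FitnessLandscape(rainy@space, rep(1, 9))
  trc <- runTrajectory("asexual", randDistribution(rainy@space),
                       fixedEnvironment(wc), 10)
  expect_true(monotonicityCheck(trc)$ok)
  # two-locus diploid with recombination can lose mean fitness
  sp2 <- GenotypeSpace(c(2, 2))
  W <- epistaticPairFitness()
  gs <- GameteState(sp2, c(0.45, 0.05, 0.05, 0.45), W)
  trd <- runTrajectory("diploid_two_locus", gs, fixedEnvironment(W), 50,
                       r = 0.5)
  mc <- monotonicityCheck(trd)
  expect_false(mc$ok)
  expect_false(is.na(mc$firstViolation))
})

test_that("regret vanishes at the optimum and is bounded by the entropy of the start", {
  rainy <- makeFixture("table3_rainy")
  # starting at the best-in-hindsight vertex: zero regret at every horizon
  tr <- runTrajectory("asexual", pointMass(rainy@space, 3),
                      fixedEnvironment(rainy), 50, stopTol = 0)
  rr <- regretReport(tr)
  expect_equal(rr$regret, 0, tolerance = 1e-12)
  expect_equal(rr$yStar, 3L)
  # uniform start over G genotypes: R_n <= ln G under any realization
  sp <- GenotypeSpace(c(2, 2, 2))
  ls <- lapply(1:3, function(i) randomLandscape(sp, seed = 700 + i))
  env <- iidEnvironment(ls, rep(1 / 3, 3), seed = 5)
  tru <- runTrajectory("asexual", uniformDistribution(sp), env, 3000,
                       recordEvery = 3000, stopTol = 0)
  rru <- regretReport(tru)
  expect_lte(rru$regret, log(8) + 1e-9)
  expect_gte(rru$regret, -1e-9)
})

test_that("the periodic schedule realizes the printed average growth rate", {
  pe <- makeFixture("periodic_exp")
  n <- 2000  # ten whole periods
  tr <- runTrajectory("asexual", uniformDistribution(GenotypeSpace(2)),
                      pe, n, stopTol = 0)
  rr <- regretReport(tr)
  # both genotypes tie in hindsight at average log growth 5/12
  expect_equal(rr$bestCum / n, 5 / 12, tolerance = 1e-12)
  # the population's realized average log growth approaches the same value
  expect_lte(rr$regret, log(2) + 1e-12)
  expect_equal(rr$realizedCum / n, 5 / 12, tolerance = log(2) / n + 1e-9)
})

test_that("virtual convergence: the regret gap closes even without state convergence", {
  sp <- GenotypeSpace(c(2, 2, 2))
  ls <- lapply(1:2, function(i) randomLandscape(sp, seed = 800 + i))
  env <- iidEnvironment(ls, c(0.5, 0.5), seed = 6)
  n <- 20000
  tr <- runTrajectory("asexual", uniformDistribution(sp), env, n,
                      recordEvery = n, stopTol = 0)
  vg <- virtualConvergenceGap(tr)
  expect_lte(vg$joint, log(8) / n + 1e-12)
  # per-locus gaps under an alternating rainy/drought realization shrink
  rainy <- makeFixture("table3_rainy")
  drought <- makeFixture("table3_drought")
  envA <- scheduleEnvironment(list(rainy, drought), c(1L, 2L))
  gapAt <- function(n) {
    tr <- runTrajectory("haploid", uniformProfile(rainy@space), envA, n,
                        stopTol = 0)
    virtualConvergenceGap(tr, perLocus = TRUE)$perLocus
  }
  g500 <- gapAt(500)
  g2000 <- gapAt(2000)
  expect_true(all(g2000 < g500))
})

test_that("basin mapping finds the unique basin and splits coordination starts", {
  rainy <- makeFixture("table3_rainy")
  bm <- basinMap(rainy, "haploid", nSamples = 30, seed = 4,
                 nSteps = 20000)
  expect_equal(unname(bm$counts[["(1,3)"]]), 30)
  # identical seed reproduces the map exactly
  bm2 <- basinMap(rainy, "haploid", nSamples = 30, seed = 4,
                  nSteps = 20000)
  expect_identical(bm$samples$label, bm2$samples$label)
  # 2x2 coordination landscape: both vertices attract a positive fraction
  coord <- FitnessLandscape(GenotypeSpace(c(2, 2)), c(2, 0, 0, 1),
                            "coordination")
  bmc <- basinMap(coord, "haploid", nSamples = 40, seed = 7,
                  nSteps = 20000)
  expect_gt(bmc$counts[["(1,1)"]], 0)
  expect_gt(bmc$counts[["(2,2)"]], 0)
  expect_equal(sum(bmc$counts), 40)
  # single-genotype space: one trivial basin
  w1 <- FitnessLandscape(GenotypeSpace(1), 1)
  bm1 <- basinMap(w1, "asexual", nSamples = 3, seed = 1, nSteps = 10)
  expect_equal(unname(bm1$counts[["(1)"]]), 3)
  # diploid heterozygote advantage: everything falls into the mixed ESS
  het <- makeFixture("hetero_advantage")
  bmh <- basinMap(het, "diploid_single", nSamples = 15, seed = 2,
                  nSteps = 3000)
  expect_equal(unname(bmh$counts[[grep("mixed:", names(bmh$counts),
                                       value = TRUE)]]), 15)
})

test_that("exponential rates recover the closed-form two-genotype decay", {
  sp <- GenotypeSpace(2)
  w <- FitnessLandscape(sp, c(0.8, 0.4))
  tr <- runTrajectory("asexual", GenotypeDistribution(sp, c(0.5, 0.5)),
                      fixedEnvironment(w), 60)
  er <- exponentialRate(tr, c(1, 0))
  expect_equal(er$rate, log(0.4 / 0.8), tolerance = 1e-6)
  # constant landscape: no movement, flagged exact
  wc <- FitnessLandscape(sp, c(1, 1))
  trc <- runTrajectory("asexual", GenotypeDistribution(sp, c(0.5, 0.5)),
                       fixedEnvironment(wc), 10)
  expect_true(exponentialRate(trc, c(0.5, 0.5))$exact)
  # haploid on the rainy-year landscape: negative tail slope
  rainy <- makeFixture("table3_rainy")
  trh <- runTrajectory("haploid", uniformProfile(rainy@space),
                       fixedEnvironment(rainy), 10000)
  lim <- AllelicProfile(rainy@space, list(c(1, 0, 0), c(0, 0, 1)))
  erh <- exponentialRate(trh, lim)
  expect_true(erh$exact || erh$rate < 0)
})

test_that("diploid equilibrium finding classifies stability by invasion and local maxima", {
  het <- makeFixture("hetero_advantage")
  eq <- diploidEquilibria(het)
  stable <- Filter(function(e) e$stable, eq)
  expect_equal(length(stable), 1L)
  expect_equal(stable[[1]]$p, c(0.5, 0.5))
  expect_equal(stable[[1]]$meanFitness, 0.5)
  # homozygote advantage: both pure states stable, the mixed one is not
  hom <- DiploidLandscape(diag(2))
  eq2 <- diploidEquilibria(hom)
  lab <- vapply(eq2, function(e)
    paste0(paste(e$support, collapse = ","), ":", e$stable),
    character(1))
  expect_true("1:TRUE" %in% lab)
  expect_true("2:TRUE" %in% lab)
  expect_true("1,2:FALSE" %in% lab)
})
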