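# Convergence classification, Lyapunov monotonicity, regret and virtual
# convergence, basins of attraction, local exponential rates.

.vertexVals <- function(land) {
  if (is(land, "FitnessLandscape")) land@values
  else if (is(land, "DiploidLandscape")) diag(land@values)
  else if (is.matrix(land)) diag(land)
  else stop("unsupported landscape type", call. = FALSE)
}

#' Classify the convergence of a trajectory
#'
#' Monomorphic: the final state puts weight at least `1 - tolVertex` on a
#' single allele at every locus (a vertex). Polymorphic: not vertex-like,
#' but the state has stopped moving (successive-state max-norm distance
#' below `tolFixed`). Otherwise `"none"`. Two tolerances are used because
#' fixed-point detection must be much tighter than vertex proximity:
#' trajectories can crawl through the interior near saddles long before
#' committing to a vertex.
#'
#' @param traj a [Trajectory-class].
#' @param tolVertex vertex-proximity tolerance (default 1e-6).
#' @param tolFixed fixed-point tolerance (default 1e-9).
#' @return a list of class `"ConvergenceReport"`: `status`, `limitState`,
#'   `limitMeanFitness`, `perLocusMax`, `limitAlleles` (per-locus argmax,
#'   meaningful when monomorphic), `stepsUsed`, tolerances.
#' @export
classifyConvergence <- function(traj, tolVertex = 1e-6, tolFixed = 1e-9) {
  nrec <- length(traj@states)
  stopifnot(nrec >= 2L)
  fin <- traj@states[[nrec]]
  prv <- traj@states[[nrec - 1L]]
  if (diff(traj@recordedAt[(nrec - 1L):nrec]) != 1L)
    stop("final two recorded states are not consecutive", call. = FALSE)
  pl <- .statePerLocus(fin)
  plMax <- vapply(pl, max, numeric(1))
  moving <- max(abs(stateCoords(fin) - stateCoords(prv)))
  status <- if (all(plMax >= 1 - tolVertex)) "monomorphic"
            else if (moving < tolFixed) "polymorphic"
            else "none"
  lastLand <- traj@env@landscapes[[traj@envIndex[traj@steps]]]
  lmf <- if (traj@dynamic == "baum_eagon")
    traj@meanFitness[traj@steps]
  else .dynMeanFitness(traj@dynamic, fin, lastLand)
  structure(list(
    status = status,
    limitState = fin,
    limitMeanFitness = lmf,
    perLocusMax = plMax,
    limitAlleles = vapply(pl, which.max, integer(1)),
    stepsUsed = traj@steps,
    tolVertex = tolVertex,
    tolFixed = tolFixed), class = "ConvergenceReport")
}

#' @export
print.ConvergenceReport <- function(x, ...) {
  cat("ConvergenceReport:", x$status, "after", x$stepsUsed, "steps\n")
  cat("  limiting mean fitness:", format(x$limitMeanFitness, digits = 8),
      "\n")
  if (x$status == "monomorphic")
    cat("  limit alleles: (", paste(x$limitAlleles, collapse = ", "),
        ")\n")
  invisible(x)
}

#' Check mean-fitness monotonicity along a trajectory
#'
#' True when the recorded per-step mean fitness is nondecreasing within
#' tolerance. Mean fitness is a Lyapunov function for the asexual,
#' haploid (from linkage equilibrium), partition/tuple and single-locus
#' diploid dynamics under fixed fitness; the two-locus diploid dynamic
#' with recombination can genuinely violate it, which this reports rather
#' than treats as an error.
#'
#' @param traj a [Trajectory-class].
#' @param tol tolerated per-step decrease (default 1e-12).
#' @return list with `ok`, `firstViolation` (step index or `NA`), and
#'   `nViolations`.
#' @export
monotonicityCheck <- function(traj, tol = 1e-12) {
  dmf <- diff(traj@meanFitness)
  bad <- which(dmf < -tol)
  list(ok = length(bad) == 0L,
       firstViolation = if (length(bad)) bad[1L] else NA_integer_,
       nViolations = length(bad))
}

# per-step vertex payoff matrix (vertices x steps) along the realization
.vertexPayoffMatrix <- function(traj) {
  vals <- lapply(traj@env@landscapes, .vertexVals)
  vapply(traj@envIndex, function(i) vals[[i]],
         numeric(length(vals[[1L]])))
}

#' Regret of a trajectory against the best vertex in hindsight
#'
#' In `"log-growth"` mode (the multiplicative-fitness reading), the
#' per-round payoff of the population is `ln wbar_t` and the best fixed
#' choice in hindsight is the genotype vertex maximizing
#' `sum_t ln w_g^t`; the regret is their cumulative difference. For the
#' asexual replicator the exact telescoping identity
#' `prod_t wbar_t = sum_g d_g^0 prod_t w_g^t` bounds the regret by
#' `-ln(min_g d_g^0)` under every environment realization. `"linear"`
#' mode uses raw payoffs instead of logs.
#'
#' @param traj a [Trajectory-class].
#' @param mode `"log-growth"` (default) or `"linear"`.
#' @return a list of class `"RegretRecord"`: `horizon`, `bestCum`,
#'   `realizedCum`, `regret`, `avgRegret`, `yStar` (vertex index).
#' @export
regretReport <- function(traj, mode = c("log-growth", "linear")) {
  mode <- match.arg(mode)
  V <- .vertexPayoffMatrix(traj)
  n <- traj@steps
  if (mode == "log-growth") {
    if (any(V <= 0) || any(traj@meanFitness <= 0))
      stop("domain error: log-growth regret needs strictly positive ",
           "fitness along the realization", call. = FALSE)
    cum <- rowSums(log(V))
    realized <- sum(log(traj@meanFitness))
  } else {
    cum <- rowSums(V)
    realized <- sum(traj@meanFitness)
  }
  yStar <- which.max(cum)
  best <- cum[yStar]
  structure(list(horizon = n, bestCum = best, realizedCum = realized,
                 regret = best - realized, avgRegret = (best - realized) / n,
                 yStar = yStar, mode = mode), class = "RegretRecord")
}

#' @export
print.RegretRecord <- function(x, ...) {
  cat("RegretRecord (", x$mode, "): horizon ", x$horizon, ", regret ",
      format(x$regret, digits = 6), " (average ",
      format(x$avgRegret, digits = 6), "), best vertex ", x$yStar, "\n",
      sep = "")
  invisible(x)
}

#' Virtual-convergence gap of a trajectory
#'
#' The finite-horizon gap `|(1/n) sum_t l_t(y*) - (1/n) sum_t l_t(x_t)|`
#' between the realized average log growth and that of the best vertex in
#' hindsight. Virtual (monomorphic) convergence means this gap vanishes
#' even when the state itself never converges. With `perLocus = TRUE`
#' each locus is scored against its best allele in hindsight given the
#' internal environment (the other loci's realized frequencies), which
#' requires every state to have been recorded (`recordEvery = 1`).
#'
#' @param traj a [Trajectory-class].
#' @param perLocus also compute per-locus gaps.
#' @return list with `joint` (gap), `yStar`, and when requested
#'   `perLocus` (numeric vector of gaps) and `perLocusYStar`.
#' @export
virtualConvergenceGap <- function(traj, perLocus = FALSE) {
  rr <- regretReport(traj, "log-growth")
  out <- list(joint = abs(rr$avgRegret), yStar = rr$yStar)
  if (perLocus) {
    n <- traj@steps
    if (!all(0:(n - 1L) %in% traj@recordedAt))
      stop("per-locus gaps need every state recorded (recordEvery = 1)",
           call. = FALSE)
    stateAt <- traj@states[match(0:(n - 1L), traj@recordedAt)]
    land1 <- traj@env@landscapes[[1L]]
    if (!is(land1, "FitnessLandscape"))
      stop("per-locus gaps are defined for genotype fitness landscapes",
           call. = FALSE)
    sp <- land1@space
    tup <- genotypeTuples(sp)
    k <- sp@allelesPerLocus
    m <- length(k)
    cumAllele <- lapply(k, function(ki) numeric(ki))
    for (t in seq_len(n)) {
      q <- .statePerLocus(stateAt[[t]])
      vals <- traj@env@landscapes[[traj@envIndex[t]]]@values
      for (i in seq_len(m)) {
        pr <- rep(1, nrow(tup))
        for (u in seq_len(m)) if (u != i) pr <- pr * q[[u]][tup[, u]]
        wij <- vapply(seq_len(k[i]), function(j)
          sum(vals[tup[, i] == j] * pr[tup[, i] == j]), numeric(1))
        if (any(wij <= 0))
          stop("domain error: zero marginal allele payoff in log mode",
               call. = FALSE)
        cumAllele[[i]] <- cumAllele[[i]] + log(wij)
      }
    }
    realized <- sum(log(traj@meanFitness))
    out$perLocus <- vapply(cumAllele, function(cl)
      abs(max(cl) - realized) / n, numeric(1))
    out$perLocusYStar <- vapply(cumAllele, which.max, integer(1))
  }
  out
}

#' Map basins of attraction by seeded sampling
#'
#' Samples initial states from the flat (Dirichlet(1,...,1)) distribution
#' on the appropriate simplex/product of simplices, runs each to
#' convergence under a fixed landscape, and labels each sample by the
#' nearest equilibrium within `tol` (max norm): a pure-Nash vertex label
#' for genotype dynamics, a pure/mixed stable equilibrium for the
#' single-locus diploid dynamic, `"mixed"` for converged non-vertex
#' limits matching no catalogued equilibrium, `"none"` for non-converged
#' samples (never dropped).
#'
#' @param landscape a [FitnessLandscape-class] (dynamics `"asexual"`,
#'   `"haploid"`, `"t1"`, `"tuple"`) or [DiploidLandscape-class]
#'   (`"diploid_single"`).
#' @param dynamic step operator name.
#' @param nSamples number of sampled initial states.
#' @param seed integer seed for the initial-state sampler.
#' @param nSteps generations per sample.
#' @param tol matching tolerance to an equilibrium.
#' @param rTuple optional [RecombinationTuple-class] for `"tuple"`.
#' @return a list of class `"BasinMap"`: `samples` (data.frame with
#'   `label` and `steps`), `counts`, `fractions`, `equilibria`, `seed`.
#' @export
basinMap <- function(landscape, dynamic = "haploid", nSamples = 100,
                     seed = 1L, nSteps = 10000, tol = 1e-3,
                     rTuple = NULL) {
  dynamic <- match.arg(dynamic,
    c("haploid", "asexual", "t1", "tuple", "diploid_single"))
  env <- fixedEnvironment(landscape)
  rdirichlet1 <- function(k) {
    x <- -log(runif(k))
    x / sum(x)
  }
  if (is(landscape, "FitnessLandscape")) {
    sp <- landscape@space
    nash <- enumeratePureNash(gameFromLandscape(landscape))
    eqLabels <- apply(nash, 1L, function(a)
      paste0("(", paste(a, collapse = ","), ")"))
    eqCoords <- lapply(seq_len(nrow(nash)), function(e) {
      if (dynamic == "haploid") {
        unlist(lapply(seq_along(sp@allelesPerLocus), function(i) {
          v <- numeric(sp@allelesPerLocus[i]); v[nash[e, i]] <- 1; v
        }))
      } else {
        v <- numeric(numGenotypes(sp))
        v[genotypeIndex(sp, nash[e, ])] <- 1
        v
      }
    })
    drawInit <- function() {
      if (dynamic == "haploid")
        AllelicProfile(sp, lapply(sp@allelesPerLocus, rdirichlet1))
      else GenotypeDistribution(sp, rdirichlet1(numGenotypes(sp)))
    }
  } else if (is(landscape, "DiploidLandscape")) {
    stopifnot(dynamic == "diploid_single")
    eqs <- diploidEquilibria(landscape)
    eqs <- eqs[vapply(eqs, function(e) e$stable, logical(1))]
    eqLabels <- vapply(eqs, function(e)
      if (length(e$support) == 1L) paste0("pure:", e$support)
      else paste0("mixed:(", paste(format(e$p[e$support], digits = 4),
                                   collapse = ","), ")"),
      character(1))
    eqCoords <- lapply(eqs, function(e) e$p)
    k <- landscape@numAlleles
    drawInit <- function() rdirichlet1(k)
  } else stop("unsupported landscape type", call. = FALSE)

  inits <- .withSeed(seed, lapply(seq_len(nSamples), function(i)
    drawInit()))
  labels <- character(nSamples)
  steps <- integer(nSamples)
  for (s in seq_len(nSamples)) {
    traj <- runTrajectory(dynamic, inits[[s]], env, nSteps,
                          recordEvery = nSteps, rTuple = rTuple)
    rep_ <- classifyConvergence(traj)
    steps[s] <- traj@steps
    fc <- stateCoords(finalState(traj))
    dists <- vapply(eqCoords, function(e) max(abs(fc - e)), numeric(1))
    labels[s] <- if (length(dists) && min(dists) <= tol)
      eqLabels[which.min(dists)]
    else if (rep_$status != "none") "mixed"
    else "none"
  }
  counts <- table(factor(labels, levels = unique(c(eqLabels, "mixed",
                                                   "none"))))
  structure(list(
    samples = data.frame(sample = seq_len(nSamples), label = labels,
                         steps = steps),
    counts = counts,
    fractions = counts / nSamples,
    equilibria = eqLabels,
    seed = seed), class = "BasinMap")
}

#' @export
print.BasinMap <- function(x, ...) {
  cat("BasinMap over", nrow(x$samples), "sampled starts (seed",
      x$seed, "):\n")
  print(x$fractions)
  invisible(x)
}

#' Local exponential convergence rate toward a limit
#'
#' Least-squares slope of `ln(max-norm distance to the limit)` against
#' time over the trailing fraction of a trajectory. A negative slope
#' certifies locally exponential convergence; a trajectory that reaches
#' the limit exactly (zero tail distances) is flagged with `exact = TRUE`
#' and rate `-Inf`.
#'
#' @param traj a [Trajectory-class].
#' @param limit limit state (any supported state object or coordinate
#'   vector).
#' @param tailFraction trailing fraction of recorded times used.
#' @return list with `rate`, `exact`, and `nPoints`.
#' @export
exponentialRate <- function(traj, limit, tailFraction = 0.2) {
  lim <- if (is.numeric(limit)) as.numeric(limit) else stateCoords(limit)
  d <- vapply(traj@states, function(s) max(abs(stateCoords(s) - lim)),
              numeric(1))
  tt <- traj@recordedAt
  keep <- tt >= (1 - tailFraction) * max(tt)
  d <- d[keep]
  tt <- tt[keep]
  if (any(d == 0) || length(d) < 2L)
    return(list(rate = -Inf, exact = TRUE, nPoints = sum(d > 0)))
  fit <- stats::lm.fit(cbind(1, tt), log(d))
  list(rate = unname(fit$coefficients[2L]), exact = FALSE,
       nPoints = length(d))
}

#' Equilibria of the single-locus diploid dynamic
#'
#' Enumerates candidate equilibria by support: on each support the
#' marginal fitnesses must be equal, a linear system; solutions inside
#' the simplex are kept. Each is classified as stable (an evolutionarily
#' stable state) when no off-support allele has higher marginal fitness
#' and mean fitness is a strict local maximum under feasible directional
#' perturbations of size `step`.
#'
#' @param W a [DiploidLandscape-class] (intended for up to ~10 alleles;
#'   the enumeration is exponential in the allele count).
#' @param tol numeric tolerance for simplex membership and fitness
#'   comparisons.
#' @param step perturbation size for the local-maximum test.
#' @return list of records: `p` (frequency vector), `support`,
#'   `meanFitness`, `stable`.
#' @export
diploidEquilibria <- function(W, tol = 1e-9, step = 1e-4) {
  stopifnot(is(W, "DiploidLandscape"))
  n <- W@numAlleles
  A <- W@values
  out <- list()
  for (size in seq_len(n)) {
    for (supp in utils::combn(n, size, simplify = FALSE)) {
      p <- numeric(n)
      if (size == 1L) {
        p[supp] <- 1
      } else {
        M <- rbind(cbind(A[supp, supp, drop = FALSE], -1),
                   c(rep(1, size), 0))
        sol <- tryCatch(solve(M, c(rep(0, size), 1)),
                        error = function(e) NULL)
        if (is.null(sol)) next
        ps <- sol[seq_len(size)]
        if (any(ps < -tol)) next
        ps <- pmax(ps, 0)
        p[supp] <- ps / sum(ps)
      }
      Wi <- as.numeric(A %*% p)
      c0 <- sum(p * Wi)
      # no off-support allele may strictly out-earn the equilibrium payoff
      off <- setdiff(seq_len(n), supp)
      invadable <- length(off) > 0L && any(Wi[off] > c0 + max(tol, 1e-9))
      localMax <- TRUE
      if (!invadable) {
        for (j in seq_len(n)) {
          ej <- numeric(n)
          ej[j] <- 1
          q <- p + step * (ej - p)
          if (meanFitness(q, W) > c0 + max(tol, 1e-9) * step) {
            localMax <- FALSE
            break
          }
        }
      }
      out[[length(out) + 1L]] <- list(p = p, support = supp,
                                      meanFitness = c0,
                                      stable = !invadable && localMax)
    }
  }
  out
}
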