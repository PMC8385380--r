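# Trajectory runner: iterates a named step operator under an environment
# process, recording per-step mean fitness and state snapshots.

# flatten any supported state to a numeric coordinate vector
stateCoords <- function(state) {
  if (is(state, "GenotypeDistribution")) state@weights
  else if (is(state, "AllelicProfile")) unlist(state@freqs,
                                               use.names = FALSE)
  else if (is(state, "GameteState")) state@freqs
  else if (is.numeric(state)) as.numeric(state)
  else stop("unsupported state type: ", class(state)[1L], call. = FALSE)
}

# per-locus probability vectors of any supported state
.statePerLocus <- function(state) {
  if (is(state, "GenotypeDistribution")) projectRho(state)@freqs
  else if (is(state, "AllelicProfile")) state@freqs
  else if (is(state, "GameteState"))
    projectRho(GenotypeDistribution(state@space, state@freqs))@freqs
  else if (is.numeric(state)) list(as.numeric(state))
  else stop("unsupported state type", call. = FALSE)
}

.DYNAMICS <- c("asexual", "haploid", "t1", "lambda", "tuple", "mwu_poly",
               "mwu_exp", "diploid_single", "diploid_two_locus",
               "baum_eagon")

# mean fitness of `state` under `land` for a given dynamic
.dynMeanFitness <- function(dynamic, state, land, poly = NULL) {
  switch(dynamic,
    asexual = , t1 = , lambda = , tuple = meanFitness(state, land),
    haploid = meanFitness(state, land),
    mwu_poly = , mwu_exp = sum(state * fitnessValues(land)),
    diploid_single = meanFitness(state, land),
    diploid_two_locus = meanFitness(state),
    baum_eagon = bePolyValue(poly, unlist(state@freqs, use.names = FALSE)))
}

#' Run a discrete evolutionary dynamic
#'
#' Iterates one of the package's step operators for `nSteps` generations,
#' drawing the generation-`t` landscape from the environment process.
#' Stops early at a numerical fixed point (successive states closer than
#' `stopTol` in max norm). Mean fitness and the environment index are
#' recorded for every step; state snapshots are kept at every
#' `recordEvery`-th generation plus, always, the initial state and the
#' final two consecutive states.
#'
#' @param dynamic one of `"asexual"`, `"haploid"`, `"t1"`, `"lambda"`,
#'   `"tuple"`, `"mwu_poly"`, `"mwu_exp"`, `"diploid_single"`,
#'   `"diploid_two_locus"`, `"baum_eagon"`.
#' @param init initial state of the matching type
#'   ([GenotypeDistribution-class], [AllelicProfile-class], numeric
#'   frequency vector, or [GameteState-class]).
#' @param env an [EnvironmentProcess-class]; for `diploid_two_locus` its
#'   landscapes may be plain pair-fitness matrices, and for
#'   `"baum_eagon"` it only supplies labels.
#' @param nSteps number of generations (>= 1).
#' @param recordEvery snapshot stride (default 1: record every state).
#' @param stopTol fixed-point detection threshold (max-norm change per
#'   generation); set to 0 to disable early stopping.
#' @param eta step size for the MWU dynamics (`"parameter-free"` default
#'   for `mwu_poly`, 1 for `mwu_exp`).
#' @param partition a [Partition-class] (`lambda` dynamic).
#' @param rTuple a [RecombinationTuple-class] (`tuple` dynamic).
#' @param r recombination rate (`diploid_two_locus`).
#' @param poly a `"bePolynomial"` (`baum_eagon` dynamic).
#' @return a [Trajectory-class].
#' @examples
#' rainy <- makeFixture("table3_rainy")
#' tr <- runTrajectory("asexual", uniformDistribution(rainy@space),
#'                     fixedEnvironment(rainy), nSteps = 200)
#' tail(tr@meanFitness, 1)  # approaches the fittest genotype's 0.80
#' @export
runTrajectory <- function(dynamic, init, env, nSteps, recordEvery = 1L,
                          stopTol = 1e-14, eta = NULL, partition = NULL,
                          rTuple = NULL, r = 0, poly = NULL) {
  dynamic <- match.arg(dynamic, .DYNAMICS)
  stopifnot(is(env, "EnvironmentProcess"), nSteps >= 1)
  nSteps <- as.integer(nSteps)
  recordEvery <- max(1L, as.integer(recordEvery))
  idx <- realize(env, nSteps)

  if (dynamic == "mwu_poly" && is.null(eta)) eta <- "parameter-free"
  if (dynamic == "mwu_exp" && is.null(eta)) eta <- 1
  if (dynamic == "lambda" && is.null(partition))
    stop("the lambda dynamic needs a partition", call. = FALSE)
  if (dynamic == "tuple" && is.null(rTuple))
    stop("the tuple dynamic needs a recombination tuple", call. = FALSE)
  if (dynamic == "baum_eagon" && is.null(poly))
    stop("the baum_eagon dynamic needs a bePolynomial", call. = FALSE)

  # the single-simplex dynamics run on raw numeric vectors (S4 wrapping
  # every generation would dominate the runtime of long horizons)
  rawMode <- dynamic %in% c("asexual", "mwu_poly", "mwu_exp",
                            "diploid_single")
  if (rawMode) {
    sp0 <- if (is(init, "GenotypeDistribution")) init@space else NULL
    wrap <- if (dynamic == "asexual" && !is.null(sp0))
      function(v) GenotypeDistribution(sp0, v) else function(v) v
    cur <- stateCoords(init)
    vals <- lapply(env@landscapes, function(l)
      if (is(l, "DiploidLandscape")) l@values else fitnessValues(l))
    etaFree <- identical(eta, "parameter-free") ||
      (is.numeric(eta) && is.infinite(eta))
    stepRaw <- switch(dynamic,
      asexual = , mwu_poly = if (dynamic == "asexual" || etaFree)
        function(v, fv) {
          if (dynamic == "mwu_poly" && any(v > 0 & fv <= 0))
            stop("step-size error: parameter-free updating requires ",
                 "strictly positive payoffs on the support", call. = FALSE)
          u <- v * fv
          s <- sum(u)
          if (s <= 0) .extinct()
          list(u / s, sum(v * fv))
        }
      else function(v, fv) {
        f <- 1 + eta * fv
        if (any(v > 0 & f <= 0))
          stop("step-size error: 1 + eta * payoff must stay positive",
               call. = FALSE)
        u <- v * f
        list(u / sum(u), sum(v * fv))
      },
      mwu_exp = function(v, fv) {
        z <- eta * fv
        u <- v * exp(z - max(z))
        list(u / sum(u), sum(v * fv))
      },
      diploid_single = function(v, fv) {
        Wi <- as.numeric(fv %*% v)
        wb <- sum(v * Wi)
        if (wb <= 0) .extinct()
        list(v * Wi / wb, wb)
      })
  } else {
    wrap <- identity
    cur <- init
    stepFun <- switch(dynamic,
      haploid = function(s, l) haploidStep(s, l),
      t1 = function(s, l) t1Step(s, l),
      lambda = function(s, l) lambdaStep(s, l, partition),
      tuple = function(s, l) recombinationTupleStep(s, l, rTuple),
      diploid_two_locus = function(s, l) {
        if (is.matrix(l)) s <- GameteState(s@space, s@freqs, l)
        diploidTwoLocusStep(s, r)
      },
      baum_eagon = function(s, l) baumEagonStep(s, poly))
  }

  states <- list()
  times <- integer()
  rec <- function(t, s) {
    states[[length(states) + 1L]] <<- wrap(s)
    times[length(times) + 1L] <<- t
  }
  rec(0L, if (rawMode) cur else init)

  mf <- numeric(nSteps)
  prev <- NULL
  used <- nSteps
  reason <- "completed"
  for (t in seq_len(nSteps)) {
    if (rawMode) {
      res <- tryCatch(stepRaw(cur, vals[[idx[t]]]), error = function(e)
        stop("step ", t, ": ", conditionMessage(e), call. = FALSE))
      nxt <- res[[1L]]
      mf[t] <- res[[2L]]
      if (t %% recordEvery == 0L) rec(t, nxt)
      prev <- cur
      cur <- nxt
      if (stopTol > 0 && max(abs(cur - prev)) < stopTol) {
        used <- t
        reason <- "fixed_point"
        break
      }
    } else {
      land <- env@landscapes[[idx[t]]]
      mf[t] <- .dynMeanFitness(dynamic, cur, land, poly)
      nxt <- tryCatch(stepFun(cur, land), error = function(e)
        stop("step ", t, ": ", conditionMessage(e), call. = FALSE))
      if (t %% recordEvery == 0L) rec(t, nxt)
      prev <- cur
      cur <- nxt
      if (stopTol > 0 &&
          max(abs(stateCoords(cur) - stateCoords(prev))) < stopTol) {
        used <- t
        reason <- "fixed_point"
        break
      }
    }
  }
  # mean fitness is a Lyapunov function for these dynamics under fixed
  # fitness; a violation indicates numerical trouble and is reported (not
  # fatal: exact-tie steps can round either way)
  if (env@mode == "fixed" &&
      dynamic %in% c("asexual", "haploid", "t1", "lambda", "tuple",
                     "diploid_single", "baum_eagon")) {
    bad <- which(diff(mf[seq_len(used)]) < -1e-12)
    if (length(bad))
      warning("mean fitness decreased at step ", bad[1L], " under the ",
              dynamic, " dynamic", call. = FALSE)
  }
  # guarantee the final two consecutive states are recorded
  for (pair in list(list(used - 1L, prev), list(used, cur))) {
    t <- pair[[1L]]
    if (t >= 0L && !(t %in% times)) rec(t, pair[[2L]])
  }
  ord <- order(times)
  new("Trajectory", dynamic = dynamic, states = states[ord],
      recordedAt = times[ord], meanFitness = mf[seq_len(used)],
      envIndex = idx[seq_len(used)], env = env, steps = used,
      stopReason = reason)
}

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", object@dynamic, "dynamic,", object@steps, "steps (",
      object@stopReason, ")\n")
  cat("  mean fitness:", format(object@meanFitness[1L], digits = 6), "->",
      format(object@meanFitness[object@steps], digits = 6), "\n")
  cat(" ", length(object@states), "recorded states\n")
})

#' Final state of a trajectory
#'
#' @param traj a [Trajectory-class].
#' @return the last recorded state object.
#' @export
finalState <- function(traj) traj@states[[length(traj@states)]]
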