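# Environment processes: one fitness landscape per generation, plus the
# one-step-ahead expected log-fitness statistics used to decide which
# genotype a temporally varying environment favours.

# evaluate expr under a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.envNew <- function(mode, landscapes, labels = NULL, schedule = integer(),
                    probs = numeric(), transition = matrix(0, 0, 0),
                    init = numeric(), callback = NULL, seed = 1L) {
  if (is.null(labels)) {
    labels <- vapply(seq_along(landscapes), function(i) {
      l <- landscapes[[i]]
      lab <- if (.hasLabel(l)) landscapeLabel(l) else ""
      if (nzchar(lab)) lab else paste0("env", i)
    }, character(1))
  }
  new("EnvironmentProcess", mode = mode, landscapes = landscapes,
      labels = labels, schedule = as.integer(schedule),
      probs = as.numeric(probs), transition = transition,
      init = as.numeric(init), callback = callback,
      seed = as.integer(seed))
}

.hasLabel <- function(x)
  is(x, "FitnessLandscape") || is(x, "DiploidLandscape")

#' Environment process constructors
#'
#' Build the seeded per-generation landscape sources used by
#' [runTrajectory()]: a fixed landscape, an explicit (cycled) schedule,
#' i.i.d. draws, a finite-state Markov chain, or an arbitrary callback
#' `t -> landscape index`. Landscapes may be [FitnessLandscape-class],
#' [DiploidLandscape-class] or plain pair-fitness matrices (for the
#' two-locus diploid dynamic), but all entries of one process must share
#' a class and a state space.
#'
#' @param landscape,landscapes one landscape, or a list of them.
#' @param labels optional character labels (default: landscape labels).
#' @param schedule integer indices into `landscapes`, cycled as needed.
#' @param probs probability of drawing each landscape (iid mode).
#' @param transition row-stochastic matrix over landscapes (markov mode).
#' @param init initial state distribution (markov mode; default: first
#'   state).
#' @param callback function mapping the generation index to a landscape
#'   index.
#' @param seed integer seed making realizations reproducible.
#' @return an [EnvironmentProcess-class].
#' @examples
#' sp <- GenotypeSpace(2)
#' wet <- FitnessLandscape(sp, c(exp(1/2), exp(1/3)), "wet")
#' dry <- FitnessLandscape(sp, c(exp(1/3), exp(1/2)), "dry")
#' env <- iidEnvironment(list(wet, dry), c(0.5, 0.5), seed = 7)
#' realize(env, 5)
#' @export
fixedEnvironment <- function(landscape, labels = NULL)
  .envNew("fixed", list(landscape), labels)

#' @rdname fixedEnvironment
#' @export
scheduleEnvironment <- function(landscapes, schedule, labels = NULL)
  .envNew("schedule", landscapes, labels, schedule = schedule)

#' @rdname fixedEnvironment
#' @export
iidEnvironment <- function(landscapes, probs, seed = 1L, labels = NULL)
  .envNew("iid", landscapes, labels, probs = probs, seed = seed)

#' @rdname fixedEnvironment
#' @export
markovEnvironment <- function(landscapes, transition, init = NULL,
                              seed = 1L, labels = NULL) {
  k <- length(landscapes)
  if (is.null(init)) init <- c(1, rep(0, k - 1L))
  .envNew("markov", landscapes, labels, transition = as.matrix(transition),
          init = init, seed = seed)
}

#' @rdname fixedEnvironment
#' @export
callbackEnvironment <- function(landscapes, callback, labels = NULL)
  .envNew("callback", landscapes, labels, callback = callback)

setMethod("show", "EnvironmentProcess", function(object) {
  cat("EnvironmentProcess mode '", object@mode, "' over ",
      length(object@landscapes), " landscape(s): ",
      paste(object@labels, collapse = ", "), "\n", sep = "")
})

#' Realize an environment process
#'
#' Draws the sequence of landscape indices for `n` generations.
#' Deterministic given the process seed; the caller's RNG stream is left
#' untouched.
#'
#' @param env an [EnvironmentProcess-class].
#' @param n number of generations (>= 1).
#' @return integer vector of landscape indices of length `n`, with the
#'   labels as a `"labels"` attribute.
#' @export
realize <- function(env, n) {
  stopifnot(is(env, "EnvironmentProcess"), n >= 1)
  n <- as.integer(n)
  k <- length(env@landscapes)
  idx <- switch(env@mode,
    fixed = rep(1L, n),
    schedule = rep_len(env@schedule, n),
    iid = .withSeed(env@seed,
                    sample.int(k, n, replace = TRUE, prob = env@probs)),
    markov = .withSeed(env@seed, {
      out <- integer(n)
      out[1L] <- sample.int(k, 1L, prob = env@init)
      if (n > 1L) for (t in 2:n)
        out[t] <- sample.int(k, 1L, prob = env@transition[out[t - 1L], ])
      out
    }),
    callback = vapply(seq_len(n), function(t) as.integer(env@callback(t)),
                      integer(1)))
  structure(idx, labels = env@labels[idx])
}

#' Realized log-fitness panel
#'
#' The matrix of realized log fitnesses `ln w_g` (one row per genotype,
#' one column per generation) along a realization of the environment
#' process. Errors if any realized fitness is zero, since log fitness is
#' then undefined.
#'
#' @param env an [EnvironmentProcess-class] over
#'   [FitnessLandscape-class] objects.
#' @param n horizon.
#' @param realization optional pre-drawn index vector from [realize()].
#' @return numeric matrix with the environment indices as attribute
#'   `"realization"`.
#' @export
logFitnessPanel <- function(env, n, realization = NULL) {
  if (is.null(realization)) realization <- realize(env, n)
  vals <- vapply(env@landscapes, fitnessValues,
                 numeric(length(fitnessValues(env@landscapes[[1L]]))))
  if (any(vals[, unique(realization)] <= 0))
    stop("log fitness undefined: a realized landscape assigns fitness 0",
         call. = FALSE)
  panel <- log(vals[, realization, drop = FALSE])
  structure(panel, realization = realization)
}

#' Average one-step-ahead expected log-fitness
#'
#' `rhohat_t^g = (1/t) sum_{s=1..t} E[ln w_g(next) | state at s]`, the
#' running average of the conditional expectation of next-period log
#' fitness. Computable in closed form for fixed, i.i.d. (where it is the
#' constant `sum_omega mu(omega) ln w_g(omega)`) and Markov modes (where
#' the conditional expectation given the whole past reduces to the
#' current chain state). For schedules and callbacks no conditional law
#' exists; use the empirical plug-in estimator
#' [empiricalOneStepAhead()] instead.
#'
#' @param env an [EnvironmentProcess-class].
#' @param realization index vector from [realize()] (ignored for fixed
#'   and iid modes).
#' @param g genotype index.
#' @param t horizon of the running average (`>= 1`).
#' @return a single number.
#' @export
oneStepAheadAverage <- function(env, realization, g, t) {
  stopifnot(t >= 1)
  lw <- vapply(env@landscapes, function(l) {
    v <- fitnessValues(l)[g]
    if (v <= 0) stop("log fitness undefined for genotype ", g,
                     call. = FALSE)
    log(v)
  }, numeric(1))
  switch(env@mode,
    fixed = lw[1L],
    iid = sum(env@probs * lw),
    markov = {
      stopifnot(length(realization) >= t)
      mean(as.numeric(env@transition[realization[seq_len(t)], ,
                                     drop = FALSE] %*% lw))
    },
    stop("unsupported-mode error: one-step-ahead expectations need a ",
         "fixed, iid or markov environment; use empiricalOneStepAhead() ",
         "for arbitrary schedules", call. = FALSE))
}

#' Empirical plug-in one-step-ahead average (an estimator)
#'
#' Replaces the conditional expectation in [oneStepAheadAverage()] by the
#' realized next-period log fitness:
#' `(1/t) sum_{s=1..t} ln w_g(realization[s + 1])`. Usable for any mode,
#' including explicit schedules; it is an estimator, not the exact
#' conditional statistic.
#'
#' @inheritParams oneStepAheadAverage
#' @export
empiricalOneStepAhead <- function(env, realization, g, t) {
  stopifnot(t >= 1, length(realization) >= t + 1L)
  lw <- vapply(env@landscapes, function(l) log(fitnessValues(l)[g]),
               numeric(1))
  if (any(!is.finite(lw[unique(realization[2:(t + 1L)])])))
    stop("log fitness undefined along realization", call. = FALSE)
  mean(lw[realization[2:(t + 1L)]])
}

#' Tail-window superiority check over genotypes
#'
#' Finite-horizon surrogate for asymptotic one-step-ahead superiority: a
#' genotype is superior when the minimum of its running-average series
#' over the tail window strictly exceeds the maximum of every other
#' genotype's series over the same window (liminf/limsup replaced by
#' tail-window min/max).
#'
#' @param rhoHat numeric matrix of running averages, one row per
#'   genotype, one column per time point.
#' @param window number of trailing columns to examine (default: last
#'   20 percent of the horizon, at least 1).
#' @return the superior genotype's index, or `NA` if none dominates.
#' @export
superiorityCheck <- function(rhoHat, window = NULL) {
  rhoHat <- as.matrix(rhoHat)
  n <- ncol(rhoHat)
  if (is.null(window)) window <- max(1L, floor(0.2 * n))
  stopifnot(window >= 1L, n >= window)
  if (nrow(rhoHat) == 1L) return(1L)
  tail_ <- rhoHat[, (n - window + 1L):n, drop = FALSE]
  tmin <- apply(tail_, 1L, min)
  tmax <- apply(tail_, 1L, max)
  for (g in seq_len(nrow(rhoHat)))
    if (tmin[g] > max(tmax[-g])) return(g)
  NA_integer_
}
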