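# File formats (landscape/environment JSON, trajectory TSV, report JSON),
# built-in worked fixtures, and the seeded random-instance generator.

#' Read and write fitness landscapes as JSON
#'
#' Schema: `{"loci": m, "alleles": [k_1, ...], "fitness": [...], "label":
#' str}` with the fitness array flat in row-major genotype order (last
#' locus fastest). Round-trips are bit-exact.
#'
#' @param path file path.
#' @return `loadLandscape`: a [FitnessLandscape-class].
#' @export
loadLandscape <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("loci", "alleles", "fitness"))
    if (is.null(x[[f]]))
      stop("parse error: landscape JSON is missing field '", f, "'",
           call. = FALSE)
  if (length(x$alleles) != x$loci)
    stop("parse error: field 'alleles' must list one count per locus",
         call. = FALSE)
  sp <- GenotypeSpace(x$alleles)
  if (length(x$fitness) != numGenotypes(sp))
    stop("dimension error: fitness array has length ", length(x$fitness),
         ", expected ", numGenotypes(sp), call. = FALSE)
  FitnessLandscape(sp, x$fitness, if (is.null(x$label)) "" else x$label)
}

#' @rdname loadLandscape
#' @param w a [FitnessLandscape-class].
#' @export
saveLandscape <- function(w, path) {
  jsonlite::write_json(
    list(loci = w@space@numLoci,
         alleles = w@space@allelesPerLocus,
         fitness = w@values,
         label = w@label),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read and write diploid landscapes as JSON
#'
#' Schema: `{"alleles": k, "W": [[...], ...], "label": str}` with `W` the
#' full symmetric matrix.
#'
#' @param path file path.
#' @return `loadDiploidLandscape`: a [DiploidLandscape-class].
#' @export
loadDiploidLandscape <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("alleles", "W"))
    if (is.null(x[[f]]))
      stop("parse error: diploid JSON is missing field '", f, "'",
           call. = FALSE)
  W <- as.matrix(x$W)
  if (!all(dim(W) == c(x$alleles, x$alleles)))
    stop("dimension error: W must be ", x$alleles, " x ", x$alleles,
         call. = FALSE)
  DiploidLandscape(W, if (is.null(x$label)) "" else x$label)
}

#' @rdname loadDiploidLandscape
#' @param W a [DiploidLandscape-class].
#' @export
saveDiploidLandscape <- function(W, path) {
  jsonlite::write_json(
    list(alleles = W@numAlleles,
         W = W@values,
         label = W@label),
    path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read and write environment processes as JSON
#'
#' Schema: `{"mode": ..., "landscapes": [<landscape JSON>, ...],
#' "schedule"/"probs"/"transition"/"init": ..., "seed": int}`. Callback
#' environments cannot be serialized.
#'
#' @param path file path.
#' @return `loadEnvironment`: an [EnvironmentProcess-class].
#' @export
loadEnvironment <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$mode) || is.null(x$landscapes))
    stop("parse error: environment JSON needs 'mode' and 'landscapes'",
         call. = FALSE)
  ls <- lapply(seq_len(nrow(x$landscapes)), function(i) {
    l <- x$landscapes[i, ]
    FitnessLandscape(GenotypeSpace(unlist(l$alleles)),
                     unlist(l$fitness),
                     if (is.null(l$label)) "" else l$label)
  })
  seed <- if (is.null(x$seed)) 1L else as.integer(x$seed)
  switch(x$mode,
    fixed = fixedEnvironment(ls[[1L]]),
    schedule = scheduleEnvironment(ls, as.integer(x$schedule)),
    iid = iidEnvironment(ls, x$probs, seed = seed),
    markov = markovEnvironment(ls, as.matrix(x$transition),
                               init = x$init, seed = seed),
    stop("parse error: unsupported environment mode '", x$mode, "'",
         call. = FALSE))
}

#' @rdname loadEnvironment
#' @param env an [EnvironmentProcess-class].
#' @export
saveEnvironment <- function(env, path) {
  if (env@mode == "callback")
    stop("callback environments cannot be serialized", call. = FALSE)
  if (!all(vapply(env@landscapes, is, logical(1), "FitnessLandscape")))
    stop("only fitness-landscape environments serialize to JSON",
         call. = FALSE)
  out <- list(
    mode = env@mode,
    landscapes = lapply(env@landscapes, function(w)
      list(loci = w@space@numLoci, alleles = w@space@allelesPerLocus,
           fitness = w@values, label = w@label)),
    seed = env@seed)
  if (env@mode == "schedule") out$schedule <- env@schedule
  if (env@mode == "iid") out$probs <- env@probs
  if (env@mode == "markov") {
    out$transition <- env@transition
    out$init <- env@init
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' Built-in worked fixtures
#'
#' The printed objects every example and test can rebuild exactly:
#' \describe{
#'   \item{`table3_rainy`}{two-locus, three-alleles-per-locus fitness
#'     matrix of a rainy-year environment; unique fitness peak 0.80 at
#'     alleles (1, 3).}
#'   \item{`table3_drought`}{its drought-year counterpart, peak 0.80 at
#'     alleles (3, 1).}
#'   \item{`coord_2x2`}{the symphony/beach coordination game: common
#'     payoff 2 at (S, S), 1 at (B, B), 0 off-diagonal.}
#'   \item{`periodic_exp`}{two-genotype periodic environment: fitnesses
#'     `(e^{1/2}, e^{1/3})` for 100 generations, then swapped for 100,
#'     cycled; neither genotype can fix.}
#'   \item{`hetero_advantage`}{two-allele diploid landscape
#'     `W = [[0, 1], [1, 0]]` whose only stable state is the 50/50
#'     polymorphism.}
#' }
#'
#' @param name one of the five fixture names.
#' @return a [FitnessLandscape-class], [PotentialGame-class],
#'   [EnvironmentProcess-class] or [DiploidLandscape-class].
#' @examples
#' fitnessValues(makeFixture("table3_rainy"))
#' @export
makeFixture <- function(name) {
  switch(name,
    table3_rainy = FitnessLandscape(GenotypeSpace(c(3L, 3L)),
      c(0.40, 0.60, 0.80,
        0.48, 0.55, 0.75,
        0.20, 0.51, 0.70), label = "table3_rainy"),
    table3_drought = FitnessLandscape(GenotypeSpace(c(3L, 3L)),
      c(0.40, 0.48, 0.20,
        0.60, 0.55, 0.51,
        0.80, 0.75, 0.70), label = "table3_drought"),
    coord_2x2 = {
      fg <- FiniteGame(c(2L, 2L), c(2, 0, 0, 1))
      new("PotentialGame", game = fg, potential = c(2, 0, 0, 1))
    },
    periodic_exp = {
      sp <- GenotypeSpace(2L)
      scheduleEnvironment(
        list(FitnessLandscape(sp, c(exp(1 / 2), exp(1 / 3)), "phaseA"),
             FitnessLandscape(sp, c(exp(1 / 3), exp(1 / 2)), "phaseB")),
        schedule = c(rep(1L, 100L), rep(2L, 100L)))
    },
    hetero_advantage = DiploidLandscape(matrix(c(0, 1, 1, 0), 2, 2),
                                        label = "hetero_advantage"),
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtureNames(), collapse = ", "), call. = FALSE))
}

#' @rdname makeFixture
#' @export
fixtureNames <- function()
  c("table3_rainy", "table3_drought", "coord_2x2", "periodic_exp",
    "hetero_advantage")

#' Seeded random fitness landscape in generic position
#'
#' Draws strictly positive fitness values, redrawing until all values are
#' pairwise distinct so that the landscape is generic (isolated Nash
#' equilibria, no payoff ties).
#'
#' @param space a [GenotypeSpace-class].
#' @param distribution `"uniform"` on (0, 1] or `"lognormal"`.
#' @param seed integer seed; the same seed reproduces the landscape.
#' @param meanlog,sdlog lognormal parameters.
#' @return a [FitnessLandscape-class].
#' @export
randomLandscape <- function(space, distribution = c("uniform",
                                                    "lognormal"),
                            seed = 1L, meanlog = 0, sdlog = 1) {
  distribution <- match.arg(distribution)
  n <- numGenotypes(space)
  vals <- .withSeed(seed, {
    repeat {
      v <- switch(distribution,
                  uniform = runif(n),
                  lognormal = rlnorm(n, meanlog, sdlog))
      if (!anyDuplicated(v) && all(v > 0)) break
    }
    v
  })
  FitnessLandscape(space, vals,
                   label = paste0("random_", distribution, "_", seed))
}

#' Write a trajectory as TSV
#'
#' One row per recorded state: `t`, `env_label`, `mean_fitness`, then the
#' flattened state coordinates in row-major order. Floats are written
#' with 17 significant digits so re-reads are bit-exact; a comment line
#' names the dynamic and landscape.
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @export
writeTrajectoryTSV <- function(traj, path) {
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  coords <- t(vapply(traj@states, stateCoords,
                     numeric(length(stateCoords(traj@states[[1L]])))))
  lab1 <- traj@env@labels[traj@envIndex[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dynamic=", traj@dynamic, " landscape=", lab1,
                    " steps=", traj@steps, " stop=", traj@stopReason),
             con)
  writeLines(paste(c("t", "env_label", "mean_fitness",
                     paste0("x", seq_len(ncol(coords))), collapse = NULL),
                   collapse = "\t"), con)
  for (i in seq_along(traj@recordedAt)) {
    t <- traj@recordedAt[i]
    stepIdx <- min(max(t, 1L), traj@steps)
    mfRow <- if (t < traj@steps) traj@meanFitness[t + 1L] else
      traj@meanFitness[traj@steps]
    writeLines(paste(c(t, traj@env@labels[traj@envIndex[stepIdx]],
                       fmt(mfRow), fmt(coords[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

# serialize a report-ish object to plain lists for JSON output
.reportToList <- function(x) {
  if (inherits(x, "ConvergenceReport")) {
    list(status = x$status,
         limit_state = stateCoords(x$limitState),
         limit_mean_fitness = x$limitMeanFitness,
         per_locus_max = x$perLocusMax,
         limit_alleles = x$limitAlleles,
         steps_used = x$stepsUsed,
         tol_vertex = x$tolVertex,
         tol_fixed = x$tolFixed)
  } else if (inherits(x, "RegretRecord")) {
    list(horizon = x$horizon, best_cum = x$bestCum,
         realized_cum = x$realizedCum, regret = x$regret,
         avg_regret = x$avgRegret, y_star = x$yStar, mode = x$mode)
  } else x
}

#' Write a diagnostic report as JSON
#'
#' @param x a `"ConvergenceReport"` or `"RegretRecord"`.
#' @param path output path.
#' @export
writeReportJSON <- function(x, path) {
  jsonlite::write_json(.reportToList(x), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
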