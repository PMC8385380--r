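#' Construct a GenotypeSpace
#'
#' @param allelesPerLocus integer vector giving the number of alleles at
#'   each locus; its length is the number of loci.
#' @return a [GenotypeSpace-class].
#' @examples
#' sp <- GenotypeSpace(c(3, 3))  # two loci, three alleles each
#' numGenotypes(sp)
#' @export
GenotypeSpace <- function(allelesPerLocus) {
  k <- as.integer(allelesPerLocus)
  new("GenotypeSpace", numLoci = length(k), allelesPerLocus = k)
}

#' @rdname GenotypeSpace
#' @param x a GenotypeSpace (or object carrying one).
#' @export
setGeneric("numLoci", function(x) standardGeneric("numLoci"))

#' @rdname GenotypeSpace
#' @export
setMethod("numLoci", "GenotypeSpace", function(x) x@numLoci)

#' @rdname GenotypeSpace
#' @export
setGeneric("allelesPerLocus", function(x) standardGeneric("allelesPerLocus"))

#' @rdname GenotypeSpace
#' @export
setMethod("allelesPerLocus", "GenotypeSpace", function(x) x@allelesPerLocus)

#' @rdname GenotypeSpace
#' @export
setGeneric("numGenotypes", function(x) standardGeneric("numGenotypes"))

#' @rdname GenotypeSpace
#' @export
setMethod("numGenotypes", "GenotypeSpace",
          function(x) prod(x@allelesPerLocus))

setMethod("show", "GenotypeSpace", function(object) {
  cat("GenotypeSpace:", object@numLoci, "loci, alleles per locus (",
      paste(object@allelesPerLocus, collapse = ", "), "), ",
      numGenotypes(object), "genotypes\n")
})

#' Enumerate all genotypes of a space
#'
#' Returns the full genotype table in the package's canonical row-major
#' order: row `g` holds the 1-based allele index at each locus for the
#' `g`-th genotype, with the last locus varying fastest.
#'
#' @param space a [GenotypeSpace-class].
#' @return integer matrix, `numGenotypes x numLoci`.
#' @export
genotypeTuples <- function(space) {
  k <- space@allelesPerLocus
  m <- length(k)
  n <- prod(k)
  out <- matrix(1L, n, m)
  rem <- 0:(n - 1L)
  for (i in m:1) {
    out[, i] <- as.integer(rem %% k[i]) + 1L
    rem <- rem %/% k[i]
  }
  out
}

#' Convert between genotype indices and allele tuples
#'
#' `genotypeIndex` maps a tuple of 1-based allele indices to the 1-based
#' row-major genotype index; `genotypeAlleles` is its inverse.
#'
#' @param space a [GenotypeSpace-class].
#' @param alleles integer vector of allele indices, one per locus.
#' @return `genotypeIndex`: a single integer; `genotypeAlleles`: an
#'   integer vector of allele indices.
#' @export
genotypeIndex <- function(space, alleles) {
  k <- space@allelesPerLocus
  stopifnot(length(alleles) == length(k),
            all(alleles >= 1L), all(alleles <= k))
  idx <- 0L
  for (i in seq_along(k)) idx <- idx * k[i] + (as.integer(alleles[i]) - 1L)
  idx + 1L
}

#' @rdname genotypeIndex
#' @param index 1-based genotype index.
#' @export
genotypeAlleles <- function(space, index) {
  k <- space@allelesPerLocus
  m <- length(k)
  rem <- as.integer(index) - 1L
  out <- integer(m)
  for (i in m:1) {
    out[i] <- as.integer(rem %% k[i]) + 1L
    rem <- rem %/% k[i]
  }
  out
}

.sameSpace <- function(a, b) {
  identical(a@space@allelesPerLocus, b@space@allelesPerLocus)
}

.checkSameSpace <- function(a, b, what = "objects") {
  if (!.sameSpace(a, b))
    stop("dimension error: ", what, " are defined on different genotype ",
         "spaces", call. = FALSE)
  invisible(TRUE)
}

#' Construct a FitnessLandscape
#'
#' @param space a [GenotypeSpace-class].
#' @param values numeric vector of fitnesses in row-major genotype order.
#' @param label optional environment tag.
#' @return a [FitnessLandscape-class].
#' @examples
#' sp <- GenotypeSpace(c(2, 2))
#' w <- FitnessLandscape(sp, c(1, 0.5, 0.5, 0.9), label = "additive")
#' @export
FitnessLandscape <- function(space, values, label = "") {
  new("FitnessLandscape", space = space, values = as.numeric(values),
      label = as.character(label)[1L])
}

#' @rdname FitnessLandscape
#' @param x a FitnessLandscape (or other landscape object).
#' @export
setGeneric("fitnessValues", function(x) standardGeneric("fitnessValues"))

#' @rdname FitnessLandscape
#' @export
setMethod("fitnessValues", "FitnessLandscape", function(x) x@values)

#' @rdname FitnessLandscape
#' @export
setMethod("fitnessValues", "DiploidLandscape", function(x) x@values)

#' @rdname FitnessLandscape
#' @export
setGeneric("landscapeLabel", function(x) standardGeneric("landscapeLabel"))

#' @rdname FitnessLandscape
#' @export
setMethod("landscapeLabel", "FitnessLandscape", function(x) x@label)

#' @rdname FitnessLandscape
#' @export
setMethod("landscapeLabel", "DiploidLandscape", function(x) x@label)

setMethod("show", "FitnessLandscape", function(object) {
  cat("FitnessLandscape",
      if (nzchar(object@label)) paste0("'", object@label, "'") else "",
      "on", numGenotypes(object@space), "genotypes (",
      object@space@numLoci, "loci )\n")
  cat("  fitness range [", format(min(object@values)), ",",
      format(max(object@values)), "]\n")
})

#' Construct a GenotypeDistribution
#'
#' @param space a [GenotypeSpace-class].
#' @param weights probability vector over genotypes; renormalized if it
#'   sums to 1 only within 1e-12.
#' @return a [GenotypeDistribution-class].
#' @export
GenotypeDistribution <- function(space, weights) {
  w <- as.numeric(weights)
  w[w < 0 & w > -.PROB_TOL] <- 0
  s <- sum(w)
  if (abs(s - 1) <= 1e-9 && s > 0) w <- w / s
  new("GenotypeDistribution", space = space, weights = w)
}

#' Uniform and point-mass genotype distributions
#'
#' @param space a [GenotypeSpace-class].
#' @return a [GenotypeDistribution-class].
#' @export
uniformDistribution <- function(space) {
  n <- numGenotypes(space)
  GenotypeDistribution(space, rep(1 / n, n))
}

#' @rdname uniformDistribution
#' @param genotype 1-based genotype index receiving all mass.
#' @export
pointMass <- function(space, genotype) {
  n <- numGenotypes(space)
  stopifnot(genotype >= 1L, genotype <= n)
  w <- numeric(n)
  w[genotype] <- 1
  GenotypeDistribution(space, w)
}

#' @rdname GenotypeDistribution
#' @param x a GenotypeDistribution.
#' @export
setGeneric("genotypeWeights", function(x) standardGeneric("genotypeWeights"))

#' @rdname GenotypeDistribution
#' @export
setMethod("genotypeWeights", "GenotypeDistribution", function(x) x@weights)

setMethod("show", "GenotypeDistribution", function(object) {
  cat("GenotypeDistribution on", numGenotypes(object@space), "genotypes;",
      "max weight", format(max(object@weights), digits = 4), "at genotype",
      which.max(object@weights), "\n")
})

#' Construct an AllelicProfile
#'
#' @param space a [GenotypeSpace-class].
#' @param freqs list of per-locus allele-frequency vectors.
#' @return an [AllelicProfile-class].
#' @export
AllelicProfile <- function(space, freqs) {
  freqs <- lapply(freqs, function(q) {
    q <- as.numeric(q)
    q[q < 0 & q > -.PROB_TOL] <- 0
    s <- sum(q)
    if (abs(s - 1) <= 1e-9 && s > 0) q / s else q
  })
  new("AllelicProfile", space = space, freqs = freqs)
}

#' @rdname AllelicProfile
#' @param space a [GenotypeSpace-class].
#' @export
uniformProfile <- function(space) {
  AllelicProfile(space, lapply(space@allelesPerLocus,
                               function(k) rep(1 / k, k)))
}

#' @rdname AllelicProfile
#' @param x an AllelicProfile.
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname AllelicProfile
#' @export
setMethod("alleleFreqs", "AllelicProfile", function(x) x@freqs)

setMethod("show", "AllelicProfile", function(object) {
  cat("AllelicProfile on", object@space@numLoci, "loci\n")
  for (i in seq_along(object@freqs))
    cat("  locus", i, ": (",
        paste(format(object@freqs[[i]], digits = 4), collapse = ", "),
        ")\n")
})

#' Construct a DiploidLandscape
#'
#' @param values symmetric numeric matrix of genotype fitnesses for
#'   unordered allele pairs.
#' @param label optional tag.
#' @return a [DiploidLandscape-class].
#' @examples
#' heteroAdv <- DiploidLandscape(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
DiploidLandscape <- function(values, label = "") {
  values <- as.matrix(values)
  values <- (values + t(values)) / 2  # enforce symmetry
  new("DiploidLandscape", numAlleles = nrow(values), values = values,
      label = as.character(label)[1L])
}

setMethod("show", "DiploidLandscape", function(object) {
  cat("DiploidLandscape on", object@numAlleles, "alleles",
      if (nzchar(object@label)) paste0("('", object@label, "')") else "",
      "\n")
  print(object@values)
})

#' Construct a GameteState
#'
#' @param space a two-locus [GenotypeSpace-class] (the gamete space).
#' @param freqs probability vector over gametes.
#' @param pairFitness symmetric matrix of gamete-pairing fitnesses.
#' @return a [GameteState-class].
#' @export
GameteState <- function(space, freqs, pairFitness) {
  f <- as.numeric(freqs)
  s <- sum(f)
  if (abs(s - 1) <= 1e-9 && s > 0) f <- f / s
  W <- as.matrix(pairFitness)
  W <- (W + t(W)) / 2
  new("GameteState", space = space, freqs = f, pairFitness = W)
}

#' @rdname GameteState
#' @param x a GameteState.
#' @export
setGeneric("gameteFreqs", function(x) standardGeneric("gameteFreqs"))

#' @rdname GameteState
#' @export
setMethod("gameteFreqs", "GameteState", function(x) x@freqs)

#' @rdname GameteState
#' @export
setGeneric("pairFitness", function(x) standardGeneric("pairFitness"))

#' @rdname GameteState
#' @export
setMethod("pairFitness", "GameteState", function(x) x@pairFitness)

setMethod("show", "GameteState", function(object) {
  cat("GameteState on", numGenotypes(object@space), "gametes; freqs (",
      paste(format(object@freqs, digits = 4), collapse = ", "), ")\n")
})

# ---- fitness aggregation -------------------------------------------------

#' Population mean fitness
#'
#' The expected fitness of a random individual: `sum_g d_g w_g` for a
#' genotype distribution, `p' W p` for diploid allele frequencies, and
#' `x' W x` for a gamete state.
#'
#' @param d state object (distribution, profile, frequency vector, ...).
#' @param w matching landscape (ignored for [GameteState-class], which
#'   carries its own pair fitnesses).
#' @return a single non-negative number.
#' @examples
#' sp <- GenotypeSpace(c(2, 2))
#' w <- FitnessLandscape(sp, c(1, .5, .5, .9))
#' meanFitness(uniformDistribution(sp), w)
#' @export
setGeneric("meanFitness", function(d, w) standardGeneric("meanFitness"))

#' @rdname meanFitness
#' @export
setMethod("meanFitness", signature("GenotypeDistribution", "FitnessLandscape"),
  function(d, w) {
    .checkSameSpace(d, w, "distribution and landscape")
    sum(d@weights * w@values)
  })

#' @rdname meanFitness
#' @export
setMethod("meanFitness", signature("AllelicProfile", "FitnessLandscape"),
  function(d, w) {
    .checkSameSpace(d, w, "profile and landscape")
    sum(.liftWeights(d) * w@values)
  })

#' @rdname meanFitness
#' @export
setMethod("meanFitness", signature("numeric", "DiploidLandscape"),
  function(d, w) {
    stopifnot(length(d) == w@numAlleles)
    as.numeric(d %*% w@values %*% d)
  })

#' @rdname meanFitness
#' @export
setMethod("meanFitness", signature("GameteState", "missing"),
  function(d, w) as.numeric(d@freqs %*% d@pairFitness %*% d@freqs))

#' Marginal fitness of an allele
#'
#' The mean fitness of the genotypes carrying a given allele, weighted by
#' their current frequencies:
#' `w_ij = sum_{g in C_ij} w_g d_g / sum_{g in C_ij} d_g`.
#' Undefined (an error) when the allele has zero marginal probability,
#' since the defining ratio divides by that marginal.
#'
#' @param d a [GenotypeDistribution-class].
#' @param w a [FitnessLandscape-class] on the same space.
#' @param locus 1-based locus index.
#' @param allele 1-based allele index at that locus.
#' @return a single number.
#' @export
marginalFitness <- function(d, w, locus, allele) {
  .checkSameSpace(d, w, "distribution and landscape")
  tup <- genotypeTuples(d@space)
  sel <- tup[, locus] == allele
  marg <- sum(d@weights[sel])
  if (marg <= 0)
    stop("undefined marginal: allele ", allele, " at locus ", locus,
         " has zero marginal probability", call. = FALSE)
  sum(w@values[sel] * d@weights[sel]) / marg
}

# internal: linkage-equilibrium lift of an AllelicProfile, as raw weights
.liftWeights <- function(q) {
  tup <- genotypeTuples(q@space)
  n <- nrow(tup)
  out <- rep(1, n)
  for (i in seq_len(ncol(tup))) out <- out * q@freqs[[i]][tup[, i]]
  out
}

#' Project a genotype distribution to its allelic profile
#'
#' The per-locus marginal allele frequencies of a genotype distribution
#' (the map from the genotype simplex to the product of locus simplices).
#'
#' @param d a [GenotypeDistribution-class].
#' @return an [AllelicProfile-class].
#' @export
projectRho <- function(d) {
  tup <- genotypeTuples(d@space)
  k <- d@space@allelesPerLocus
  freqs <- lapply(seq_along(k), function(i) {
    q <- numeric(k[i])
    for (j in seq_len(k[i])) q[j] <- sum(d@weights[tup[, i] == j])
    q / sum(q)
  })
  AllelicProfile(d@space, freqs)
}

#' Lift an allelic profile to its linkage-equilibrium distribution
#'
#' The product distribution `d_g = prod_i q_{i, g_i}`: the unique
#' genotype distribution in linkage equilibrium with the given per-locus
#' allele frequencies. `projectRho(liftRhoInverse(q))` recovers `q`.
#'
#' @param q an [AllelicProfile-class].
#' @return a [GenotypeDistribution-class] in linkage equilibrium.
#' @export
liftRhoInverse <- function(q) {
  w <- .liftWeights(q)
  GenotypeDistribution(q@space, w / sum(w))
}

#' Distance from linkage equilibrium
#'
#' `max_g | d_g - [rho^{-1}(rho(d))]_g |`: the max-norm distance between a
#' genotype distribution and the product of its own per-locus marginals.
#' Zero exactly when the population is in linkage equilibrium; single-locus
#' spaces always return 0.
#'
#' @param d a [GenotypeDistribution-class].
#' @return a non-negative number.
#' @export
linkageDeviation <- function(d) {
  if (d@space@numLoci == 1L) return(0)
  le <- liftRhoInverse(projectRho(d))
  max(abs(d@weights - le@weights))
}
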