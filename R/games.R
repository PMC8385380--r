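# Finite games, potential construction/verification, Nash enumeration.
#
# Pure action profiles are enumerated row-major (last player's action
# varies fastest), exactly as genotypes are, so a loci-as-players game and
# its source landscape index their profiles/genotypes identically.

.enumTuples <- function(k) {
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

.profileIndex <- function(k, a) {
  idx <- 0L
  for (i in seq_along(k)) idx <- idx * k[i] + (as.integer(a[i]) - 1L)
  idx + 1L
}

# strides for unilateral moves of each player in the flat enumeration
.strides <- function(k) {
  m <- length(k)
  s <- integer(m)
  s[m] <- 1L
  if (m > 1L) for (i in (m - 1L):1L) s[i] <- s[i + 1L] * k[i + 1L]
  s
}

# max over unilateral edges of |dPhi - du|; 0 for an exact potential
.maxPotentialDeviation <- function(game, potential) {
  k <- game@actionCounts
  tup <- .enumTuples(k)
  s <- .strides(k)
  dev <- 0
  for (i in seq_along(k)) {
    base <- seq_len(nrow(tup)) - (tup[, i] - 1L) * s[i]
    ui <- game@payoffs[[i]]
    dev <- max(dev, max(abs((potential - potential[base]) -
                            (ui - ui[base]))))
  }
  dev
}

#' Construct a FiniteGame
#'
#' @param actionCounts integer vector: number of actions per player.
#' @param payoffs list with one numeric payoff vector per player, each
#'   over pure profiles in row-major order (last player fastest); or a
#'   single vector, interpreted as an identical-interests game.
#' @return a [FiniteGame-class].
#' @examples
#' # 2x2 coordination game: meet at the symphony (2) or the beach (1)
#' coord <- FiniteGame(c(2, 2), c(2, 0, 0, 1))
#' @export
FiniteGame <- function(actionCounts, payoffs) {
  k <- as.integer(actionCounts)
  if (!is.list(payoffs)) payoffs <- rep(list(as.numeric(payoffs)), length(k))
  payoffs <- lapply(payoffs, as.numeric)
  new("FiniteGame", numPlayers = length(k), actionCounts = k,
      payoffs = payoffs)
}

#' @rdname FiniteGame
#' @param x a FiniteGame or PotentialGame.
#' @export
setGeneric("actionCounts", function(x) standardGeneric("actionCounts"))

#' @rdname FiniteGame
#' @export
setMethod("actionCounts", "FiniteGame", function(x) x@actionCounts)

#' @rdname FiniteGame
#' @export
setMethod("actionCounts", "PotentialGame", function(x) x@game@actionCounts)

#' @rdname FiniteGame
#' @export
setGeneric("payoffs", function(x) standardGeneric("payoffs"))

#' @rdname FiniteGame
#' @export
setMethod("payoffs", "FiniteGame", function(x) x@payoffs)

#' @rdname FiniteGame
#' @export
setMethod("payoffs", "PotentialGame", function(x) x@game@payoffs)

#' @rdname FiniteGame
#' @param x a PotentialGame.
#' @export
setGeneric("potentialFunction", function(x)
  standardGeneric("potentialFunction"))

#' @rdname FiniteGame
#' @export
setMethod("potentialFunction", "PotentialGame", function(x) x@potential)

setMethod("show", "FiniteGame", function(object) {
  cat("FiniteGame:", object@numPlayers, "players, actions (",
      paste(object@actionCounts, collapse = ", "), ")\n")
})

setMethod("show", "PotentialGame", function(object) {
  cat("PotentialGame:", object@game@numPlayers, "players, actions (",
      paste(object@game@actionCounts, collapse = ", "), "); potential range [",
      format(min(object@potential)), ",", format(max(object@potential)),
      "]\n")
})

.asFiniteGame <- function(g) if (is(g, "PotentialGame")) g@game else g

# validate/coerce a mixed profile (list of per-player probability vectors)
.asMixedProfile <- function(game, x) {
  if (is(x, "AllelicProfile")) x <- x@freqs
  k <- game@actionCounts
  if (!is.list(x) || length(x) != length(k))
    stop("dimension error: mixed profile must have one vector per player",
         call. = FALSE)
  for (i in seq_along(k)) {
    if (length(x[[i]]) != k[i])
      stop("dimension error: player ", i, " strategy has wrong length",
           call. = FALSE)
    if (!.isProb(x[[i]], 1e-9))
      stop("player ", i, " strategy is not a probability vector",
           call. = FALSE)
  }
  x
}

#' Loci-as-players identical-interests game of a fitness landscape
#'
#' Each locus becomes a player whose actions are its alleles; every player
#' receives the common payoff `w_g` at the pure profile corresponding to
#' genotype `g`. Mean fitness is the multilinear potential of this game,
#' so its pure Nash equilibria are the local maxima of the landscape under
#' single-locus allele swaps.
#'
#' @param w a [FitnessLandscape-class].
#' @return a [PotentialGame-class] whose potential is the common payoff.
#' @export
gameFromLandscape <- function(w) {
  fg <- FiniteGame(w@space@allelesPerLocus, w@values)
  new("PotentialGame", game = fg, potential = w@values)
}

#' Expected payoff of a mixed profile
#'
#' Multilinear extension of the pure payoffs. With `action` given, the
#' payoff to `player` for playing that pure action against the others'
#' mixed strategies.
#'
#' @param g a [FiniteGame-class] or [PotentialGame-class].
#' @param x mixed profile: list of per-player probability vectors (an
#'   [AllelicProfile-class] is accepted).
#' @param player player index.
#' @param action optional pure action for `player`.
#' @return a single number.
#' @export
expectedPayoff <- function(g, x, player, action = NULL) {
  game <- .asFiniteGame(g)
  x <- .asMixedProfile(game, x)
  tup <- .enumTuples(game@actionCounts)
  u <- game@payoffs[[player]]
  if (is.null(action)) {
    pr <- rep(1, nrow(tup))
    for (i in seq_along(x)) pr <- pr * x[[i]][tup[, i]]
    sum(u * pr)
  } else {
    pr <- rep(1, nrow(tup))
    for (i in seq_along(x)) if (i != player) pr <- pr * x[[i]][tup[, i]]
    sel <- tup[, player] == action
    sum(u[sel] * pr[sel])
  }
}

#' Potential of a mixed profile
#'
#' The multilinear extension of the potential:
#' `sum_a prod_i x_i(a_i) * Phi(a)`. For a game built with
#' [gameFromLandscape()] this equals the mean fitness of the
#' linkage-equilibrium lift of `x`.
#'
#' @param g a [PotentialGame-class].
#' @param x mixed profile (list of probability vectors or
#'   [AllelicProfile-class]).
#' @return a single number.
#' @export
potentialValue <- function(g, x) {
  stopifnot(is(g, "PotentialGame"))
  x <- .asMixedProfile(g@game, x)
  tup <- .enumTuples(g@game@actionCounts)
  pr <- rep(1, nrow(tup))
  for (i in seq_along(x)) pr <- pr * x[[i]][tup[, i]]
  sum(g@potential * pr)
}

#' Enumerate the pure Nash equilibria of a finite game
#'
#' A pure profile is Nash when no unilateral deviation strictly improves
#' the deviator's payoff (weak inequality: payoff ties still count as
#' equilibria, so degenerate games may return plateaus). For a potential
#' game the result is the set of local maxima of the potential and is
#' never empty.
#'
#' @param g a [FiniteGame-class] or [PotentialGame-class].
#' @param tol numeric slack on payoff comparisons (default 0: exact).
#' @return integer matrix, one row per equilibrium profile (1-based
#'   action indices).
#' @examples
#' coord <- FiniteGame(c(2, 2), c(2, 0, 0, 1))
#' enumeratePureNash(coord)  # (1,1) and (2,2)
#' @export
enumeratePureNash <- function(g, tol = 0) {
  game <- .asFiniteGame(g)
  k <- game@actionCounts
  tup <- .enumTuples(k)
  s <- .strides(k)
  isNash <- rep(TRUE, nrow(tup))
  for (i in seq_along(k)) {
    ui <- game@payoffs[[i]]
    # best payoff attainable by player i holding the others fixed
    base <- seq_len(nrow(tup)) - (tup[, i] - 1L) * s[i]
    best <- rep(-Inf, nrow(tup))
    for (j in seq_len(k[i])) {
      idx <- base + (j - 1L) * s[i]
      best <- pmax(best, ui[idx])
    }
    isNash <- isNash & (ui >= best - tol)
  }
  tup[isNash, , drop = FALSE]
}

#' Construct an exact potential for a finite game, if one exists
#'
#' Integrates payoff differences along coordinate deviation paths from the
#' all-ones reference profile, then verifies the potential condition on
#' every unilateral edge. Returns `NULL` when no exact potential exists
#' (deviation above `tol`); potentials are unique up to an additive
#' constant, and the returned one is anchored at 0 on the reference
#' profile.
#'
#' @param g a [FiniteGame-class].
#' @param tol tolerance on the edge-consistency check.
#' @return a [PotentialGame-class], or `NULL`.
#' @export
findPotential <- function(g, tol = 1e-9) {
  game <- .asFiniteGame(g)
  k <- game@actionCounts
  tup <- .enumTuples(k)
  m <- length(k)
  n <- nrow(tup)
  phi <- numeric(n)
  ref <- rep(1L, m)
  for (gi in seq_len(n)) {
    a <- tup[gi, ]
    cur <- ref
    total <- 0
    for (i in seq_len(m)) {
      prev <- .profileIndex(k, cur)
      cur[i] <- a[i]
      nxt <- .profileIndex(k, cur)
      total <- total + game@payoffs[[i]][nxt] - game@payoffs[[i]][prev]
    }
    phi[gi] <- total
  }
  if (.maxPotentialDeviation(game, phi) > tol) return(NULL)
  new("PotentialGame", game = game, potential = phi)
}

#' Simultaneous best-reply step
#'
#' Every player switches at once to a best reply against the others'
#' current pure actions; ties are broken toward the lowest action index so
#' the dynamic is deterministic (on the 2x2 coordination game this
#' reproduces the (S,B) <-> (B,S) miscoordination cycle).
#'
#' @param g a [FiniteGame-class] or [PotentialGame-class].
#' @param a integer vector of current pure actions (1-based).
#' @return integer vector of next-period actions.
#' @export
bestReplyStep <- function(g, a) {
  game <- .asFiniteGame(g)
  k <- game@actionCounts
  stopifnot(length(a) == length(k), all(a >= 1L), all(a <= k))
  s <- .strides(k)
  cur <- .profileIndex(k, a)
  out <- integer(length(k))
  for (i in seq_along(k)) {
    base <- cur - (a[i] - 1L) * s[i]
    vals <- game@payoffs[[i]][base + (seq_len(k[i]) - 1L) * s[i]]
    out[i] <- which.max(vals)  # first max = lowest-index tie-break
  }
  out
}

#' Best unilateral improvement available at a mixed profile
#'
#' `max_i [ max_a u_i(a; x_-i) - u_i(x) ]`, floored at zero: the largest
#' payoff gain any single player could get by deviating to a pure action.
#' Zero (up to tolerance) exactly at Nash equilibria, so it certifies
#' epsilon-Nash limits of the dynamics.
#'
#' @param g a [FiniteGame-class] or [PotentialGame-class].
#' @param x mixed profile (list of probability vectors or
#'   [AllelicProfile-class]).
#' @return a single non-negative number.
#' @export
epsilonNashGap <- function(g, x) {
  game <- .asFiniteGame(g)
  x <- .asMixedProfile(game, x)
  gap <- 0
  for (i in seq_len(game@numPlayers)) {
    ui <- expectedPayoff(game, x, i)
    for (a in seq_len(game@actionCounts[i]))
      gap <- max(gap, expectedPayoff(game, x, i, a) - ui)
  }
  max(gap, 0)
}
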