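# Seed construction: exhaustive optimal single seeds, and multiple-seed
# design by overlap-complexity hill climbing with sensitivity selection.

# Cross-correlation of the 1-positions of two patterns: for each relative
# shift where the spans overlap, the number of coinciding 1s.
.shiftOverlaps <- function(aOnes, bOnes) {
  M <- outer(aOnes, bOnes)
  rowsum(as.vector(M), as.vector(row(M) - col(M)))[, 1L]
}

#' Overlap complexity of a seed set
#'
#' The sum, over all ordered pairs of member seeds (including each seed
#' with itself) and all relative shifts at which their spans overlap, of
#' \code{2^m} where m is the number of positions at which two 1s coincide.
#' Lower values indicate less redundant seed sets; it is the cheap
#' surrogate objective used during hill climbing in
#' \code{\link{designSeedSet}}.
#'
#' @param seeds a \linkS4class{SeedSet} (or coercible).
#' @return a single numeric value.
#' @examples
#' overlapComplexity(SeedSet("11"))  # shifts -1, 0, 1 give 2 + 4 + 2 = 8
#' @export
overlapComplexity <- function(seeds) {
  seeds <- .asSeedSet(seeds)
  ones <- lapply(seeds@seeds, function(s)
    as.integer(.patternChars(s@pattern) == "1"))
  total <- 0
  for (a in ones)
    for (b in ones)
      total <- total + sum(2^.shiftOverlaps(a, b))
  total
}

# Overlap complexity between one pattern (char vector) and a list of
# patterns, counting ordered pairs in both directions plus nothing else.
.ocAgainst <- function(chSelf, chOthers) {
  a <- as.integer(chSelf == "1")
  total <- 0
  for (ch in chOthers) {
    b <- as.integer(ch == "1")
    total <- total + 2 * sum(2^.shiftOverlaps(a, b))
  }
  total + sum(2^.shiftOverlaps(a, a))
}

#' Optimal single spaced seed by exhaustive enumeration
#'
#' Enumerates every pattern of the given weight with span between
#' \code{weight} and \code{maxSpan} (first and last characters 1) and
#' returns the one maximizing exact sensitivity under \code{model}. Ties
#' break toward the lexicographically smallest pattern. Only feasible for
#' modest weights/spans; the candidate count is capped.
#'
#' @param weight seed weight.
#' @param maxSpan maximum span to consider (must stay within the DP
#'   feasibility cap of 22).
#' @param model an \linkS4class{AlignmentModel}.
#' @param candidateCap maximum number of candidate patterns (default
#'   100000).
#' @param stateCap passed to \code{\link{sensitivityExact}}.
#' @return the sensitivity-optimal \linkS4class{Seed}.
#' @examples
#' m <- AlignmentModel(N = 16, p = 0.7)
#' optimalSingleSeed(weight = 3, maxSpan = 5, model = m)
#' @export
optimalSingleSeed <- function(weight, maxSpan = weight, model,
                              candidateCap = 1e5, stateCap = 2^24) {
  stopifnot(weight >= 1, maxSpan >= weight)
  if (maxSpan > 22)
    stop("maxSpan exceeds the DP feasibility cap of 22")
  if (model@N < maxSpan)
    maxSpan <- model@N
  if (maxSpan < weight)
    stop("region length is shorter than the seed weight")
  cands <- character(0L)
  for (span in weight:maxSpan) {
    if (weight == 1L) {
      if (span == 1L) cands <- c(cands, "1")
      next
    }
    interior <- span - 2L
    nOnes <- weight - 2L
    n <- choose(interior, nOnes)
    if (length(cands) + n > candidateCap)
      stop(sprintf("candidate count exceeds cap (%g); reduce maxSpan",
                   candidateCap))
    combos <- if (nOnes == 0L) matrix(integer(0L), nrow = 0L, ncol = 1L)
              else utils::combn(interior, nOnes)
    pats <- apply(combos, 2L, function(ix) {
      ch <- rep("*", interior)
      ch[ix] <- "1"
      paste(c("1", ch, "1"), collapse = "")
    })
    if (nOnes == 0L && interior >= 0L)
      pats <- paste(c("1", rep("*", interior), "1"), collapse = "")
    cands <- c(cands, pats)
  }
  if (!length(cands))
    stop("no candidate seeds in the given weight/span range")
  cands <- sort(unique(cands))
  best <- NULL
  bestSens <- -Inf
  for (p in cands) {
    sens <- sensitivityExact(p, model, stateCap = stateCap)
    if (sens > bestSens + 1e-15) {
      bestSens <- sens
      best <- p
    }
  }
  Seed(best)
}

# Random pattern of given weight/span with first/last fixed to 1 and
# optionally nTransition @ characters in the interior.
.randomPattern <- function(weight, span, nTransition = 0L) {
  interior <- span - 2L
  stopifnot(interior >= (weight - 2L) + nTransition)
  ch <- rep("*", interior)
  pick <- sample.int(interior, (weight - 2L) + nTransition)
  ch[pick[seq_len(weight - 2L)]] <- "1"
  if (nTransition > 0L)
    ch[pick[(weight - 1L):length(pick)]] <- "@"
  paste(c("1", ch, "1"), collapse = "")
}

# One first-improvement hill-climbing pass over a list of pattern char
# vectors: swap an interior 1 with an interior * in one seed whenever the
# swap lowers the set's overlap complexity (duplicates rejected).
.hillClimb <- function(chs, maxSweeps = 30L) {
  repeat {
    improved <- FALSE
    for (i in seq_along(chs)) {
      ch <- chs[[i]]
      interior <- seq_along(ch)[-c(1L, length(ch))]
      ones <- interior[ch[interior] == "1"]
      stars <- interior[ch[interior] == "*"]
      if (!length(ones) || !length(stars)) next
      baseOC <- .ocAgainst(ch, chs[-i])
      # note: sample(x) on a length-1 vector would expand to 1:x
      for (o in ones[sample.int(length(ones))]) {
        done <- FALSE
        for (s in stars[sample.int(length(stars))]) {
          cand <- ch
          cand[o] <- "*"
          cand[s] <- "1"
          pat <- paste(cand, collapse = "")
          if (pat %in% vapply(chs[-i], paste, character(1L), collapse = ""))
            next
          if (.ocAgainst(cand, chs[-i]) < baseOC - 1e-9) {
            chs[[i]] <- cand
            improved <- TRUE
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
    maxSweeps <- maxSweeps - 1L
    if (!improved || maxSweeps <= 0L) break
  }
  chs
}

# Sensitivity used to select among design restarts: exact DP when the
# state space is small enough, Monte Carlo otherwise.
.designSensitivity <- function(set, model, rngSeed,
                               exactCap = 2^19, mcTrials = 20000L) {
  base <- if (.hasTransitions(set)) 3 else 2
  if (base^(maxSpan(set) - 1L) <= exactCap)
    sensitivityExact(set, model, stateCap = exactCap)
  else
    sensitivityMC(set, model, trials = mcTrials, rngSeed = rngSeed)[["estimate"]]
}

#' Design a multiple (or single) seed set by hill climbing
#'
#' Starts from random distinct patterns of the requested weight and span,
#' hill-climbs by swapping an interior 1 with an interior * in one seed
#' whenever the swap lowers the set's overlap complexity, and over
#' \code{restarts} restarts keeps the set with the highest sensitivity
#' under \code{model} (exact DP when the state space permits, Monte Carlo
#' beyond it). With \code{nTransition > 0} each seed carries that many
#' fixed \code{@} positions (placed at random per restart) and the 1s are
#' hill-climbed around them.
#'
#' @param k number of seeds.
#' @param weight weight of every seed.
#' @param span common span (default \code{min(weight + 7, 22)}).
#' @param model an \linkS4class{AlignmentModel} used for selection.
#' @param nTransition number of \code{@} positions per seed (default 0).
#' @param restarts number of random restarts (default 20).
#' @param rngSeed integer seed making the design reproducible.
#' @return the selected \linkS4class{SeedSet}.
#' @examples
#' m <- AlignmentModel(N = 20, p = 0.75)
#' designSeedSet(k = 2, weight = 4, span = 6, model = m, restarts = 3,
#'               rngSeed = 7)
#' @export
designSeedSet <- function(k, weight, span = min(weight + 7, 22), model,
                          nTransition = 0, restarts = 20, rngSeed = 1) {
  stopifnot(k >= 1, weight >= 2, span >= weight + nTransition, span <= 22)
  if (model@N < span)
    stop("region length N is shorter than the requested span")
  nTransition <- as.integer(nTransition)
  best <- NULL
  bestSens <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(.deriveSeed(rngSeed, r))
    chs <- list()
    guard <- 0L
    while (length(chs) < k) {
      p <- .patternChars(.randomPattern(weight, span, nTransition))
      if (!any(vapply(chs, identical, logical(1L), y = p)))
        chs[[length(chs) + 1L]] <- p
      guard <- guard + 1L
      if (guard > 1000L)
        stop("cannot draw k distinct random seeds; increase span")
    }
    chs <- .hillClimb(chs)
    set <- SeedSet(vapply(chs, paste, character(1L), collapse = ""))
    sens <- .designSensitivity(set, model, rngSeed = .deriveSeed(rngSeed, r, 999L))
    if (sens > bestSens + 1e-12) {
      bestSens <- sens
      best <- set
    }
  }
  best
}
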