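#' Construct a Bernoulli alignment model
#'
#' @param N region length (positions in the random gap-free alignment).
#' @param p per-position match probability (the similarity level).
#' @param q per-position transition probability; only used when a seed set
#'   contains \code{@} positions. Defaults to \code{(1 - p) / 2}, i.e. half
#'   of the mismatch mass; the true transition/transversion split of a
#'   dataset can be supplied instead.
#' @return an \linkS4class{AlignmentModel}.
#' @examples
#' AlignmentModel(N = 64, p = 0.7)
#' @export
AlignmentModel <- function(N, p, q = (1 - p) / 2) {
  stopifnot(.isWholeNumber(N))
  new("AlignmentModel", N = as.integer(N), p = as.numeric(p),
      q = as.numeric(q))
}

setMethod("show", "AlignmentModel", function(object) {
  cat(sprintf("AlignmentModel: N = %d, p = %g, q = %g\n",
              object@N, object@p, object@q))
})

# Per-seed hit masks for the binary DP. The rolling window value v encodes
# the last L symbols, most recent symbol in bit 0, so seed character i
# (1-based) aligns with bit (span - i). Returns a logical vector over
# v = 0 .. 2^L - 1, TRUE where any seed hits at the window's last position.
.binaryHitMask <- function(seeds, L) {
  nv <- as.integer(2^L)
  v <- 0:(nv - 1L)
  hit <- logical(nv)
  for (s in seeds@seeds) {
    ch <- .patternChars(s@pattern)
    m <- as.integer(sum(2^(s@span - which(ch == "1"))))
    hit <- hit | (bitwAnd(v, m) == m)
  }
  hit
}

# Ternary analogue: symbols 0 = transversion, 1 = transition, 2 = match,
# window value in base 3 (most recent symbol = least significant digit).
# A seed hits iff every 1 aligns to a match and every @ to match-or-transition.
.ternaryHitMask <- function(seeds, L) {
  nv <- 3^L
  v <- seq_len(nv) - 1
  hit <- logical(nv)
  for (s in seeds@seeds) {
    ch <- .patternChars(s@pattern)
    ok <- rep(TRUE, nv)
    for (i in which(ch != "*")) {
      digit <- (v %/% 3^(s@span - i)) %% 3
      ok <- ok & (if (ch[i] == "1") digit == 2 else digit >= 1)
    }
    hit <- hit | ok
  }
  hit
}

#' Exact seed-set sensitivity under the Bernoulli alignment model
#'
#' Computes the probability that at least one seed of the set hits a random
#' alignment region of length \code{N} with per-position match probability
#' \code{p}, by a position-by-position dynamic program over the
#' distribution of the last \code{maxSpan - 1} alignment symbols
#' conditioned on no hit so far. For seed sets without \code{@} the
#' alignment alphabet is binary (match/mismatch, \code{2^(maxSpan-1)}
#' states); with \code{@} it is ternary (match/transition/transversion with
#' probabilities \code{p}, \code{q}, \code{1-p-q}, \code{3^(maxSpan-1)}
#' states).
#'
#' @param seeds a \linkS4class{SeedSet}, \linkS4class{Seed} or character
#'   vector of patterns.
#' @param model an \linkS4class{AlignmentModel}.
#' @param stateCap maximum admissible number of DP states (default
#'   \code{2^24}); larger state spaces raise an error suggesting
#'   \code{\link{sensitivityMC}} rather than silently approximating.
#' @return the sensitivity, a probability in [0, 1].
#' @examples
#' m <- AlignmentModel(N = 64, p = 0.7)
#' sensitivityExact("11111111111", m)           # about 0.30
#' \donttest{
#' sensitivityExact("111*1**1*1**11*111", m)    # about 0.467
#' }
#' @seealso \code{\link{sensitivityMC}}, \code{\link{expectedHits}}
#' @export
sensitivityExact <- function(seeds, model, stateCap = 2^24) {
  seeds <- .asSeedSet(seeds)
  stopifnot(is(model, "AlignmentModel"))
  L <- maxSpan(seeds)
  N <- model@N
  if (N < L)
    stop(sprintf("region length N = %d is shorter than the maximum span %d",
                 N, L))
  ternary <- .hasTransitions(seeds)
  base <- if (ternary) 3 else 2
  S <- base^(L - 1L)
  if (S > stateCap)
    stop(sprintf(paste0("DP state space %s^%d exceeds the cap (%g); ",
                        "use sensitivityMC() instead"),
                 base, L - 1L, stateCap))
  probs <- if (ternary)
    c(1 - model@p - model@q, model@q, model@p)
  else
    c(1 - model@p, model@p)
  hit <- if (ternary) .ternaryHitMask(seeds, L) else .binaryHitMask(seeds, L)

  # dist[s + 1] = P(no hit in first t positions, last L-1 symbols encode s).
  # The initial all-zero state is safe: phantom pre-start symbols are
  # mismatches/transversions, which can never satisfy a 1 or @ constraint.
  dist <- numeric(S)
  dist[1L] <- 1
  idx <- lapply(seq_len(base), function(b) seq(b, base * S, by = base))
  fold <- lapply(seq_len(base), function(b) ((b - 1L) * S + 1L):(b * S))
  nextv <- numeric(base * S)
  for (t in seq_len(N)) {
    for (b in seq_len(base))
      nextv[idx[[b]]] <- dist * probs[b]
    nextv[hit] <- 0
    dist <- nextv[fold[[1L]]]
    for (b in seq_len(base)[-1L])
      dist <- dist + nextv[fold[[b]]]
  }
  1 - sum(dist)
}

#' Monte-Carlo seed-set sensitivity
#'
#' Estimates sensitivity as the fraction of simulated Bernoulli alignment
#' regions hit by the seed set, with the binomial standard error. Serves as
#' an independent check on (and fallback beyond the state-space cap of)
#' \code{\link{sensitivityExact}}.
#'
#' @inheritParams sensitivityExact
#' @param trials number of simulated regions.
#' @param rngSeed integer seed; results are reproducible given the seed.
#' @return named numeric vector with elements \code{estimate} and \code{se}.
#' @export
sensitivityMC <- function(seeds, model, trials = 1e5, rngSeed = 1) {
  seeds <- .asSeedSet(seeds)
  stopifnot(is(model, "AlignmentModel"), trials >= 1)
  trials <- as.integer(trials)
  N <- model@N
  ternary <- .hasTransitions(seeds)
  set.seed(rngSeed)
  hits <- 0L
  block <- 50000L
  done <- 0L
  while (done < trials) {
    nb <- min(block, trials - done)
    M <- if (ternary)
      matrix(sample.int(3L, nb * N, replace = TRUE,
                        prob = c(1 - model@p - model@q, model@q, model@p)) - 1L,
             nrow = nb)
    else
      matrix((runif(nb * N) < model@p) * 2L, nrow = nb)
    anyhit <- rep(FALSE, nb)
    for (s in seeds@seeds) {
      if (s@span > N) next
      ch <- .patternChars(s@pattern)
      npos <- N - s@span + 1L
      A <- matrix(TRUE, nb, npos)
      for (i in which(ch != "*")) {
        cols <- seq_len(npos) + i - 1L
        A <- A & (if (ch[i] == "1") M[, cols, drop = FALSE] == 2L
                  else M[, cols, drop = FALSE] >= 1L)
      }
      anyhit <- anyhit | (rowSums(A) > 0L)
    }
    hits <- hits + sum(anyhit)
    done <- done + nb
  }
  est <- hits / trials
  c(estimate = est, se = sqrt(est * (1 - est) / trials))
}

#' Expected number of hits of a single seed in a random region
#'
#' For a seed of weight w and span l, a region of length N offers
#' \code{N - l + 1} placements, each hitting with probability \code{p^w}
#' (times \code{(p+q)^a} for a seed with a transition positions), so the
#' expected hit count is \code{(N - l + 1) * p^w * (p+q)^a}.
#'
#' @param seed a \linkS4class{Seed} or pattern string.
#' @param model an \linkS4class{AlignmentModel} with \code{N >= seedSpan}.
#' @return expected number of hits (numeric).
#' @examples
#' expectedHits("11111111111", AlignmentModel(N = 64, p = 0.7)) # 54 * 0.7^11
#' @export
expectedHits <- function(seed, model) {
  if (!is(seed, "Seed")) seed <- Seed(seed)
  stopifnot(is(model, "AlignmentModel"))
  if (model@N < seed@span)
    stop(sprintf("region length N = %d is shorter than the seed span %d",
                 model@N, seed@span))
  nAt <- sum(.patternChars(seed@pattern) == "@")
  (model@N - seed@span + 1) * model@p^seed@weight *
    (if (nAt) (model@p + model@q)^nAt else 1)
}
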