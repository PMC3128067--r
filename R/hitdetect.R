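#' Construct an oligo group
#'
#' @param main the main (target) DNA sequence.
#' @param secondaries character vector of secondary sequences, same length
#'   as \code{main}.
#' @param labels \code{"oligo"}/\code{"non-oligo"} labels parallel to
#'   \code{secondaries}.
#' @param info optional data.frame of per-secondary metrics.
#' @return an \linkS4class{OligoGroup}.
#' @export
OligoGroup <- function(main, secondaries, labels,
                       info = data.frame()) {
  new("OligoGroup", main = toupper(main),
      secondaries = toupper(secondaries),
      labels = labels, info = info)
}

#' @rdname OligoGroup-class
#' @export
setMethod("mainSequence", "OligoGroup", function(x) x@main)

#' @rdname OligoGroup-class
#' @export
setMethod("secondarySequences", "OligoGroup", function(x) x@secondaries)

#' @rdname OligoGroup-class
#' @export
setMethod("secondaryLabels", "OligoGroup", function(x) x@labels)

setMethod("show", "OligoGroup", function(object) {
  cat(sprintf("OligoGroup: main of %d bp, %d secondaries (%d oligo, %d non-oligo)\n",
              nchar(object@main), length(object@secondaries),
              sum(object@labels == "oligo"),
              sum(object@labels == "non-oligo")))
})

#' @rdname OligoDataset-class
#' @param groups list of \linkS4class{OligoGroup}.
#' @param config generator configuration echo (list).
#' @export
OligoDataset <- function(groups, config = list()) {
  new("OligoDataset", groups = groups, config = config)
}

#' @rdname OligoDataset-class
#' @export
setMethod("oligoGroups", "OligoDataset", function(x) x@groups)

#' @rdname OligoDataset-class
#' @export
setMethod("length", "OligoDataset", function(x) length(x@groups))

setMethod("show", "OligoDataset", function(object) {
  labs <- unlist(lapply(object@groups, secondaryLabels))
  cat(sprintf("OligoDataset: %d groups, %d secondaries (%d oligo, %d non-oligo)\n",
              length(object@groups), length(labs),
              sum(labs == "oligo"), sum(labs == "non-oligo")))
})

#' Build the hash-key index of a main sequence
#'
#' For every seed of the set, collects the set of hash keys occurring at
#' any window of the main sequence (windows containing ambiguous bases at
#' constrained positions are skipped). Seeds longer than the main sequence
#' contribute an empty key set; if no seed fits at all, an empty index is
#' returned with a warning.
#'
#' @param seeds a \linkS4class{SeedSet} (or coercible).
#' @param main the main DNA sequence.
#' @param bothStrands also index the reverse complement of \code{main}
#'   (off by default: generated datasets are same-strand variants).
#' @return a \linkS4class{SeedIndex}.
#' @examples
#' buildSeedIndex(SeedSet("11"), "ACGT")   # keys AC, CG, GT
#' @export
buildSeedIndex <- function(seeds, main, bothStrands = FALSE) {
  seeds <- .asSeedSet(seeds)
  if (!is.character(main) || length(main) != 1L || !nzchar(main))
    stop("'main' must be a single non-empty DNA sequence")
  enc <- .encodeDNA(main)
  encs <- list(enc)
  if (bothStrands)
    encs <- c(encs, list(rev(3L - enc)))
  keys <- lapply(seeds@seeds, function(s) {
    k <- unlist(lapply(encs, .seedKeys, seed = s))
    unique(k[!is.na(k)])
  })
  if (all(lengths(keys) == 0L) && all(seedSpan(seeds) > nchar(main)))
    warning("main sequence is shorter than every seed span; index is empty")
  new("SeedIndex", keys = keys, patterns = seedPattern(seeds),
      seeds = seeds@seeds)
}

#' Count hits of an indexed seed set in a secondary sequence
#'
#' A hit is a pair (seed, position j in the secondary) such that the seed's
#' hash key at j also occurs somewhere in the main sequence. Multiple
#' occurrences of the same key in the main count once per (seed, j),
#' matching the one-lookup-per-position cost the efficiency measure
#' captures.
#'
#' @param index a \linkS4class{SeedIndex} built from the same seed set.
#' @param secondary a DNA sequence.
#' @return list with elements \code{hit} (logical) and \code{hitCount}
#'   (integer).
#' @export
countHits <- function(index, secondary) {
  stopifnot(is(index, "SeedIndex"))
  enc <- .encodeDNA(secondary)
  total <- 0L
  for (j in seq_along(index@patterns)) {
    k <- .seedKeys(index@seeds[[j]], enc)
    if (length(k))
      total <- total + sum(k %in% index@keys[[j]], na.rm = TRUE)
  }
  list(hit = total >= 1L, hitCount = total)
}

#' Hit report for a whole group
#'
#' Builds the index of the group's main sequence and counts hits in each
#' secondary, preserving order.
#'
#' @param seeds a \linkS4class{SeedSet} (or coercible).
#' @param group an \linkS4class{OligoGroup}.
#' @param bothStrands passed to \code{\link{buildSeedIndex}}.
#' @return a \linkS4class{HitReport}.
#' @export
groupHits <- function(seeds, group, bothStrands = FALSE) {
  stopifnot(is(group, "OligoGroup"))
  seeds <- .asSeedSet(seeds)
  idx <- buildSeedIndex(seeds, mainSequence(group), bothStrands = bothStrands)
  counts <- vapply(secondarySequences(group), function(sec)
    countHits(idx, sec)$hitCount, integer(1L), USE.NAMES = FALSE)
  new("HitReport", hit = counts >= 1L, hitCount = counts,
      totalHits = sum(counts))
}

setMethod("show", "HitReport", function(object) {
  cat(sprintf("HitReport: %d/%d secondaries hit, %d total hits\n",
              sum(object@hit), length(object@hit), object@totalHits))
})
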