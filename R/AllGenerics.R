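#' @rdname Seed-class
#' @param x a \linkS4class{Seed} or \linkS4class{SeedSet}.
#' @export
setGeneric("seedPattern", function(x) standardGeneric("seedPattern"))

#' @rdname Seed-class
#' @export
setGeneric("seedWeight", function(x) standardGeneric("seedWeight"))

#' @rdname Seed-class
#' @export
setGeneric("seedSpan", function(x) standardGeneric("seedSpan"))

#' @rdname SeedSet-class
#' @param x a \linkS4class{SeedSet}.
#' @export
setGeneric("maxSpan", function(x) standardGeneric("maxSpan"))

#' @rdname OligoGroup-class
#' @param x an \linkS4class{OligoGroup}.
#' @export
setGeneric("mainSequence", function(x) standardGeneric("mainSequence"))

#' @rdname OligoGroup-class
#' @export
setGeneric("secondarySequences",
           function(x) standardGeneric("secondarySequences"))

#' @rdname OligoGroup-class
#' @export
setGeneric("secondaryLabels", function(x) standardGeneric("secondaryLabels"))

#' @rdname OligoDataset-class
#' @param x an \linkS4class{OligoDataset}.
#' @export
setGeneric("oligoGroups", function(x) standardGeneric("oligoGroups"))

#' Precision, recall, F-score and efficiency of a seed
#'
#' Given confusion counts (TP oligos hit, FP non-oligos hit, FN oligos
#' missed, TN non-oligos missed, H total hits), precision is
#' \eqn{P = TP/(TP+FP)}, recall \eqn{R = TP/(TP+FN)}, the F-score their
#' harmonic mean \eqn{F = 2PR/(P+R)} (0 when \eqn{P + R = 0}), and the
#' efficiency \eqn{E = TP/H}, the reciprocal of the average number of hits
#' spent per detected oligo. Undefined metrics (empty denominators) are
#' returned as \code{NA} with a message, so they can be distinguished from
#' a true zero.
#'
#' @param x a \linkS4class{ConfusionCounts}.
#' @return a single numeric value, or \code{NA} if undefined.
#' @examples
#' cc <- ConfusionCounts(TP = 3L, FP = 2L, TN = 4L, FN = 1L, H = 6L)
#' precision(cc)   # 0.6
#' recall(cc)      # 0.75
#' fScore(cc)      # 0.667
#' efficiency(cc)  # 0.5
#' @name seed-metrics
#' @export
setGeneric("precision", function(x) standardGeneric("precision"))

#' @rdname seed-metrics
#' @export
setGeneric("recall", function(x) standardGeneric("recall"))

#' @rdname seed-metrics
#' @export
setGeneric("fScore", function(x) standardGeneric("fScore"))

#' @rdname seed-metrics
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
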