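#' @import methods
NULL

#' Seed: a match pattern over \{1, *, @\}
#'
#' A seed is a string over \code{1} (required match), \code{*} (don't care)
#' and \code{@} (match or transition, i.e. A<->G or C<->T). The number of 1s
#' is the seed's \emph{weight} and the total number of characters its
#' \emph{span} (often called length). The BLAST seed is \code{11111111111};
#' the PatternHunter seed is \code{111*1**1*1**11*111}.
#'
#' @slot pattern single character string over \code{1}, \code{*}, \code{@};
#'   first and last characters are \code{1}.
#' @slot weight integer, number of \code{1}s.
#' @slot span integer, number of characters in \code{pattern}.
#' @name Seed-class
#' @aliases Seed-class
#' @exportClass Seed
setClass("Seed",
  representation(pattern = "character", weight = "integer", span = "integer"))

setValidity("Seed", function(object) {
  p <- object@pattern
  if (length(p) != 1L || is.na(p) || !nzchar(p))
    return("'pattern' must be a single non-empty string")
  ch <- strsplit(p, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% c("1", "*", "@"))
  if (length(bad))
    return(sprintf("illegal character '%s' at position %d", ch[bad[1L]], bad[1L]))
  if (!any(ch == "1"))
    return("pattern has zero match (1) positions")
  if (ch[1L] != "1" || ch[length(ch)] != "1")
    return("pattern must start and end with '1'")
  if (object@weight != sum(ch == "1"))
    return("stored weight does not match pattern")
  if (object@span != length(ch))
    return("stored span does not match pattern")
  TRUE
})

#' SeedSet: an ordered set of seeds (a k-seed)
#'
#' A multiple spaced seed containing k >= 1 member seeds; it hits wherever
#' any member hits.
#'
#' @slot seeds list of \linkS4class{Seed} objects, duplicates forbidden.
#' @name SeedSet-class
#' @aliases SeedSet-class
#' @exportClass SeedSet
setClass("SeedSet", representation(seeds = "list"))

setValidity("SeedSet", function(object) {
  if (length(object@seeds) < 1L)
    return("a seed set must contain at least one seed")
  if (!all(vapply(object@seeds, is, logical(1L), class2 = "Seed")))
    return("'seeds' must be a list of Seed objects")
  pats <- vapply(object@seeds, slot, character(1L), name = "pattern")
  if (anyDuplicated(pats))
    return(sprintf("duplicate seed pattern: %s", pats[duplicated(pats)][1L]))
  TRUE
})

#' AlignmentModel: the Bernoulli model of gap-free alignments
#'
#' An alignment of length \code{N} is a random sequence of per-position
#' outcomes: match with probability \code{p} (the \emph{similarity}) and
#' mismatch otherwise. When a seed set contains transition (\code{@})
#' positions the mismatch mass is split into transitions (probability
#' \code{q}) and transversions (probability \code{1 - p - q}); for sets
#' without \code{@}, \code{q} plays no role.
#'
#' @slot N integer, alignment region length.
#' @slot p numeric in [0, 1], per-position match probability.
#' @slot q numeric in [0, 1 - p], per-position transition probability.
#' @name AlignmentModel-class
#' @aliases AlignmentModel-class
#' @exportClass AlignmentModel
setClass("AlignmentModel",
  representation(N = "integer", p = "numeric", q = "numeric"))

setValidity("AlignmentModel", function(object) {
  if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
    return("'N' must be a single integer >= 1")
  if (length(object@p) != 1L || is.na(object@p) || object@p < 0 || object@p > 1)
    return("'p' must be a single probability in [0, 1]")
  if (length(object@q) != 1L || is.na(object@q) || object@q < 0 ||
      object@q > 1 - object@p + 1e-12)
    return("'q' must lie in [0, 1 - p]")
  TRUE
})

#' OligoGroup: one target sequence with labelled variants
#'
#' A group consists of a main (target) sequence and equal-length secondary
#' sequences, each labelled \code{"oligo"} (similar to the main, i.e. a
#' cross-hybridization risk) or \code{"non-oligo"}.
#'
#' @slot main character, the main DNA sequence.
#' @slot secondaries character vector of secondary DNA sequences, all the
#'   same length as \code{main}.
#' @slot labels character vector over \code{"oligo"}/\code{"non-oligo"},
#'   parallel to \code{secondaries}.
#' @slot info data.frame of per-secondary generation metrics (identity,
#'   stretch, dG); may have zero rows for externally loaded data.
#' @name OligoGroup-class
#' @aliases OligoGroup-class
#' @exportClass OligoGroup
setClass("OligoGroup",
  representation(main = "character", secondaries = "character",
                 labels = "character", info = "data.frame"),
  prototype(info = data.frame()))

setValidity("OligoGroup", function(object) {
  if (length(object@main) != 1L || !nzchar(object@main))
    return("'main' must be a single non-empty sequence")
  if (length(object@secondaries) < 1L)
    return("a group needs at least one secondary sequence")
  if (any(nchar(object@secondaries) != nchar(object@main)))
    return("all secondary sequences must have the same length as 'main'")
  if (length(object@labels) != length(object@secondaries))
    return("'labels' must be parallel to 'secondaries'")
  if (!all(object@labels %in% c("oligo", "non-oligo")))
    return("labels must be 'oligo' or 'non-oligo'")
  if (nrow(object@info) && nrow(object@info) != length(object@secondaries))
    return("'info' must have one row per secondary (or none)")
  TRUE
})

#' OligoDataset: a collection of oligo groups
#'
#' @slot groups list of \linkS4class{OligoGroup}.
#' @slot config list echoing the generator configuration (may be empty for
#'   externally loaded data).
#' @name OligoDataset-class
#' @aliases OligoDataset-class
#' @exportClass OligoDataset
setClass("OligoDataset",
  representation(groups = "list", config = "list"),
  prototype(config = list()))

setValidity("OligoDataset", function(object) {
  if (length(object@groups) < 1L)
    return("a dataset must contain at least one group")
  if (!all(vapply(object@groups, is, logical(1L), class2 = "OligoGroup")))
    return("'groups' must be a list of OligoGroup objects")
  TRUE
})

#' HitReport: per-secondary hit flags and counts for one group
#'
#' @slot hit logical vector, whether each secondary is hit at all.
#' @slot hitCount integer vector of per-secondary hit counts, where one hit
#'   is a (seed, secondary position) pair whose hash key also occurs in the
#'   main sequence.
#' @slot totalHits integer, sum of \code{hitCount}.
#' @name HitReport-class
#' @aliases HitReport-class
#' @exportClass HitReport
setClass("HitReport",
  representation(hit = "logical", hitCount = "integer", totalHits = "integer"))

setValidity("HitReport", function(object) {
  if (length(object@hit) != length(object@hitCount))
    return("'hit' and 'hitCount' must be parallel")
  if (any(object@hitCount < 0L))
    return("hit counts must be non-negative")
  if (!identical(object@hit, object@hitCount >= 1L))
    return("'hit' must equal 'hitCount >= 1'")
  if (object@totalHits != sum(object@hitCount))
    return("'totalHits' must equal sum(hitCount)")
  TRUE
})

#' SeedIndex: hash-key index of a main sequence
#'
#' For each seed, the set of hash keys occurring at any position of the main
#' sequence (keys are numeric encodings of the bases at 1 positions and the
#' purine/pyrimidine classes at @ positions).
#'
#' @slot keys list of numeric key vectors, one per seed.
#' @slot patterns character vector of the indexed seed patterns.
#' @slot seeds list of the indexed \linkS4class{Seed} objects.
#' @name SeedIndex-class
#' @aliases SeedIndex-class
#' @exportClass SeedIndex
setClass("SeedIndex",
  representation(keys = "list", patterns = "character", seeds = "list"))

setValidity("SeedIndex", function(object) {
  if (length(object@keys) != length(object@patterns))
    return("'keys' must have one element per seed pattern")
  if (length(object@seeds) != length(object@patterns))
    return("'seeds' must have one element per seed pattern")
  TRUE
})

#' ConfusionCounts: sufficient statistics of a seed's filtering performance
#'
#' @slot TP integer, oligos that are hit.
#' @slot FP integer, non-oligos that are hit.
#' @slot TN integer, non-oligos that are not hit.
#' @slot FN integer, oligos that are not hit.
#' @slot H integer, total number of hits over all secondary sequences.
#' @name ConfusionCounts-class
#' @aliases ConfusionCounts-class
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(TP = "integer", FP = "integer", TN = "integer",
                 FN = "integer", H = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN, object@H)
  if (any(is.na(v)) || any(v < 0L))
    return("all counts must be non-negative integers")
  if (object@H < object@TP + object@FP)
    return("H must be >= TP + FP (every hit sequence has at least one hit)")
  TRUE
})

#' GenConfig: synthetic dataset generator configuration
#'
#' Defaults follow the two study regimes: 50-mers are screened at 85\%
#' identity, 15 bp contiguous-match stretch and -30 kcal/mol duplex free
#' energy; 70-mers at 85\%, 20 bp and -40 kcal/mol.
#'
#' @slot oligoLength integer, sequence length (50 and 70 are the standard
#'   regimes; other values are allowed).
#' @slot nGroups integer, groups per dataset.
#' @slot nSecondaries integer, secondary sequences per group.
#' @slot nDatasets integer, number of replicate datasets.
#' @slot identityThreshold numeric in (0, 1).
#' @slot stretchThreshold integer (bp).
#' @slot dGThreshold numeric (kcal/mol, negative).
#' @slot identityRange numeric length 2, sampling range for variant identity.
#' @slot rngSeed integer master seed.
#' @name GenConfig-class
#' @aliases GenConfig-class
#' @exportClass GenConfig
setClass("GenConfig",
  representation(oligoLength = "integer", nGroups = "integer",
                 nSecondaries = "integer", nDatasets = "integer",
                 identityThreshold = "numeric", stretchThreshold = "integer",
                 dGThreshold = "numeric", identityRange = "numeric",
                 rngSeed = "integer"))

setValidity("GenConfig", function(object) {
  if (object@oligoLength < 2L) return("'oligoLength' must be >= 2")
  if (object@nGroups < 1L || object@nSecondaries < 1L || object@nDatasets < 1L)
    return("'nGroups', 'nSecondaries' and 'nDatasets' must be >= 1")
  if (object@identityThreshold <= 0 || object@identityThreshold >= 1)
    return("'identityThreshold' must lie in (0, 1)")
  if (object@stretchThreshold > object@oligoLength)
    return("'stretchThreshold' cannot exceed 'oligoLength'")
  if (object@dGThreshold >= 0) return("'dGThreshold' must be negative")
  r <- object@identityRange
  if (length(r) != 2L || r[1L] > r[2L] || r[1L] <= 0 || r[2L] > 1)
    return("'identityRange' must be (low, high) within (0, 1]")
  TRUE
})

#' ThermoParams: nearest-neighbour duplex free-energy parameters
#'
#' Watson-Crick nearest-neighbour stack free energies (dG37, kcal/mol) plus
#' duplex initiation terms, used by the dataset classifier's hybridization
#' criterion.
#'
#' @slot stackDG named numeric of length 16: dG37 for every dinucleotide
#'   step of the probe strand (complementary stacks share values).
#' @slot initAT numeric, initiation term per A/T duplex terminus.
#' @slot initGC numeric, initiation term per G/C duplex terminus.
#' @name ThermoParams-class
#' @aliases ThermoParams-class
#' @exportClass ThermoParams
setClass("ThermoParams",
  representation(stackDG = "numeric", initAT = "numeric", initGC = "numeric"))

setValidity("ThermoParams", function(object) {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  if (!all(dinucs %in% names(object@stackDG)))
    return("'stackDG' must name all 16 dinucleotide steps")
  if (any(object@stackDG >= 0))
    return("all stack free energies must be negative")
  TRUE
})

#' SeedCatalog: seed sets organised by (type, k, weight)
#'
#' @slot index data.frame with columns \code{seed_type}, \code{k},
#'   \code{weight} and \code{name}.
#' @slot sets named list of \linkS4class{SeedSet}, parallel to
#'   \code{index$name}.
#' @name SeedCatalog-class
#' @aliases SeedCatalog-class
#' @exportClass SeedCatalog
setClass("SeedCatalog",
  representation(index = "data.frame", sets = "list"))

setValidity("SeedCatalog", function(object) {
  if (nrow(object@index) != length(object@sets))
    return("'index' must have one row per seed set")
  need <- c("seed_type", "k", "weight", "name")
  if (!all(need %in% colnames(object@index)))
    return("'index' must have columns seed_type, k, weight, name")
  TRUE
})
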