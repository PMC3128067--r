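#' Parse a seed pattern
#'
#' Constructs a validated \linkS4class{Seed} from a pattern string over
#' \code{1} (match), \code{*} (don't care) and \code{@} (match or
#' transition). Surrounding whitespace is stripped; leading or trailing
#' \code{*}/\code{@} characters are normalized away with a warning, since
#' they only pad the span without constraining interior hits. Characters
#' outside the alphabet, empty patterns and patterns without any \code{1}
#' are rejected with an error naming the offending character and position.
#'
#' @param pattern single character string, e.g. \code{"111*1**1*1**11*111"}.
#' @return a \linkS4class{Seed}.
#' @examples
#' Seed("111*1**1*1**11*111")   # the PatternHunter seed: weight 11, span 18
#' Seed("1@1**11**1*11@1")      # the YASS transition seed: weight 9, span 15
#' @export
Seed <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop("'pattern' must be a single character string")
  p <- gsub("[[:space:]]+", "", pattern)
  if (!nzchar(p))
    stop("empty seed pattern")
  ch <- .patternChars(p)
  bad <- which(!ch %in% c("1", "*", "@"))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d in seed pattern",
                 ch[bad[1L]], bad[1L]))
  if (!any(ch == "1"))
    stop("seed pattern has zero match (1) positions")
  first <- match("1", ch)
  last <- length(ch) + 1L - match("1", rev(ch))
  if (first > 1L || last < length(ch)) {
    warning(sprintf(
      "stripping leading/trailing non-1 characters: '%s' normalized to '%s'",
      p, paste(ch[first:last], collapse = "")))
    ch <- ch[first:last]
    p <- paste(ch, collapse = "")
  }
  new("Seed", pattern = p, weight = sum(ch == "1"), span = length(ch))
}

#' Construct a seed set (k-seed)
#'
#' @param seeds a character vector of patterns, a list of
#'   \linkS4class{Seed} objects, or a single \linkS4class{Seed}.
#' @return a \linkS4class{SeedSet}.
#' @examples
#' SeedSet(c("111*111", "11*1*11"))
#' @export
SeedSet <- function(seeds) {
  if (is(seeds, "Seed"))
    seeds <- list(seeds)
  else if (is.character(seeds))
    seeds <- lapply(seeds, Seed)
  else if (is(seeds, "SeedSet"))
    return(seeds)
  else if (!is.list(seeds))
    stop("'seeds' must be patterns, Seed objects, or a list of them")
  new("SeedSet", seeds = seeds)
}

# Coerce Seed/SeedSet/character to SeedSet.
.asSeedSet <- function(x) {
  if (is(x, "SeedSet")) x else SeedSet(x)
}

#' Read a seed file
#'
#' A seed file is UTF-8 text with one pattern per line; blank lines are
#' ignored and \code{#} starts a comment. A file with k patterns defines a
#' k-seed. Duplicate patterns and unparsable lines are errors reporting the
#' offending line number.
#'
#' @param path path to the seed file.
#' @return a \linkS4class{SeedSet}.
#' @export
readSeedFile <- function(path) {
  if (!file.exists(path))
    stop(sprintf("seed file not found: %s", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  stripped <- sub("#.*$", "", raw)
  stripped <- gsub("[[:space:]]+", "", stripped)
  keep <- which(nzchar(stripped))
  if (!length(keep))
    stop(sprintf("no seed patterns in file: %s", path))
  seeds <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    seeds[[i]] <- tryCatch(Seed(stripped[keep[i]]), error = function(e)
      stop(sprintf("line %d of %s: %s", keep[i], path, conditionMessage(e)),
           call. = FALSE))
  }
  pats <- vapply(seeds, seedPattern, character(1L))
  if (anyDuplicated(pats)) {
    d <- pats[duplicated(pats)][1L]
    stop(sprintf("duplicate seed pattern '%s' at line %d of %s",
                 d, keep[which(pats == d)[2L]], path))
  }
  new("SeedSet", seeds = seeds)
}

#' Write a seed set to a seed file
#'
#' @param seeds a \linkS4class{SeedSet} (or anything \code{SeedSet()} accepts).
#' @param path output path.
#' @param header optional comment line(s) written with a \code{#} prefix.
#' @return \code{path}, invisibly.
#' @export
writeSeedFile <- function(seeds, path, header = NULL) {
  seeds <- .asSeedSet(seeds)
  lines <- seedPattern(seeds)
  if (!is.null(header))
    lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname Seed-class
#' @export
setMethod("seedPattern", "Seed", function(x) x@pattern)

#' @rdname Seed-class
#' @export
setMethod("seedWeight", "Seed", function(x) x@weight)

#' @rdname Seed-class
#' @export
setMethod("seedSpan", "Seed", function(x) x@span)

#' @rdname SeedSet-class
#' @export
setMethod("seedPattern", "SeedSet", function(x)
  vapply(x@seeds, seedPattern, character(1L)))

#' @rdname SeedSet-class
#' @export
setMethod("seedWeight", "SeedSet", function(x)
  vapply(x@seeds, seedWeight, integer(1L)))

#' @rdname SeedSet-class
#' @export
setMethod("seedSpan", "SeedSet", function(x)
  vapply(x@seeds, seedSpan, integer(1L)))

#' @rdname SeedSet-class
#' @export
setMethod("maxSpan", "SeedSet", function(x) max(seedSpan(x)))

#' @rdname SeedSet-class
#' @param i index.
#' @export
setMethod("[[", "SeedSet", function(x, i) x@seeds[[i]])

#' @rdname SeedSet-class
#' @export
setMethod("length", "SeedSet", function(x) length(x@seeds))

setMethod("show", "Seed", function(object) {
  cat(sprintf("Seed: %s (weight %d, span %d)\n",
              object@pattern, object@weight, object@span))
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet with %d seed(s), max span %d\n",
              length(object), maxSpan(object)))
  for (s in object@seeds)
    cat(sprintf("  %s (w=%d, span=%d)\n", s@pattern, s@weight, s@span))
})

# Does any member seed contain a transition (@) position?
.hasTransitions <- function(seeds) {
  any(grepl("@", seedPattern(.asSeedSet(seeds)), fixed = TRUE))
}

#' Hash key of a DNA window under a seed
#'
#' Projects a window of length \code{seedSpan(seed)} onto the seed's
#' constrained positions: at each \code{1} position the base itself, at each
#' \code{@} position the base's purine/pyrimidine class (\code{A,G -> R};
#' \code{C,T -> Y}); \code{*} positions contribute nothing. Two windows have
#' equal keys iff they agree at every \code{1} position and are equal or
#' transition-related at every \code{@} position.
#'
#' @param seed a \linkS4class{Seed} (or pattern string).
#' @param window DNA string of length \code{seedSpan(seed)}.
#' @return character vector of key symbols, one per constrained position.
#'   A window containing an ambiguity letter (e.g. N) at a constrained
#'   position raises an error of class \code{"unhashableWindow"}; callers
#'   scanning a sequence should skip such windows.
#' @examples
#' hashKey(Seed("11*1"), "ACGT")            # c("A", "C", "T")
#' identical(hashKey("1@1", "AAT"), hashKey("1@1", "AGT"))  # TRUE
#' @export
hashKey <- function(seed, window) {
  if (!is(seed, "Seed")) seed <- Seed(seed)
  if (!is.character(window) || length(window) != 1L)
    stop("'window' must be a single DNA string")
  if (nchar(window) != seed@span)
    stop(sprintf("window length %d does not equal seed span %d",
                 nchar(window), seed@span))
  v <- .encodeDNA(window)
  ch <- .patternChars(seed@pattern)
  out <- character(0L)
  for (i in seq_along(ch)) {
    if (ch[i] == "*") next
    if (is.na(v[i]))
      stop(errorCondition(
        sprintf("unhashable window: ambiguous base at position %d", i),
        class = c("unhashableWindow", "error", "condition")))
    out <- c(out,
             if (ch[i] == "1") .BASES[v[i] + 1L]
             else c("R", "Y")[v[i] %% 2L + 1L])
  }
  out
}

# Numeric hash keys for every window start of an integer-encoded sequence.
# Returns a numeric vector of length max(0, length(seqint) - span + 1);
# unhashable windows are NA. Keys pack base-4 digits (bases at 1 positions,
# purine/pyrimidine class at @ positions) in pattern order; with at most
# 26 constrained positions the key stays below 2^53 and is exact.
.seedKeys <- function(seed, seqint) {
  span <- seed@span
  n <- length(seqint) - span + 1L
  if (n < 1L) return(numeric(0L))
  ch <- .patternChars(seed@pattern)
  keep <- which(ch != "*")
  if (length(keep) > 26L)
    stop("seed has too many constrained positions for exact numeric hashing")
  key <- numeric(n)
  starts <- seq_len(n) - 1L
  for (i in keep) {
    b <- seqint[starts + i]
    if (ch[i] == "@") b <- b %% 2L
    key <- key * 4 + b
  }
  key
}
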