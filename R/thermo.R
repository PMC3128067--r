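#' Unified nearest-neighbour duplex free-energy parameters
#'
#' Loads the packaged unified Watson-Crick nearest-neighbour stack table
#' (dG37, kcal/mol; 10 unique stacks expanded to all 16 dinucleotide steps
#' via reverse-complement symmetry) and the per-terminus initiation terms.
#'
#' @param path path to a parameter CSV; defaults to the packaged table.
#' @return a \linkS4class{ThermoParams}.
#' @examples
#' tp <- unifiedThermoParams()
#' @export
unifiedThermoParams <- function(path = system.file("extdata",
                                                   "nn_unified_dG37.csv",
                                                   package = "oligoSeeds")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  st <- tab[tab$type == "stack", ]
  stack <- stats::setNames(st$dG37, st$stack)
  # reverse-complement symmetry: dG(xy) = dG(rc(y) rc(x))
  rc <- function(d) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ch <- strsplit(d, "")[[1L]]
    paste0(comp[ch[2L]], comp[ch[1L]])
  }
  full <- stack
  for (d in names(stack)) {
    r <- rc(d)
    if (!r %in% names(full))
      full[r] <- stack[[d]]
  }
  init <- tab[tab$type == "init", ]
  new("ThermoParams",
      stackDG = full[order(names(full))],
      initAT = init$dG37[init$stack == "AT_terminus"],
      initGC = init$dG37[init$stack == "GC_terminus"])
}

setMethod("show", "ThermoParams", function(object) {
  cat(sprintf(
    "ThermoParams: %d stacks (mean %.2f kcal/mol), init A/T %+.2f, G/C %+.2f\n",
    length(object@stackDG), mean(object@stackDG),
    object@initAT, object@initGC))
})

#' Positional duplex free energy of a probe against a target
#'
#' Computes dG37 of the gap-free duplex formed by \code{a} (probe) and the
#' complement of \code{b} (target), summing the nearest-neighbour stack
#' term for every dinucleotide step whose two positions are both matches
#' (\code{a[i] == b[i]} and \code{a[i+1] == b[i+1]}); steps touching a
#' mismatch contribute 0. Initiation terms for the two probe termini are
#' always added. More negative values mean a more stable duplex.
#'
#' @param a probe DNA sequence.
#' @param b target DNA sequence of the same length, compared positionally.
#' @param thermo a \linkS4class{ThermoParams}.
#' @return dG37 in kcal/mol.
#' @examples
#' tp <- unifiedThermoParams()
#' duplexDeltaG("ACGT", "ACGT", tp)
#' @export
duplexDeltaG <- function(a, b, thermo = unifiedThermoParams()) {
  if (nchar(a) != nchar(b))
    stop("'a' and 'b' must have equal lengths")
  ea <- .encodeDNA(a)
  eb <- .encodeDNA(b)
  if (anyNA(ea) || anyNA(eb))
    stop("sequences must contain only A, C, G, T")
  L <- length(ea)
  m <- ea == eb
  init <- sum(ifelse(ea[c(1L, L)] %in% c(1L, 2L), thermo@initGC,
                     thermo@initAT))
  if (L < 2L) return(init)
  stepOK <- m[-L] & m[-1L]
  if (!any(stepOK)) return(init)
  dinuc <- paste0(.BASES[ea[-L] + 1L], .BASES[ea[-1L] + 1L])
  sum(thermo@stackDG[dinuc[stepOK]]) + init
}
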