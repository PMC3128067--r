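#' Contiguous (BLAST-like) seed of a given weight
#'
#' @param weight number of consecutive 1s.
#' @return a \linkS4class{Seed}.
#' @examples
#' contiguousSeed(11)   # the BLAST default seed
#' @export
contiguousSeed <- function(weight) {
  stopifnot(weight >= 1)
  Seed(strrep("1", weight))
}

#' Load a seed catalogue from a directory of seed files
#'
#' Catalogue files are ordinary seed files named
#' \code{<type>_w<weight>_k<k>.txt} (e.g. \code{2seed_w12_k2.txt});
#' \code{type} is a free token such as \code{contiguous},
#' \code{transition}, \code{1seed}, \code{2seed}, ...
#'
#' @param dir directory containing the seed files.
#' @return a \linkS4class{SeedCatalog}.
#' @seealso \code{\link{packagedSeedCatalog}}
#' @export
loadSeedCatalog <- function(dir) {
  files <- list.files(dir, pattern = "^[A-Za-z0-9]+_w[0-9]+_k[0-9]+\\.txt$",
                      full.names = TRUE)
  if (!length(files))
    stop(sprintf("no catalogue seed files (<type>_w<weight>_k<k>.txt) in %s",
                 dir))
  base <- sub("\\.txt$", "", basename(files))
  parts <- regmatches(base, regexec("^([A-Za-z0-9]+)_w([0-9]+)_k([0-9]+)$",
                                    base))
  idx <- data.frame(
    seed_type = vapply(parts, `[`, character(1L), 2L),
    weight = as.integer(vapply(parts, `[`, character(1L), 3L)),
    k = as.integer(vapply(parts, `[`, character(1L), 4L)),
    name = base, stringsAsFactors = FALSE)
  sets <- lapply(files, readSeedFile)
  names(sets) <- base
  for (i in seq_along(sets)) {
    if (length(sets[[i]]) != idx$k[i])
      stop(sprintf("%s declares k=%d but contains %d seeds",
                   basename(files[i]), idx$k[i], length(sets[[i]])))
    if (!all(seedWeight(sets[[i]]) == idx$weight[i]))
      stop(sprintf("%s declares weight %d but member weights differ",
                   basename(files[i]), idx$weight[i]))
  }
  new("SeedCatalog", index = idx[, c("seed_type", "k", "weight", "name")],
      sets = sets)
}

setMethod("show", "SeedCatalog", function(object) {
  cat(sprintf("SeedCatalog: %d seed sets\n", length(object@sets)))
  tab <- table(object@index$seed_type)
  for (ty in names(tab))
    cat(sprintf("  %s: %d weights\n", ty, tab[[ty]]))
})

#' Packaged seed catalogues for the two study regimes
#'
#' The package ships seed catalogues designed for the 50-mer regime
#' (alignment model N = 50, p = 0.85) and the 70-mer regime (N = 70,
#' p = 0.85): contiguous, transition-constrained and single spaced seeds,
#' plus multiple spaced seed sets with k = 2, 4, 8 and 16, across a range
#' of weights. The multi-seed and spaced sets were produced by
#' \code{\link{designSeedSet}}; the files are plain seed files and can be
#' regenerated with \code{scripts/build_catalogues.R}.
#'
#' @param regime \code{"50mer"} or \code{"70mer"}.
#' @return a \linkS4class{SeedCatalog}.
#' @export
packagedSeedCatalog <- function(regime = c("50mer", "70mer")) {
  regime <- match.arg(regime)
  dir <- system.file("extdata", "seeds", regime, package = "oligoSeeds")
  if (!nzchar(dir))
    stop("packaged seed catalogues not found; reinstall the package")
  loadSeedCatalog(dir)
}
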