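#' Generator configuration
#'
#' Builds a \linkS4class{GenConfig} with regime-appropriate defaults: for
#' 50-mers the screening thresholds are 85\% identity, 15 bp
#' contiguous-match stretch and -30 kcal/mol; for 70-mers 85\%, 20 bp and
#' -40 kcal/mol. Other lengths require explicit thresholds.
#'
#' @param oligoLength sequence length in bp (50 or 70 select default
#'   thresholds).
#' @param nGroups groups per dataset.
#' @param nSecondaries secondary sequences per group.
#' @param nDatasets number of replicate datasets.
#' @param identityThreshold identity fraction above which a variant is a
#'   cross-hybridization risk.
#' @param stretchThreshold contiguous-match stretch threshold in bp.
#' @param dGThreshold duplex free-energy threshold in kcal/mol.
#' @param identityRange range from which per-variant target identity is
#'   drawn uniformly; the default straddles the effective oligo/non-oligo
#'   boundary so both labels occur.
#' @param rngSeed master seed; all randomness derives from it.
#' @return a \linkS4class{GenConfig}.
#' @export
genConfig <- function(oligoLength = 50, nGroups = 50, nSecondaries = 20,
                      nDatasets = 3, identityThreshold = 0.85,
                      stretchThreshold = NULL, dGThreshold = NULL,
                      identityRange = c(0.60, 0.95), rngSeed = 1) {
  if (is.null(stretchThreshold))
    stretchThreshold <- switch(as.character(oligoLength),
                               "50" = 15L, "70" = 20L,
                               stop("supply 'stretchThreshold' for lengths other than 50/70"))
  if (is.null(dGThreshold))
    dGThreshold <- switch(as.character(oligoLength),
                          "50" = -30, "70" = -40,
                          stop("supply 'dGThreshold' for lengths other than 50/70"))
  new("GenConfig", oligoLength = as.integer(oligoLength),
      nGroups = as.integer(nGroups), nSecondaries = as.integer(nSecondaries),
      nDatasets = as.integer(nDatasets),
      identityThreshold = as.numeric(identityThreshold),
      stretchThreshold = as.integer(stretchThreshold),
      dGThreshold = as.numeric(dGThreshold),
      identityRange = as.numeric(identityRange),
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "GenConfig", function(object) {
  cat(sprintf(
    "GenConfig: %d-mers, %d dataset(s) x %d groups x %d secondaries\n",
    object@oligoLength, object@nDatasets, object@nGroups,
    object@nSecondaries))
  cat(sprintf(
    "  thresholds: identity >= %.2f | stretch >= %d bp | dG <= %g kcal/mol\n",
    object@identityThreshold, object@stretchThreshold, object@dGThreshold))
  cat(sprintf("  identity range (%.2f, %.2f), master seed %d\n",
              object@identityRange[1L], object@identityRange[2L],
              object@rngSeed))
})

.configAsList <- function(cfg) {
  list(oligoLength = cfg@oligoLength, nGroups = cfg@nGroups,
       nSecondaries = cfg@nSecondaries, nDatasets = cfg@nDatasets,
       identityThreshold = cfg@identityThreshold,
       stretchThreshold = cfg@stretchThreshold,
       dGThreshold = cfg@dGThreshold,
       identityRange = cfg@identityRange, rngSeed = cfg@rngSeed)
}

#' Random DNA sequence
#'
#' I.i.d. uniform sequence over A, C, G, T, drawn from R's current RNG
#' stream (seed it with \code{set.seed} for reproducibility).
#'
#' @param length sequence length in bp.
#' @return a DNA string.
#' @export
randomDNA <- function(length) {
  stopifnot(length >= 1)
  paste(sample(.BASES, length, replace = TRUE), collapse = "")
}

#' Substitution-only variant of a sequence at a target identity
#'
#' Substitutes exactly \code{round((1 - targetIdentity) * L)} positions
#' (round-half-even, R's default rounding), sampled without replacement;
#' each substituted base is drawn uniformly from the three alternatives.
#' No indels are introduced, so positional identity is exact by
#' construction.
#'
#' @param main the sequence to mutate.
#' @param targetIdentity fraction in (0, 1].
#' @return a DNA string of the same length.
#' @export
mutateSequence <- function(main, targetIdentity) {
  stopifnot(targetIdentity > 0, targetIdentity <= 1)
  enc <- .encodeDNA(main)
  L <- length(enc)
  nSub <- round((1 - targetIdentity) * L)
  if (nSub == 0) return(toupper(main))
  pos <- sample.int(L, nSub)
  shift <- sample.int(3L, nSub, replace = TRUE)
  enc[pos] <- (enc[pos] + shift) %% 4L
  .decodeDNA(enc)
}

#' Positional identity of two equal-length sequences
#'
#' @param a,b DNA strings of equal length.
#' @return fraction of positions with equal bases.
#' @export
sequenceIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("'a' and 'b' must have equal lengths")
  mean(.encodeDNA(a) == .encodeDNA(b))
}

#' Longest stretch of contiguous matches
#'
#' @param a,b DNA strings of equal length.
#' @return length (bp) of the longest run of consecutive equal positions
#'   (0 if none).
#' @export
longestMatchStretch <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("'a' and 'b' must have equal lengths")
  m <- .encodeDNA(a) == .encodeDNA(b)
  r <- rle(m)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Classify a secondary sequence as oligo or non-oligo
#'
#' A secondary is labelled \code{"oligo"} (a cross-hybridization risk for
#' its group's main sequence) if \emph{any} of the three screening criteria
#' fires: identity at or above the identity threshold, a contiguous match
#' stretch at or above the stretch threshold, or duplex free energy at or
#' below the dG threshold. Otherwise it is a \code{"non-oligo"}.
#'
#' @param main,secondary equal-length DNA sequences.
#' @param cfg a \linkS4class{GenConfig} holding the thresholds.
#' @param thermo a \linkS4class{ThermoParams}.
#' @return \code{"oligo"} or \code{"non-oligo"}.
#' @export
classifySecondary <- function(main, secondary, cfg,
                              thermo = unifiedThermoParams()) {
  m <- .secondaryMetrics(main, secondary, cfg, thermo)
  m$label
}

.secondaryMetrics <- function(main, secondary, cfg, thermo) {
  id <- sequenceIdentity(main, secondary)
  st <- longestMatchStretch(main, secondary)
  dg <- duplexDeltaG(secondary, main, thermo)
  oligo <- id >= cfg@identityThreshold || st >= cfg@stretchThreshold ||
    dg <= cfg@dGThreshold
  list(identity = id, stretch = st, dG = dg,
       label = if (oligo) "oligo" else "non-oligo")
}

#' Generate a synthetic oligo dataset
#'
#' Emulates an OligoGenerator-style build: each group gets an i.i.d.
#' uniform main sequence; each secondary is a substitution-only variant at
#' a target identity drawn uniformly from \code{identityRange}, then
#' labelled by \code{\link{classifySecondary}}. Group generation is
#' rejection-balanced: the secondaries are redrawn (up to \code{maxRetries}
#' times) until the group contains at least one oligo and one non-oligo.
#' Each group uses its own RNG stream derived from
#' \code{(rngSeed, datasetIndex, group)}, so datasets and groups are
#' individually reproducible.
#'
#' @param cfg a \linkS4class{GenConfig}.
#' @param datasetIndex which replicate dataset to generate (1-based;
#'   affects the derived RNG streams).
#' @param thermo a \linkS4class{ThermoParams}.
#' @param maxRetries retry cap for the oligo/non-oligo balance per group.
#' @return an \linkS4class{OligoDataset}.
#' @examples
#' ds <- generateDataset(genConfig(nGroups = 2, nSecondaries = 5))
#' @export
generateDataset <- function(cfg, datasetIndex = 1,
                            thermo = unifiedThermoParams(),
                            maxRetries = 200) {
  stopifnot(is(cfg, "GenConfig"))
  groups <- vector("list", cfg@nGroups)
  for (g in seq_len(cfg@nGroups)) {
    set.seed(.deriveSeed(cfg@rngSeed, datasetIndex, g))
    main <- randomDNA(cfg@oligoLength)
    for (attempt in seq_len(maxRetries)) {
      ids <- stats::runif(cfg@nSecondaries, cfg@identityRange[1L],
                          cfg@identityRange[2L])
      secs <- vapply(ids, function(t) mutateSequence(main, t), character(1L))
      met <- lapply(secs, function(s)
        .secondaryMetrics(main, s, cfg, thermo))
      labels <- vapply(met, `[[`, character(1L), "label")
      if (any(labels == "oligo") && any(labels == "non-oligo")) break
      if (attempt == maxRetries)
        stop(paste("could not balance oligo/non-oligo labels in a group;",
                   "widen 'identityRange'"))
    }
    info <- data.frame(
      identity = vapply(met, `[[`, numeric(1L), "identity"),
      stretch = vapply(met, `[[`, numeric(1L), "stretch"),
      dG = vapply(met, `[[`, numeric(1L), "dG"))
    groups[[g]] <- OligoGroup(main, secs, labels, info)
  }
  OligoDataset(groups, config = c(.configAsList(cfg),
                                  list(datasetIndex = datasetIndex)))
}

#' Generate all replicate datasets of a configuration
#'
#' @param cfg a \linkS4class{GenConfig}.
#' @param thermo a \linkS4class{ThermoParams}.
#' @return named list of \linkS4class{OligoDataset} (\code{"ds1"}, ...).
#' @export
generateDatasets <- function(cfg, thermo = unifiedThermoParams()) {
  out <- lapply(seq_len(cfg@nDatasets), function(i)
    generateDataset(cfg, datasetIndex = i, thermo = thermo))
  names(out) <- paste0("ds", seq_len(cfg@nDatasets))
  out
}

#' Write an oligo dataset to FASTA + manifest
#'
#' Writes \code{sequences.fasta} (ids encode group, role and index),
#' \code{manifest.tsv} (id, group, role, label, identity, stretch, dG) and
#' \code{config.json} (generator configuration echo) into \code{dir}.
#'
#' @param dataset an \linkS4class{OligoDataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeOligoDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "OligoDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- character(0L)
  rows <- list()
  for (g in seq_along(dataset@groups)) {
    grp <- dataset@groups[[g]]
    idm <- sprintf("g%03d_main", g)
    seqs[idm] <- mainSequence(grp)
    rows[[length(rows) + 1L]] <- data.frame(
      id = idm, group = g, role = "main", label = NA_character_,
      identity = NA_real_, stretch = NA_real_, dG = NA_real_)
    info <- grp@info
    for (j in seq_along(grp@secondaries)) {
      ids <- sprintf("g%03d_sec%03d", g, j)
      seqs[ids] <- grp@secondaries[j]
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids, group = g, role = "secondary", label = grp@labels[j],
        identity = if (nrow(info)) info$identity[j] else NA_real_,
        stretch = if (nrow(info)) info$stretch[j] else NA_real_,
        dG = if (nrow(info)) info$dG[j] else NA_real_)
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              file.path(dir, "sequences.fasta"))
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an oligo dataset from FASTA + manifest
#'
#' @param dir directory written by \code{\link{writeOligoDataset}} (or an
#'   externally prepared one with the same layout).
#' @return an \linkS4class{OligoDataset}.
#' @export
readOligoDataset <- function(dir) {
  fa <- file.path(dir, "sequences.fasta")
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(fa) || !file.exists(mf))
    stop(sprintf("expected sequences.fasta and manifest.tsv under %s", dir))
  seqs <- Biostrings::readDNAStringSet(fa)
  seqv <- stats::setNames(as.character(seqs), names(seqs))
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  cfgPath <- file.path(dir, "config.json")
  config <- if (file.exists(cfgPath))
    jsonlite::read_json(cfgPath, simplifyVector = TRUE) else list()
  groups <- lapply(sort(unique(manifest$group)), function(g) {
    sub <- manifest[manifest$group == g, ]
    mainId <- sub$id[sub$role == "main"]
    secs <- sub[sub$role == "secondary", ]
    info <- data.frame(identity = secs$identity, stretch = secs$stretch,
                       dG = secs$dG)
    OligoGroup(seqv[[mainId]], unname(seqv[secs$id]), secs$label, info)
  })
  OligoDataset(groups, config = config)
}
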