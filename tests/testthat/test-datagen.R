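test_that("mutation hits the target identity exactly (round-half-even)", {
  set.seed(3)
  main <- randomDNA(50)
  expect_identical(mutateSequence(main, 1), main)
  # round((1 - 0.85) * 50) = round(7.5) = 8 substitutions (banker's rounding)
  v <- mutateSequence(main, 0.85)
  expect_equal(sum(strsplit(main, "")[[1]] != strsplit(v, "")[[1]]), 8L)
  for (t in c(0.95, 0.9, 0.8, 0.7, 0.62)) {
    for (L in c(50, 70)) {
      m2 <- randomDNA(L)
      v2 <- mutateSequence(m2, t)
      expect_equal(sequenceIdentity(m2, v2), 1 - round((1 - t) * L) / L,
                   info = paste(t, L))
    }
  }
})

test_that("identity and longest stretch match direct scans", {
  expect_equal(sequenceIdentity("AAAA", "AAAA"), 1)
  expect_equal(sequenceIdentity("AAAA", "AAAT"), 0.75)
  expect_error(sequenceIdentity("AAA", "AAAA"), "equal lengths")
  expect_equal(longestMatchStretch("AATAA", "AAAAA"), 2L)
  expect_equal(longestMatchStretch("AAAAA", "AAAAA"), 5L)
  expect_equal(longestMatchStretch("ACGT", "TGCA"), 0L)
  expect_error(longestMatchStretch("AC", "ACG"), "equal lengths")
  set.seed(8)
  for (rep in 1:20) {
    a <- randomDNAString(30)
    b <- mutateSequence(a, runif(1, 0.5, 1))
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    expect_equal(sequenceIdentity(a, b), mean(av == bv))
    best <- 0L; run <- 0L
    for (i in seq_along(av)) {
      run <- if (av[i] == bv[i]) run + 1L else 0L
      best <- max(best, run)
    }
    expect_equal(longestMatchStretch(a, b), best)
  }
})

test_that("random sequences are uniform over the four bases", {
  set.seed(19)
  x <- randomDNA(1e5)
  counts <- table(strsplit(x, "")[[1]])
  expect_setequal(names(counts), c("A", "C", "G", "T"))
  cs <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(cs$p.value, 1e-4)
  set.seed(99); a <- randomDNA(40)
  set.seed(99); b <- randomDNA(40)
  expect_identical(a, b)
})

test_that("duplex free energy sums matched stacks plus initiation", {
  tp <- unifiedThermoParams()
  # independent hand-sum from the packaged table
  tab <- read.csv(system.file("extdata", "nn_unified_dG37.csv",
                              package = "oligoSeeds"), comment.char = "#")
  stacks <- setNames(tab$dG37[tab$type == "stack"],
                     tab$stack[tab$type == "stack"])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lookup <- function(d) {
    if (d %in% names(stacks)) return(stacks[[d]])
    ch <- strsplit(d, "")[[1]]
    stacks[[paste0(comp[ch[2]], comp[ch[1]])]]
  }
  initOf <- function(b) if (b %in% c("G", "C")) 0.98 else 1.03

  set.seed(4)
  for (rep in 1:10) {
    a <- randomDNAString(sample(10:30, 1))
    ch <- strsplit(a, "")[[1]]
    L <- length(ch)
    want <- sum(vapply(1:(L - 1), function(i)
      lookup(paste0(ch[i], ch[i + 1])), numeric(1))) +
      initOf(ch[1]) + initOf(ch[L])
    expect_equal(duplexDeltaG(a, a, tp), want, tolerance = 1e-10)
  }

  # no two consecutive matches -> initiation only
  a <- "ACACACAC"
  b <- "ATATATAT"  # matches only at odd positions
  expect_equal(duplexDeltaG(a, b, tp),
               initOf("A") + initOf("C"), tolerance = 1e-10)

  expect_error(duplexDeltaG("ACG", "AC", tp), "equal lengths")
  expect_error(duplexDeltaG("ANG", "ACG", tp), "A, C, G, T")
})

test_that("introducing mismatches never stabilizes the duplex", {
  tp <- unifiedThermoParams()
  set.seed(6)
  for (rep in 1:10) {
    a <- randomDNAString(12)
    b <- a
    prev <- duplexDeltaG(a, b, tp)
    for (pos in sample(12)) {
      bv <- strsplit(b, "")[[1]]
      alt <- setdiff(c("A", "C", "G", "T"), bv[pos])
      bv[pos] <- sample(alt, 1)
      b <- paste(bv, collapse = "")
      cur <- duplexDeltaG(a, b, tp)
      expect_gte(cur, prev - 1e-10)
      prev <- cur
    }
  }
})

test_that("classification applies the OR of the three screening criteria", {
  cfg <- genConfig(oligoLength = 50)
  expect_equal(cfg@identityThreshold, 0.85)
  expect_equal(cfg@stretchThreshold, 15L)
  expect_equal(cfg@dGThreshold, -30)
  cfg70 <- genConfig(oligoLength = 70)
  expect_equal(cfg70@stretchThreshold, 20L)
  expect_equal(cfg70@dGThreshold, -40)
  expect_error(genConfig(oligoLength = 60), "stretchThreshold")

  tp <- unifiedThermoParams()
  set.seed(12)
  main <- randomDNA(50)
  expect_equal(classifySecondary(main, main, cfg, tp), "oligo")

  # substitute every third position: identity 0.66, stretch 2, weak duplex
  mv <- strsplit(main, "")[[1]]
  for (pos in seq(1, 50, by = 3))
    mv[pos] <- setdiff(c("A", "C", "G", "T"), mv[pos])[1]
  weak <- paste(mv, collapse = "")
  expect_lt(sequenceIdentity(main, weak), 0.85)
  expect_lt(longestMatchStretch(main, weak), 15)
  expect_gt(duplexDeltaG(weak, main, tp), -30)
  expect_equal(classifySecondary(main, weak, cfg, tp), "non-oligo")

  # a long perfect stretch alone is enough, even at low identity
  sv <- strsplit(mutateSequence(main, 0.5), "")[[1]]
  sv[1:15] <- strsplit(main, "")[[1]][1:15]
  stretchy <- paste(sv, collapse = "")
  if (sequenceIdentity(main, stretchy) < 0.85 &&
      duplexDeltaG(stretchy, main, tp) > -30)
    expect_equal(classifySecondary(main, stretchy, cfg, tp), "oligo")
})

test_that("labels are monotone along a chain of accumulating substitutions", {
  cfg <- genConfig(oligoLength = 50)
  tp <- unifiedThermoParams()
  set.seed(44)
  main <- randomDNA(50)
  mv <- strsplit(main, "")[[1]]
  b <- main
  labels <- character(0)
  for (step in 1:30) {
    bv <- strsplit(b, "")[[1]]
    pos <- sample(50, 1)
    # never revert toward the main sequence, so divergence only accumulates
    bv[pos] <- sample(setdiff(c("A", "C", "G", "T"), c(bv[pos], mv[pos])), 1)
    b <- paste(bv, collapse = "")
    labels <- c(labels, classifySecondary(main, b, cfg, tp))
  }
  # once non-oligo, never back to oligo as mismatches accumulate on a chain
  firstNon <- match("non-oligo", labels)
  if (!is.na(firstNon))
    expect_true(all(labels[firstNon:length(labels)] == "non-oligo"))
})

test_that("generated datasets are balanced, labelled consistently and reproducible", {
  cfg <- genConfig(oligoLength = 50, nGroups = 3, nSecondaries = 10,
                   rngSeed = 7)
  tp <- unifiedThermoParams()
  ds <- generateDataset(cfg, thermo = tp)
  expect_s4_class(ds, "OligoDataset")
  expect_equal(length(ds), 3L)
  for (grp in oligoGroups(ds)) {
    expect_equal(length(secondarySequences(grp)), 10L)
    labs <- secondaryLabels(grp)
    expect_true(any(labs == "oligo") && any(labs == "non-oligo"))
    # emitted labels re-verified by the classifier
    relabel <- vapply(secondarySequences(grp), function(s)
      classifySecondary(mainSequence(grp), s, cfg, tp), character(1),
      USE.NAMES = FALSE)
    expect_identical(labs, relabel)
  }
  ds2 <- generateDataset(cfg, thermo = tp)
  expect_identical(lapply(oligoGroups(ds), mainSequence),
                   lapply(oligoGroups(ds2), mainSequence))
  expect_identical(lapply(oligoGroups(ds), secondarySequences),
                   lapply(oligoGroups(ds2), secondarySequences))
  # different dataset index -> different stream
  ds3 <- generateDataset(cfg, datasetIndex = 2, thermo = tp)
  expect_false(identical(mainSequence(oligoGroups(ds)[[1]]),
                         mainSequence(oligoGroups(ds3)[[1]])))
  # both labels occur overall with the default identity range
  labs <- unlist(lapply(oligoGroups(ds), secondaryLabels))
  expect_gt(mean(labs == "oligo"), 0.05)
  expect_gt(mean(labs == "non-oligo"), 0.05)
})

test_that("datasets round-trip through FASTA + manifest", {
  cfg <- genConfig(oligoLength = 50, nGroups = 2, nSecondaries = 6,
                   rngSeed = 21)
  tp <- unifiedThermoParams()
  ds <- generateDataset(cfg, thermo = tp)
  dir <- withr::local_tempdir()
  writeOligoDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "sequences.fasta")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- readOligoDataset(dir)
  expect_equal(length(back), length(ds))
  for (g in seq_along(oligoGroups(ds))) {
    a <- oligoGroups(ds)[[g]]; b <- oligoGroups(back)[[g]]
    expect_identical(mainSequence(a), mainSequence(b))
    expect_identical(unname(secondarySequences(a)),
                     unname(secondarySequences(b)))
    expect_identical(secondaryLabels(a), secondaryLabels(b))
    # recomputing labels from the sequences agrees with the manifest
    relabel <- vapply(secondarySequences(b), function(s)
      classifySecondary(mainSequence(b), s, cfg, tp), character(1),
      USE.NAMES = FALSE)
    expect_identical(secondaryLabels(b), relabel)
  }
})
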