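# Independent brute-force oracles used to validate the DP and the hash
# index. These deliberately share no code with the package internals:
# sensitivity enumerates whole alignment regions, hit counting tries every
# (seed, main position, secondary position) alignment directly.

# Exact sensitivity by enumerating all 2^N binary regions. Region bit j-1
# is position j; a placement at i requires 1-bits at i + (1-offsets).
bruteSensitivityBinary <- function(patterns, N, p) {
  v <- 0:(2^N - 1L)
  hit <- rep(FALSE, length(v))
  for (pat in patterns) {
    ch <- strsplit(pat, "", fixed = TRUE)[[1L]]
    L <- length(ch)
    if (L > N) next
    ones <- which(ch == "1") - 1L
    for (i in 0:(N - L)) {
      m <- as.integer(sum(2^(i + ones)))
      hit <- hit | (bitwAnd(v, m) == m)
    }
  }
  # popcount, one bit layer at a time
  pc <- integer(length(v))
  for (b in 0:(N - 1L))
    pc <- pc + bitwAnd(bitwShiftR(v, b), 1L)
  sum((p^pc * (1 - p)^(N - pc))[hit])
}

# Exact sensitivity under the ternary match/transition/transversion model,
# enumerating all 3^N regions (tiny N only).
bruteSensitivityTernary <- function(patterns, N, p, q) {
  sets <- lapply(patterns, function(pp) strsplit(pp, "", fixed = TRUE)[[1L]])
  total <- 0
  for (v in 0:(3^N - 1)) {
    d <- (v %/% 3^(0:(N - 1L))) %% 3  # 0 transversion, 1 transition, 2 match
    hit <- FALSE
    for (ch in sets) {
      L <- length(ch)
      if (L > N) next
      for (i in 1:(N - L + 1L)) {
        w <- d[i:(i + L - 1L)]
        if (all(w[ch == "1"] == 2) && all(w[ch == "@"] >= 1)) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (hit) total <- total + prod(c(1 - p - q, q, p)[d + 1])
  }
  total
}

# Does the seed match secondary window at j against main window at i?
.bruteWindowMatch <- function(ch, mainCh, secCh, i, j) {
  for (t in seq_along(ch)) {
    a <- mainCh[i + t - 1L]
    b <- secCh[j + t - 1L]
    if (ch[t] == "1" && a != b) return(FALSE)
    if (ch[t] == "@") {
      pur <- c(A = "R", G = "R", C = "Y", T = "Y")
      if (pur[[a]] != pur[[b]]) return(FALSE)
    }
  }
  TRUE
}

# Hit count by trying all (seed, i, j) alignments, collapsed over i.
bruteHitCount <- function(patterns, main, secondary) {
  mainCh <- strsplit(main, "", fixed = TRUE)[[1L]]
  secCh <- strsplit(secondary, "", fixed = TRUE)[[1L]]
  count <- 0L
  for (pat in patterns) {
    ch <- strsplit(pat, "", fixed = TRUE)[[1L]]
    L <- length(ch)
    if (L > length(mainCh)) next
    for (j in 1:(length(secCh) - L + 1L)) {
      found <- FALSE
      for (i in 1:(length(mainCh) - L + 1L)) {
        if (.bruteWindowMatch(ch, mainCh, secCh, i, j)) {
          found <- TRUE
          break
        }
      }
      if (found) count <- count + 1L
    }
  }
  count
}

# Overlap complexity by direct double loop over ordered pairs and shifts.
bruteOverlapComplexity <- function(patterns) {
  ones <- lapply(patterns, function(pp)
    which(strsplit(pp, "", fixed = TRUE)[[1L]] == "1"))
  spans <- nchar(patterns)
  total <- 0
  for (a in seq_along(patterns)) {
    for (b in seq_along(patterns)) {
      for (s in -(spans[b] - 1L):(spans[a] - 1L)) {
        co <- sum((ones[[a]]) %in% (ones[[b]] + s))
        total <- total + 2^co
      }
    }
  }
  total
}

# Safe scalar sample: draw one weight in [2, span] (sample() misbehaves on
# length-1 vectors).
randomWeight <- function(span) 1L + sample.int(span - 1L, 1L)

# Random seed pattern (first/last 1) for property tests.
randomSeedPattern <- function(weight, span) {
  stopifnot(span >= weight, weight >= 2)
  ch <- rep("*", span)
  ch[c(1L, span)] <- "1"
  if (weight > 2L)
    ch[sample(2:(span - 1L), weight - 2L)] <- "1"
  paste(ch, collapse = "")
}

randomDNAString <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# Shared small evaluation fixture: a reproducible generated dataset and a
# tiny catalogue, reused across evaluate/cli tests.
tinyDataset <- function(seed = 42, nGroups = 4, nSecondaries = 8,
                        oligoLength = 50) {
  generateDataset(genConfig(oligoLength = oligoLength, nGroups = nGroups,
                            nSecondaries = nSecondaries, rngSeed = seed))
}

tinyCatalog <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSeedFile(contiguousSeed(8), file.path(dir, "contiguous_w8_k1.txt"))
  writeSeedFile(contiguousSeed(10), file.path(dir, "contiguous_w10_k1.txt"))
  writeSeedFile(SeedSet("111*1*1111"), file.path(dir, "1seed_w8_k1.txt"))
  writeSeedFile(SeedSet(c("11*11*111", "1*111*111")),
                file.path(dir, "2seed_w7_k2.txt"))
  loadSeedCatalog(dir)
}
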