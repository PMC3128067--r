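# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integers A=0, C=1, G=2, T=3 (case-insensitive,
# U treated as T). Any other IUPAC letter becomes NA, which makes windows
# covering it unhashable rather than raising.
.encodeDNA <- function(x) {
  stopifnot(length(x) == 1L)
  ch <- strsplit(chartr("u", "U", toupper(x)), "", fixed = TRUE)[[1L]]
  ch[ch == "U"] <- "T"
  match(ch, .BASES) - 1L
}

.decodeDNA <- function(v) paste(.BASES[v + 1L], collapse = "")

# Split a seed pattern into its character vector.
.patternChars <- function(pattern) strsplit(pattern, "", fixed = TRUE)[[1L]]

# Derive a reproducible child RNG seed (< 2^31) from a master seed and a
# sequence of stream indices, via a multiply-add mix in exact double
# arithmetic (69069 * 2^31 < 2^53, so no precision is lost).
.deriveSeed <- function(master, ...) {
  idx <- c(...)
  x <- as.numeric(master) %% 2147483647
  for (i in idx)
    x <- (x * 69069 + as.numeric(i) + 1) %% 2147483647
  as.integer(x)
}

.isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && abs(x - round(x)) < 1e-8
}
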