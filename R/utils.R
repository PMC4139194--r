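# Internal helpers: sequence canonicalisation, seeded evaluation, hashing.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` leaves the global stream in use.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uppercase RNA with T -> U; validates alphabet (N optionally allowed).
canon_rna <- function(x, allow_n = FALSE, what = "sequence") {
  x <- chartr("t", "T", toupper(x))
  x <- chartr("T", "U", x)
  ok_chars <- if (allow_n) "ACGUN" else "ACGU"
  bad <- grepl(sprintf("[^%s]", ok_chars), x)
  if (any(bad))
    stop(sprintf("%s contains non-nucleotide characters: %s",
                 what, paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  if (any(!nzchar(x))) stop(sprintf("empty %s", what), call. = FALSE)
  x
}

# Uppercase DNA with U -> T; N allowed (never matches a motif).
canon_dna <- function(x, what = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(sprintf("%s contains non-nucleotide characters", what), call. = FALSE)
  x
}

# Reverse complement of RNA (character vector in/out).
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Random RNA sequences, one per element of `len`.
random_rna <- function(len, alphabet = c("A", "C", "G", "U")) {
  vapply(len, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1L))
}

# 32-bit FNV-1a over a raw vector, as 8 hex digits. Used to stamp output
# files with a config fingerprint; not cryptographic. State is kept as a
# double; the modular multiply is split 16/16 so intermediates stay exact.
fnv1a32 <- function(raw_bytes) {
  h <- 2166136261
  for (b in as.integer(raw_bytes)) {
    lo16 <- h %% 65536
    h <- h - lo16 + bitwXor(as.integer(lo16), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  fnv1a32(charToRaw(txt))
}
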