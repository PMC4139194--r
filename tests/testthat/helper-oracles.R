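# Independent brute-force oracles and small fixture builders shared across
# test files. The oracles deliberately use a different construction from
# the package code (character loops, no vectorised tricks).

# Position-by-position read/reference comparator: 5'-anchored, gapless.
bf_match <- function(read, ref, max_mm_seed17 = 2, max_overhang = 4) {
  norm <- function(s) chartr("T", "U", toupper(s))
  read <- norm(read); ref <- norm(ref)
  if (nchar(read) < 17) return(FALSE)
  if (nchar(read) - nchar(ref) > max_overhang) return(FALSE)
  mm <- 0
  for (i in seq_len(min(17, nchar(read), nchar(ref)))) {
    if (substr(read, i, i) != substr(ref, i, i)) mm <- mm + 1
  }
  mm <= max_mm_seed17
}

# Sliding-window exact-match scanner, 0-based starts.
bf_scan <- function(seq, motif) {
  norm <- function(s) chartr("U", "T", toupper(s))
  seq <- norm(seq); motif <- norm(motif)
  n <- nchar(seq); m <- nchar(motif)
  hits <- integer(0)
  if (m == 0 || n < m) return(hits)
  for (i in seq_len(n - m + 1)) {
    if (substr(seq, i, i + m - 1) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# Random nucleotide string.
rand_nt <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Mutate specific 1-based positions of a sequence to a different base.
mutate_at <- function(seq, positions) {
  s <- strsplit(seq, "")[[1]]
  for (p in positions) {
    s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1)
  }
  paste(s, collapse = "")
}

# Plate table with prescribed per-day normalised ratios for one construct
# (empty vector ratio fixed at 1).
plates_from_ratios <- function(q, construct = "m1") {
  days <- seq_along(q)
  rbind(
    data.frame(construct = construct, day = days, renilla = q * 1000,
               firefly = 1000),
    data.frame(construct = "EMPTY", day = days, renilla = 1000,
               firefly = 1000))
}

# Small deterministic reference panel for quantification tests.
tiny_refs <- function() {
  c(mirA = "UGAGGUAGUAGGUUGUAUAGUU",
    mirB = "ACCCGUAGAUCCGAACUUGUGA",
    mirC = "UCACAACCUCCUAGAAAGAGUAGA")
}
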