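# Read-to-mature assignment policy, blacklist filtering, RPM
# normalisation and arm classification.

test_that("match_read applies the 5'-anchored mismatch policy", {
  ref <- "UGAGGUAGUAGGUUGUAUAGUU"  # 22 nt

  expect_true(match_read(ref, ref)$accept)
  expect_equal(match_read(ref, ref)$n_mm_seed17, 0L)

  set.seed(21)
  # two mismatches within positions 1-17 are tolerated
  r2 <- mutate_at(ref, c(5, 12))
  expect_true(match_read(r2, ref)$accept)
  expect_setequal(match_read(r2, ref)$mismatches, c(5L, 12L))
  # three are not
  r3 <- mutate_at(ref, c(3, 9, 15))
  expect_false(match_read(r3, ref)$accept)
  # any number of mismatches from position 18 onward is fine
  r18 <- mutate_at(ref, c(19, 21, 22))
  expect_true(match_read(r18, ref)$accept)

  # short reads reject; DNA input is treated as RNA
  expect_false(match_read(substr(ref, 1, 16), ref)$accept)
  expect_true(match_read(chartr("U", "T", ref), ref)$accept)
  # 3' overhang tolerated up to 4 nt
  expect_true(match_read(paste0(ref, "AAAA"), ref)$accept)
  expect_false(match_read(paste0(ref, "AAAAA"), ref)$accept)
  expect_error(match_read("", ref), "empty")
  expect_error(match_read("UGAXGUAGUAGGUUGUAUAGUU", ref),
               "non-nucleotide")
})

test_that("match_read agrees with the brute-force comparator", {
  set.seed(314)
  for (i in 1:2000) {
    ref <- rand_nt(sample(17:24, 1))
    read <- if (runif(1) < 0.5) {
      # perturbed copy of the reference, maybe extended
      base <- mutate_at(ref, sample(nchar(ref), sample(0:4, 1)))
      paste0(base, rand_nt(sample(0:6, 1)))
    } else {
      rand_nt(sample(15:28, 1))
    }
    expect_identical(match_read(read, ref)$accept, bf_match(read, ref),
                     info = paste(read, ref))
  }
})

test_that("quantify counts reads under the multi-mapping policy", {
  refs <- tiny_refs()
  expect_equal(quantify(rep(refs[["mirA"]], 10), refs),
               c(mirA = 10, mirB = 0, mirC = 0))

  # a read matching two references equally splits under "fractional"
  twins <- c(t1 = "UGAGGUAGUAGGUUGUAUAGUU",
             t2 = "UGAGGUAGUAGGUUGUAUAGAA")  # differ only at 21-22
  both <- quantify("UGAGGUAGUAGGUUGUAUAGUU", twins)
  expect_equal(both, c(t1 = 0.5, t2 = 0.5))
  all_mode <- quantify("UGAGGUAGUAGGUUGUAUAGUU", twins, policy = "all")
  expect_equal(all_mode, c(t1 = 1, t2 = 1))

  # blacklisted reads (substrings of blacklist sequences) are excluded
  bl <- paste0("GGG", refs[["mirA"]], "CCC")
  expect_equal(quantify(rep(refs[["mirA"]], 5), refs, blacklist = bl),
               c(mirA = 0, mirB = 0, mirC = 0))

  expect_error(quantify("ACGU", character(0)), "non-empty")
})

test_that("quantification is order-independent and matches emitted copies", {
  p <- gen_panel(3, seed = 8)
  copies <- setNames(sample(1:6, 6, replace = TRUE), p$mirnas$name)
  reads <- gen_reads(p, mode = "exact", copies = copies)
  refs <- setNames(p$mirnas$sequence, p$mirnas$name)
  counts <- quantify(reads, refs)
  expect_equal(unname(counts[names(copies)]), as.numeric(copies))
  set.seed(9)
  shuffled <- quantify(sample(reads), refs)
  expect_identical(counts, shuffled)
})

test_that("normalize_rpm computes per-replicate RPM and summaries", {
  pr <- normalize_rpm(c(a = 2, b = 8))
  expect_equal(pr$rpm_rep1, c(200000, 800000))

  m <- cbind(rep1 = c(a = 2, b = 8), rep2 = c(a = 2, b = 8))
  pr2 <- normalize_rpm(m)
  expect_equal(pr2$sd_rpm, c(0, 0))
  expect_equal(pr2$mean_rpm, c(200000, 800000))

  # per-replicate RPM sums to 1e6 under mirna_mapped
  set.seed(30)
  m3 <- matrix(rpois(9, 40), 3, dimnames = list(letters[1:3], NULL))
  pr3 <- normalize_rpm(m3)
  expect_equal(colSums(as.matrix(pr3[grep("^rpm_", names(pr3))])),
               setNames(rep(1e6, 3), paste0("rpm_rep", 1:3)))

  # genome_mapped rescales by total_mirna / total_genome
  counts <- c(x = 10, y = 30, z = 60)
  a <- normalize_rpm(counts)                      # denominator 100
  b <- normalize_rpm(counts, "genome_mapped", external_totals = 1000)
  expect_equal(b$rpm_rep1, a$rpm_rep1 * 100 / 1000)

  expect_error(normalize_rpm(c(a = 0, b = 0)), "positive")
  expect_error(normalize_rpm(counts, "genome_mapped"), "external_totals")
})

test_that("classify_arms applies the strict 4:1 star rule", {
  pairing <- data.frame(hairpin = c("h1", "h2", "h3", "h4"),
                        name_5p = paste0("h", 1:4, "-5p"),
                        name_3p = paste0("h", 1:4, "-3p"))
  rpm <- c(`h1-5p` = 100, `h1-3p` = 20,   # ratio 5: star
           `h2-5p` = 100, `h2-3p` = 25,   # ratio exactly 4: no star
           `h3-5p` = 20,  `h3-3p` = 1000, # bantam-like, ratio 50: star
           `h4-5p` = 50)                  # missing arm -> ratio Inf
  calls <- classify_arms(rpm, pairing)
  expect_equal(calls$star_name,
               c("h1-3p", NA, "h3-5p", "h4-3p"))
  expect_equal(calls$dominant_arm, c("5p", "5p", "3p", "5p"))
  expect_equal(calls$ratio[1], 5)
  expect_equal(calls$ratio[2], 4)
  # custom threshold
  calls10 <- classify_arms(rpm, pairing, ratio_threshold = 10)
  expect_true(is.na(calls10$star_name[1]))
  expect_equal(calls10$star_name[3], "h3-5p")
})
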