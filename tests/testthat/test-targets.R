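# Seed motifs, site scanning, per-gene aggregation, target-site abundance
# and junction screening.

test_that("seed_motif is the reverse complement of positions 2-8", {
  mo <- seed_motif("UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(mo$seed, "GAGGUAG")
  expect_equal(mo$motif_rna, "CUACCUC")
  expect_equal(mo$motif_dna, "CTACCTC")

  expect_equal(seed_motif(strrep("A", 22))$motif_rna, "UUUUUUU")
  # motifs depend only on positions 2-8
  a <- seed_motif("AGAGGUAGCCCCCCCCCCCCCC")$motif_dna
  b <- seed_motif("UGAGGUAGGGGGGGGGGGGGGG")$motif_dna
  expect_identical(a, b)
  expect_error(seed_motif("ACGUACG"), "shorter")
})

test_that("scan_sequence reports all overlapping exact matches", {
  expect_equal(scan_sequence("CTACCTC", "CTACCTC"), 0L)
  expect_equal(scan_sequence("CTACCTCCTACCTC", "CTACCTC"), c(0L, 7L))
  expect_equal(scan_sequence(strrep("A", 9), "AAAAAAA"), c(0L, 1L, 2L))
  expect_equal(scan_sequence("CTANCTC", "CTACCTC"), integer(0))
  # RNA/DNA equivalence
  expect_equal(scan_sequence("CUACCUC", "CTACCTC"), 0L)
  expect_length(scan_sequence("ACGT", "CTACCTC"), 0L)
})

test_that("scan_sequence agrees with the sliding-window oracle", {
  set.seed(27)
  for (i in 1:300) {
    seq <- rand_nt(sample(10:60, 1), alphabet = c("A", "C", "G", "T", "N"))
    motif <- rand_nt(sample(2:7, 1), alphabet = c("A", "C", "G", "T"))
    expect_identical(scan_sequence(seq, motif), bf_scan(seq, motif),
                     info = paste(seq, motif))
  }
})

test_that("gene_site_counts takes the maximum over UTR isoforms", {
  mo <- seed_motif("UGAGGUAGUAGGUUGUAUAGUU", name = "let7")
  utrs <- c("g1|u1" = "AAACTACCTCAAA",                     # 1 site
            "g1|u2" = "CTACCTCAACTACCTCAACTACCTCAA",       # 3 sites
            "g2|u1" = "AAAAAAAAAA")                        # none
  cat1 <- gene_site_counts(utrs, mo)
  expect_equal(cat1$counts["let7", "g1"], 3L)
  expect_equal(cat1$counts["let7", "g2"], 0L)
  expect_error(gene_site_counts(c("g1|u1" = "A", "g1|u1" = "C"), mo),
               "duplicate")
})

test_that("planted-site fixtures match the ledger maxima per gene", {
  p <- gen_panel(3, seed = 15)
  motifs <- seed_motif(p$mirnas$sequence, name = p$mirnas$name)
  u <- gen_utr_set(p, n_genes = 12, site_rate = 0.25, seed = 16,
                   isoforms_per_gene = 2)
  cat1 <- gene_site_counts(u$utrs, motifs)
  for (m in motifs$name) {
    for (g in cat1$genes) {
      led <- u$ledger[u$ledger$mirna == m & u$ledger$gene == g, ]
      expected <- if (nrow(led)) max(tapply(led$start, led$utr, length))
                  else 0L
      expect_equal(unname(cat1$counts[m, g]), as.integer(expected))
    }
  }
})

test_that("target-site abundance is the expression-weighted site sum", {
  mo <- seed_motif(c(mir1 = "UGAGGUAGUAGGUUGUAUAGUU"))
  utrs <- c("A|u1" = "CTACCTCACTACCTC",  # 2 sites
            "B|u1" = "AACTACCTCAA",      # 1 site
            "C|u1" = "AAAAAAAAAAA")      # 0 sites
  cat1 <- gene_site_counts(utrs, mo)
  expect_equal(unname(target_site_abundance(cat1, c(A = 10, B = 5, C = 99))),
               25)
  expect_equal(unname(target_site_abundance(cat1, c(A = 0, B = 0, C = 0))),
               0)
  # linearity in expression
  e <- c(A = 3, B = 7, C = 2)
  expect_equal(target_site_abundance(cat1, 2 * e),
               2 * target_site_abundance(cat1, e))
  expect_warning(tsa <- target_site_abundance(cat1, c(A = 10, B = 5)),
                 "without expression")
  expect_equal(unname(tsa), 25)
  expect_error(target_site_abundance(cat1, c(A = -1, B = 0, C = 0)),
               "negative")
})

test_that("junction_scan finds designed and adventitious sites", {
  mir <- c(designed = "UGAGGUAGUAGGUUGUAUAGUU",
           other = "ACCCGUAGAUCCGAACUUGUGA")
  motifs <- seed_motif(mir)
  rpm <- c(designed = 1000, other = 250)

  # a perfect-complement insert always carries the designed miRNA's motif
  insert <- chartr("U", "T", paste(rev(strsplit(chartr("ACGU", "UGCA",
    mir[["designed"]]), "")[[1]]), collapse = ""))
  jr <- junction_scan(insert, "GGGGGG", "GGGGGG", motifs, rpm,
                      designed = "designed")
  expect_true("designed" %in% jr$mirnas)
  expect_false("other" %in% jr$mirnas)
  expect_equal(jr$additive_expression, 1000)

  # plant the second miRNA's motif across the insert/flank boundary
  other_motif <- motifs$motif_dna[motifs$name == "other"]
  up <- paste0("CC", substr(other_motif, 1, 4))
  insert2 <- paste0(substr(other_motif, 5, 7), insert)
  jr2 <- junction_scan(insert2, up, "GGGGGG", motifs, rpm,
                       designed = "designed")
  expect_setequal(jr2$mirnas, c("designed", "other"))
  expect_equal(jr2$additive_expression, 1250)
  # each miRNA is summed once regardless of site multiplicity
  insert3 <- paste0(insert, other_motif, other_motif)
  jr3 <- junction_scan(insert3, "GGGGGG", "GGGGGG", motifs, rpm,
                       designed = "designed")
  expect_equal(jr3$additive_expression, 1250)
  # excluding the designed miRNA from the additive sum
  jr4 <- junction_scan(insert3, "GGGGGG", "GGGGGG", motifs, rpm,
                       designed = "designed", include_designed = FALSE)
  expect_equal(jr4$additive_expression, 250)

  expect_error(junction_scan(insert, "GGG", "GGGGGG", motifs, rpm),
               "flanks")
  expect_silent(junction_scan(insert, "GGG", "GGGGGG", motifs, rpm,
                              designed = "designed",
                              strict_flanks = FALSE))
})
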