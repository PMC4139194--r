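# Synthetic-data generator: panels, repression law, plates, Ago counts,
# planted-site UTR sets.

test_that("gen_panel builds hairpin pairs spanning the abundance range", {
  p <- gen_panel(16, seed = 1)
  expect_equal(nrow(p$mirnas), 32L)
  expect_gte(max(p$true_rpm) / min(p$true_rpm), 1e5)
  # one 5p and one 3p mature per hairpin
  tab <- table(p$mirnas$hairpin, p$mirnas$arm)
  expect_true(all(tab == 1L))
  # no shared 7-nt seeds
  seeds <- substr(p$mirnas$sequence, 2, 8)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(nchar(p$mirnas$sequence) %in% 21:23))

  p1 <- gen_panel(1, seed = 7)
  expect_setequal(p1$mirnas$arm, c("5p", "3p"))
  expect_error(gen_panel(0), "positive")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_panel(8, seed = 42), gen_panel(8, seed = 42))
  p <- gen_panel(4, seed = 3)
  tr <- synthetic_truth(rng_seed = 11)
  expect_identical(gen_true_repression(p, tr), gen_true_repression(p, tr))
  rep0 <- gen_true_repression(p, tr)
  expect_identical(gen_luciferase(rep0, truth = tr, seed = 5),
                   gen_luciferase(rep0, truth = tr, seed = 5))
  expect_identical(gen_ago_counts(p, tr, seed = 5),
                   gen_ago_counts(p, tr, seed = 5))
  expect_identical(gen_utr_set(p, 5, 0.1, seed = 9),
                   gen_utr_set(p, 5, 0.1, seed = 9))
})

test_that("gen_true_repression follows the clamped log-linear law", {
  p <- gen_panel(4, seed = 2)
  p$true_rpm[] <- 1e3
  tr <- gen_true_repression(p, synthetic_truth(slope = 10, intercept = 0,
                                               noise_sd_repression = 0))
  expect_equal(unname(tr), rep(30, 8))

  p2 <- gen_panel(16, seed = 2)  # spans ~6 decades
  tr2 <- gen_true_repression(p2, synthetic_truth(slope = 10.4,
                                                 noise_sd_repression = 0))
  expect_true(all(tr2 <= 80))
  expect_true(all(tr2 >= 0))
  # ceiling is configurable
  tr3 <- gen_true_repression(p2, synthetic_truth(slope = 20, intercept = 40,
                                                 noise_sd_repression = 0,
                                                 ceiling = 60))
  expect_true(all(tr3 <= 60))
})

test_that("noise calibration keeps log-expression vs repression r near 0.7", {
  set.seed(1401)
  rs <- replicate(200, {
    p <- gen_panel(16)
    cor(log10(p$true_rpm), gen_true_repression(p))
  })
  expect_gte(median(rs), 0.6)
  expect_lte(median(rs), 0.8)
})

test_that("gen_luciferase encodes repression in the normalised ratio", {
  quiet <- synthetic_truth(luciferase_day_cv = 0, luciferase_well_cv = 0)
  pl <- gen_luciferase(c(m1 = 50), days = 3, truth = quiet, seed = 1)
  ratio <- pl$renilla / pl$firefly
  r_m1 <- ratio[pl$construct == "m1"]
  r_empty <- ratio[pl$construct == "EMPTY"]
  expect_equal(r_m1, r_empty / 2)

  pl0 <- gen_luciferase(c(m1 = 0), days = 2, truth = quiet, seed = 1)
  ratio0 <- pl0$renilla / pl0$firefly
  expect_equal(ratio0[pl0$construct == "m1"],
               ratio0[pl0$construct == "EMPTY"])

  expect_error(gen_luciferase(c(m1 = 120), truth = quiet, seed = 1),
               "\\[0, 100\\]")
  expect_error(gen_luciferase(c(m1 = -3), truth = quiet, seed = 1),
               "\\[0, 100\\]")
})

test_that("day-level luciferase noise cancels in recovered repression", {
  # day CV perturbs both luciferases together; recovery stays exact up to
  # the (tiny) well-level noise
  tr <- synthetic_truth(luciferase_day_cv = 0.05)
  p <- gen_panel(16, seed = 5)
  rep_true <- gen_true_repression(p, tr, seed = 6)
  err <- replicate(5, {
    pl <- gen_luciferase(rep_true, days = 3, truth = tr,
                         seed = sample.int(1e6, 1))
    rec <- repression_from_raw(pl)
    est <- setNames(rec$repression_pct, rec$construct)[names(rep_true)]
    mean(abs(est - rep_true))
  })
  expect_lt(mean(err), 0.5)
})

test_that("gen_ago_counts tracks cellular abundance", {
  p <- gen_panel(8, seed = 4)
  a0 <- gen_ago_counts(p, synthetic_truth(occupancy_log_sd = 0), seed = 1)
  expect_equal(cor(log10(a0$cell_rpm), log10(a0$ago_rpm)), 1)
  expect_equal(a0$ago_rpm, a0$cell_rpm)

  aoff <- gen_ago_counts(p, synthetic_truth(occupancy_log_sd = 0,
                                            occupancy_offset = 0.5),
                         seed = 1)
  expect_equal(aoff$ago_rpm / aoff$cell_rpm,
               rep(10^0.5, nrow(aoff)))
})

test_that("calibrated occupancy noise gives cell-Ago correlation near 0.98", {
  set.seed(77)
  rs <- replicate(200, {
    p <- gen_panel(16)
    a <- gen_ago_counts(p)
    cor(log10(a$cell_rpm), log10(a$ago_rpm))
  })
  expect_gte(median(rs), 0.97)
  expect_lte(median(rs), 0.99)
})

test_that("gen_utr_set plants sites exactly as recorded in the ledger", {
  p <- gen_panel(3, seed = 10)
  motifs <- seed_motif(p$mirnas$sequence, name = p$mirnas$name)

  # zero rate: no sites anywhere, for any panel miRNA
  u0 <- gen_utr_set(p, n_genes = 8, site_rate = 0, seed = 11)
  for (i in seq_len(nrow(motifs)))
    for (utr in u0$utrs)
      expect_length(scan_sequence(utr, motifs$motif_dna[i]), 0)
  expect_equal(nrow(u0$ledger), 0L)

  # positive rate: scanner hits equal the ledger, exactly
  u <- gen_utr_set(p, n_genes = 20, site_rate = 0.3, seed = 12)
  expect_gt(nrow(u$ledger), 0L)
  for (id in names(u$utrs)) {
    gene <- sub("\\|.*$", "", id)
    utr <- sub("^.*\\|", "", id)
    for (i in seq_len(nrow(motifs))) {
      found <- scan_sequence(u$utrs[[id]], motifs$motif_dna[i])
      planted <- sort(u$ledger$start[u$ledger$gene == gene &
                                       u$ledger$utr == utr &
                                       u$ledger$mirna == motifs$name[i]])
      expect_identical(sort(found), as.integer(planted))
    }
  }
  expect_error(gen_utr_set(p, 5, site_rate = -1), "site_rate")
})

test_that("gen_reads emits exact copies in the requested proportions", {
  p <- gen_panel(2, seed = 6)
  copies <- setNames(c(3, 1, 2, 4), p$mirnas$name)
  reads <- gen_reads(p, mode = "exact", copies = copies)
  expect_length(reads, 10L)
  counts <- table(factor(reads, levels = p$mirnas$sequence))
  expect_equal(as.integer(counts), unname(copies))
})
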