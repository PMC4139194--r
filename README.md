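# mirepress

Quantitative analysis of how endogenous microRNA abundance relates to the
repression of perfectly complementary reporter targets.

## The problem and who this is for

A miRNA's cellular concentration is routinely used as a proxy for its
repressive activity. Testing that assumption requires wiring together
several measurements for a panel of miRNAs: small-RNA sequencing to
estimate abundance, dual-luciferase reporters to measure repression,
Ago-1 RIP to measure RISC loading, and sequence analysis to rule out
confounders (adventitious seed sites created during cloning, target-site
load, duplex stability). `mirepress` implements that full analysis as a
tested R package, for groups running reporter panels in cell lines and
for anyone who needs the individual pieces (a seed scanner, an RPM
normaliser, a plate-ratio repression calculator) with well-defined
policies.

The core model is ordinary least squares of percent repression on log10
abundance:

    R_i = b0 + b1 * log10(RPM_i) + e_i

with the slope `b1` in percentage points of repression per decade of
expression, a t-based 95% CI, and Pearson r on both the log and linear
scales. A slope near 10 with a repression ceiling near 80% means
repression responds only logarithmically to abundance: a 10-fold
abundance change moves repression by ~10 points, a 2-fold change by ~3.

Around the model the package provides: read-to-mature assignment (at most
2 mismatches in reference positions 1–17, free 3′ end, ≤ 4 nt overhang),
blacklist filtering, RPM normalisation (miRNA-mapped or genome-mapped
denominators), strict 4:1 guide/star arm classification, per-day
empty-vector-normalised luciferase repression with paired t-tests,
canonical seed (positions 2–8) site prediction with per-gene isoform
maxima and target-site abundance, 6-nt cloning-junction screens with
additive expression, a nearest-neighbour free-energy score for perfect
miRNA:target helices, Ago-1 occupancy analysis, and a seeded
synthetic-data generator with exact ground-truth ledgers.

## Worked example

A complete synthetic study — 16 hairpin pairs (32 mature miRNAs) tiling
six decades of abundance, three transfection days, Ago-1 counts, a UTR
set with planted seed sites — generated, written to interchange files,
and analysed end to end:

```r
library(mirepress)

study <- simulate_study(16, seed = 42,
                        truth = synthetic_truth(luciferase_well_cv = 0.05),
                        n_genes = 40, site_rate = 0.02)
cfg <- write_study(study, tempfile("study_"))
res <- run_pipeline(cfg)

res$fit
#> Log-linear expression-repression fit
#>   n = 32 miRNAs, pseudocount = 0.5 RPM
#>   slope: 10.9 % per decade (95% CI 7.63 - 14.1)
#>   intercept: 15.9 %
#>   Pearson r (log scale): 0.78

res$occupancy
#> Ago-1 occupancy analysis: 32 shared miRNAs
#>   Pearson r, log10 cell vs log10 Ago RPM: 0.986
#>   Pearson r, log10 Ago RPM vs repression: 0.764

res$nonsignificant$n
#> [1] 4
max(res$repression$repression_pct)
#> [1] 81.17737
predict_delta_repression(res$fit, 2)
#> [1] 3.283869
```

Reading the output: the fitted slope (10.9 here; the generating value is
10.4) says each decade of abundance adds ~11 points of repression; its CI
comes from the OLS standard error. The cell-vs-Ago correlation of 0.99
says RISC loading tracks cellular abundance, and Ago abundance predicts
repression no better than cellular abundance does. Four low-abundance
constructs are statistically indistinguishable from the empty vector, and
no construct exceeds the ~80% repression ceiling beyond plate noise. The
run directory (`cfg$outdir`) contains every stage's TSV plus
`summary.txt`, each stamped with the package version and config hash.

Individual stages work standalone, e.g.

```r
seed_motif("UGAGGUAGUAGGUUGUAUAGUU")   # -> motif CUACCUC / CTACCTC
match_read("UGAGGUAGUAGGUUGUAUAGUUAA", "UGAGGUAGUAGGUUGUAUAGUU")
repression_from_raw(read_plates("plates.tsv"))
duplex_mfe(c(bantam = "UGAGAUCAUUUUGAAAGCUGAUU"))
```

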