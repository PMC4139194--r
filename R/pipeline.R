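# Pipeline orchestration: validated run configuration, a one-call synthetic
# study, and the end-to-end quant -> repression -> targets -> duplex ->
# model run writing all interchange tables.

#' Build a run configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()].
#' Required: `refs_fasta`, `plates_tsv`, and one of `reads` (FASTA/FASTQ
#' paths, one per replicate) or `counts_tsv` (pre-tabulated counts, column
#' `name` plus one column per replicate). Everything else is optional.
#'
#' @param refs_fasta Mature miRNA reference FASTA.
#' @param plates_tsv Raw luciferase plate TSV
#'   (construct/day/renilla/firefly).
#' @param reads Character vector of small-RNA read files (one replicate
#'   each); `.fastq`/`.fq` suffixes are parsed as FASTQ, otherwise FASTA.
#' @param counts_tsv Pre-tabulated read counts (alternative to `reads`).
#' @param blacklist_fasta Optional FASTA of sequences to filter (rRNA,
#'   tRNA).
#' @param pairing_tsv Optional hairpin pairing table (for arm calls).
#' @param utr_fasta,expression_tsv Optional UTR set (headers `gene|utr`)
#'   and mRNA expression table (for target-site abundance).
#' @param constructs_tsv Optional reporter construct table with columns
#'   `construct`, `mature_sequence`, `insert_with_flanks` (6-nt vector
#'   flank on each side).
#' @param ago_counts_tsv Optional Ago-1 RIP count table (same layout as
#'   `counts_tsv`).
#' @param denominator_mode,external_totals See [normalize_rpm()].
#' @param multimap_policy See [quantify()].
#' @param pseudocount RPM pseudocount used before log10.
#' @param alpha Significance level for the paired t-tests.
#' @param star_ratio_threshold Arm-ratio threshold for star calls.
#' @param outdir Output directory (created if needed).
#' @return A list of class `"run_config"` (validated lazily by
#'   [validate_config()]).
#' @export
run_config <- function(refs_fasta, plates_tsv, reads = NULL,
                       counts_tsv = NULL, blacklist_fasta = NULL,
                       pairing_tsv = NULL, utr_fasta = NULL,
                       expression_tsv = NULL, constructs_tsv = NULL,
                       ago_counts_tsv = NULL,
                       denominator_mode = "mirna_mapped",
                       external_totals = NULL,
                       multimap_policy = "fractional",
                       pseudocount = 0.5, alpha = 0.05,
                       star_ratio_threshold = 4,
                       outdir = tempfile("mirepress_run_")) {
  structure(list(refs_fasta = refs_fasta, plates_tsv = plates_tsv,
                 reads = reads, counts_tsv = counts_tsv,
                 blacklist_fasta = blacklist_fasta,
                 pairing_tsv = pairing_tsv, utr_fasta = utr_fasta,
                 expression_tsv = expression_tsv,
                 constructs_tsv = constructs_tsv,
                 ago_counts_tsv = ago_counts_tsv,
                 denominator_mode = denominator_mode,
                 external_totals = external_totals,
                 multimap_policy = multimap_policy,
                 pseudocount = pseudocount, alpha = alpha,
                 star_ratio_threshold = star_ratio_threshold,
                 outdir = outdir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks that required inputs are present, that every referenced path
#' exists (errors name the offending field), and that numeric parameters
#' are within range.
#'
#' @param config A [run_config()] list.
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  path_fields <- c("refs_fasta", "plates_tsv", "blacklist_fasta",
                   "pairing_tsv", "utr_fasta", "expression_tsv",
                   "constructs_tsv", "ago_counts_tsv", "counts_tsv")
  for (f in path_fields) {
    p <- config[[f]]
    if (!is.null(p) && !all(file.exists(p)))
      stop(sprintf("config field '%s': file not found: %s", f,
                   paste(p[!file.exists(p)], collapse = ", ")),
           call. = FALSE)
  }
  if (!is.null(config$reads) && !all(file.exists(config$reads)))
    stop(sprintf("config field 'reads': file not found: %s",
                 paste(config$reads[!file.exists(config$reads)],
                       collapse = ", ")), call. = FALSE)
  if (is.null(config$reads) && is.null(config$counts_tsv))
    stop("config requires either 'reads' or 'counts_tsv'", call. = FALSE)
  if (config$pseudocount < 0)
    stop("config field 'pseudocount': must be >= 0", call. = FALSE)
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("config field 'alpha': must be in (0, 1)", call. = FALSE)
  if (config$star_ratio_threshold < 1)
    stop("config field 'star_ratio_threshold': must be >= 1",
         call. = FALSE)
  if (!config$denominator_mode %in% c("mirna_mapped", "genome_mapped"))
    stop("config field 'denominator_mode': unknown mode", call. = FALSE)
  if (config$denominator_mode == "genome_mapped" &&
      is.null(config$external_totals))
    stop("config field 'external_totals': required for genome_mapped mode",
         call. = FALSE)
  invisible(config)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A validated `"run_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  cfg <- do.call(run_config, vals)
  validate_config(cfg)
  cfg
}

#' Simulate a complete synthetic study
#'
#' Generates, under one seed, everything the pipeline consumes: a miRNA
#' panel with known abundances, true repression values, raw luciferase
#' plates, Ago-1 counts, and a UTR set with planted seed sites.
#'
#' @param n_hairpins Hairpins in the panel (the study assayed 16 pairs).
#' @param seed Integer master seed; sub-seeds for each generator are drawn
#'   from it.
#' @param truth A [synthetic_truth()].
#' @param days Luciferase transfection days.
#' @param n_genes,site_rate UTR set parameters (see [gen_utr_set()]).
#' @return A list of class `"synthetic_study"`: `panel`, `truth`,
#'   `true_repression`, `plates`, `ago`, `utr_set`, `seed`.
#' @examples
#' st <- simulate_study(4, seed = 1, n_genes = 10)
#' names(st)
#' @export
simulate_study <- function(n_hairpins = 16L, seed = 1L,
                           truth = synthetic_truth(), days = 3L,
                           n_genes = 100L, site_rate = 0.02) {
  subseeds <- with_seed(seed, sample.int(2^31 - 1L, 4L))
  panel <- gen_panel(n_hairpins, seed = subseeds[1L])
  repression <- gen_true_repression(panel, truth, seed = subseeds[2L])
  plates <- gen_luciferase(repression, days = days, truth = truth,
                           seed = subseeds[3L])
  ago <- gen_ago_counts(panel, truth, seed = subseeds[4L])
  utr_set <- gen_utr_set(panel, n_genes = n_genes, site_rate = site_rate,
                         seed = subseeds[1L])
  structure(list(panel = panel, truth = truth,
                 true_repression = repression, plates = plates,
                 ago = ago, utr_set = utr_set, seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study to pipeline input files
#'
#' Emits the FASTA/TSV files [run_pipeline()] reads: mature references,
#' per-replicate counts, pairing, plates, UTRs, mRNA expression, reporter
#' constructs (perfect-complement inserts with fixed 6-nt vector flanks)
#' and Ago-1 counts. Cellular counts are written as two identical
#' replicates scaled from the true RPM.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return A [run_config()] pointing at the written files.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  panel <- study$panel
  write_fasta(setNames(panel$mirnas$sequence, panel$mirnas$name),
              p("mature_refs.fasta"))
  counts <- round(panel$true_rpm)
  write_tsv(data.frame(name = names(counts), rep1 = unname(counts),
                       rep2 = unname(counts)),
            p("counts.tsv"))
  write_tsv(panel$hairpin_pairs, p("pairing.tsv"))
  write_tsv(as.data.frame(study$plates), p("plates.tsv"))
  write_fasta(study$utr_set$utrs, p("utrs.fasta"))
  write_tsv(data.frame(gene = names(study$utr_set$expression),
                       expression = unname(study$utr_set$expression)),
            p("expression.tsv"))
  insert <- chartr("U", "T", revcomp_rna(panel$mirnas$sequence))
  write_tsv(data.frame(construct = panel$mirnas$name,
                       mature_sequence = panel$mirnas$sequence,
                       insert_with_flanks = paste0("CTCGAG", insert,
                                                   "GCGGCC"),
                       stringsAsFactors = FALSE),
            p("constructs.tsv"))
  write_tsv(data.frame(name = study$ago$name,
                       rep1 = round(study$ago$ago_rpm),
                       rep2 = round(study$ago$ago_rpm)),
            p("ago_counts.tsv"))
  run_config(refs_fasta = p("mature_refs.fasta"),
             plates_tsv = p("plates.tsv"),
             counts_tsv = p("counts.tsv"),
             pairing_tsv = p("pairing.tsv"),
             utr_fasta = p("utrs.fasta"),
             expression_tsv = p("expression.tsv"),
             constructs_tsv = p("constructs.tsv"),
             ago_counts_tsv = p("ago_counts.tsv"),
             outdir = p("out"))
}

read_counts_table <- function(path) {
  df <- read_tsv(path, required_cols = "name")
  m <- as.matrix(df[setdiff(names(df), "name")])
  rownames(m) <- df$name
  m
}

read_reads_file <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) read_fastq(path)
  else read_fasta(path)
}

#' Run the full analysis pipeline
#'
#' Executes quantification, repression, target prediction, junction
#' screening, duplex scoring and model fitting in order, writing every
#' result table (with provenance headers) into `config$outdir` plus a
#' human-readable `summary.txt`. Fully deterministic given the
#' configuration.
#'
#' @param config A validated [run_config()].
#' @return A list of class `"mirepress_run"` with elements `profile`,
#'   `repression`, `arm_calls`, `catalog`, `tsa`, `junctions`, `duplex`,
#'   `fit`, `fit_significant_only`, `nonsignificant`, `occupancy`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  refs <- stage("quant", {
    r <- read_fasta(config$refs_fasta)
    canon_rna(r, what = "reference")
  })
  blacklist <- if (!is.null(config$blacklist_fasta))
    read_fasta(config$blacklist_fasta) else NULL

  counts <- stage("quant", {
    if (!is.null(config$counts_tsv)) {
      m <- read_counts_table(config$counts_tsv)
      m[names(refs)[names(refs) %in% rownames(m)], , drop = FALSE]
    } else {
      reps <- lapply(config$reads, function(f)
        quantify(read_reads_file(f), refs, blacklist = blacklist,
                 policy = config$multimap_policy))
      do.call(cbind, setNames(reps, paste0("rep", seq_along(reps))))
    }
  })
  profile <- stage("quant",
    normalize_rpm(counts, denominator_mode = config$denominator_mode,
                  external_totals = config$external_totals))
  write_tsv(as.data.frame(profile), out("expression_profile.tsv"),
            config = config,
            comments = sprintf("denominator_mode: %s",
                               config$denominator_mode))

  arm_calls <- NULL
  if (!is.null(config$pairing_tsv)) {
    arm_calls <- stage("quant",
      classify_arms(profile, read_pairing(config$pairing_tsv),
                    ratio_threshold = config$star_ratio_threshold))
    write_tsv(as.data.frame(arm_calls), out("arm_calls.tsv"),
              config = config)
  }

  repression <- stage("repression",
    repression_from_raw(read_plates(config$plates_tsv),
                        alpha = config$alpha))
  write_tsv(as.data.frame(repression), out("repression.tsv"),
            config = config)
  nonsig <- count_nonsignificant(repression)

  motifs <- seed_motif(refs, name = names(refs))
  catalog <- NULL; tsa <- NULL
  if (!is.null(config$utr_fasta)) {
    catalog <- stage("targets",
      gene_site_counts(read_fasta(config$utr_fasta), motifs))
    if (!is.null(config$expression_tsv)) {
      tsa <- stage("targets",
        target_site_abundance(catalog,
                              read_expression(config$expression_tsv)))
      write_tsv(data.frame(name = names(tsa), tsa = unname(tsa)),
                out("target_site_abundance.tsv"), config = config)
    }
  }

  junctions <- NULL
  if (!is.null(config$constructs_tsv)) {
    ctab <- read_tsv(config$constructs_tsv,
                     required_cols = c("construct", "mature_sequence",
                                       "insert_with_flanks"))
    mean_rpm <- setNames(profile$mean_rpm, profile$name)
    junctions <- stage("junctions", {
      rows <- lapply(seq_len(nrow(ctab)), function(i) {
        s <- ctab$insert_with_flanks[i]
        jr <- junction_scan(substr(s, 7L, nchar(s) - 6L),
                            substr(s, 1L, 6L),
                            substr(s, nchar(s) - 5L, nchar(s)),
                            motifs, mean_rpm,
                            designed = ctab$construct[i])
        others <- setdiff(jr$mirnas, jr$designed)
        data.frame(construct = ctab$construct[i],
                   n_sites = nrow(jr$hits),
                   other_mirnas = paste(others, collapse = ","),
                   additive_expression = jr$additive_expression,
                   comparably_expressed_cotarget = length(others) > 0 &&
                     any(mean_rpm[others] >=
                           mean_rpm[jr$designed], na.rm = TRUE),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    write_tsv(junctions, out("junctions.tsv"), config = config)
  }

  duplex <- stage("duplex", duplex_mfe(refs))
  write_tsv(as.data.frame(duplex), out("duplex.tsv"), config = config)

  fit <- NULL; fit_sig <- NULL; occupancy <- NULL
  mean_rpm <- setNames(profile$mean_rpm, profile$name)
  assayed <- repression$construct[repression$construct %in%
                                    names(mean_rpm)]
  if (length(assayed) >= 3L) {
    rep_v <- setNames(repression$repression_pct,
                      repression$construct)[assayed]
    fit <- stage("fit",
      fit_loglinear(mean_rpm[assayed], rep_v,
                    pseudocount = config$pseudocount, names = assayed))
    excl <- intersect(nonsig$names, assayed)
    fit_sig <- if (length(assayed) - length(excl) >= 3L && length(excl))
      refit_excluding(fit, excl) else fit
    write_tsv(data.frame(
      quantity = c("slope", "slope_ci_lower", "slope_ci_upper",
                   "intercept", "pearson_r_log", "pearson_r_linear", "n",
                   "slope_excl_nonsig", "pearson_r_log_excl_nonsig"),
      value = c(fit$coefficients[["slope"]], fit$ci_slope[["lower"]],
                fit$ci_slope[["upper"]], fit$coefficients[["intercept"]],
                fit$pearson_r, pearson_linear(mean_rpm[assayed], rep_v),
                fit$n, fit_sig$coefficients[["slope"]],
                fit_sig$pearson_r)),
      out("fit.tsv"), config = config)
  }

  if (!is.null(config$ago_counts_tsv)) {
    ago_counts <- read_counts_table(config$ago_counts_tsv)
    ago_profile <- normalize_rpm(ago_counts,
                                 denominator_mode = config$denominator_mode)
    rep_v <- setNames(repression$repression_pct, repression$construct)
    occupancy <- stage("occupancy",
      occupancy_analysis(mean_rpm,
                         setNames(ago_profile$mean_rpm, ago_profile$name),
                         repression = rep_v,
                         pseudocount = config$pseudocount))
    write_tsv(occupancy$records, out("occupancy.tsv"), config = config,
              comments = sprintf("r_cell_ago: %.6g; r_ago_repression: %.6g",
                                 occupancy$r_cell_ago,
                                 occupancy$r_ago_repression))
  }

  summary_lines <- c(
    sprintf("mirepress %s pipeline run",
            as.character(packageVersion("mirepress"))),
    sprintf("config hash: %s", config_hash(config)),
    sprintf("mature references: %d", length(refs)),
    sprintf("constructs assayed: %d (non-significant: %d)",
            sum(repression$construct != "EMPTY"), nonsig$n),
    if (!is.null(fit))
      sprintf("fit: slope %.3f (95%% CI %.3f - %.3f), r = %.3f, n = %d",
              fit$coefficients[["slope"]], fit$ci_slope[["lower"]],
              fit$ci_slope[["upper"]], fit$pearson_r, fit$n),
    if (!is.null(occupancy))
      sprintf("occupancy: r(cell, Ago) = %.3f; r(Ago, repression) = %.3f",
              occupancy$r_cell_ago, occupancy$r_ago_repression))
  writeLines(summary_lines, out("summary.txt"))

  structure(list(profile = profile, repression = repression,
                 arm_calls = arm_calls, catalog = catalog, tsa = tsa,
                 junctions = junctions, duplex = duplex, fit = fit,
                 fit_significant_only = fit_sig,
                 nonsignificant = nonsig, occupancy = occupancy,
                 config = config),
            class = "mirepress_run")
}

#' @export
print.mirepress_run <- function(x, ...) {
  cat("mirepress pipeline run\n")
  cat(sprintf("  output: %s\n", x$config$outdir))
  if (!is.null(x$fit)) { cat("\n"); print(x$fit) }
  if (!is.null(x$occupancy)) { cat("\n"); print(x$occupancy) }
  invisible(x)
}
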