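# Synthetic-data generator: miRNA panels, luciferase plates, Ago-1 counts
# and UTR sets with a known ground truth, so every downstream stage can be
# tested without external data.

#' Ground-truth parameters for the synthetic study
#'
#' Bundles the generating parameters used by [gen_true_repression()],
#' [gen_luciferase()] and [gen_ago_counts()]. Defaults were calibrated by
#' Monte-Carlo simulation so that, on a 16-hairpin panel spanning six
#' decades of abundance, the implied repression follows a log-linear law of
#' about 10% per decade with Pearson r of log-abundance versus repression
#' near 0.7, and Ago-1 counts track cellular counts with r near 0.98.
#'
#' @param slope Percent repression gained per decade of abundance.
#' @param intercept Percent repression at 1 RPM (before clamping).
#' @param noise_sd_repression SD of the per-miRNA repression noise, in
#'   percentage points.
#' @param luciferase_day_cv Coefficient of variation of the day-level
#'   multiplicative factor shared by both luciferases on a plate day
#'   (transfection efficiency); it cancels in the Renilla/firefly ratio.
#' @param luciferase_well_cv Per-well multiplicative CV on each luminescence
#'   reading (instrument noise).
#' @param occupancy_log_sd SD, in log10 units, of Ago-1 loading noise
#'   around cellular abundance.
#' @param occupancy_offset Constant log10 offset of Ago-1 RPM relative to
#'   cellular RPM (0 = equal loading on average).
#' @param ceiling Maximum attainable repression, percent. Repression is
#'   clamped to `[0, ceiling]`; 80 reflects the observed maximum for
#'   endogenous miRNAs on perfect sites.
#' @param rng_seed Default seed used when a generator is called without one.
#' @return A list of class `"synthetic_truth"`.
#' @examples
#' synthetic_truth(noise_sd_repression = 0)
#' @export
synthetic_truth <- function(slope = 10.4, intercept = 8,
                            noise_sd_repression = 18,
                            luciferase_day_cv = 0.05,
                            luciferase_well_cv = 0.002,
                            occupancy_log_sd = 0.35,
                            occupancy_offset = 0,
                            ceiling = 80,
                            rng_seed = NULL) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(num1(slope), num1(intercept), num1(noise_sd_repression),
            num1(luciferase_day_cv), num1(luciferase_well_cv),
            num1(occupancy_log_sd), num1(occupancy_offset), num1(ceiling))
  if (slope < 0 || noise_sd_repression < 0 || luciferase_day_cv < 0 ||
      luciferase_well_cv < 0 || occupancy_log_sd < 0)
    stop("slope, noise SDs and CVs must be non-negative", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 noise_sd_repression = noise_sd_repression,
                 luciferase_day_cv = luciferase_day_cv,
                 luciferase_well_cv = luciferase_well_cv,
                 occupancy_log_sd = occupancy_log_sd,
                 occupancy_offset = occupancy_offset,
                 ceiling = ceiling, rng_seed = rng_seed),
            class = "synthetic_truth")
}

#' Generate a panel of miRNA hairpins with known abundances
#'
#' Each hairpin contributes one 5p and one 3p mature sequence (21-23 nt over
#' A/C/G/U). True abundances (RPM) are sampled log-uniformly with one draw
#' per stratum of the log10 range, so the panel tiles the whole abundance
#' range: with `n_hairpins >= 8` the max/min ratio is guaranteed to exceed
#' 1e5 for the default range. Mature sequences are drawn by rejection so
#' that no two share a 7-nt seed (positions 2-8) unless
#' `allow_shared_seeds = TRUE`.
#'
#' @param n_hairpins Number of hairpins (>= 1); the panel holds
#'   `2 * n_hairpins` mature sequences.
#' @param seed Integer seed; identical seeds give identical panels.
#' @param log10_range Range of log10 RPM tiled by the panel.
#' @param length_range Mature sequence length range, nt.
#' @param allow_shared_seeds Permit seed collisions between matures.
#' @return A list of class `"synthetic_panel"` with elements `mirnas`
#'   (data.frame: name, hairpin, arm, sequence), `true_rpm` (named numeric)
#'   and `hairpin_pairs` (data.frame: hairpin, name_5p, name_3p).
#' @examples
#' p <- gen_panel(4, seed = 1)
#' p$mirnas$name
#' @export
gen_panel <- function(n_hairpins, seed = NULL, log10_range = c(0, 6),
                      length_range = c(21L, 23L),
                      allow_shared_seeds = FALSE) {
  stopifnot(is.numeric(n_hairpins), length(n_hairpins) == 1L)
  if (!is.finite(n_hairpins) || n_hairpins < 1)
    stop("n_hairpins must be a positive integer", call. = FALSE)
  n_hairpins <- as.integer(n_hairpins)
  stopifnot(length(log10_range) == 2L, diff(log10_range) > 0)
  with_seed(seed, {
    m <- 2L * n_hairpins
    hairpin <- sprintf("syn-mir-%d", rep(seq_len(n_hairpins), each = 2L))
    arm <- rep(c("5p", "3p"), n_hairpins)
    name <- paste0(hairpin, "-", arm)

    seqs <- character(m)
    seen_seeds <- character(0)
    for (i in seq_len(m)) {
      repeat {
        s <- random_rna(sample(seq(length_range[1L], length_range[2L]), 1L))
        sd7 <- substr(s, 2L, 8L)
        if (allow_shared_seeds || !(sd7 %in% seen_seeds)) {
          seqs[i] <- s
          seen_seeds <- c(seen_seeds, sd7)
          break
        }
      }
    }

    # stratified log-uniform abundance: one draw per stratum, shuffled
    width <- diff(log10_range)
    strata <- (seq_len(m) - 1L + runif(m)) / m * width + log10_range[1L]
    log_rpm <- sample(strata)
    true_rpm <- setNames(10^log_rpm, name)

    structure(list(
      mirnas = data.frame(name = name, hairpin = hairpin, arm = arm,
                          sequence = seqs, stringsAsFactors = FALSE),
      true_rpm = true_rpm,
      hairpin_pairs = data.frame(hairpin = unique(hairpin),
                                 name_5p = name[arm == "5p"],
                                 name_3p = name[arm == "3p"],
                                 stringsAsFactors = FALSE)
    ), class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("Synthetic miRNA panel: %d hairpins, %d mature sequences\n",
              nrow(x$hairpin_pairs), nrow(x$mirnas)))
  cat(sprintf("  true RPM range: %.3g - %.3g\n",
              min(x$true_rpm), max(x$true_rpm)))
  invisible(x)
}

#' True percent repression implied by abundance
#'
#' Inverts the fitted expression-to-repression law: each miRNA's repression
#' is `intercept + slope * log10(rpm)` plus Gaussian noise, clamped to
#' `[0, ceiling]`.
#'
#' @param panel A [gen_panel()] result.
#' @param truth A [synthetic_truth()] object.
#' @param seed Integer seed (defaults to `truth$rng_seed`).
#' @return Named numeric vector of percent repression, one per mature miRNA.
#' @examples
#' p <- gen_panel(4, seed = 1)
#' gen_true_repression(p, synthetic_truth(noise_sd_repression = 0))
#' @export
gen_true_repression <- function(panel, truth = synthetic_truth(),
                                seed = truth$rng_seed) {
  stopifnot(inherits(panel, "synthetic_panel"),
            inherits(truth, "synthetic_truth"))
  with_seed(seed, {
    mu <- truth$intercept + truth$slope * log10(panel$true_rpm)
    eps <- rnorm(length(mu), 0, truth$noise_sd_repression)
    pmin(pmax(mu + eps, 0), truth$ceiling)
  })
}

#' Simulate raw dual-luciferase plates
#'
#' For each construct and day, firefly luminescence carries a day-level
#' multiplicative factor (shared with Renilla, so it cancels in the ratio)
#' and per-well instrument noise; Renilla is firefly times a base ratio,
#' attenuated by the construct's true repression. An `EMPTY` vector with
#' zero repression is always included.
#'
#' @param repression Named numeric vector of true percent repression in
#'   `[0, 100]`.
#' @param days Number of independent transfection days (>= 1).
#' @param truth A [synthetic_truth()] (noise CVs are read from it).
#' @param seed Integer seed.
#' @param base_ratio Renilla/firefly ratio of the empty vector.
#' @param firefly_mean Mean firefly luminescence per well.
#' @return A data.frame of class `"plate_table"` with columns
#'   `construct`, `day`, `renilla`, `firefly`.
#' @examples
#' rep0 <- c(`syn-mir-1-5p` = 50)
#' gen_luciferase(rep0, days = 3,
#'                truth = synthetic_truth(luciferase_day_cv = 0,
#'                                        luciferase_well_cv = 0),
#'                seed = 1)
#' @export
gen_luciferase <- function(repression, days = 3L, truth = synthetic_truth(),
                           seed = truth$rng_seed, base_ratio = 2,
                           firefly_mean = 1e5) {
  stopifnot(is.numeric(repression), !is.null(names(repression)))
  if (any(!is.finite(repression)) || any(repression < 0 | repression > 100))
    stop("repression must lie in [0, 100]", call. = FALSE)
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  days <- as.integer(days)
  # mean-one lognormal factor with a given CV
  rln <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdl <- sqrt(log1p(cv^2))
    rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  constructs <- c(names(repression), "EMPTY")
  rep_all <- c(repression, EMPTY = 0)
  with_seed(seed, {
    out <- vector("list", days)
    for (d in seq_len(days)) {
      dayfac <- rln(1L, truth$luciferase_day_cv)
      ff <- firefly_mean * dayfac * rln(length(constructs),
                                        truth$luciferase_well_cv)
      rr <- ff * base_ratio * (1 - rep_all / 100) *
        rln(length(constructs), truth$luciferase_well_cv)
      out[[d]] <- data.frame(construct = constructs, day = d,
                             renilla = rr, firefly = ff,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("plate_table", "data.frame")
    res
  })
}

#' Simulate Ago-1-associated miRNA counts
#'
#' Ago-1 RPM tracks cellular RPM on the log scale with a constant offset
#' plus Gaussian loading noise:
#' `log10(ago) = log10(cell) + offset + N(0, occupancy_log_sd)`.
#'
#' @inheritParams gen_true_repression
#' @return A data.frame with columns `name`, `cell_rpm`, `ago_rpm`.
#' @examples
#' p <- gen_panel(4, seed = 1)
#' gen_ago_counts(p, synthetic_truth(occupancy_log_sd = 0))
#' @export
gen_ago_counts <- function(panel, truth = synthetic_truth(),
                           seed = truth$rng_seed) {
  stopifnot(inherits(panel, "synthetic_panel"),
            inherits(truth, "synthetic_truth"))
  with_seed(seed, {
    lg <- log10(panel$true_rpm) + truth$occupancy_offset +
      rnorm(length(panel$true_rpm), 0, truth$occupancy_log_sd)
    data.frame(name = names(panel$true_rpm),
               cell_rpm = unname(panel$true_rpm),
               ago_rpm = unname(10^lg),
               stringsAsFactors = FALSE)
  })
}

#' Generate a UTR set with planted seed sites and an exact ledger
#'
#' Builds random-composition DNA 3'UTRs in which, for every (gene, miRNA)
#' pair, `Poisson(site_rate)` exact seed matches are planted at recorded
#' positions. Background sequence is re-randomised wherever it would spell
#' an accidental seed match for any panel miRNA, so the returned ledger is
#' an exact oracle for any scanner.
#'
#' @param panel A [gen_panel()] result.
#' @param n_genes Number of genes.
#' @param site_rate Expected planted sites per gene per miRNA (>= 0).
#' @param seed Integer seed.
#' @param utr_length UTR length, nt.
#' @param isoforms_per_gene UTR isoforms per gene (site counts per gene are
#'   aggregated downstream by taking the per-gene maximum).
#' @param expr_meanlog,expr_sdlog Lognormal parameters for the mRNA
#'   expression table.
#' @return A list of class `"utr_set"`: `utrs` (named character; names are
#'   `gene|utr`), `expression` (named numeric per gene), `ledger`
#'   (data.frame: gene, utr, mirna, start — 0-based site starts).
#' @examples
#' p <- gen_panel(2, seed = 1)
#' u <- gen_utr_set(p, n_genes = 5, site_rate = 0.2, seed = 2)
#' head(u$ledger)
#' @export
gen_utr_set <- function(panel, n_genes, site_rate, seed = NULL,
                        utr_length = 400L, isoforms_per_gene = 1L,
                        expr_meanlog = log(50), expr_sdlog = 1) {
  stopifnot(inherits(panel, "synthetic_panel"), n_genes >= 1)
  if (site_rate < 0) stop("site_rate must be >= 0", call. = FALSE)
  motifs <- seed_motif(panel$mirnas$sequence, name = panel$mirnas$name)
  motif_dna <- setNames(motifs$motif_dna, motifs$name)
  dna <- c("A", "C", "G", "T")
  with_seed(seed, {
    utrs <- character(0)
    ledger <- list()
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    for (g in gene_ids) {
      for (iso in seq_len(isoforms_per_gene)) {
        utr_id <- sprintf("utr%d", iso)
        # planted sites per miRNA for this isoform
        k <- rpois(length(motif_dna), site_rate)
        total <- sum(k)
        repeat {
          s <- sample(dna, utr_length, replace = TRUE)
          # choose non-overlapping planted windows
          ok <- TRUE
          starts <- integer(0)
          if (total > 0) {
            cand <- seq_len(utr_length - 7L + 1L)
            starts <- integer(total)
            taken <- logical(utr_length)
            for (j in seq_len(total)) {
              free <- cand[vapply(cand, function(p) !any(taken[p:(p + 6L)]),
                                  logical(1L))]
              if (!length(free)) { ok <- FALSE; break }
              pos <- sample(free, 1L)
              starts[j] <- pos
              taken[pos:(pos + 6L)] <- TRUE
            }
          }
          if (!ok) next
          who <- rep(names(motif_dna), k)
          for (j in seq_along(who))
            s[starts[j]:(starts[j] + 6L)] <-
              strsplit(motif_dna[[who[j]]], "", fixed = TRUE)[[1L]]
          seq_chr <- paste(s, collapse = "")
          # re-randomise accidental matches; planted windows are protected
          planted_by_motif <- split(starts - 1L, factor(who, levels = names(motif_dna)))
          fixed <- clean_background(seq_chr, motif_dna, planted_by_motif,
                                    starts)
          if (!is.null(fixed)) { seq_chr <- fixed; break }
          # pathological collision with planted windows: redraw everything
        }
        utrs[[paste0(g, "|", utr_id)]] <- seq_chr
        if (total > 0)
          ledger[[length(ledger) + 1L]] <-
            data.frame(gene = g, utr = utr_id, mirna = who,
                       start = starts - 1L, stringsAsFactors = FALSE)
      }
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(gene = character(0), utr = character(0),
                 mirna = character(0), start = integer(0),
                 stringsAsFactors = FALSE)
    expression <- setNames(rlnorm(n_genes, expr_meanlog, expr_sdlog),
                           gene_ids)
    structure(list(utrs = utrs, expression = expression, ledger = ledger,
                   site_rate = site_rate),
              class = "utr_set")
  })
}

# Remove accidental motif occurrences from a sequence by re-randomising the
# offending 7-mers, leaving planted windows untouched. Returns the cleaned
# sequence, or NULL if an accidental match overlaps a planted window (the
# caller then redraws the whole UTR).
clean_background <- function(seq_chr, motif_dna, planted_by_motif,
                             planted_starts1) {
  taken <- logical(nchar(seq_chr))
  for (p in planted_starts1) taken[p:(p + 6L)] <- TRUE
  dna <- c("A", "C", "G", "T")
  for (iter in 1:100) {
    extra <- list()
    for (m in names(motif_dna)) {
      hits <- scan_sequence(seq_chr, motif_dna[[m]])
      bad <- setdiff(hits, planted_by_motif[[m]])
      if (length(bad)) extra[[m]] <- bad
    }
    if (!length(extra)) return(seq_chr)
    s <- strsplit(seq_chr, "", fixed = TRUE)[[1L]]
    for (bad in extra) {
      for (b in bad) {
        win <- (b + 1L):(b + 7L)
        if (any(taken[win])) return(NULL)
        s[win] <- sample(dna, 7L, replace = TRUE)
      }
    }
    seq_chr <- paste(s, collapse = "")
  }
  NULL
}

#' Emit synthetic small-RNA reads for a panel
#'
#' Reads are exact copies of the mature sequences (no sequencing error).
#' In `"exact"` mode each mature contributes `round(copies)` reads; in
#' `"multinomial"` mode `total_reads` reads are drawn with probabilities
#' proportional to the panel's true RPM.
#'
#' @param panel A [gen_panel()] result.
#' @param mode `"exact"` or `"multinomial"`.
#' @param copies Named numeric vector of copy numbers (exact mode);
#'   defaults to the panel's `true_rpm`.
#' @param total_reads Library size (multinomial mode).
#' @param seed Integer seed (multinomial mode).
#' @return Character vector of reads (RNA alphabet), named `read000001`...
#' @examples
#' p <- gen_panel(2, seed = 1)
#' reads <- gen_reads(p, mode = "exact", copies = c(2, 1, 1, 3))
#' @export
gen_reads <- function(panel, mode = c("exact", "multinomial"),
                      copies = NULL, total_reads = NULL, seed = NULL) {
  stopifnot(inherits(panel, "synthetic_panel"))
  mode <- match.arg(mode)
  n <- if (mode == "exact") {
    if (is.null(copies)) copies <- panel$true_rpm
    if (!is.null(names(copies)))
      copies <- copies[panel$mirnas$name]
    round(unname(copies))
  } else {
    stopifnot(!is.null(total_reads))
    with_seed(seed,
      as.vector(rmultinom(1L, total_reads,
                          panel$true_rpm[panel$mirnas$name])))
  }
  reads <- rep(panel$mirnas$sequence, n)
  setNames(reads, sprintf("read%06d", seq_along(reads)))
}
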