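# Canonical 7-nt seed-site prediction, per-gene aggregation, target-site
# abundance, and reporter cloning-junction screening.

#' Target-side seed motif of a mature miRNA
#'
#' The canonical 7-nt seed motif is the reverse complement of miRNA
#' positions 2-8 (1-based from the 5' end), written in the target strand's
#' 5'->3' orientation. Returned in both RNA and DNA alphabets.
#'
#' @param mature Character vector of mature miRNA sequences (>= 8 nt).
#' @param name Optional names; defaults to `names(mature)` or `m1`, `m2`...
#' @return data.frame: `name`, `seed` (miRNA positions 2-8), `motif_rna`,
#'   `motif_dna`.
#' @examples
#' seed_motif("UGAGGUAGUAGGUUGUAUAGUU")  # let-7 family seed -> CUACCUC
#' @export
seed_motif <- function(mature, name = NULL) {
  mature <- canon_rna(mature, what = "mature sequence")
  if (any(nchar(mature) < 8L))
    stop("mature sequence shorter than 8 nt", call. = FALSE)
  if (is.null(name))
    name <- if (!is.null(names(mature))) names(mature)
            else paste0("m", seq_along(mature))
  seed <- substr(mature, 2L, 8L)
  motif_rna <- revcomp_rna(seed)
  data.frame(name = name, seed = seed, motif_rna = motif_rna,
             motif_dna = chartr("U", "T", motif_rna),
             stringsAsFactors = FALSE)
}

#' All exact occurrences of a motif in a sequence
#'
#' Overlapping matches are reported as 0-based start positions on the given
#' strand. Matching is exact after canonicalisation to DNA (T/U
#' equivalent); `N` in the subject never matches.
#'
#' @param seq Subject sequence (DNA or RNA; may contain N).
#' @param motif Motif to search for (DNA or RNA, typically 7 nt).
#' @return Integer vector of 0-based match starts (possibly empty).
#' @examples
#' scan_sequence("CTACCTCCTACCTC", "CTACCTC")
#' @export
scan_sequence <- function(seq, motif) {
  stopifnot(length(seq) == 1L, length(motif) == 1L)
  seq <- canon_dna(seq, what = "subject sequence")
  motif <- canon_dna(motif, what = "motif")
  if (grepl("N", motif, fixed = TRUE))
    stop("motif must not contain N", call. = FALSE)
  if (nchar(motif) == 0L || nchar(seq) < nchar(motif)) return(integer(0))
  # lookahead regex reports overlapping occurrences
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Per-gene seed-site counts, maximised over UTR isoforms
#'
#' Counts exact seed-motif occurrences in every UTR and combines isoforms
#' of the same gene by taking the maximal count, per miRNA.
#'
#' @param utrs Named character vector of UTR sequences; names carry the
#'   gene and isoform id, parsed with `id_split` (default `"gene|utr"`).
#' @param motifs data.frame from [seed_motif()] (columns `name`,
#'   `motif_dna`).
#' @param id_split Regular expression separating gene from isoform id.
#' @return A list of class `"site_catalog"`: `counts` (integer matrix,
#'   miRNA x gene, max sites per gene) and `genes`.
#' @examples
#' mo <- seed_motif("UGAGGUAGUAGGUUGUAUAGUU", name = "let7")
#' utrs <- c("g1|a" = "AACTACCTCAA", "g1|b" = "AACTACCTCACTACCTCA")
#' gene_site_counts(utrs, mo)$counts
#' @export
gene_site_counts <- function(utrs, motifs, id_split = "\\|") {
  stopifnot(!is.null(names(utrs)), all(nzchar(names(utrs))))
  if (anyDuplicated(names(utrs)))
    stop("duplicate UTR ids", call. = FALSE)
  gene <- vapply(strsplit(names(utrs), id_split),
                 `[[`, character(1L), 1L)
  genes <- unique(gene)
  counts <- matrix(0L, nrow(motifs), length(genes),
                   dimnames = list(motifs$name, genes))
  for (i in seq_len(nrow(motifs))) {
    per_utr <- vapply(utrs, function(u)
      length(scan_sequence(u, motifs$motif_dna[i])), integer(1L))
    counts[i, ] <- vapply(genes, function(g)
      max(per_utr[gene == g]), integer(1L))
  }
  structure(list(counts = counts, genes = genes, motifs = motifs),
            class = "site_catalog")
}

#' Target-site abundance per miRNA
#'
#' The target-site abundance (TSA) of a miRNA is the sum over genes of the
#' gene's mRNA expression multiplied by the maximal number of predicted
#' seed sites in that gene's UTR set — a proxy for the cellular target
#' load competing for the miRNA.
#'
#' @param catalog A `"site_catalog"` from [gene_site_counts()].
#' @param expression Named non-negative numeric vector of mRNA expression
#'   per gene. Genes counted in the catalog but missing here are treated
#'   as 0 with a warning.
#' @return Named numeric vector of TSA values, one per miRNA.
#' @examples
#' mo <- seed_motif("UGAGGUAGUAGGUUGUAUAGUU", name = "let7")
#' cat1 <- gene_site_counts(c("g1|a" = "ACTACCTCCTACCTC"), mo)
#' target_site_abundance(cat1, c(g1 = 10))
#' @export
target_site_abundance <- function(catalog, expression) {
  stopifnot(inherits(catalog, "site_catalog"))
  if (any(expression < 0)) stop("negative expression", call. = FALSE)
  miss <- setdiff(catalog$genes, names(expression))
  if (length(miss)) {
    warning(sprintf("%d gene(s) without expression values; treated as 0",
                    length(miss)))
    expression <- c(expression, setNames(numeric(length(miss)), miss))
  }
  drop(catalog$counts %*% expression[catalog$genes])
}

#' Screen a reporter cloning junction for adventitious seed sites
#'
#' Scans the inserted target sequence together with exactly 6 nt of vector
#' sequence on each side, on the reporter (sense) strand, for the seed
#' motifs of all supplied miRNAs. The additive expression is the sum of
#' mean RPM over the distinct miRNAs with at least one match — each miRNA
#' counted once however many sites it has. The designed miRNA is included
#' by default.
#'
#' @param insert Inserted target sequence (sense strand).
#' @param upstream_flank,downstream_flank Vector sequence flanking the
#'   insert; must be exactly 6 nt unless `strict_flanks = FALSE`.
#' @param motifs data.frame from [seed_motif()] covering all miRNAs to
#'   screen.
#' @param mean_rpm Named numeric vector of mean RPM per miRNA; miRNAs with
#'   a match but no RPM value contribute 0 with a warning.
#' @param designed Name of the miRNA the construct was designed for.
#' @param include_designed Include the designed miRNA in the additive sum.
#' @param strict_flanks Enforce 6-nt flanks.
#' @return A list of class `"junction_report"`: `designed`, `region`
#'   (flank+insert+flank, DNA), `hits` (data.frame: mirna, start — 0-based
#'   in the region), `mirnas` (distinct matching names),
#'   `additive_expression`.
#' @examples
#' mo <- seed_motif(c(a = "UGAGGUAGUAGGUUGUAUAGUU"))
#' junction_scan("TTAACTACCTCATT", "CTCGAG", "GTTTAA", mo,
#'               mean_rpm = c(a = 1000), designed = "a")
#' @export
junction_scan <- function(insert, upstream_flank, downstream_flank,
                          motifs, mean_rpm, designed = NA_character_,
                          include_designed = TRUE, strict_flanks = TRUE) {
  if (strict_flanks &&
      (nchar(upstream_flank) != 6L || nchar(downstream_flank) != 6L))
    stop("flanks must be exactly 6 nt (set strict_flanks = FALSE to override)",
         call. = FALSE)
  region <- canon_dna(paste0(upstream_flank, insert, downstream_flank),
                      what = "junction region")
  hits <- lapply(seq_len(nrow(motifs)), function(i) {
    st <- scan_sequence(region, motifs$motif_dna[i])
    if (!length(st)) return(NULL)
    data.frame(mirna = motifs$name[i], start = st,
               stringsAsFactors = FALSE)
  })
  hits <- if (all(vapply(hits, is.null, logical(1L))))
    data.frame(mirna = character(0), start = integer(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, hits)
  mirnas <- unique(hits$mirna)
  summed <- mirnas
  if (!include_designed && !is.na(designed))
    summed <- setdiff(summed, designed)
  known <- summed %in% names(mean_rpm)
  if (any(!known))
    warning(sprintf("no RPM value for: %s (treated as 0)",
                    paste(summed[!known], collapse = ", ")))
  additive <- sum(mean_rpm[summed[known]])
  structure(list(designed = designed, region = region, hits = hits,
                 mirnas = mirnas, additive_expression = additive),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat(sprintf("Junction scan (designed: %s)\n", x$designed))
  cat(sprintf("  region: %s\n", x$region))
  if (nrow(x$hits) == 0) cat("  no seed sites found\n")
  else {
    cat(sprintf("  %d site(s) for %d miRNA(s): %s\n", nrow(x$hits),
                length(x$mirnas), paste(x$mirnas, collapse = ", ")))
  }
  cat(sprintf("  additive expression: %.4g RPM\n", x$additive_expression))
  invisible(x)
}
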