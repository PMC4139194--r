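# Small-RNA quantification: read-to-mature assignment under a 5'-anchored
# mismatch policy, blacklist filtering, RPM normalisation and guide/star
# arm classification.

#' Match a read against a mature miRNA reference
#'
#' Alignment is anchored at the reference 5' end, gapless. A read is
#' accepted when it carries at most `max_mm_seed17` mismatches within
#' reference positions 1-17; positions 18 to the reference end are
#' unconstrained (isomiR 3' variability). Read positions beyond the
#' reference 3' end are treated as non-templated additions and ignored, up
#' to `max_overhang` nt; longer overhangs reject. Reads shorter than 17 nt
#' reject. T is read as U.
#'
#' @param read Read sequence (character scalar, DNA or RNA).
#' @param ref Mature reference sequence (>= 17 nt).
#' @param max_mm_seed17 Mismatch budget within reference positions 1-17.
#' @param max_overhang Maximum tolerated 3' overhang of the read, nt.
#' @return A list: `accept` (logical), `mismatches` (1-based reference
#'   positions of all mismatches over the compared range), `n_mm_seed17`
#'   (mismatch count within positions 1-17).
#' @examples
#' match_read("UGAGGUAGUAGGUUGUAUAGUU", "UGAGGUAGUAGGUUGUAUAGUU")
#' @export
match_read <- function(read, ref, max_mm_seed17 = 2L, max_overhang = 4L) {
  read <- canon_rna(read, what = "read")
  ref <- canon_rna(ref, what = "reference")
  if (nchar(ref) < 17L)
    stop("reference shorter than 17 nt", call. = FALSE)
  nr <- nchar(read)
  if (nr < 17L)
    return(list(accept = FALSE, mismatches = integer(0),
                n_mm_seed17 = NA_integer_))
  if (nr - nchar(ref) > max_overhang)
    return(list(accept = FALSE, mismatches = integer(0),
                n_mm_seed17 = NA_integer_))
  L <- min(nr, nchar(ref))
  a <- utf8ToInt(substr(read, 1L, L))
  b <- utf8ToInt(substr(ref, 1L, L))
  mm <- which(a != b)
  n17 <- sum(mm <= 17L)
  list(accept = n17 <= max_mm_seed17, mismatches = mm,
       n_mm_seed17 = as.integer(n17))
}

#' Count reads per mature miRNA reference
#'
#' Each read is screened against a blacklist (rejected when it occurs as an
#' exact substring of any blacklist sequence, e.g. rRNA/tRNA), then scored
#' against every reference with [match_read()]. A read accepted by `k`
#' references contributes `1/k` to each under the default `"fractional"`
#' multi-mapping policy, or 1 to each under `"all"`. Counting is performed
#' on the table of unique read sequences, so it is independent of read
#' order.
#'
#' @param reads Character vector of read sequences (one replicate), e.g.
#'   from [read_fasta()] or [gen_reads()].
#' @param refs Named character vector of mature reference sequences, or a
#'   data.frame with columns `name` and `sequence`.
#' @param blacklist Optional character vector of blacklist sequences.
#' @param policy Multi-mapping policy: `"fractional"` or `"all"`.
#' @param ... Passed to [match_read()].
#' @return Named numeric vector of counts, one per reference (zeros kept).
#' @examples
#' refs <- c(miR_a = "UGAGGUAGUAGGUUGUAUAGUU")
#' quantify(rep("UGAGGUAGUAGGUUGUAUAGUU", 10), refs)
#' @export
quantify <- function(reads, refs, blacklist = NULL,
                     policy = c("fractional", "all"), ...) {
  policy <- match.arg(policy)
  if (is.data.frame(refs)) refs <- setNames(refs$sequence, refs$name)
  if (!length(refs)) stop("refs must be non-empty", call. = FALSE)
  refs <- canon_rna(refs, what = "reference")
  counts <- setNames(numeric(length(refs)), names(refs))
  if (!length(reads)) return(counts)
  reads <- canon_rna(reads, what = "read")
  if (!is.null(blacklist) && length(blacklist))
    blacklist <- canon_rna(blacklist, what = "blacklist sequence")
  tab <- table(reads)
  for (i in seq_along(tab)) {
    r <- names(tab)[i]
    if (!is.null(blacklist) &&
        any(vapply(blacklist, function(b) grepl(r, b, fixed = TRUE),
                   logical(1L))))
      next
    hits <- which(vapply(refs, function(f) match_read(r, f, ...)$accept,
                         logical(1L)))
    if (!length(hits)) next
    w <- if (policy == "fractional") tab[[i]] / length(hits) else tab[[i]]
    counts[hits] <- counts[hits] + w
  }
  counts
}

#' Normalise counts to reads per million and summarise replicates
#'
#' RPM is `1e6 * count / denominator`. Under `"mirna_mapped"` (default) the
#' denominator is the per-replicate total of reads assigned to mature
#' miRNAs; under `"genome_mapped"` it is a supplied per-replicate total of
#' genome-mapping reads. Replicates are normalised individually, then
#' averaged.
#'
#' @param counts Named numeric vector (one replicate) or matrix with one
#'   column per replicate and one row per mature miRNA.
#' @param denominator_mode `"mirna_mapped"` or `"genome_mapped"`.
#' @param external_totals Per-replicate genome-mapped totals (required for
#'   `"genome_mapped"`).
#' @return A data.frame of class `"expression_profile"`: raw counts and RPM
#'   per replicate plus `mean_rpm` and `sd_rpm`. Attributes record the
#'   denominator mode and totals.
#' @examples
#' normalize_rpm(cbind(rep1 = c(a = 2, b = 8)))
#' @export
normalize_rpm <- function(counts,
                          denominator_mode = c("mirna_mapped",
                                               "genome_mapped"),
                          external_totals = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1L,
                     dimnames = list(names(counts), "rep1"))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("rep", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("m", seq_len(nrow(counts)))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  totals <- if (denominator_mode == "mirna_mapped") {
    colSums(counts)
  } else {
    if (is.null(external_totals))
      stop("genome_mapped mode requires external_totals", call. = FALSE)
    if (length(external_totals) != ncol(counts))
      stop("external_totals must have one value per replicate",
           call. = FALSE)
    as.numeric(external_totals)
  }
  if (any(totals <= 0))
    stop("denominator total must be positive in every replicate",
         call. = FALSE)
  rpm <- sweep(counts, 2L, totals, "/") * 1e6
  out <- data.frame(name = rownames(counts), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(counts)))
    out[[paste0("raw_", colnames(counts)[j])]] <- counts[, j]
  for (j in seq_len(ncol(rpm)))
    out[[paste0("rpm_", colnames(rpm)[j])]] <- rpm[, j]
  out$mean_rpm <- rowMeans(rpm)
  out$sd_rpm <- apply(rpm, 1L, sd)
  if (ncol(rpm) == 1L) out$sd_rpm <- rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  structure(out,
            denominator_mode = denominator_mode,
            totals = setNames(totals, colnames(counts)),
            class = c("expression_profile", "data.frame"))
}

#' Classify dominant and star arms per hairpin
#'
#' The star (passenger) arm is the less abundant arm of a hairpin, assigned
#' only when the arm abundance ratio strictly exceeds `ratio_threshold`
#' (default 4:1). At or below the threshold neither arm is labelled star.
#' A missing arm is treated as abundance 0 (ratio infinite).
#'
#' @param profile An `"expression_profile"` or a named numeric vector of
#'   mean RPM.
#' @param pairing data.frame with columns `hairpin`, `name_5p`, `name_3p`
#'   (e.g. `panel$hairpin_pairs`).
#' @param ratio_threshold Strict ratio above which the minor arm is star.
#' @return data.frame of class `"arm_calls"`: `hairpin`, `dominant_name`,
#'   `dominant_arm`, `star_name` (NA when no star call), `ratio`.
#' @examples
#' rpm <- c(`syn-mir-1-5p` = 100, `syn-mir-1-3p` = 20)
#' pairing <- data.frame(hairpin = "syn-mir-1", name_5p = "syn-mir-1-5p",
#'                       name_3p = "syn-mir-1-3p")
#' classify_arms(rpm, pairing)
#' @export
classify_arms <- function(profile, pairing, ratio_threshold = 4) {
  rpm <- if (inherits(profile, "expression_profile"))
    setNames(profile$mean_rpm, profile$name) else profile
  stopifnot(is.numeric(rpm), !is.null(names(rpm)))
  stopifnot(all(c("hairpin", "name_5p", "name_3p") %in% names(pairing)))
  get0rpm <- function(nm) if (nm %in% names(rpm)) unname(rpm[[nm]]) else 0
  res <- lapply(seq_len(nrow(pairing)), function(i) {
    r5 <- get0rpm(pairing$name_5p[i])
    r3 <- get0rpm(pairing$name_3p[i])
    hi_is_5p <- r5 >= r3
    hi <- max(r5, r3); lo <- min(r5, r3)
    ratio <- if (lo == 0 && hi == 0) NA_real_ else hi / lo
    star <- !is.na(ratio) && ratio > ratio_threshold
    data.frame(
      hairpin = pairing$hairpin[i],
      dominant_name = if (hi_is_5p) pairing$name_5p[i] else pairing$name_3p[i],
      dominant_arm = if (hi_is_5p) "5p" else "3p",
      star_name = if (star) {
        if (hi_is_5p) pairing$name_3p[i] else pairing$name_5p[i]
      } else NA_character_,
      ratio = ratio,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("arm_calls", "data.frame")
  out
}
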