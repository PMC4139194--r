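# Interchange formats: TSV with '#' comment headers, FASTA/FASTQ via
# Biostrings. Every written table carries the package version and, when a
# config is in play, its hash.

#' Read a tab-separated table
#'
#' Header row required; lines starting with `#` are comments.
#'
#' @param path File path.
#' @param required_cols Optional character vector of columns that must be
#'   present (schema check with a named error).
#' @return data.frame.
#' @export
read_tsv <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    if (length(miss))
      stop(sprintf("%s: missing required column(s): %s", basename(path),
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a tab-separated table with a provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param config Optional configuration list; its hash is stamped into the
#'   header.
#' @param comments Additional comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, config = NULL, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mirepress %s",
                     as.character(packageVersion("mirepress"))), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash %s", config_hash(config)), con)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file (gzip allowed).
#' @param as `"character"` (default) or `"BStringSet"`.
#' @return Named character vector (uppercased) or a Biostrings object.
#' @export
read_fasta <- function(path, as = c("character", "BStringSet")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (as == "BStringSet") return(x)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(!is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(path)
}

#' Read reads from FASTQ
#'
#' @param path FASTQ file (gzip allowed).
#' @return Named character vector of read sequences (DNA alphabet).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Read a raw luciferase plate table
#'
#' Expects columns `construct`, `day`, `renilla`, `firefly` and checks that
#' every day carries an empty-vector record.
#'
#' @param path TSV path.
#' @param empty Empty-vector construct id.
#' @return data.frame of class `"plate_table"`.
#' @export
read_plates <- function(path, empty = "EMPTY") {
  df <- read_tsv(path, required_cols = c("construct", "day", "renilla",
                                         "firefly"))
  miss <- setdiff(unique(df$day), df$day[df$construct == empty])
  if (length(miss))
    stop(sprintf("%s: day(s) without an '%s' record: %s", basename(path),
                 empty, paste(miss, collapse = ", ")), call. = FALSE)
  class(df) <- c("plate_table", "data.frame")
  df
}

#' Read a hairpin-pairing table
#'
#' @param path TSV with columns `hairpin`, `name_5p`, `name_3p`.
#' @return data.frame.
#' @export
read_pairing <- function(path) {
  read_tsv(path, required_cols = c("hairpin", "name_5p", "name_3p"))
}

#' Read a gene expression table
#'
#' @param path TSV with columns `gene`, `expression`.
#' @return Named numeric vector.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path, required_cols = c("gene", "expression"))
  setNames(df$expression, df$gene)
}
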