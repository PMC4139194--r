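# Nearest-neighbour free energy of perfectly paired miRNA:target duplexes,
# and GC content. Reporter target sites are exact reverse complements, so
# the minimum-free-energy structure is the fully paired helix and the
# closed-form sum of stack terms applies; no hybridisation DP is needed.

#' Bundled nearest-neighbour parameter set
#'
#' Watson-Crick RNA/RNA stacking free energies at 37 C (kcal/mol) with
#' helix initiation, duplex symmetry and terminal A:U penalty terms,
#' transcribed from the published Xia/Turner parameter set. Dangling-end
#' terms are omitted.
#'
#' @return A list: `init`, `symmetry`, `terminal_au`, `stack` (named
#'   numeric, keyed by top-strand dinucleotide), `parameter_set` (version
#'   id).
#' @examples
#' nn_parameters()$stack[["GC"]]
#' @export
nn_parameters <- function() {
  if (!is.null(.mirepress_env$nn)) return(.mirepress_env$nn)
  path <- system.file("extdata", "rna_nn_wc_v1.tsv", package = "mirepress",
                      mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stacks <- tab[tab$type == "stack", ]
  pars <- list(
    init = tab$dg[tab$type == "init"],
    symmetry = tab$dg[tab$type == "symmetry"],
    terminal_au = tab$dg[tab$type == "terminal_au"],
    stack = setNames(stacks$dg, stacks$key),
    parameter_set = "xia1998-wc-v1")
  .mirepress_env$nn <- pars
  pars
}

#' Free energy of a perfectly complementary miRNA:target duplex
#'
#' Computes the helix free energy of the mature sequence paired with its
#' exact reverse complement: initiation, the sum of nearest-neighbour
#' stack terms over adjacent base pairs, a penalty per terminal A:U pair,
#' and the symmetry correction for self-complementary duplexes. More
#' negative is more stable.
#'
#' @param mature Character vector of mature miRNA sequences (RNA, >= 2 nt).
#' @param parameters Parameter list from [nn_parameters()].
#' @return data.frame of class `"duplex_score"`: `name`, `delta_g`
#'   (kcal/mol), `gc_fraction`, `parameter_set`.
#' @examples
#' duplex_mfe(c(gc = "GCGCGC", au = "AUAUAU"))
#' @export
duplex_mfe <- function(mature, parameters = nn_parameters()) {
  seqs <- canon_rna(mature, what = "mature sequence")
  if (any(nchar(seqs) < 2L))
    stop("duplex requires length >= 2", call. = FALSE)
  nm <- if (!is.null(names(mature))) names(mature)
        else paste0("m", seq_along(mature))
  dg <- vapply(seqs, function(s) {
    n <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    dinucs <- paste0(chars[-n], chars[-1L])
    g <- parameters$init + sum(parameters$stack[dinucs])
    g <- g + parameters$terminal_au *
      sum(chars[c(1L, n)] %in% c("A", "U"))
    if (identical(s, revcomp_rna(s))) g <- g + parameters$symmetry
    g
  }, numeric(1L), USE.NAMES = FALSE)
  structure(data.frame(name = nm, delta_g = dg,
                       gc_fraction = gc_content(seqs),
                       parameter_set = parameters$parameter_set,
                       stringsAsFactors = FALSE),
            class = c("duplex_score", "data.frame"))
}

#' GC content of nucleotide sequences
#'
#' @param seq Character vector of non-empty DNA/RNA sequences.
#' @return Numeric vector of (G + C) / length, in `[0, 1]`.
#' @examples
#' gc_content(c("GCGC", "AUAU", "GAUC"))
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence", call. = FALSE)
  s <- toupper(seq)
  gc <- nchar(gsub("[^GCgc]", "", s))
  gc / nchar(s)
}
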