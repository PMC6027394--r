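#' Map a template protein onto a target proteome by local alignment
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps, open 11 / extend 1)
#' of the template against every proteome entry, with a Karlin-Altschul
#' E-value (ungapped BLOSUM62 parameters lambda = 0.3176, K = 0.134) on the
#' best raw score: `E = K * m * n * exp(-lambda * S)` with `m` the template
#' length and `n` the summed proteome length. The best hit is returned when
#' its E-value falls below the cutoff. Alternatively, a pre-computed tabular
#' alignment file (12-column BLAST outfmt-6 dialect) can be supplied, in
#' which case the best row per template below the cutoff is used instead of
#' the built-in scan.
#'
#' @param template_name Label for the template (TF or literature gene).
#' @param template_seq Amino-acid sequence (character scalar).
#' @param proteome Named character vector of amino-acid sequences, or a path
#'   to a protein FASTA.
#' @param evalue_max E-value cutoff for reporting a hit.
#' @param alignment_table Optional tibble or path of pre-computed tabular
#'   alignments (columns query, subject, identity, length, mismatches,
#'   gap_opens, qstart, qend, sstart, send, evalue, bitscore).
#' @return A one-row tibble (`template`, `target_gene`, `score`, `e_value`)
#'   or a zero-row tibble when nothing passes the cutoff.
#' @export
map_tf <- function(template_name, template_seq, proteome, evalue_max = 10,
                   alignment_table = NULL) {
  empty <- tibble::tibble(template = character(), target_gene = character(),
                          score = numeric(), e_value = numeric())
  if (!is.null(alignment_table)) {
    tab <- if (is.character(alignment_table))
      readr::read_tsv(alignment_table,
                      col_names = c("query", "subject", "identity", "length",
                                    "mismatches", "gap_opens", "qstart",
                                    "qend", "sstart", "send", "evalue",
                                    "bitscore"),
                      show_col_types = FALSE, progress = FALSE)
    else alignment_table
    tab <- tab[tab$query == template_name & tab$evalue < evalue_max, ]
    if (nrow(tab) == 0L) return(empty)
    best <- tab[order(tab$evalue, -tab$bitscore), ][1, ]
    return(tibble::tibble(template = template_name,
                          target_gene = best$subject,
                          score = best$bitscore, e_value = best$evalue))
  }
  prot <- load_proteome(proteome)
  if (length(prot) == 0L) return(empty)
  scores <- score_against_proteome(template_seq, prot)
  best <- which.max(scores)
  m <- nchar(template_seq)
  n <- sum(nchar(prot))
  e <- karlin_altschul_evalue(scores[best], m, n)
  if (!is.finite(e) || e >= evalue_max) return(empty)
  tibble::tibble(template = template_name, target_gene = names(prot)[best],
                 score = scores[best], e_value = e)
}

load_proteome <- function(proteome) {
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome)) {
    set <- Biostrings::readAAStringSet(proteome)
    prot <- as.character(set)
    names(prot) <- sub("\\s.*$", "", names(set))
    return(prot)
  }
  stopifnot(is.character(proteome))
  if (length(proteome) && is.null(names(proteome))) {
    stop("proteome sequences must be named", call. = FALSE)
  }
  proteome
}

score_against_proteome <- function(template_seq, prot) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  pattern <- Biostrings::AAString(template_seq)
  vapply(prot, function(s) {
    Biostrings::pairwiseAlignment(
      pattern, Biostrings::AAString(s), type = "local",
      substitutionMatrix = data_env$BLOSUM62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }, numeric(1))
}

karlin_altschul_evalue <- function(score, m, n, lambda = 0.3176, K = 0.134) {
  K * m * n * exp(-lambda * score)
}

#' Map a set of template TF proteins onto a proteome
#'
#' Vectorized driver over [map_tf()]; one best hit per template.
#'
#' @param templates Tibble with `name` and `sequence` columns.
#' @param proteome See [map_tf()].
#' @param evalue_max E-value cutoff.
#' @param alignment_table Optional pre-computed alignments (see [map_tf()]).
#' @return Tibble of hits, one row per template that mapped.
#' @export
map_tfs <- function(templates, proteome, evalue_max = 10,
                    alignment_table = NULL) {
  prot <- if (is.null(alignment_table)) load_proteome(proteome) else proteome
  purrr::map2_dfr(templates$name, templates$sequence, function(nm, sq)
    map_tf(nm, sq, prot, evalue_max, alignment_table))
}
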