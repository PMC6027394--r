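#' Extract the upstream promoter region of each operon
#'
#' For every operon, extracts the fixed-length sequence immediately upstream
#' of its translation start: for a `+`-strand operon the `upstream` bases
#' ending just before the first (leftmost) gene's start, read 5'->3' on the
#' plus strand; for a `-`-strand operon the `upstream` bases beginning just
#' after the last (rightmost) gene's end, reverse-complemented so that the
#' 3' end of the returned sequence abuts the translation start. On a circular
#' genome the region may wrap the origin; on a linear genome an insufficient
#' upstream region is truncated and flagged.
#'
#' @param operons Operon tibble from [read_operons()].
#' @param genome A `genome_record`.
#' @param upstream Promoter length in bp (default 300).
#' @return A tibble with `operon_id`, `strand`, `sequence`, `start`, `end`
#'   (1-based inclusive genomic interval of the extracted region; `start` may
#'   exceed `end` when the region wraps the origin), `wraps_origin` and
#'   `truncated`.
#' @export
#' @examples
#' g <- structure(list(id = "g", sequence = "AAACCCGGGTTT", length = 12L,
#'                     circular = TRUE, n_fraction = 0), class = "genome_record")
#' ops <- tibble::tibble(
#'   operon_id = "op1", strand = "+", n_genes = 1L,
#'   first_start = 7L, last_end = 9L,
#'   genes = list(tibble::tibble(locus_tag = "gene1", start = 7L, end = 9L,
#'                               strand = "+")))
#' extract_promoters(ops, g, upstream = 3)$sequence
extract_promoters <- function(operons, genome, upstream = 300L) {
  stopifnot(inherits(genome, "genome_record"))
  upstream <- as.integer(upstream)
  if (upstream < 1L) stop("upstream must be >= 1", call. = FALSE)
  if (upstream > genome$length) {
    stop("upstream length (", upstream, ") exceeds genome length (",
         genome$length, ")", call. = FALSE)
  }
  if (nrow(operons) == 0L) {
    return(tibble::tibble(operon_id = character(), strand = character(),
                          sequence = character(), start = integer(),
                          end = integer(), wraps_origin = logical(),
                          truncated = logical()))
  }
  if (anyDuplicated(operons$operon_id)) {
    stop("duplicate operon ids", call. = FALSE)
  }
  L <- genome$length
  doubled <- paste0(genome$sequence, genome$sequence)
  one <- function(strand, first_start, last_end) {
    if (strand == "+") {
      # positions first_start - upstream .. first_start - 1, possibly < 1
      lo <- first_start - upstream
      hi <- first_start - 1L
      if (lo >= 1L) {
        seq <- substr(genome$sequence, lo, hi)
        return(list(seq = seq, start = lo, end = hi, wraps = FALSE,
                    trunc = FALSE))
      }
      if (genome$circular) {
        start0 <- ((lo - 1L) %% L) + 1L
        seq <- substr(doubled, start0, start0 + upstream - 1L)
        return(list(seq = seq, start = start0,
                    end = ((hi - 1L) %% L) + 1L, wraps = hi >= 1L,
                    trunc = FALSE))
      }
      seq <- substr(genome$sequence, max(lo, 1L), max(hi, 0L))
      list(seq = seq, start = max(lo, 1L), end = max(hi, 0L), wraps = FALSE,
           trunc = TRUE)
    } else {
      # positions last_end + 1 .. last_end + upstream, reverse-complemented
      lo <- last_end + 1L
      hi <- last_end + upstream
      if (hi <= L) {
        seq <- revcomp(substr(genome$sequence, lo, hi))
        return(list(seq = seq, start = lo, end = hi, wraps = FALSE,
                    trunc = FALSE))
      }
      if (genome$circular) {
        start0 <- ((lo - 1L) %% L) + 1L
        seq <- revcomp(substr(doubled, start0, start0 + upstream - 1L))
        return(list(seq = seq, start = start0, end = ((hi - 1L) %% L) + 1L,
                    wraps = lo <= L, trunc = FALSE))
      }
      seq <- revcomp(substr(genome$sequence, min(lo, L + 1L), min(hi, L)))
      list(seq = seq, start = min(lo, L), end = min(hi, L), wraps = FALSE,
           trunc = TRUE)
    }
  }
  parts <- purrr::pmap(
    list(operons$strand, operons$first_start, operons$last_end), one)
  res <- tibble::tibble(
    operon_id = operons$operon_id,
    strand = operons$strand,
    sequence = purrr::map_chr(parts, "seq"),
    start = purrr::map_int(parts, ~ as.integer(.x$start)),
    end = purrr::map_int(parts, ~ as.integer(.x$end)),
    wraps_origin = purrr::map_lgl(parts, "wraps"),
    truncated = purrr::map_lgl(parts, "trunc")
  )
  if (any(res$truncated)) {
    warning(sum(res$truncated),
            " promoter(s) truncated (linear genome, insufficient upstream)",
            call. = FALSE)
  }
  dup <- duplicated(res$sequence) & !res$truncated
  if (any(dup)) {
    message(sum(dup), " duplicate promoter interval(s) (divergent operons)")
  }
  res
}

#' Write promoter intervals as a BED-like TSV
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  readr::write_tsv(
    promoters[, c("operon_id", "start", "end", "strand", "wraps_origin")],
    path, progress = FALSE)
  invisible(path)
}
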