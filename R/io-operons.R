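#' Read an operon table
#'
#' Reads a DOOR2-style tab-separated operon table with columns `operon_id`,
#' `locus_tag`, `start`, `end`, `strand` (1-based inclusive coordinates,
#' strand `+`/`-`). Genes are grouped by operon, sorted by ascending start,
#' and validated against the genome: every operon must be single-stranded and
#' every coordinate in range.
#'
#' @param path Path to the TSV file.
#' @param genome A `genome_record` used for coordinate validation.
#' @return A tibble with one row per operon: `operon_id`, `strand`,
#'   `n_genes`, `first_start`, `last_end`, and a `genes` list-column of
#'   per-gene tibbles (`locus_tag`, `start`, `end`, `strand`).
#' @export
read_operons <- function(path, genome) {
  stopifnot(inherits(genome, "genome_record"))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("operon_id", "locus_tag", "start", "end", "strand")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("operon table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab <- dplyr::mutate(tab,
                       operon_id = as.character(.data$operon_id),
                       locus_tag = as.character(.data$locus_tag),
                       start = as.integer(.data$start),
                       end = as.integer(.data$end))
  if (anyNA(tab$start) || anyNA(tab$end)) {
    stop("non-numeric gene coordinates in operon table", call. = FALSE)
  }
  if (!all(tab$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(tab$start < 1L) || any(tab$end > genome$length) ||
      any(tab$end < tab$start)) {
    bad <- which(tab$start < 1L | tab$end > genome$length | tab$end < tab$start)[1]
    stop("gene coordinates out of range for ", tab$locus_tag[bad],
         " (genome length ", genome$length, "; wrap-around genes not accepted)",
         call. = FALSE)
  }
  if (anyDuplicated(tab$locus_tag)) {
    stop("duplicated locus_tag: ",
         tab$locus_tag[duplicated(tab$locus_tag)][1], call. = FALSE)
  }
  operons <- tab |>
    dplyr::arrange(.data$operon_id, .data$start) |>
    tidyr::nest(genes = c("locus_tag", "start", "end", "strand")) |>
    dplyr::mutate(
      strand = purrr::map_chr(.data$genes, function(g) {
        s <- unique(g$strand)
        if (length(s) != 1L) {
          stop("operon with genes on both strands", call. = FALSE)
        }
        s
      }),
      n_genes = purrr::map_int(.data$genes, nrow),
      first_start = purrr::map_int(.data$genes, ~ min(.x$start)),
      last_end = purrr::map_int(.data$genes, ~ max(.x$end))
    ) |>
    dplyr::select("operon_id", "strand", "n_genes", "first_start",
                  "last_end", "genes")
  operons
}

#' Write an operon table
#'
#' Inverse of [read_operons()]: writes the long per-gene TSV.
#'
#' @param operons Operon tibble from [read_operons()] or the synthetic
#'   generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_operons <- function(operons, path) {
  long <- operons |>
    dplyr::select("operon_id", "genes") |>
    tidyr::unnest("genes") |>
    dplyr::select("operon_id", "locus_tag", "start", "end", "strand")
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

# Flat operon_id -> locus_tag map.
operon_gene_map <- function(operons) {
  operons |>
    dplyr::select("operon_id", "genes") |>
    tidyr::unnest("genes") |>
    dplyr::select("operon_id", "locus_tag")
}
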