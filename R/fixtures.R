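#' Packaged worked-example tables
#'
#' The package ships three small plain-text tables transcribed from the
#' published acid-stress case study in *Lactococcus lactis* MG1363, used as
#' worked-example inputs for the annotation and network stages:
#'
#' * `regulon_tf_table()` — the 14 TFBS-significant regulons with operon
#'   counts, DEG status, template TF and the TF gene mapped in MG1363.
#' * `literature_gene_table()` — the 33 literature-supported acid-stress
#'   genes mapped into MG1363, organized into nine functional modules, with
#'   the regulons each gene hits (`regulons` is parsed into a `regulons_hit`
#'   list-column of regulon names).
#' * `network_curation_table()` — the curated network elements (proton
#'   sensor, global initiator rcfB, transmembrane proteins) that enter the
#'   regulatory network as literature edges rather than computed output.
#'
#' @return A tibble (see above).
#' @name fixtures
NULL

fixture_path <- function(file) {
  system.file("extdata", file, package = "regulonr", mustWork = TRUE)
}

#' @rdname fixtures
#' @export
regulon_tf_table <- function() {
  tab <- readr::read_tsv(fixture_path("table1.tsv"), show_col_types = FALSE,
                         progress = FALSE, na = "NA")
  dplyr::mutate(tab, has_deg = .data$deg == "Y")
}

#' @rdname fixtures
#' @export
literature_gene_table <- function() {
  tab <- readr::read_tsv(fixture_path("table2.tsv"), show_col_types = FALSE,
                         progress = FALSE, na = "NA")
  dplyr::mutate(tab, regulons_hit = purrr::map(.data$regulons, function(r) {
    if (is.na(r)) character() else strsplit(r, ",", fixed = TRUE)[[1]]
  }))
}

#' @rdname fixtures
#' @export
network_curation_table <- function() {
  readr::read_tsv(fixture_path("fig3_curation.tsv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Regulon ids carried by each named regulon in the TF table
#'
#' Several regulons share a mapped TF (e.g. one TF regulating two motif
#' clusters); this helper expands a regulon name (mapped TF gene, template
#' for unmapped entries, or `"Regulon<N>"`) to the numeric regulon ids it
#' covers.
#'
#' @param names Character vector of regulon names.
#' @return Integer vector of regulon ids (unique, sorted).
#' @export
regulon_ids_for_names <- function(names) {
  tab <- regulon_tf_table()
  ids <- purrr::map(names, function(nm) {
    direct <- regmatches(nm, regexec("^Regulon\\s*#?(\\d+)$", nm))[[1]]
    if (length(direct)) return(as.integer(direct[2]))
    hit <- tab$regulon_id[!is.na(tab$mapped_tf_gene) &
                            tab$mapped_tf_gene == nm]
    if (length(hit)) return(hit)
    tab$regulon_id[tab$tf_template == nm]
  })
  sort(unique(unlist(ids, use.names = FALSE)))
}
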