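#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least `k` differentially expressed genes in a
#' regulon of `n` genes drawn from a universe of `N` genes of which `K` are
#' differentially expressed: `P(X >= k)` under Hypergeometric(N, K, n).
#'
#' @param k DEGs in the regulon.
#' @param n Genes in the regulon.
#' @param K DEGs in the universe.
#' @param N Genes in the universe.
#' @return The exact upper-tail probability.
#' @export
#' @examples
#' hypergeom_test(5, 10, 10, 100)
hypergeom_test <- function(k, n, K, N) {
  if (!(n <= N && K <= N && k <= min(n, K) && k >= max(0, n + K - N))) {
    stop("inconsistent hypergeometric counts (k=", k, ", n=", n, ", K=", K,
         ", N=", N, ")", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Sieve verdicts for annotated regulons
#'
#' Applies the regulon filtering rule: a regulon is
#' `computationally_verified` when it both contains at least one
#' differentially expressed gene and has a successfully mapped transcription
#' factor; a TFBS-matched regulon missing either is a `candidate`; a regulon
#' with no significant TFBS match is `excluded`.
#'
#' @param annotated Tibble with columns `regulon_id`, `has_tfbs_match`
#'   (logical), `has_deg` (logical) and `mapped_tf` (character, `NA` when no
#'   TF mapped).
#' @return The input with a `verdict` column; attribute `sieve` holds the
#'   stage counts (total, TFBS-matched, DEG-containing, TF-mapped, verified).
#' @export
regulon_verdicts <- function(annotated) {
  stopifnot(all(c("regulon_id", "has_tfbs_match", "has_deg", "mapped_tf")
                %in% names(annotated)))
  has_tf <- !is.na(annotated$mapped_tf) & annotated$mapped_tf != ""
  verdict <- dplyr::case_when(
    !annotated$has_tfbs_match ~ "excluded",
    annotated$has_deg & has_tf ~ "computationally_verified",
    TRUE ~ "candidate"
  )
  out <- dplyr::mutate(annotated, verdict = verdict)
  attr(out, "sieve") <- c(
    total = nrow(out),
    tfbs_matched = sum(out$has_tfbs_match),
    deg_containing = sum(out$has_tfbs_match & out$has_deg),
    tf_mapped = sum(out$has_tfbs_match & has_tf),
    verified = sum(verdict == "computationally_verified")
  )
  out
}

#' Annotate regulons with TFBS matches, TF mappings, DEGs and enrichment
#'
#' Combines the annotation evidence for every regulon: whether any member
#' motif matched the TFBS library (E below the configured cutoff), the
#' best-matching template TF and its mapping onto the target proteome,
#' whether the regulon's gene set intersects the DEG set, and the
#' hypergeometric enrichment p-value of its DEG count against the clustered
#' gene universe.
#'
#' @param regulons A `regulon_set`.
#' @param tfbs_matches Output of [match_tfbs()].
#' @param tf_mappings Output of [map_tfs()] (template column must match the
#'   library `tf_name`).
#' @param degs A `deg_result`.
#' @param universe Character vector of gene ids forming the enrichment
#'   universe (defaults to the union of regulon gene sets).
#' @return Tibble of class `annotated_regulons` with verdicts and the sieve
#'   attribute of [regulon_verdicts()].
#' @export
annotate_regulons <- function(regulons, tfbs_matches, tf_mappings, degs,
                              universe = NULL) {
  deg_set <- degs$gene_id[degs$direction != "none"]
  if (is.null(universe)) {
    universe <- unique(unlist(regulons$gene_ids, use.names = FALSE))
  }
  deg_universe <- intersect(deg_set, universe)
  best_match <- tfbs_matches |>
    dplyr::group_by(.data$regulon_id) |>
    dplyr::slice_min(.data$e_value, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  ann <- tibble::tibble(
    regulon_id = regulons$regulon_id,
    tier = regulons$tier,
    n_operons = regulons$n_operons,
    n_genes = regulons$n_genes,
    deg_genes = purrr::map(regulons$gene_ids, ~ intersect(.x, deg_set)),
    has_deg = purrr::map_lgl(regulons$gene_ids,
                             ~ length(intersect(.x, deg_set)) > 0),
    tf_template = best_match$tf_name[match(regulons$regulon_id,
                                           best_match$regulon_id)],
    tfbs_evalue = best_match$e_value[match(regulons$regulon_id,
                                           best_match$regulon_id)]
  )
  ann$has_tfbs_match <- !is.na(ann$tf_template)
  ann$mapped_tf <- tf_mappings$target_gene[match(ann$tf_template,
                                                 tf_mappings$template)]
  ann$hypergeom_p <- purrr::map2_dbl(
    regulons$gene_ids, ann$deg_genes,
    function(genes, dg) {
      genes <- intersect(genes, universe)
      if (length(genes) == 0L) return(1)
      hypergeom_test(length(intersect(dg, universe)), length(genes),
                     length(deg_universe), length(universe))
    })
  out <- regulon_verdicts(ann)
  class(out) <- c("annotated_regulons", class(out))
  out
}

#' @export
glance.annotated_regulons <- function(x, ...) {
  tibble::as_tibble(as.list(attr(x, "sieve")))
}

#' Map literature-curated proteins onto the proteome and into regulons
#'
#' Each template protein is mapped with [map_tf()] at the stricter
#' literature E-value cutoff; mapped locus tags are then assigned to every
#' regulon whose gene set contains them.
#'
#' @param literature Tibble with `template_gene`, `template_organism`,
#'   `functional_module`, `sequence`.
#' @param proteome See [map_tf()].
#' @param regulons A `regulon_set`.
#' @param evalue_max Literature mapping cutoff (default 1e-10).
#' @param alignment_table Optional pre-computed alignments.
#' @return Tibble with one row per template: `template_gene`,
#'   `template_organism`, `functional_module`, `mapped_locus_tag` (`NA` when
#'   unmapped) and `regulons_hit` (list-column of regulon ids, possibly
#'   empty).
#' @export
map_literature_genes <- function(literature, proteome, regulons,
                                 evalue_max = 1e-10,
                                 alignment_table = NULL) {
  if (nrow(literature) == 0L) {
    return(tibble::tibble(template_gene = character(),
                          template_organism = character(),
                          functional_module = character(),
                          mapped_locus_tag = character(),
                          regulons_hit = list()))
  }
  hits <- purrr::map2_dfr(
    literature$template_gene, literature$sequence,
    function(nm, sq) {
      h <- map_tf(nm, sq, proteome, evalue_max, alignment_table)
      if (nrow(h) == 0L) {
        tibble::tibble(template = nm, target_gene = NA_character_)
      } else h[, c("template", "target_gene")]
    })
  tibble::tibble(
    template_gene = literature$template_gene,
    template_organism = literature$template_organism,
    functional_module = literature$functional_module,
    mapped_locus_tag = hits$target_gene[match(literature$template_gene,
                                              hits$template)],
    regulons_hit = purrr::map(mapped_locus_tag,
                              function(tag) {
                                if (is.na(tag)) return(integer())
                                regulons$regulon_id[purrr::map_lgl(
                                  regulons$gene_ids, ~ tag %in% .x)]
                              })
  )
}

#' Compare computationally verified and literature-supported regulon sets
#'
#' Reports the false-positive fraction — verified regulons without
#' literature support over all verified regulons — and the
#' insignificant-but-supported fraction — literature-supported regulons
#' among the regulons that never reached TFBS significance (the complement
#' of the significant set). The latter corresponds to what the source data
#' tables describe as a "true negative rate".
#'
#' @param computational Regulon ids verified by the computational sieve.
#' @param literature Regulon ids with literature support.
#' @param significant Regulon ids with a significant TFBS match.
#' @param all_regulons All regulon ids.
#' @return A list with `fp_fraction`, `fp_ids`, `insignificant_supported_fraction`,
#'   `insignificant_supported_ids`, and the component counts.
#' @export
compare_regulon_sets <- function(computational, literature, significant,
                                 all_regulons) {
  stopifnot(all(computational %in% all_regulons),
            all(literature %in% all_regulons),
            all(significant %in% all_regulons))
  fp_ids <- setdiff(computational, literature)
  fp_fraction <- if (length(computational) == 0L) NA_real_ else
    length(fp_ids) / length(computational)
  insig <- setdiff(all_regulons, significant)
  is_ids <- intersect(literature, insig)
  list(
    fp_fraction = fp_fraction,
    fp_ids = fp_ids,
    n_computational = length(computational),
    insignificant_supported_fraction =
      if (length(insig) == 0L) NA_real_ else length(is_ids) / length(insig),
    insignificant_supported_ids = is_ids,
    n_insignificant = length(insig)
  )
}
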