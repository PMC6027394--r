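#' Run the full regulon-discovery pipeline
#'
#' Executes every stage in order: promoter extraction, differential
#' expression, co-expression module construction, per-module motif
#' discovery, motif pooling and similarity clustering into regulons, TFBS /
#' TF / DEG annotation, literature mapping and network assembly. Stages
#' needing optional inputs (TFBS library, proteome, TF templates, literature
#' list) are skipped gracefully when those inputs are `NULL`.
#'
#' @param genome A `genome_record`.
#' @param operons Operon tibble.
#' @param expr An `expression_matrix`.
#' @param config A [regulon_config()]; `t1 >= t2` is validated before any
#'   stage runs.
#' @param tfbs_library Optional TFBS library tibble ([read_motifs_meme()]).
#' @param proteome Optional named character vector or FASTA path.
#' @param tf_templates Optional tibble with `name`, `sequence`.
#' @param literature Optional literature tibble (`template_gene`,
#'   `template_organism`, `functional_module`, `sequence`).
#' @param output_dir Optional directory; when given every intermediate is
#'   written there as TSV/MEME/JSON.
#' @return A list of class `regulon_run` with all stage outputs
#'   (`promoters`, `degs`, `cems`, `motifs`, `edges`, `regulons`,
#'   `tfbs_matches`, `tf_mappings`, `annotated`, `literature_mapped`, `grn`)
#'   and a `report` tibble of per-stage counts.
#' @export
run_pipeline <- function(genome, operons, expr, config = regulon_config(),
                         tfbs_library = NULL, proteome = NULL,
                         tf_templates = NULL, literature = NULL,
                         output_dir = NULL) {
  validate_config(config)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list(config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  save_tsv <- function(df, file) {
    if (!is.null(output_dir)) {
      readr::write_tsv(df, file.path(output_dir, file), progress = FALSE)
    }
  }

  out$promoters <- stage("promoters",
                         extract_promoters(operons, genome, config$upstream))
  save_tsv(out$promoters[, c("operon_id", "start", "end", "strand",
                             "wraps_origin")], "promoters.tsv")

  out$degs <- stage("deg", call_degs(expr, config))
  save_tsv(tidy(out$degs), "deg_table.tsv")

  out$cems <- stage("cems", {
    prof <- operon_profiles(expr, operons)
    build_cems(prof, config)
  })
  if (!is.null(output_dir)) {
    write_cems(out$cems, file.path(output_dir, "cems.tsv"),
               file.path(output_dir, "removed_clusters.log"))
  }

  background <- background_model(genome)
  out$motifs <- stage("motifs", {
    per_cem <- purrr::map2(out$cems$cem_id, out$cems$operon_ids,
                           function(cid, ops) {
      proms <- out$promoters[out$promoters$operon_id %in% ops, ]
      found <- find_motifs(proms, background, config, cem_id = cid)
      top_k_motifs(found, config$top_k)
    })
    pooled <- dplyr::bind_rows(per_cem)
    class(pooled) <- c("motif_set", class(pooled))
    pooled
  })
  if (!is.null(output_dir) && nrow(out$motifs)) {
    write_motifs_meme(out$motifs, file.path(output_dir, "motifs.meme"),
                      background = background)
    save_tsv(tidyr::unnest(out$motifs[, c("motif_id", "sites")], "sites"),
             "motif_sites.tsv")
  }

  out$edges <- stage("cluster", motif_similarity_edges(out$motifs))
  out$regulons <- stage("cluster",
                        assemble_regulons(out$motifs, out$edges, operons,
                                          config))
  if (!is.null(output_dir)) {
    write_regulons(out$regulons, file.path(output_dir, "regulons.tsv"))
  }

  t1_regulons <- out$regulons[out$regulons$tier == "highly_reliable", ]
  out$tfbs_matches <- stage("annotate", {
    if (is.null(tfbs_library)) NULL else
      match_tfbs(t1_regulons, out$motifs, tfbs_library, config)
  })
  out$tf_mappings <- stage("annotate", {
    if (is.null(tf_templates) || is.null(proteome)) NULL else
      map_tfs(tf_templates, proteome)
  })
  out$annotated <- stage("annotate", {
    if (is.null(out$tfbs_matches)) NULL else {
      universe <- unique(operon_gene_map(operons)$locus_tag[
        operon_gene_map(operons)$operon_id %in%
          unlist(out$cems$operon_ids, use.names = FALSE)])
      annotate_regulons(
        t1_regulons, out$tfbs_matches,
        out$tf_mappings %||%
          tibble::tibble(template = character(), target_gene = character()),
        out$degs, universe = universe)
    }
  })
  if (!is.null(out$annotated)) {
    save_tsv(dplyr::select(out$annotated, -"deg_genes"),
             "regulon_verdicts.tsv")
  }

  out$literature_mapped <- stage("literature", {
    if (is.null(literature) || is.null(proteome)) NULL else
      map_literature_genes(literature, proteome, t1_regulons,
                           config$literature_evalue)
  })

  out$grn <- stage("grn", {
    lit_for_grn <- NULL
    if (!is.null(out$literature_mapped)) {
      lit_for_grn <- out$literature_mapped |>
        dplyr::filter(!is.na(.data$mapped_locus_tag)) |>
        dplyr::transmute(
          functional_module = .data$functional_module,
          locus_tag = .data$mapped_locus_tag,
          regulons_hit = purrr::map(.data$regulons_hit,
                                    ~ paste0("Regulon", .x)))
    }
    verified <- NULL
    if (!is.null(out$annotated)) {
      ver <- out$annotated[out$annotated$verdict == "computationally_verified", ]
      if (nrow(ver)) {
        verified <- tibble::tibble(regulon = paste0("Regulon",
                                                    ver$regulon_id),
                                   tf_locus = ver$mapped_tf)
      }
    }
    if (is.null(lit_for_grn) && is.null(verified)) NULL else
      build_grn(lit_for_grn, verified)
  })
  if (!is.null(out$grn) && !is.null(output_dir)) {
    export_network(out$grn, file.path(output_dir, "network.json"), "json")
    export_network(out$grn, file.path(output_dir, "network.graphml"),
                   "graphml")
  }

  sieve <- if (is.null(out$annotated)) NULL else attr(out$annotated, "sieve")
  out$report <- tibble::tibble(
    stage = c("operons", "promoters", "degs_up", "degs_down",
              "cems_kept", "cems_removed_oversize", "cems_singletons",
              "motifs", "regulons_t1", "regulons_t2",
              "tfbs_matched", "deg_containing", "tf_mapped", "verified"),
    count = c(nrow(operons), nrow(out$promoters),
              sum(out$degs$direction == "up"),
              sum(out$degs$direction == "down"),
              nrow(out$cems), length(attr(out$cems, "removed_oversize")),
              length(attr(out$cems, "singletons")),
              nrow(out$motifs),
              sum(out$regulons$tier == "highly_reliable"),
              sum(out$regulons$tier == "relatively_reliable"),
              if (is.null(sieve)) NA_integer_ else sieve[["tfbs_matched"]],
              if (is.null(sieve)) NA_integer_ else sieve[["deg_containing"]],
              if (is.null(sieve)) NA_integer_ else sieve[["tf_mapped"]],
              if (is.null(sieve)) NA_integer_ else sieve[["verified"]])
  )
  save_tsv(out$report, "run_report.tsv")
  class(out) <- "regulon_run"
  out
}

#' @export
print.regulon_run <- function(x, ...) {
  cat("<regulon_run>\n")
  print(x$report, n = Inf)
  invisible(x)
}

#' @export
glance.regulon_run <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "stage", values_from = "count")
}

#' Run the pipeline from input files
#'
#' Thin wrapper around [run_pipeline()] that reads every input from disk
#' (formats as written by [generate_synthetic()]).
#'
#' @param genome_path Genome FASTA.
#' @param operons_path Operon TSV.
#' @param expression_path,design_path Expression matrix and design TSVs.
#' @param tfbs_library_path Optional MEME-minimal TFBS library.
#' @param proteome_path Optional proteome FASTA.
#' @param tf_templates_path Optional TF template FASTA (record names are
#'   template TF names).
#' @param literature_path Optional literature TSV with a `sequence` column.
#' @param config A [regulon_config()].
#' @param output_dir Optional output directory for intermediates.
#' @return A `regulon_run` list.
#' @export
run_all <- function(genome_path, operons_path, expression_path, design_path,
                    tfbs_library_path = NULL, proteome_path = NULL,
                    tf_templates_path = NULL, literature_path = NULL,
                    config = regulon_config(), output_dir = NULL) {
  genome <- read_genome(genome_path)
  operons <- read_operons(operons_path, genome)
  expr <- read_expression(expression_path, design_path, operons)
  tfbs_library <- if (is.null(tfbs_library_path)) NULL else
    read_motifs_meme(tfbs_library_path)
  proteome <- if (is.null(proteome_path)) NULL else
    load_proteome(proteome_path)
  tf_templates <- if (is.null(tf_templates_path)) NULL else {
    set <- Biostrings::readAAStringSet(tf_templates_path)
    tibble::tibble(name = sub("\\s.*$", "", names(set)),
                   sequence = as.character(set))
  }
  literature <- if (is.null(literature_path)) NULL else
    readr::read_tsv(literature_path, show_col_types = FALSE,
                    progress = FALSE)
  run_pipeline(genome, operons, expr, config,
               tfbs_library = tfbs_library, proteome = proteome,
               tf_templates = tf_templates, literature = literature,
               output_dir = output_dir)
}
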