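#' Assemble the typed gene regulatory network
#'
#' Builds a network of typed nodes (`regulon`, `tf_gene`,
#' `functional_module`, `gene`, `transmembrane_protein`, `sensor`) and typed
#' edges (`regulates`, `contains`, `maps_to`, `uncertain`) from three
#' ingredients:
#'
#' * `literature` — one row per mapped gene with `functional_module`,
#'   `locus_tag` and a `regulons_hit` list-column of regulon names; creates
#'   `gene` and `functional_module` nodes, `contains` edges module -> gene,
#'   and `regulates` edges regulon -> module for every regulon hitting a
#'   gene of the module. Modules hit by no regulon are retained as orphans.
#' * `verified` — optional tibble with `regulon` (name) and `tf_locus`
#'   columns; adds regulon nodes and `maps_to` edges to their `tf_gene`
#'   nodes.
#' * `curation` — optional pre-curated node/edge rows (see
#'   [network_curation_table()]), appended as given.
#'
#' @param literature Literature mapping tibble (see above); may be the
#'   packaged [literature_gene_table()] or derived from
#'   [map_literature_genes()].
#' @param verified Optional verified-regulon tibble.
#' @param curation Optional curation tibble.
#' @return An object of class `regulatory_network`: a list with `nodes`
#'   (tibble `id`, `type`) and `edges` (tibble `from`, `to`, `type`,
#'   `provenance`).
#' @export
build_grn <- function(literature, verified = NULL, curation = NULL) {
  nodes <- tibble::tibble(id = character(), type = character())
  edges <- tibble::tibble(from = character(), to = character(),
                          type = character(), provenance = character())
  add_nodes <- function(ids, type) {
    nodes <<- dplyr::bind_rows(nodes, tibble::tibble(id = ids, type = type))
  }
  if (!is.null(literature) && nrow(literature)) {
    stopifnot(all(c("functional_module", "locus_tag", "regulons_hit")
                  %in% names(literature)))
    add_nodes(unique(literature$functional_module), "functional_module")
    add_nodes(unique(literature$locus_tag), "gene")
    reg_names <- unique(unlist(literature$regulons_hit, use.names = FALSE))
    add_nodes(reg_names, "regulon")
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(from = literature$functional_module,
                     to = literature$locus_tag,
                     type = "contains", provenance = "literature"),
      literature |>
        dplyr::select("functional_module", "regulons_hit") |>
        tidyr::unnest_longer("regulons_hit") |>
        dplyr::distinct() |>
        dplyr::transmute(from = .data$regulons_hit,
                         to = .data$functional_module,
                         type = "regulates", provenance = "literature")
    )
  }
  if (!is.null(verified) && nrow(verified)) {
    stopifnot(all(c("regulon", "tf_locus") %in% names(verified)))
    add_nodes(unique(verified$regulon), "regulon")
    with_tf <- verified[!is.na(verified$tf_locus), , drop = FALSE]
    if (nrow(with_tf)) {
      add_nodes(unique(with_tf$tf_locus), "tf_gene")
      edges <- dplyr::bind_rows(
        edges,
        tibble::tibble(from = with_tf$regulon, to = with_tf$tf_locus,
                       type = "maps_to", provenance = "computational"))
    }
  }
  if (!is.null(curation) && nrow(curation)) {
    add_nodes(curation$source, curation$source_type)
    add_nodes(curation$target, curation$target_type)
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(from = curation$source, to = curation$target,
                     type = curation$edge_type,
                     provenance = curation$provenance))
  }
  # first-seen type wins (a locus that is both a mapped gene and a TF stays
  # a gene node); self-loops and duplicate edges dropped
  nodes <- dplyr::distinct(nodes, .data$id, .keep_all = TRUE)
  edges <- dplyr::distinct(edges)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "regulatory_network")
  validate_grn(net)
}

validate_grn <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  missing <- setdiff(c(net$edges$from, net$edges$to), net$nodes$id)
  if (length(missing)) {
    stop("edge references unknown node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  src_type <- net$nodes$type[match(net$edges$from, net$nodes$id)]
  bad <- net$edges$type == "regulates" &
    !src_type %in% c("regulon", "tf_gene", "sensor")
  if (any(bad)) {
    stop("regulates edge from non-regulatory node: ",
         paste(net$edges$from[bad], collapse = ", "), call. = FALSE)
  }
  if (any(net$edges$from == net$edges$to)) {
    stop("self-loop in network", call. = FALSE)
  }
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  print(table(x$nodes$type))
  invisible(x)
}

#' @export
glance.regulatory_network <- function(x, ...) {
  counts <- table(x$nodes$type)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_regulons = as.integer(counts["regulon"] %|NA|% 0L),
    n_modules = as.integer(counts["functional_module"] %|NA|% 0L),
    n_genes = as.integer(counts["gene"] %|NA|% 0L)
  )
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' @export
tidy.regulatory_network <- function(x, ...) tibble::as_tibble(x$edges)

#' Export a regulatory network
#'
#' Formats: `graphml` (via igraph, node/edge type and provenance carried as
#' attributes), `json` (lossless; see [read_network_json()]) and
#' `edge-tsv` (flat edge list with node types joined in).
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"json"`, `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "json", "edge-tsv")) {
  validate_grn(network)
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(
      list(nodes = network$nodes, edges = network$edges), path,
      dataframe = "columns", auto_unbox = TRUE, digits = NA)
  } else {
    types <- stats::setNames(network$nodes$type, network$nodes$id)
    flat <- dplyr::mutate(network$edges,
                          from_type = unname(types[.data$from]),
                          to_type = unname(types[.data$to]))
    readr::write_tsv(flat, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a regulatory network from its JSON export
#'
#' @param path Path written by [export_network()] with `format = "json"`.
#' @return A `regulatory_network`.
#' @export
read_network_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_nodes <- tibble::tibble(id = character(), type = character())
  empty_edges <- tibble::tibble(from = character(), to = character(),
                                type = character(), provenance = character())
  nodes <- if (length(raw$nodes)) tibble::as_tibble(raw$nodes) else empty_nodes
  edges <- if (length(raw$edges)) tibble::as_tibble(raw$edges) else empty_edges
  validate_grn(structure(list(nodes = nodes, edges = edges),
                         class = "regulatory_network"))
}

#' Plot a regulatory network
#'
#' Simple ggplot rendering on an igraph layout, nodes coloured by type and
#' uncertain edges dashed.
#'
#' @param object A `regulatory_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regulatory_network <- function(object, ...) {
  if (nrow(object$nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  g <- igraph::graph_from_data_frame(object$edges, directed = TRUE,
                                     vertices = object$nodes)
  xy <- igraph::layout_with_fr(g)
  nd <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- dplyr::select(nd, "id", "x", "y")
  ed <- object$edges |>
    dplyr::rename(edge_type = "type") |>
    dplyr::left_join(dplyr::rename(pos, x0 = "x", y0 = "y"),
                     by = c(from = "id")) |>
    dplyr::left_join(pos, by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linetype = .data$edge_type),
      colour = "grey50", alpha = 0.6) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type), size = 3) +
    ggplot2::geom_text(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      size = 2.5, vjust = -1) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, linetype = NULL)
}
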