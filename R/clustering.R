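#' Threshold clustering of motifs via Kruskal-style union-find
#'
#' Sorts similarity edges in descending order and merges components with
#' union-find for every edge whose similarity reaches the threshold; the
#' result equals the connected components of the similarity-thresholded
#' graph, so the partition is independent of edge order and tie-breaking.
#'
#' @param motif_ids Character vector of motif ids (the node set).
#' @param edges Tibble with `motif_a`, `motif_b`, `similarity`.
#' @param threshold Minimum similarity for an edge to merge two clusters.
#' @return A tibble with `motif_id` and `cluster` (integer labels numbered by
#'   first appearance in sorted motif-id order).
#' @export
#' @examples
#' e <- tibble::tibble(motif_a = c("a", "b"), motif_b = c("b", "c"),
#'                     similarity = c(0.9, 0.85))
#' kruskal_cluster(c("a", "b", "c", "d"), e, 0.8)
kruskal_cluster <- function(motif_ids, edges, threshold) {
  stopifnot(is.character(motif_ids), !anyDuplicated(motif_ids))
  parent <- seq_along(motif_ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    keep <- edges$similarity >= threshold
    es <- edges[keep, , drop = FALSE]
    es <- es[order(-es$similarity), , drop = FALSE]
    ia <- match(es$motif_a, motif_ids)
    ib <- match(es$motif_b, motif_ids)
    if (anyNA(ia) || anyNA(ib)) {
      stop("edge references a motif id absent from motif_ids", call. = FALSE)
    }
    for (k in seq_len(nrow(es))) {
      ra <- find(ia[k])
      rb <- find(ib[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_along(motif_ids), find, integer(1))
  ord <- order(motif_ids)
  labels <- integer(length(motif_ids))
  next_lab <- 0L
  seen <- integer(0)
  for (i in ord) {
    r <- root[i]
    if (is.na(match(r, seen))) {
      seen <- c(seen, r)
      next_lab <- next_lab + 1L
    }
    labels[i] <- match(r, seen)
  }
  tibble::tibble(motif_id = motif_ids, cluster = labels)
}

#' Assemble regulons from motif clusters at two similarity thresholds
#'
#' Each cluster at the higher threshold `t1` becomes a highly reliable
#' regulon whose operon set is the exact union of its member motifs' site
#' operons (and gene set the union over those operons). Clusters at the lower
#' threshold `t2` that merge two or more `t1` clusters are additionally
#' recorded as relatively reliable regulons referencing their `t1` children.
#' Regulons are renumbered deterministically: highly reliable first, by
#' descending operon count then smallest member motif id, then the relatively
#' reliable merges by the same rule.
#'
#' @param motifs Pooled `motif_set` (with `sites` list-column).
#' @param edges Pairwise similarity edges from [motif_similarity_edges()].
#' @param operons Operon tibble (for the operon-to-gene map).
#' @param config A [regulon_config()] supplying `t1` and `t2`.
#' @return A tibble of class `regulon_set`: `regulon_id`, `tier`
#'   (`"highly_reliable"` or `"relatively_reliable"`), `motif_ids`,
#'   `operon_ids`, `gene_ids`, `source_cems` (list-columns), `n_operons`,
#'   `n_genes`, and `t1_children` (list-column of child regulon ids; empty
#'   for tier-1 regulons).
#' @export
assemble_regulons <- function(motifs, edges, operons,
                              config = regulon_config()) {
  stopifnot(inherits(motifs, "motif_set") || is.data.frame(motifs))
  gmap <- operon_gene_map(operons)
  part1 <- kruskal_cluster(motifs$motif_id, edges, config$t1)
  part2 <- kruskal_cluster(motifs$motif_id, edges, config$t2)

  materialize <- function(member_ids) {
    rows <- match(member_ids, motifs$motif_id)
    ops <- sort(unique(unlist(purrr::map(motifs$sites[rows], "operon_id"),
                              use.names = FALSE)))
    genes <- sort(unique(gmap$locus_tag[gmap$operon_id %in% ops]))
    list(motif_ids = sort(member_ids), operon_ids = ops, gene_ids = genes,
         source_cems = sort(unique(motifs$cem_id[rows])))
  }

  groups1 <- split(part1$motif_id, part1$cluster)
  t1_rows <- purrr::map(groups1, materialize)
  ord1 <- order(-lengths(purrr::map(t1_rows, "operon_ids")),
                vapply(t1_rows, function(r) r$motif_ids[1], character(1)))
  t1_rows <- t1_rows[ord1]

  # T2 clusters that merge several T1 clusters -> relatively reliable regulons
  cluster1_newid <- match(seq_along(groups1), ord1)
  groups2 <- split(part2$motif_id, part2$cluster)
  t2_rows <- purrr::map(groups2, function(ids) {
    children <- sort(unique(cluster1_newid[part1$cluster[
      match(ids, part1$motif_id)]]))
    if (length(children) < 2L) return(NULL)
    c(materialize(ids), list(children = children))
  })
  t2_rows <- purrr::compact(t2_rows)
  if (length(t2_rows)) {
    ord2 <- order(-lengths(purrr::map(t2_rows, "operon_ids")),
                  vapply(t2_rows, function(r) r$motif_ids[1], character(1)))
    t2_rows <- t2_rows[ord2]
  }

  build <- function(rows, tier, id_offset) {
    if (!length(rows)) return(NULL)
    tibble::tibble(
      regulon_id = id_offset + seq_along(rows),
      tier = tier,
      motif_ids = purrr::map(rows, "motif_ids"),
      operon_ids = purrr::map(rows, "operon_ids"),
      gene_ids = purrr::map(rows, "gene_ids"),
      source_cems = purrr::map(rows, "source_cems"),
      n_operons = unname(lengths(purrr::map(rows, "operon_ids"))),
      n_genes = unname(lengths(purrr::map(rows, "gene_ids"))),
      t1_children = purrr::map(rows, ~ .x$children %||% integer())
    )
  }
  proto <- tibble::tibble(
    regulon_id = integer(), tier = character(), motif_ids = list(),
    operon_ids = list(), gene_ids = list(), source_cems = list(),
    n_operons = integer(), n_genes = integer(), t1_children = list())
  out <- dplyr::bind_rows(
    proto,
    build(t1_rows, "highly_reliable", 0L),
    build(t2_rows, "relatively_reliable", length(t1_rows))
  )
  class(out) <- c("regulon_set", class(out))
  out
}

#' @export
glance.regulon_set <- function(x, ...) {
  tibble::tibble(
    n_regulons_t1 = sum(x$tier == "highly_reliable"),
    n_regulons_t2 = sum(x$tier == "relatively_reliable"),
    n_operons_covered = length(unique(unlist(
      x$operon_ids[x$tier == "highly_reliable"])))
  )
}

#' @export
tidy.regulon_set <- function(x, ...) {
  tibble::tibble(
    regulon_id = rep(x$regulon_id, lengths(x$operon_ids)),
    tier = rep(x$tier, lengths(x$operon_ids)),
    operon_id = unlist(x$operon_ids, use.names = FALSE)
  )
}

#' Write regulon membership as TSV
#'
#' @param regulons A `regulon_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulons <- function(regulons, path) {
  flat <- tibble::tibble(
    regulon_id = regulons$regulon_id,
    tier = regulons$tier,
    motif_ids = purrr::map_chr(regulons$motif_ids, paste, collapse = ","),
    operon_ids = purrr::map_chr(regulons$operon_ids, paste, collapse = ","),
    n_operons = regulons$n_operons, n_genes = regulons$n_genes
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
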