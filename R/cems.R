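#' Average gene expression profiles into operon profiles
#'
#' The profile of an operon is the arithmetic mean of its member genes'
#' expression profiles. Operons with no gene present in the matrix are
#' dropped with a message.
#'
#' @param expr An `expression_matrix`.
#' @param operons Operon tibble.
#' @return A numeric matrix (operon x sample) with operon ids as row names.
#' @export
operon_profiles <- function(expr, operons) {
  stopifnot(inherits(expr, "expression_matrix"))
  gmap <- operon_gene_map(operons)
  gmap <- gmap[gmap$locus_tag %in% rownames(expr$values), ]
  if (nrow(gmap) == 0L) stop("no operon gene present in the expression matrix",
                             call. = FALSE)
  kept <- unique(gmap$operon_id)
  dropped <- setdiff(operons$operon_id, kept)
  if (length(dropped)) {
    message(length(dropped), " operon(s) without expressed genes dropped")
  }
  prof <- t(vapply(kept, function(op) {
    rows <- gmap$locus_tag[gmap$operon_id == op]
    colMeans(expr$values[rows, , drop = FALSE])
  }, numeric(ncol(expr$values))))
  rownames(prof) <- kept
  prof[match(intersect(operons$operon_id, kept), rownames(prof)), ,
       drop = FALSE]
}

#' Build co-expression modules (CEMs) from operon profiles
#'
#' Operon profiles are clustered by Euclidean distance with agglomerative
#' hierarchical clustering; the dendrogram is cut at height
#' `h = cut_fraction * max(pairwise distance)`. Clusters larger than
#' `max_cem_size` operons are removed (large clusters tend to aggregate
#' unrelated operons), as are singletons. Surviving modules are renumbered
#' deterministically by descending size, then by the lexicographically
#' smallest member operon id, making the partition invariant to input row
#' order.
#'
#' @param profiles Operon x sample matrix from [operon_profiles()].
#' @param config A [regulon_config()].
#' @return A tibble of class `cem_set`: `cem_id`, `size`, `operon_ids`
#'   (list-column), `profile` (list-column, mean member profile). Attributes
#'   `removed_oversize` (list of operon-id vectors of removed clusters),
#'   `singletons` (character vector) and `cut_height`.
#' @export
build_cems <- function(profiles, config = regulon_config()) {
  if (!is.matrix(profiles) || nrow(profiles) < 2L) {
    stop("need profiles for at least 2 operons", call. = FALSE)
  }
  # deterministic under row permutation: cluster on id-sorted rows
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- stats::dist(profiles, method = "euclidean")
  h <- config$cut_fraction * max(d)
  tree <- stats::hclust(d, method = config$linkage)
  member <- stats::cutree(tree, h = h)
  groups <- split(rownames(profiles), member)
  sizes <- lengths(groups)
  oversize <- groups[sizes > config$max_cem_size]
  singletons <- unlist(groups[sizes == 1L], use.names = FALSE)
  kept <- groups[sizes >= 2L & sizes <= config$max_cem_size]
  if (length(kept)) {
    ord <- order(-lengths(kept),
                 vapply(kept, function(g) sort(g)[1], character(1)))
    kept <- kept[ord]
  }
  out <- tibble::tibble(
    cem_id = sprintf("CEM_%03d", seq_along(kept)),
    size = unname(lengths(kept)),
    operon_ids = purrr::map(kept, ~ sort(unname(.x))),
    profile = purrr::map(kept, function(g)
      colMeans(profiles[g, , drop = FALSE]))
  )
  class(out) <- c("cem_set", class(out))
  attr(out, "removed_oversize") <- unname(oversize)
  attr(out, "singletons") <- if (is.null(singletons)) character() else
    sort(singletons)
  attr(out, "cut_height") <- h
  if (length(oversize)) {
    message(length(oversize), " cluster(s) larger than ", config$max_cem_size,
            " operons removed")
  }
  out
}

#' @export
glance.cem_set <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x),
    n_operons = sum(x$size),
    n_removed_oversize = length(attr(x, "removed_oversize")),
    n_singletons = length(attr(x, "singletons")),
    cut_height = attr(x, "cut_height")
  )
}

#' @export
tidy.cem_set <- function(x, ...) {
  tibble::tibble(cem_id = rep(x$cem_id, x$size),
                 operon_id = unlist(x$operon_ids, use.names = FALSE))
}

#' Bar plot of co-expression module sizes
#'
#' @param object A `cem_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cem_set <- function(object, ...) {
  df <- tibble::tibble(cem_id = factor(object$cem_id, levels = object$cem_id),
                       size = object$size)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cem_id, y = .data$size)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::labs(x = NULL, y = "operons per module") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write CEM membership and removed-cluster log
#'
#' @param cems A `cem_set`.
#' @param path Membership TSV path.
#' @param log_path Optional path for the removed-cluster log.
#' @return `path`, invisibly.
#' @export
write_cems <- function(cems, path, log_path = NULL) {
  readr::write_tsv(tidy(cems), path, progress = FALSE)
  if (!is.null(log_path)) {
    removed <- attr(cems, "removed_oversize")
    lines <- c(
      purrr::imap_chr(removed, ~ sprintf("oversize\t%d\t%s", length(.x),
                                         paste(sort(.x), collapse = ","))),
      sprintf("singleton\t1\t%s", attr(cems, "singletons"))
    )
    writeLines(lines, log_path)
  }
  invisible(path)
}
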