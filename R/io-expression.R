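#' Read a normalized expression matrix with its paired design
#'
#' The expression file is a TSV with a `gene_id` column followed by one
#' numeric column per sample (log-ratio scale, already normalized). The design
#' file is a TSV with columns `sample_id`, `condition` (`control` or
#' `treatment`) and `pair` (replicate index); each pair index must occur
#' exactly once per condition.
#'
#' @param path Expression TSV path.
#' @param design_path Design TSV path.
#' @param operons Optional operon tibble; genes absent from it are retained
#'   but flagged `in_operons = FALSE`.
#' @return A list of class `expression_matrix` with elements `values` (gene x
#'   sample numeric matrix), `design` (tibble), and `genes` (tibble with
#'   `gene_id`, `in_operons`).
#' @export
read_expression <- function(path, design_path, operons = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(tab)) {
    stop("expression table must have a gene_id column", call. = FALSE)
  }
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  validate_design(design)
  sample_ids <- as.character(design$sample_id)
  missing_samp <- setdiff(sample_ids, names(tab))
  if (length(missing_samp)) {
    stop("design sample(s) absent from expression table: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab), c("gene_id", sample_ids))
  if (length(extra)) {
    stop("expression sample(s) absent from design: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  gene_id <- as.character(tab$gene_id)
  if (anyNA(gene_id) || any(gene_id == "")) {
    stop("missing gene ids in expression table", call. = FALSE)
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene id: ", gene_id[duplicated(gene_id)][1], call. = FALSE)
  }
  vals <- as.matrix(tab[, sample_ids, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[sample_ids], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(tab[[sample_ids[bad]]]))))[1]
    stop("non-numeric expression value at row ", badrow, ", column ",
         sample_ids[bad], call. = FALSE)
  }
  if (any(!is.finite(vals))) {
    idx <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at row ", idx[1], ", column ",
         sample_ids[idx[2]], call. = FALSE)
  }
  rownames(vals) <- gene_id
  in_op <- if (is.null(operons)) rep(NA, length(gene_id)) else
    gene_id %in% operon_gene_map(operons)$locus_tag
  structure(
    list(values = vals,
         design = tibble::as_tibble(design),
         genes = tibble::tibble(gene_id = gene_id, in_operons = in_op)),
    class = "expression_matrix"
  )
}

validate_design <- function(design) {
  required <- c("sample_id", "condition", "pair")
  if (!all(required %in% names(design))) {
    stop("design must have columns sample_id, condition, pair", call. = FALSE)
  }
  if (!all(design$condition %in% c("control", "treatment"))) {
    stop("condition must be 'control' or 'treatment'", call. = FALSE)
  }
  counts <- table(design$condition, design$pair)
  if (nrow(counts) != 2L || any(counts != 1L)) {
    stop("unpaired design: each pair index must occur exactly once per condition",
         call. = FALSE)
  }
  invisible(design)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d pairs)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$pair))))
  invisible(x)
}

#' Write an expression matrix and its design
#'
#' @param expr An `expression_matrix`.
#' @param path,design_path Output paths.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, design_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  tab <- tibble::as_tibble(expr$values, rownames = "gene_id")
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(expr$design, design_path, progress = FALSE)
  invisible(path)
}

# Column indices of control/treatment samples ordered by pair index.
paired_columns <- function(expr) {
  d <- expr$design
  d <- d[order(d$pair), ]
  list(
    control = match(d$sample_id[d$condition == "control"],
                    colnames(expr$values)),
    treatment = match(d$sample_id[d$condition == "treatment"],
                      colnames(expr$values)),
    pair = sort(unique(d$pair))
  )
}
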