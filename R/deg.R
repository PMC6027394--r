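#' Call differentially expressed genes
#'
#' Runs the paired Wilcoxon signed-rank test per gene between control and
#' treatment samples. Direction is the sign of the median paired difference;
#' a gene is significant when its raw two-sided p-value falls below
#' `config$deg_alpha` (Benjamini-Hochberg adjusted values are always
#' reported alongside). With `config$paired = FALSE` an unpaired Wilcoxon
#' rank-sum test is used instead.
#'
#' @param expr An `expression_matrix` from [read_expression()] or the
#'   synthetic generator.
#' @param config A [regulon_config()].
#' @return A tibble of class `deg_result` with `gene_id`, `statistic`,
#'   `p_value`, `adjusted_p`, `effect` (median paired difference) and
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
call_degs <- function(expr, config = regulon_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  cols <- paired_columns(expr)
  vals <- expr$values
  if (nrow(vals) == 0L) {
    out <- tibble::tibble(gene_id = character(), statistic = numeric(),
                          p_value = numeric(), adjusted_p = numeric(),
                          effect = numeric(), direction = character())
    class(out) <- c("deg_result", class(out))
    return(out)
  }
  res <- purrr::map(seq_len(nrow(vals)), function(i) {
    ctrl <- vals[i, cols$control]
    trt <- vals[i, cols$treatment]
    if (config$paired) {
      wilcoxon_signed_rank(ctrl, trt)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(trt, ctrl))
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           effect = stats::median(trt) - stats::median(ctrl))
    }
  })
  p <- purrr::map_dbl(res, "p_value")
  eff <- purrr::map_dbl(res, "effect")
  out <- tibble::tibble(
    gene_id = rownames(vals),
    statistic = purrr::map_dbl(res, "statistic"),
    p_value = p,
    adjusted_p = stats::p.adjust(p, method = "BH"),
    effect = eff,
    direction = dplyr::case_when(
      p >= config$deg_alpha | eff == 0 ~ "none",
      eff > 0 ~ "up",
      TRUE ~ "down"
    )
  )
  class(out) <- c("deg_result", class(out))
  out
}

#' @export
glance.deg_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_
  )
}

#' @export
tidy.deg_result <- function(x, ...) tibble::as_tibble(x)

#' Volcano-style plot of differential expression results
#'
#' @param object A `deg_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$effect,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey60")) +
    ggplot2::labs(x = "median paired log-ratio difference",
                  y = expression(-log[10] ~ p), colour = NULL) +
    ggplot2::theme_minimal()
}
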