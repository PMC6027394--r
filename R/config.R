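#' Pipeline configuration
#'
#' Collects every tunable threshold of the regulon-discovery pipeline in one
#' validated list. Defaults are the pipeline's operating values:
#'
#' * `upstream` — promoter length in bp extracted upstream of each operon's
#'   translation start (300).
#' * `motif_width` — fixed cis-regulatory motif width in bp (12).
#' * `top_k` — number of top-ranked significant motifs kept per co-expression
#'   module (5).
#' * `t1`, `t2` — the higher and lower PWM-similarity thresholds producing the
#'   highly reliable (0.8) and relatively reliable (0.6) motif clusters.
#' * `cut_fraction` — dendrogram cut height as a fraction of the maximum
#'   pairwise distance between operon expression profiles (0.05).
#' * `max_cem_size` — co-expression modules larger than this many operons are
#'   discarded as likely false-positive aggregates (200).
#' * `deg_alpha` — raw two-sided significance level for differential
#'   expression (0.05).
#' * `motif_alpha` — Bonferroni-adjusted significance level for reported
#'   motifs (0.001).
#' * `tfbs_evalue` — E-value cutoff for matches against the TFBS library
#'   (0.05).
#' * `literature_evalue` — stricter E-value cutoff for mapping
#'   literature-curated proteins onto the target proteome (1e-10).
#' * `linkage` — agglomeration method for co-expression clustering.
#' * `paired` — whether differential expression uses the paired signed-rank
#'   test (`TRUE`) or the unpaired rank-sum fallback.
#' * `rng_seed` — single seed governing every stochastic stage.
#'
#' @param upstream Promoter length (bp).
#' @param motif_width Motif width (bp).
#' @param top_k Motifs kept per module.
#' @param t1,t2 Similarity thresholds, `0 < t2 <= t1 <= 1`.
#' @param cut_fraction Dendrogram cut fraction in (0, 1).
#' @param max_cem_size Maximum module size (operons).
#' @param deg_alpha,motif_alpha,tfbs_evalue,literature_evalue Significance
#'   thresholds.
#' @param linkage One of `"complete"`, `"average"`, `"single"`.
#' @param paired Logical; paired signed-rank test for DEG calling.
#' @param rng_seed Integer seed.
#' @return A list of class `regulon_config`.
#' @export
#' @examples
#' cfg <- regulon_config(rng_seed = 1)
#' cfg$t1
regulon_config <- function(upstream = 300L,
                           motif_width = 12L,
                           top_k = 5L,
                           t1 = 0.8,
                           t2 = 0.6,
                           cut_fraction = 0.05,
                           max_cem_size = 200L,
                           deg_alpha = 0.05,
                           motif_alpha = 0.001,
                           tfbs_evalue = 0.05,
                           literature_evalue = 1e-10,
                           linkage = c("complete", "average", "single"),
                           paired = TRUE,
                           rng_seed = 1L) {
  linkage <- match.arg(linkage)
  cfg <- list(
    upstream = as.integer(upstream), motif_width = as.integer(motif_width),
    top_k = as.integer(top_k), t1 = t1, t2 = t2,
    cut_fraction = cut_fraction, max_cem_size = as.integer(max_cem_size),
    deg_alpha = deg_alpha, motif_alpha = motif_alpha,
    tfbs_evalue = tfbs_evalue, literature_evalue = literature_evalue,
    linkage = linkage, paired = isTRUE(paired),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "regulon_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "regulon_config"))
  if (cfg$upstream < 1L) stop("upstream must be >= 1", call. = FALSE)
  if (cfg$motif_width < 6L) {
    stop("motif_width must be >= 6 (similarity requires a 6-column overlap)",
         call. = FALSE)
  }
  if (cfg$top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  if (!(cfg$cut_fraction > 0 && cfg$cut_fraction < 1)) {
    stop("cut_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!(cfg$t2 > 0 && cfg$t2 <= cfg$t1 && cfg$t1 <= 1)) {
    stop("similarity thresholds must satisfy 0 < t2 <= t1 <= 1", call. = FALSE)
  }
  for (nm in c("deg_alpha", "motif_alpha", "tfbs_evalue")) {
    if (!(cfg[[nm]] > 0 && cfg[[nm]] <= 1)) {
      stop(nm, " must lie in (0, 1]", call. = FALSE)
    }
  }
  if (cfg$literature_evalue <= 0) stop("literature_evalue must be > 0", call. = FALSE)
  if (cfg$max_cem_size < 2L) stop("max_cem_size must be >= 2", call. = FALSE)
  cfg
}

#' @export
print.regulon_config <- function(x, ...) {
  cat("<regulon_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
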