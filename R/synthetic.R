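#' Synthetic study scenario
#'
#' Parameters of the ground-truthed synthetic data generator. The generator
#' emulates the structure of a paired acid-stress microarray study on a
#' circular bacterial chromosome: co-regulated operon groups sharing a
#' planted promoter motif, a latent per-replicate expression programme per
#' group, and a treatment shift for differentially expressed groups.
#'
#' @param rng_seed Integer seed governing all randomness.
#' @param genome_length Genome size in bp.
#' @param gc_content Genome GC fraction.
#' @param n_regulons Number of planted regulons.
#' @param operons_per_regulon Member operons per planted regulon.
#' @param background_operons Operons belonging to no planted regulon.
#' @param planted_pwm_ic Information content of planted motif columns
#'   (bits/column).
#' @param site_rate Fraction of member promoters carrying a planted site.
#' @param n_pairs Number of control/treatment sample pairs.
#' @param de_effect Log-ratio shift added to treatment samples of
#'   differentially expressed regulons.
#' @param noise_sd Per-gene, per-sample expression noise.
#' @param de_regulon_fraction Fraction of planted regulons that are
#'   differentially expressed.
#' @param latent_sd Spread of the per-pair latent expression programme shared
#'   by an operon group (drives co-expression structure; shared between the
#'   two samples of a pair so it cancels from paired differences).
#' @param n_decoy_tfbs Decoy PWMs added to the TFBS library.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(rng_seed = 1L,
                               genome_length = 200000L,
                               gc_content = 0.35,
                               n_regulons = 10L,
                               operons_per_regulon = 20L,
                               background_operons = 100L,
                               planted_pwm_ic = 1.5,
                               site_rate = 0.9,
                               n_pairs = 8L,
                               de_effect = 2.0,
                               noise_sd = 0.5,
                               de_regulon_fraction = 0.5,
                               latent_sd = 10,
                               n_decoy_tfbs = 20L) {
  sc <- as.list(environment())
  stopifnot(sc$genome_length > 0, sc$n_regulons > 0,
            sc$operons_per_regulon > 0, sc$background_operons >= 0,
            sc$site_rate > 0, sc$site_rate <= 1,
            sc$de_regulon_fraction >= 0, sc$de_regulon_fraction <= 1,
            sc$gc_content > 0, sc$gc_content < 1, sc$n_pairs >= 1,
            sc$noise_sd >= 0, sc$latent_sd >= 0)
  class(sc) <- "synthetic_scenario"
  sc
}

# Sharpen a probability vector to a target information content (bits) by
# exponent tempering (bisection on the exponent); when near-tied maxima keep
# tempering below the target even at the exponent cap, fall back to mixing
# with a point mass on the dominant base.
sharpen_column <- function(p, target_ic) {
  ic <- function(q) 2 + sum(ifelse(q > 0, q * log2(q), 0))
  temper <- function(beta) {
    q <- p^beta
    q / sum(q)
  }
  hi <- 400
  if (ic(temper(hi)) < target_ic) {
    base <- temper(hi)
    point <- numeric(4)
    point[which.max(p)] <- 1
    mix <- function(a) (1 - a) * base + a * point
    lo_a <- 0
    hi_a <- 1
    for (i in 1:60) {
      mid <- (lo_a + hi_a) / 2
      if (ic(mix(mid)) < target_ic) lo_a <- mid else hi_a <- mid
    }
    return(mix((lo_a + hi_a) / 2))
  }
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (ic(temper(mid)) < target_ic) lo <- mid else hi <- mid
  }
  temper((lo + hi) / 2)
}

# Random width-w PWM with the given per-column information content.
sample_planted_pwm <- function(w, ic) {
  pwm <- vapply(seq_len(w), function(j) {
    d <- stats::rgamma(4, shape = 1)
    sharpen_column(d / sum(d), ic)
  }, numeric(4))
  rownames(pwm) <- DNA_BASES
  pwm
}

sample_site <- function(pwm) {
  paste(DNA_BASES[apply(pwm, 2, function(col)
    sample.int(4, 1, prob = col))], collapse = "")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a complete synthetic input set with planted ground truth
#'
#' Produces every input the pipeline consumes — genome, operon table,
#' expression matrix with paired design, TFBS library, proteome, TF template
#' proteins and a literature gene list — together with a ground-truth
#' manifest. Operons are placed non-overlapping with at least 400 bp
#' intergenic gaps; each planted regulon gets a PWM sampled column-wise to
#' the target information content, with sites drawn from the PWM and planted
#' uniformly on either strand within member promoters; expression follows a
#' per-pair latent programme per operon group plus gene-level noise, with the
#' treatment shift added for differentially expressed regulons. All output is
#' deterministic given `scenario$rng_seed`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Optional directory; when given, all inputs are also written as
#'   files (`genome.fa`, `operons.tsv`, `expression.tsv`, `design.tsv`,
#'   `tfbs_library.meme`, `proteome.fa`, `tf_templates.fa`,
#'   `literature.tsv`, `truth.json`).
#' @return A list with `genome`, `operons`, `expr`, `tfbs_library`,
#'   `proteome`, `tf_templates`, `literature`, `truth` and (when `dir` is
#'   given) `paths`.
#' @export
generate_synthetic <- function(scenario = synthetic_scenario(), dir = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$rng_seed, generate_synthetic_impl(scenario, dir))
}

generate_synthetic_impl <- function(sc, dir) {
  L <- sc$genome_length
  w <- 12L
  upstream <- 300L
  base_prob <- c(A = (1 - sc$gc_content) / 2, C = sc$gc_content / 2,
                 G = sc$gc_content / 2, T = (1 - sc$gc_content) / 2)
  genome_chars <- sample(DNA_BASES, L, replace = TRUE, prob = base_prob)

  n_ops <- sc$n_regulons * sc$operons_per_regulon + sc$background_operons
  # place operons left to right with >= 400 bp intergenic gaps
  pos <- 400L
  rows <- vector("list", n_ops)
  for (i in seq_len(n_ops)) {
    n_genes <- sample(1:3, 1, prob = c(0.55, 0.35, 0.10))
    glens <- sample(seq(90L, 150L, by = 3L), n_genes, replace = TRUE)
    gstarts <- pos + cumsum(c(0L, utils::head(glens, -1) + 20L))
    gends <- gstarts + glens - 1L
    strand <- sample(c("+", "-"), 1)
    rows[[i]] <- tibble::tibble(
      operon_id = sprintf("O%04d", i),
      locus_tag = sprintf("g%04d_%d", i, seq_len(n_genes)),
      start = gstarts, end = gends, strand = strand)
    pos <- max(gends) + sample(400:450, 1)
  }
  if (pos > L - 400L) {
    stop("operons do not fit in a ", L, " bp genome; increase genome_length",
         call. = FALSE)
  }
  long <- dplyr::bind_rows(rows)

  # regulon membership: random operons for each regulon, rest background
  op_ids <- sprintf("O%04d", seq_len(n_ops))
  shuffled <- sample(op_ids)
  members <- purrr::map(seq_len(sc$n_regulons), function(r)
    sort(shuffled[((r - 1) * sc$operons_per_regulon + 1):
                    (r * sc$operons_per_regulon)]))
  n_de <- round(sc$n_regulons * sc$de_regulon_fraction)
  de_flags <- seq_len(sc$n_regulons) %in%
    sample.int(sc$n_regulons, n_de)

  # plant motif sites inside member promoters
  op_info <- long |>
    dplyr::group_by(.data$operon_id) |>
    dplyr::summarise(strand = .data$strand[1],
                     first_start = min(.data$start),
                     last_end = max(.data$end), .groups = "drop")
  pwms <- purrr::map(seq_len(sc$n_regulons), function(r)
    sample_planted_pwm(w, sc$planted_pwm_ic))
  sites <- vector("list", sc$n_regulons)
  for (r in seq_len(sc$n_regulons)) {
    site_rows <- purrr::map(members[[r]], function(op) {
      if (stats::runif(1) > sc$site_rate) return(NULL)
      info <- op_info[op_info$operon_id == op, ]
      offset <- sample.int(upstream - w + 1L, 1) - 1L
      site_strand <- sample(c("fwd", "rc"), 1)
      word <- sample_site(pwms[[r]])
      prom_word <- if (site_strand == "fwd") word else revcomp(word)
      if (info$strand == "+") {
        gstart <- info$first_start - upstream + offset
        genome_word <- prom_word
      } else {
        gstart <- info$last_end + upstream - offset - w + 1L
        genome_word <- revcomp(prom_word)
      }
      genome_chars[gstart:(gstart + w - 1L)] <<-
        strsplit(genome_word, "")[[1]]
      tibble::tibble(operon_id = op, offset = offset, strand = site_strand,
                     site = word)
    })
    sites[[r]] <- dplyr::bind_rows(site_rows)
  }

  genome <- structure(
    list(id = "synthetic_chromosome",
         sequence = paste(genome_chars, collapse = ""), length = L,
         circular = TRUE, n_fraction = 0), class = "genome_record")
  operons <- nest_operon_table(long)

  # expression: per-pair latent programme per operon group
  n_pairs <- sc$n_pairs
  latent_reg <- matrix(stats::rnorm(sc$n_regulons * n_pairs, 0, sc$latent_sd),
                       sc$n_regulons, n_pairs)
  background_ids <- setdiff(op_ids, unlist(members))
  latent_bg <- matrix(stats::rnorm(length(background_ids) * n_pairs, 0,
                                   sc$latent_sd),
                      length(background_ids), n_pairs)
  regulon_of_op <- stats::setNames(rep(NA_integer_, n_ops), op_ids)
  for (r in seq_len(sc$n_regulons)) regulon_of_op[members[[r]]] <- r

  genes <- long$locus_tag
  gene_op <- long$operon_id
  vals <- matrix(0, length(genes), 2L * n_pairs)
  ctrl_cols <- seq_len(n_pairs)
  trt_cols <- n_pairs + seq_len(n_pairs)
  true_dir <- stats::setNames(rep("none", length(genes)), genes)
  for (gi in seq_along(genes)) {
    r <- regulon_of_op[[gene_op[gi]]]
    lat <- if (is.na(r)) latent_bg[match(gene_op[gi], background_ids), ]
    else latent_reg[r, ]
    shift <- if (!is.na(r) && de_flags[r]) sc$de_effect else 0
    vals[gi, ctrl_cols] <- lat + stats::rnorm(n_pairs, 0, sc$noise_sd)
    vals[gi, trt_cols] <- lat + shift + stats::rnorm(n_pairs, 0, sc$noise_sd)
    if (shift != 0) true_dir[gi] <- "up"
  }
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(n_pairs)),
                  sprintf("trt_%02d", seq_len(n_pairs)))
  rownames(vals) <- genes
  colnames(vals) <- sample_ids
  design <- tibble::tibble(
    sample_id = sample_ids,
    condition = rep(c("control", "treatment"), each = n_pairs),
    pair = rep(seq_len(n_pairs), 2))
  expr <- structure(list(values = vals, design = design,
                         genes = tibble::tibble(gene_id = genes,
                                                in_operons = TRUE)),
                    class = "expression_matrix")

  # TFBS library: planted PWMs plus decoys
  tf_names <- sprintf("TF%02d", seq_len(sc$n_regulons))
  decoys <- purrr::map(seq_len(sc$n_decoy_tfbs), function(i)
    sample_planted_pwm(w, sc$planted_pwm_ic))
  tfbs_library <- tibble::tibble(
    motif_id = c(sprintf("PLANTED_%02d", seq_len(sc$n_regulons)),
                 sprintf("DECOY_%02d", seq_len(sc$n_decoy_tfbs))),
    tf_name = c(tf_names, sprintf("decoyTF%02d", seq_len(sc$n_decoy_tfbs))),
    organism = "synthetic",
    width = w,
    pwm = c(pwms, decoys))

  # proteome: one protein per gene; TF templates are diverged orthologs of
  # one designated TF gene per regulon
  proteome <- stats::setNames(
    vapply(genes, function(g) random_protein(120L), character(1)), genes)
  tf_locus <- vapply(seq_len(sc$n_regulons), function(r)
    long$locus_tag[match(members[[r]][1], long$operon_id)], character(1))
  tf_templates <- tibble::tibble(
    name = tf_names,
    target_locus = tf_locus,
    sequence = vapply(tf_locus, function(g)
      mutate_protein(proteome[[g]], 0.2), character(1)))

  # literature list: orthologs of member genes of the first three regulons,
  # plus two templates with no counterpart in the proteome
  modules <- c("LDH", "ADI pathway", "Protein repair and protease")
  lit_rows <- purrr::map(seq_len(min(3L, sc$n_regulons)), function(r) {
    ops <- members[[r]][2:3]
    tags <- long$locus_tag[match(ops, long$operon_id)]
    tibble::tibble(
      template_gene = paste0("lit_", tags),
      template_organism = "related_species",
      functional_module = modules[((r - 1) %% 3) + 1],
      sequence = vapply(tags, function(g)
        mutate_protein(proteome[[g]], 0.2), character(1)),
      true_locus = tags)
  })
  literature <- dplyr::bind_rows(
    lit_rows,
    tibble::tibble(template_gene = c("lit_orphan_1", "lit_orphan_2"),
                   template_organism = "related_species",
                   functional_module = "GAD",
                   sequence = c(random_protein(120L), random_protein(120L)),
                   true_locus = NA_character_))

  truth <- list(
    scenario = unclass(sc),
    regulons = purrr::map(seq_len(sc$n_regulons), function(r) list(
      regulon = r, tf_name = tf_names[r], tf_locus = tf_locus[r],
      consensus = pwm_consensus(pwms[[r]]), pwm = pwms[[r]],
      member_operons = members[[r]], de = de_flags[r],
      sites = sites[[r]])),
    background_operons = background_ids,
    true_direction = tibble::tibble(gene_id = genes,
                                    direction = unname(true_dir))
  )

  out <- list(genome = genome, operons = operons, expr = expr,
              tfbs_library = tfbs_library, proteome = proteome,
              tf_templates = tf_templates, literature = literature,
              truth = truth)
  if (!is.null(dir)) {
    out$paths <- write_synthetic(out, dir)
  }
  out
}

nest_operon_table <- function(long) {
  long |>
    dplyr::arrange(.data$operon_id, .data$start) |>
    tidyr::nest(genes = c("locus_tag", "start", "end", "strand")) |>
    dplyr::mutate(
      strand = purrr::map_chr(.data$genes, ~ .x$strand[1]),
      n_genes = purrr::map_int(.data$genes, nrow),
      first_start = purrr::map_int(.data$genes, ~ min(.x$start)),
      last_end = purrr::map_int(.data$genes, ~ max(.x$end))) |>
    dplyr::select("operon_id", "strand", "n_genes", "first_start",
                  "last_end", "genes")
}

write_synthetic <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    operons = file.path(dir, "operons.tsv"),
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    tfbs_library = file.path(dir, "tfbs_library.meme"),
    proteome = file.path(dir, "proteome.fa"),
    tf_templates = file.path(dir, "tf_templates.fa"),
    literature = file.path(dir, "literature.tsv"),
    truth = file.path(dir, "truth.json"))
  write_genome(out$genome, paths$genome)
  write_operons(out$operons, paths$operons)
  write_expression(out$expr, paths$expression, paths$design)
  write_motifs_meme(out$tfbs_library, paths$tfbs_library)
  writeLines(paste0(">", names(out$proteome), "\n", out$proteome),
             paths$proteome)
  writeLines(paste0(">", out$tf_templates$name, "\n",
                    out$tf_templates$sequence), paths$tf_templates)
  readr::write_tsv(out$literature, paths$literature, progress = FALSE)
  truth_json <- out$truth
  truth_json$regulons <- purrr::map(truth_json$regulons, function(r) {
    r$pwm <- apply(r$pwm, 2, as.numeric, simplify = FALSE)
    r
  })
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  paths
}

#' Score recovery of planted regulons
#'
#' Matches each planted regulon to the inferred regulon maximizing the
#' Jaccard index of their operon sets and reports per-regulon Jaccard, the
#' fraction of planted regulons recovered at Jaccard >= 0.5, and the
#' consensus distance between the planted motif and the matched regulon's
#' best motif (minimum over strand orientations and shifts up to 2 columns,
#' counting each shifted-out column as one mismatch).
#'
#' @param truth Ground-truth manifest from [generate_synthetic()].
#' @param regulons Inferred `regulon_set`.
#' @param motifs Optional pooled `motif_set` (enables consensus distances).
#' @return A list with `per_regulon` (tibble) and `recovered_fraction`.
#' @export
evaluate_recovery <- function(truth, regulons, motifs = NULL) {
  inferred <- regulons[regulons$tier == "highly_reliable", , drop = FALSE]
  per <- purrr::map_dfr(truth$regulons, function(tr) {
    if (nrow(inferred) == 0L) {
      return(tibble::tibble(regulon = tr$regulon, matched = NA_integer_,
                            jaccard = 0, consensus_distance = NA_integer_))
    }
    jac <- purrr::map_dbl(inferred$operon_ids, function(ops) {
      u <- length(union(ops, tr$member_operons))
      if (u == 0) return(0)
      length(intersect(ops, tr$member_operons)) / u
    })
    best <- which.max(jac)
    cdist <- NA_integer_
    if (!is.null(motifs) && length(inferred$motif_ids[[best]])) {
      mids <- inferred$motif_ids[[best]]
      rows <- match(mids, motifs$motif_id)
      top <- rows[which.min(motifs$adjusted_p[rows])]
      cdist <- consensus_distance(tr$consensus, motifs$consensus[[top]])
    }
    tibble::tibble(regulon = tr$regulon, matched = inferred$regulon_id[best],
                   jaccard = jac[best], consensus_distance = cdist)
  })
  list(per_regulon = per,
       recovered_fraction = mean(per$jaccard >= 0.5))
}

#' Shift- and strand-tolerant consensus distance
#'
#' Minimum over shifts of at most 2 columns and both orientations of the
#' Hamming distance over the overlap plus the number of shifted-out columns.
#'
#' @param a,b Equal-length consensus strings.
#' @return Integer distance.
#' @export
consensus_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  n <- nchar(a)
  best <- n
  for (bb in c(b, revcomp(b))) {
    for (s in -2:2) {
      a_part <- substr(a, max(1, 1 + s), min(n, n + s))
      b_part <- substr(bb, max(1, 1 - s), min(n, n - s))
      d <- hamming(a_part, b_part) + abs(s)
      if (d < best) best <- d
    }
  }
  best
}
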