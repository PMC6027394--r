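#' Order-0 background model from a genome
#'
#' Base frequencies over the whole genome (both the sequence as given; `N`
#' positions are skipped), floored at 1e-6 and renormalized.
#'
#' @param genome A `genome_record`.
#' @return Named numeric vector of A, C, G, T frequencies summing to 1.
#' @export
background_model <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  counts <- vapply(DNA_BASES, function(b)
    lengths(regmatches(genome$sequence,
                       gregexpr(b, genome$sequence, fixed = TRUE))),
    numeric(1))
  if (sum(counts) == 0) stop("no unambiguous bases in genome", call. = FALSE)
  # floor slightly above the guarantee so renormalization cannot dip below it
  freq <- pmax(counts / sum(counts), 1.01e-6)
  freq / sum(freq)
}

# Expand a set of promoter sequences into the window representation consumed
# by the compiled EM: an integer code matrix over both strands plus parallel
# promoter-index / strand / forward-offset vectors. Windows containing N are
# dropped.
build_windows <- function(sequences, w) {
  per <- purrr::imap(sequences, function(s, i) {
    len <- nchar(s)
    if (len < w) return(NULL)
    n_off <- len - w + 1L
    fwd <- encode_dna(s)
    rc <- encode_dna(revcomp(s))
    idx <- outer(seq_len(n_off) - 1L, seq_len(w), "+")
    fw <- matrix(fwd[idx], nrow = n_off)
    rv <- matrix(rc[idx], nrow = n_off)
    list(
      codes = rbind(fw, rv),
      prom = rep(i - 1L, 2L * n_off),
      strand = rep(c("fwd", "rc"), each = n_off),
      # forward-coordinate offset of the window start within the promoter
      offset = c(seq_len(n_off) - 1L, rev(seq_len(n_off) - 1L))
    )
  })
  per <- purrr::compact(per)
  codes <- do.call(rbind, purrr::map(per, "codes"))
  out <- list(codes = codes,
              prom = unlist(purrr::map(per, "prom"), use.names = FALSE),
              strand = unlist(purrr::map(per, "strand"), use.names = FALSE),
              offset = unlist(purrr::map(per, "offset"), use.names = FALSE))
  keep <- stats::complete.cases(codes)
  if (!all(keep)) {
    out$codes <- out$codes[keep, , drop = FALSE]
    out$prom <- out$prom[keep]
    out$strand <- out$strand[keep]
    out$offset <- out$offset[keep]
  }
  out$codes <- out$codes - 1L            # 0-based codes for C++
  out
}

# Scan both strands of every promoter for width-`seed_width` words; returns
# the per-position word table with canonical (strand-collapsed) forms.
seed_scan <- function(sequences, seed_width = 8L) {
  per <- purrr::imap(sequences, function(s, i) {
    len <- nchar(s)
    if (len < seed_width) return(NULL)
    starts <- seq_len(len - seed_width + 1L)
    tibble::tibble(
      prom = i,
      strand = rep(c("fwd", "rc"), each = length(starts)),
      offset = c(starts, starts),   # 1-based offset within the strand string
      word = c(substring(s, starts, starts + seed_width - 1L),
               substring(revcomp(s), starts, starts + seed_width - 1L)))
  })
  tab <- dplyr::bind_rows(per)
  tab <- tab[!grepl("N", tab$word, fixed = TRUE), , drop = FALSE]
  uw <- unique(tab$word)
  rc_map <- stats::setNames(revcomp(uw), uw)
  tab$canonical <- ifelse(tab$word <= rc_map[tab$word], tab$word,
                          rc_map[tab$word])
  tab
}

# Canonical 8-mer seed counting with Poisson over-representation gate
# against the symmetrized background.
enumerate_seeds <- function(sequences, background, seed_width = 8L,
                            scan = NULL) {
  if (is.null(scan)) scan <- seed_scan(sequences, seed_width)
  n_pos <- nrow(scan)
  # scanning both strands sees every double-stranded occurrence twice;
  # counts and expectations are on the double-stranded (ds) scale
  counts <- ceiling(table(scan$canonical) / 2)
  # symmetrized background: a double-stranded word and its complement are one
  q <- (background + background[c(4, 3, 2, 1)]) / 2
  word_prob <- vapply(names(counts), function(wd)
    prod(q[encode_dna(wd)]), numeric(1))
  expected <- n_pos * word_prob          # word or its rc at any ds position
  thr <- pmax(2, expected + 2 * sqrt(expected))
  keep <- as.integer(counts) >= thr
  tibble::tibble(word = names(counts)[keep],
                 count = as.integer(counts)[keep],
                 expected = expected[keep])
}

# Extend each gate seed to a width-w candidate consensus by majority vote
# over the flanking context of its occurrences (both strands); returns
# unique canonical candidate words.
extend_seed_candidates <- function(sequences, seed_words, scan, w,
                                   seed_width = 8L) {
  pad <- (w - seed_width) %/% 2L
  strands <- list(fwd = sequences, rc = revcomp(sequences))
  hits <- scan[scan$canonical %in% seed_words, , drop = FALSE]
  ctx_of <- function(prom, strand, offset, word, canonical) {
    s <- strands[[strand]][prom]
    lo <- offset - pad
    hi <- offset + seed_width - 1L + (w - seed_width - pad)
    if (lo < 1L || hi > nchar(s)) return(NA_character_)
    ctx <- substr(s, lo, hi)
    if (word != canonical) ctx <- revcomp(ctx)   # orient along the canonical
    ctx
  }
  hits$context <- purrr::pmap_chr(
    hits[, c("prom", "strand", "offset", "word", "canonical")], ctx_of)
  hits <- hits[!is.na(hits$context) & !grepl("N", hits$context, fixed = TRUE), ]
  if (nrow(hits) == 0L) return(character())
  cands <- vapply(split(hits$context, hits$canonical), function(ctxs) {
    mat <- do.call(rbind, strsplit(ctxs, "", fixed = TRUE))
    paste(apply(mat, 2, function(col)
      names(which.max(table(factor(col, levels = DNA_BASES))))),
      collapse = "")
  }, character(1))
  cands <- unname(cands)
  pmin_c <- pmin(cands, revcomp(cands))
  unique(pmin_c)
}

# Conservative per-promoter probability that a background window falls
# within `h` mismatches of `word` (union bound over the windows of one
# promoter, both strands scored with their strand-specific base
# distribution).
near_match_prob <- function(word, background, n_scan, h = 2L) {
  codes <- encode_dna(word)
  one_strand <- function(bg) {
    m <- bg[codes]
    r <- (1 - m) / m
    base <- prod(m)
    s1 <- sum(r)
    s2 <- (s1^2 - sum(r^2)) / 2
    base * (1 + s1 + if (h >= 2) s2 else 0)
  }
  p_fwd <- one_strand(background)
  p_rc <- one_strand(background[c(4, 3, 2, 1)])
  min(1, n_scan * (p_fwd + p_rc))
}

# Initial PWM for a seed word, centred in a width-w matrix with background
# flanks; seed columns put weight 0.7 on the seed base.
seed_pwm <- function(word, w, background) {
  sw <- nchar(word)
  left <- (w - sw) %/% 2L
  pwm <- matrix(background, nrow = 4, ncol = w)
  codes <- encode_dna(word)
  for (j in seq_len(sw)) {
    col <- background * 0.3 / sum(background[-codes[j]])
    col[codes[j]] <- 0.7
    pwm[, left + j] <- col / sum(col)
  }
  rownames(pwm) <- DNA_BASES
  pwm
}

#' De novo fixed-width motif discovery in a promoter set
#'
#' Discovers width-`motif_width` cis-regulatory motifs shared by a set of
#' promoter sequences, scored against a whole-genome order-0 background.
#' The algorithm is deterministic: (1) all canonical (strand-collapsed)
#' 8-mers over-represented versus the background — double-stranded count at
#' least `expected + 2 * sqrt(expected)` under a Poisson model, and at least
#' 2 — are taken as seeds; (2) each seed is extended to a candidate
#' full-width consensus word by majority vote over the flanking context of
#' its occurrences; (3) each candidate's p-value is a conservative binomial
#' upper tail of the number of promoters containing a window within 2
#' mismatches of the candidate on either strand (per-promoter match
#' probability by union bound over windows), Bonferroni-adjusted over all
#' canonical width-w words — the family the data-driven candidate choice
#' implicitly scans, which keeps the test valid despite the candidate being
#' picked from the data; only candidates with adjusted p below
#' `config$motif_alpha` and at least 2 matching promoters continue; (4) each
#' surviving candidate is refined by at most 20 hard-assignment EM passes
#' under a zero-or-one-occurrence-per-promoter model, collecting the best
#' match per promoter on either strand; the reported sites are the
#' significance-optimal subset — the site count whose Poisson tail against
#' the exact background score distribution of the refined PWM (computed by
#' dynamic programming) is smallest, with at least 2 sites — and the motif
#' score is the summed log2 likelihood ratio of those sites versus
#' background; (5) motifs with pairwise similarity above 0.95 are
#' deduplicated (higher score wins). Motifs are returned ranked by adjusted
#' p, then score.
#'
#' @param promoters Tibble with `operon_id` and `sequence` (one CEM's
#'   promoter set, at least 2 rows).
#' @param background Length-4 base frequency vector from
#'   [background_model()].
#' @param config A [regulon_config()].
#' @param cem_id Label used to form motif ids.
#' @return A tibble of class `motif_set`: `motif_id`, `cem_id`, `rank`,
#'   `consensus`, `n_sites`, `score`, `p_value`, `adjusted_p`,
#'   `information_content`, `pwm` (list-column) and `sites` (list-column of
#'   tibbles with `operon_id`, `offset`, `strand`, `sequence`). Attribute
#'   `n_seeds` records the Bonferroni denominator.
#' @export
find_motifs <- function(promoters, background, config = regulon_config(),
                        cem_id = "CEM") {
  stopifnot(is.data.frame(promoters),
            all(c("operon_id", "sequence") %in% names(promoters)))
  if (nrow(promoters) < 2L) {
    stop("motif discovery needs at least 2 promoters", call. = FALSE)
  }
  w <- config$motif_width
  if (any(nchar(promoters$sequence) < w)) {
    stop("promoter shorter than motif width", call. = FALSE)
  }
  bg <- as.numeric(background)
  scan <- seed_scan(promoters$sequence)
  seeds <- enumerate_seeds(promoters$sequence, bg, scan = scan)
  n_seeds <- nrow(seeds)
  if (n_seeds == 0L) return(empty_motif_set(n_seeds))
  win <- build_windows(promoters$sequence, w)
  n_prom <- nrow(promoters)
  win_per_prom <- tabulate(win$prom + 1L, nbins = n_prom)
  n_scan <- max(nchar(promoters$sequence)) - w + 1L

  # Each gate seed is extended to a candidate width-w consensus by majority
  # vote over its occurrence contexts. Significance is selection-bias free:
  # the statistic is the number of promoters containing a window within 2
  # mismatches of the candidate word, its null distribution a conservative
  # binomial (union bound within each promoter), Bonferroni-corrected over
  # every canonical width-w word — the family the data-driven candidate
  # choice implicitly scans.
  n_tests <- (4^w + 4^(w / 2)) / 2
  cand_words <- extend_seed_candidates(promoters$sequence, seeds$word, scan, w)
  if (length(cand_words) == 0L) return(empty_motif_set(n_seeds))
  cand_stats <- purrr::map_dfr(cand_words, function(cw) {
    codes <- encode_dna(cw) - 1L
    k <- cpp_near_match_promoters(win$codes, win$prom, n_prom, codes, 2L)
    pi0 <- near_match_prob(cw, bg, n_scan)
    p <- stats::pbinom(k - 1L, n_prom, pi0, lower.tail = FALSE)
    tibble::tibble(word = cw, k = k, p_value = p,
                   adjusted_p = min(1, p * n_tests))
  })
  cand_stats <- cand_stats[cand_stats$adjusted_p < config$motif_alpha &
                             cand_stats$k >= 2L, , drop = FALSE]
  if (nrow(cand_stats) == 0L) return(empty_motif_set(n_seeds))
  cand_stats <- cand_stats[order(cand_stats$adjusted_p, -cand_stats$k), ,
                           drop = FALSE]

  cand <- purrr::pmap(cand_stats, function(word, k, p_value, adjusted_p) {
    fit <- cpp_zoops_em(win$codes, win$prom, n_prom,
                        seed_pwm(word, w, bg), bg,
                        pseudo = 1, max_iter = 20L, tol = 1e-4)
    if (fit$n_sites < 2L) return(NULL)
    idx <- fit$site_window[!is.na(fit$site_window)]
    site_scores <- cpp_score_windows(win$codes[idx, , drop = FALSE],
                                     fit$pwm, bg)
    ord_sc <- order(-site_scores)
    s_sorted <- site_scores[ord_sc]
    # reported sites: the largest site count that is still collectively
    # non-random — the Poisson tail of observing >= j promoters whose best
    # window reaches the j-th site score (exact background score
    # distribution of the refined PWM) must stay below 0.01; background
    # windows enter this ranking with tail probabilities near their rank,
    # so the rule stops at the score elbow
    p0 <- cpp_score_tail_multi(fit$pwm, bg, s_sorted - 1e-9, 0.01)
    lambda <- vapply(pmin(p0, 1), function(q)
      sum(1 - (1 - q)^win_per_prom), numeric(1))
    pj <- stats::ppois(seq_along(s_sorted) - 1L, lambda, lower.tail = FALSE)
    good <- which(pj < 0.01 & seq_along(pj) >= 2L)
    j_star <- if (length(good)) max(good) else 2L
    keep_idx <- idx[ord_sc[seq_len(j_star)]]
    list(pwm = fit$pwm, site_window = keep_idx,
         score = sum(s_sorted[seq_len(j_star)]),
         n_sites = j_star, p_value = p_value, adjusted_p = adjusted_p)
  })
  cand <- purrr::compact(cand)
  if (!length(cand)) return(empty_motif_set(n_seeds))

  # deduplicate near-identical motifs, keeping the higher-scoring one
  ord <- order(purrr::map_dbl(cand, "adjusted_p"),
               -purrr::map_dbl(cand, "score"))
  cand <- cand[ord]
  kept <- list()
  for (m in cand) {
    dup <- any(purrr::map_lgl(kept, function(k)
      pwm_similarity(k$pwm, m$pwm)$similarity > 0.95))
    if (!dup) kept[[length(kept) + 1L]] <- m
  }

  rows <- purrr::imap(kept, function(m, i) {
    idx <- m$site_window[!is.na(m$site_window)]
    sites <- tibble::tibble(
      operon_id = promoters$operon_id[win$prom[idx] + 1L],
      offset = win$offset[idx],
      strand = win$strand[idx],
      sequence = vapply(idx, function(k)
        decode_dna(win$codes[k, ] + 1L), character(1))
    )
    rownames(m$pwm) <- DNA_BASES
    tibble::tibble(
      motif_id = sprintf("%s_M%02d", cem_id, i),
      cem_id = cem_id, rank = i,
      consensus = pwm_consensus(m$pwm),
      n_sites = m$n_sites, score = m$score,
      p_value = m$p_value, adjusted_p = m$adjusted_p,
      information_content = pwm_information(m$pwm),
      pwm = list(m$pwm), sites = list(sites)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("motif_set", class(out))
  attr(out, "n_seeds") <- n_seeds
  out
}

empty_motif_set <- function(n_seeds = 0L) {
  out <- tibble::tibble(
    motif_id = character(), cem_id = character(), rank = integer(),
    consensus = character(), n_sites = integer(), score = numeric(),
    p_value = numeric(), adjusted_p = numeric(),
    information_content = numeric(), pwm = list(), sites = list())
  class(out) <- c("motif_set", class(out))
  attr(out, "n_seeds") <- n_seeds
  out
}

#' Keep the top-k ranked motifs
#'
#' @param motifs A ranked `motif_set`.
#' @param k Number of motifs to keep (fewer is permitted).
#' @return The first `min(k, nrow(motifs))` rows.
#' @export
top_k_motifs <- function(motifs, k = 5L) {
  if (nrow(motifs) < k) {
    message("only ", nrow(motifs), " significant motif(s) available (k = ",
            k, ")")
  }
  out <- utils::head(motifs, k)
  class(out) <- unique(c("motif_set", class(out)))
  attr(out, "n_seeds") <- attr(motifs, "n_seeds")
  out
}

#' @export
glance.motif_set <- function(x, ...) {
  tibble::tibble(n_motifs = nrow(x),
                 n_seeds = attr(x, "n_seeds") %||% NA_integer_,
                 best_adjusted_p = if (nrow(x)) min(x$adjusted_p) else NA_real_)
}

#' @export
tidy.motif_set <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"pwm", -"sites")
}

#' Sequence-logo style tile plot of a PWM
#'
#' @param pwm A 4 x w column-stochastic matrix.
#' @return A ggplot object.
#' @export
plot_pwm <- function(pwm) {
  check_pwm(pwm)
  df <- tidyr::expand_grid(base = DNA_BASES, position = seq_len(ncol(pwm)))
  df$probability <- purrr::map2_dbl(match(df$base, DNA_BASES), df$position,
                                    ~ pwm[.x, .y])
  df$base <- factor(df$base, levels = rev(DNA_BASES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c3e50",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "motif position", y = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
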