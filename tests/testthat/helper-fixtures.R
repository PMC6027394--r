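# Shared in-code fixtures for the test suite.

# Minimal genome_record from a raw sequence string.
toy_genome <- function(seq, circular = TRUE, id = "toy") {
  structure(list(id = id, sequence = seq, length = nchar(seq),
                 circular = circular, n_fraction = 0),
            class = "genome_record")
}

# One-row-per-gene operon tibble from a compact spec list:
# list(list(id, strand, starts, ends), ...)
toy_operons <- function(spec) {
  long <- dplyr::bind_rows(purrr::imap(spec, function(op, i) {
    tibble::tibble(operon_id = op$id,
                   locus_tag = paste0(op$id, "_g", seq_along(op$starts)),
                   start = as.integer(op$starts), end = as.integer(op$ends),
                   strand = op$strand)
  }))
  regulonr:::nest_operon_table(long)
}

# i.i.d. background promoter sequences at the study GC content.
toy_bg_freq <- c(A = 0.325, C = 0.175, G = 0.175, T = 0.325)

random_promoters <- function(n, len = 300, bg = toy_bg_freq) {
  vapply(seq_len(n), function(i)
    paste(sample(names(bg), len, replace = TRUE, prob = bg), collapse = ""),
    character(1))
}

# Plant a sampled site from `pwm` into `frac` of the promoters (both strands).
plant_sites <- function(seqs, pwm, frac = 0.9) {
  w <- ncol(pwm)
  n_carry <- round(length(seqs) * frac)
  for (i in seq_len(n_carry)) {
    site <- regulonr:::sample_site(pwm)
    o <- sample.int(nchar(seqs[i]) - w + 1L, 1)
    substr(seqs[i], o, o + w - 1L) <-
      if (stats::runif(1) < 0.5) site else revcomp(site)
  }
  seqs
}

# Deterministic column-stochastic PWM concentrated on the given word.
word_pwm <- function(word, dominant = 0.97) {
  codes <- regulonr:::encode_dna(word)
  pwm <- matrix((1 - dominant) / 3, 4, length(codes))
  for (j in seq_along(codes)) pwm[codes[j], j] <- dominant
  rownames(pwm) <- c("A", "C", "G", "T")
  pwm
}

# Tiny expression_matrix with n_pairs paired samples.
toy_expression <- function(values, n_pairs) {
  sample_ids <- c(sprintf("c%02d", seq_len(n_pairs)),
                  sprintf("t%02d", seq_len(n_pairs)))
  colnames(values) <- sample_ids
  design <- tibble::tibble(
    sample_id = sample_ids,
    condition = rep(c("control", "treatment"), each = n_pairs),
    pair = rep(seq_len(n_pairs), 2))
  structure(list(values = values, design = design,
                 genes = tibble::tibble(gene_id = rownames(values),
                                        in_operons = TRUE)),
            class = "expression_matrix")
}

# Brute-force two-sided signed-rank p by enumerating all 2^n sign vectors.
brute_signed_rank <- function(control, treatment) {
  d <- treatment - control
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                      mean(w_all >= w_obs - 1e-9)))
  list(statistic = w_obs, p_value = p)
}

# Brute-force hypergeometric upper tail by direct summation.
brute_hyper <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force connected components of a thresholded similarity graph.
brute_components <- function(ids, edges, threshold) {
  adj <- matrix(FALSE, length(ids), length(ids),
                dimnames = list(ids, ids))
  keep <- edges[edges$similarity >= threshold, , drop = FALSE]
  if (nrow(keep)) {
    for (k in seq_len(nrow(keep))) {
      adj[keep$motif_a[k], keep$motif_b[k]] <- TRUE
      adj[keep$motif_b[k], keep$motif_a[k]] <- TRUE
    }
  }
  comp <- seq_along(ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
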