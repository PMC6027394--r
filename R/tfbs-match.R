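# Column-similarity tables between a query PWM and a library PWM, used to
# evaluate many column permutations of the query cheaply.
column_sim_tables <- function(query, lib) {
  one <- function(libmat) {
    outer(seq_len(ncol(query)), seq_len(ncol(libmat)),
          Vectorize(function(i, j)
            1 - sqrt(sum((query[, i] - libmat[, j])^2)) / sqrt(2)))
  }
  list(fwd = one(lib), rc = one(revcomp_pwm(lib)))
}

# Best-alignment similarity from precomputed column tables, for the identity
# permutation or any permutation of query columns.
sim_from_tables <- function(tabs, perm = NULL) {
  wq <- nrow(tabs$fwd)
  wl <- ncol(tabs$fwd)
  min_overlap <- min(6L, wq, wl)
  best <- -Inf
  for (orientation in c("fwd", "rc")) {
    S <- tabs[[orientation]]
    if (!is.null(perm)) S <- S[perm, , drop = FALSE]
    for (off in seq(-(wl - min_overlap), wq - min_overlap)) {
      q_cols <- max(1L, 1L + off):min(wq, wl + off)
      s <- mean(S[cbind(q_cols, q_cols - off)])
      if (s > best) best <- s
    }
  }
  min(1, max(0, best))
}

#' Match regulon motifs against a TFBS library
#'
#' Compares every member motif of every regulon against every library entry
#' using [pwm_similarity()], and assigns an E-value from a column-shuffle
#' null: the observed similarity is ranked within `n_shuffle` column-permuted
#' variants of the query PWM scored against the same library entry, giving
#' `p = (1 + #null >= observed) / (n_shuffle + 1)` and
#' `E = p * library size`. Only pairs with `E < config$tfbs_evalue` are
#' reported.
#'
#' @param regulons A `regulon_set`.
#' @param motifs The pooled `motif_set` the regulons were assembled from.
#' @param library TFBS library tibble from [read_motifs_meme()] (columns
#'   `motif_id`, `tf_name`, `organism`, `pwm`).
#' @param config A [regulon_config()].
#' @param n_shuffle Null sample size.
#' @return A tibble with `regulon_id`, `query_motif_id`, `library_motif_id`,
#'   `tf_name`, `organism`, `similarity`, `p_value`, `e_value`, sorted by
#'   `e_value` within regulon.
#' @export
match_tfbs <- function(regulons, motifs, library,
                       config = regulon_config(), n_shuffle = 1000L) {
  empty <- tibble::tibble(regulon_id = integer(), query_motif_id = character(),
                          library_motif_id = character(), tf_name = character(),
                          organism = character(), similarity = numeric(),
                          p_value = numeric(), e_value = numeric())
  if (is.null(library) || nrow(library) == 0L) {
    warning("empty TFBS library; no matches computed", call. = FALSE)
    return(empty)
  }
  lib_size <- nrow(library)
  queries <- tibble::tibble(
    regulon_id = rep(regulons$regulon_id, lengths(regulons$motif_ids)),
    motif_id = unlist(regulons$motif_ids, use.names = FALSE)
  )
  queries <- queries[queries$motif_id %in% motifs$motif_id, ]
  rows <- purrr::pmap(queries, function(regulon_id, motif_id) {
    query <- motifs$pwm[[match(motif_id, motifs$motif_id)]]
    wq <- ncol(query)
    seed <- derive_seed(config$rng_seed, paste0("tfbs:", motif_id))
    perms <- with_seed(seed, t(replicate(n_shuffle, sample.int(wq))))
    hits <- purrr::map_dfr(seq_len(lib_size), function(li) {
      tabs <- column_sim_tables(query, library$pwm[[li]])
      obs <- sim_from_tables(tabs)
      # sequential null: once the exceedances already guarantee
      # E >= cutoff, further shuffles cannot make the pair reportable
      exceed <- 0L
      done <- 0L
      block <- 100L
      while (done < n_shuffle) {
        take <- seq.int(done + 1L, min(done + block, n_shuffle))
        exceed <- exceed + sum(vapply(take, function(r)
          sim_from_tables(tabs, perms[r, ]), numeric(1)) >= obs)
        done <- done + length(take)
        if ((1 + exceed) / (n_shuffle + 1) * lib_size >= config$tfbs_evalue)
          break
      }
      p <- (1 + exceed) / (n_shuffle + 1)
      if (done < n_shuffle) p <- max(p, (1 + exceed) / (done + 1))
      tibble::tibble(regulon_id = regulon_id, query_motif_id = motif_id,
                     library_motif_id = library$motif_id[li],
                     tf_name = library$tf_name[li],
                     organism = library$organism[li],
                     similarity = obs, p_value = p,
                     e_value = p * lib_size)
    })
    hits[hits$e_value < config$tfbs_evalue, ]
  })
  out <- dplyr::bind_rows(empty, rows)
  dplyr::arrange(out, .data$regulon_id, .data$e_value, .data$library_motif_id)
}
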