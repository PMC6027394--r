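#' Similarity between two position weight matrices
#'
#' Symmetric similarity in `[0, 1]`. For every relative offset with at least a
#' 6-column overlap, and for both orientations (the second PWM as given and
#' reverse-complemented), the candidate similarity is the mean over aligned
#' column pairs of `1 - ||a_c - b_c||_2 / sqrt(2)`; the reported similarity is
#' the maximum. Identical PWMs score exactly 1; maximally different
#' deterministic columns (e.g. all-A vs all-C) score 0 column-wise.
#'
#' @param a,b 4 x w column-stochastic matrices (each at least 6 columns
#'   wide).
#' @return A list with `similarity`, `best_offset` (columns by which `b` is
#'   shifted right relative to `a`) and `orientation` (`"fwd"` or `"rc"`).
#' @export
#' @examples
#' pwm <- matrix(0.25, 4, 12)
#' pwm_similarity(pwm, pwm)$similarity
pwm_similarity <- function(a, b) {
  check_pwm(a)
  check_pwm(b)
  wa <- ncol(a)
  wb <- ncol(b)
  min_overlap <- 6L
  if (wa < min_overlap || wb < min_overlap) {
    stop("PWM narrower than the minimum 6-column overlap", call. = FALSE)
  }
  best <- list(similarity = -Inf, best_offset = 0L, orientation = "fwd")
  for (orientation in c("fwd", "rc")) {
    bb <- if (orientation == "rc") revcomp_pwm(b) else b
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      a_cols <- max(1L, 1L + off):min(wa, wb + off)
      b_cols <- a_cols - off
      colsim <- vapply(seq_along(a_cols), function(k) {
        1 - sqrt(sum((a[, a_cols[k]] - bb[, b_cols[k]])^2)) / sqrt(2)
      }, numeric(1))
      s <- mean(colsim)
      if (s > best$similarity) {
        best <- list(similarity = s, best_offset = as.integer(off),
                     orientation = orientation)
      }
    }
  }
  best$similarity <- min(1, max(0, best$similarity))
  best
}

#' All pairwise similarity edges among a set of motifs
#'
#' @param motifs A `motif_set` (pooled across modules).
#' @return A tibble with `motif_a`, `motif_b`, `similarity`, `best_offset`,
#'   `orientation`, one row per unordered pair.
#' @export
motif_similarity_edges <- function(motifs) {
  n <- nrow(motifs)
  if (n < 2L) {
    return(tibble::tibble(motif_a = character(), motif_b = character(),
                          similarity = numeric(), best_offset = integer(),
                          orientation = character()))
  }
  pairs <- utils::combn(n, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    s <- pwm_similarity(motifs$pwm[[i]], motifs$pwm[[j]])
    tibble::tibble(motif_a = motifs$motif_id[i], motif_b = motifs$motif_id[j],
                   similarity = s$similarity, best_offset = s$best_offset,
                   orientation = s$orientation)
  })
}
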