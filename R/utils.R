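DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Plain-character reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Encode a DNA string as integer codes A=1 C=2 G=3 T=4 (N and others -> NA).
encode_dna <- function(x) {
  m <- match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES)
  m
}

decode_dna <- function(codes) paste(DNA_BASES[codes], collapse = "")

#' Convert genomic coordinates between disk and memory conventions
#'
#' On disk, intervals are 1-based inclusive (GenBank/DOOR2 convention); in
#' memory they are 0-based half-open. The conversion is involutive:
#' `to_disk(to_memory(x)) == x`.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
to_memory_coords <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = start - 1L, end = end)
}

#' @rdname to_memory_coords
#' @export
to_disk_coords <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = start + 1L, end = end)
}

# Reverse-complement a 4 x w column-stochastic PWM: reverse columns, swap A<->T, C<->G.
revcomp_pwm <- function(pwm) {
  pwm[c(4, 3, 2, 1), ncol(pwm):1, drop = FALSE]
}

# Consensus string of a PWM (ties broken by alphabet order).
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm, 2, which.max)], collapse = "")
}

# Information content of a PWM in bits, optionally relative to uniform background.
pwm_information <- function(pwm) {
  p <- pmax(pwm, 1e-12)
  sum(p * log2(p)) + 2 * ncol(pwm)
}

check_pwm <- function(pwm, tol = 1e-9) {
  if (!is.matrix(pwm) || nrow(pwm) != 4) {
    stop("PWM must be a 4-row matrix (rows A, C, G, T)", call. = FALSE)
  }
  if (any(abs(colSums(pwm) - 1) > tol)) {
    stop("PWM columns must each sum to 1 (tolerance ", tol, ")", call. = FALSE)
  }
  invisible(pwm)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Run code with a local RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit seed from a base seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
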