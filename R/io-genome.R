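#' Read a bacterial genome from FASTA
#'
#' Reads a single-replicon genome sequence. The sequence is uppercased; if the
#' file holds several records the first is used with a warning (plasmids and
#' secondary replicons are out of scope). Only `A`, `C`, `G`, `T` and `N` are
#' accepted; the `N` fraction is recorded and all-`N` sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical; bacterial chromosomes are circular by default.
#' @return An object of class `genome_record`: a list with `id`, `sequence`
#'   (character scalar), `length`, `circular` and `n_fraction`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr", "acgtACGT"), fa)
#' g <- read_genome(fa)
#' g$length
read_genome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path, call. = FALSE)
  # read as raw strings: the DNA reader silently drops invalid letters,
  # which would defeat the alphabet validation below
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path, call. = FALSE)
  if (length(set) > 1L) {
    warning("FASTA has ", length(set), " records; using the first (",
            names(set)[1], ")", call. = FALSE)
  }
  seq <- toupper(as.character(set[[1]]))
  id <- sub("\\s.*$", "", names(set)[1])
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0) {
    stop("illegal character '", substr(seq, bad, bad), "' at position ", bad,
         " in genome sequence", call. = FALSE)
  }
  if (nchar(seq) < 1L) stop("empty genome sequence", call. = FALSE)
  n_frac <- lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE))) / nchar(seq)
  if (n_frac >= 1) stop("genome sequence is entirely N", call. = FALSE)
  structure(
    list(id = id, sequence = seq, length = nchar(seq),
         circular = isTRUE(circular), n_fraction = unname(n_frac)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, N fraction %.3g\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", x$n_fraction))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_record`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_record"))
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
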