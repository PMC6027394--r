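#' Write motifs in MEME-minimal format
#'
#' Writes a motif tibble (one row per motif, `pwm` list-column of 4 x w
#' column-stochastic matrices) as a MEME-minimal text file: a version line, an
#' alphabet line, background letter frequencies, and one
#' `letter-probability matrix` block per motif. A `# organism:` comment line
#' is emitted when an `organism` column is present, so TF library metadata
#' round-trips.
#'
#' @param motifs Tibble with at least `motif_id` and `pwm` columns; optional
#'   `tf_name`, `organism`, `n_sites`, `e_value`.
#' @param path Output path.
#' @param background Numeric length-4 vector of background frequencies.
#' @return `path`, invisibly.
#' @export
write_motifs_meme <- function(motifs, path, background = rep(0.25, 4)) {
  stopifnot(is.data.frame(motifs), "motif_id" %in% names(motifs),
            "pwm" %in% names(motifs))
  purrr::walk(motifs$pwm, check_pwm, tol = 1e-6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", background[1],
                       background[2], background[3], background[4]), ""), con)
  for (i in seq_len(nrow(motifs))) {
    pwm <- motifs$pwm[[i]]
    alt <- if ("tf_name" %in% names(motifs) && !is.na(motifs$tf_name[i]))
      paste0(" ", motifs$tf_name[i]) else ""
    writeLines(sprintf("MOTIF %s%s", motifs$motif_id[i], alt), con)
    if ("organism" %in% names(motifs) && !is.na(motifs$organism[i])) {
      writeLines(sprintf("# organism: %s", motifs$organism[i]), con)
    }
    nsites <- if ("n_sites" %in% names(motifs)) motifs$n_sites[i] else 20L
    ev <- if ("e_value" %in% names(motifs) && !is.na(motifs$e_value[i]))
      motifs$e_value[i] else 0
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
      ncol(pwm), nsites, ev), con)
    writeLines(apply(pwm, 2, function(col)
      paste(sprintf("%.10f", col), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME-minimal file
#'
#' Counterpart of [write_motifs_meme()]; also accepts count (non-stochastic)
#' matrices, which are normalized column-wise on read.
#'
#' @param path Path to a MEME-minimal text file.
#' @return A tibble with `motif_id`, `tf_name`, `organism`, `width`, `n_sites`,
#'   `e_value` and a `pwm` list-column.
#' @export
read_motifs_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME-minimal file (no version line): ", path, call. = FALSE)
  }
  bg_idx <- grep("^Background letter frequencies", lines)
  background <- rep(0.25, 4)
  if (length(bg_idx)) {
    toks <- strsplit(trimws(lines[bg_idx[1] + 1]), "\\s+")[[1]]
    background <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  motif_starts <- grep("^MOTIF\\s", lines)
  out <- purrr::map(motif_starts, function(i) {
    header <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    motif_id <- header[2]
    tf_name <- if (length(header) >= 3) header[3] else NA_character_
    organism <- NA_character_
    j <- i + 1
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) {
      if (grepl("^# organism:", lines[j])) {
        organism <- trimws(sub("^# organism:", "", lines[j]))
      }
      j <- j + 1
    }
    if (j > length(lines)) stop("MOTIF ", motif_id,
                                " has no letter-probability matrix", call. = FALSE)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    nsites <- suppressWarnings(
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[j])))
    ev <- suppressWarnings(as.numeric(sub(".*E=\\s*(\\S+).*", "\\1", lines[j])))
    rows <- lines[(j + 1):(j + w)]
    mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4)))
    if (anyNA(mat)) stop("malformed matrix row in MOTIF ", motif_id, call. = FALSE)
    pwm <- t(mat)                       # 4 x w
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    rownames(pwm) <- DNA_BASES
    if (w < 4) stop("MOTIF ", motif_id, " narrower than 4 columns", call. = FALSE)
    tibble::tibble(motif_id = motif_id, tf_name = tf_name, organism = organism,
                   width = w, n_sites = nsites, e_value = ev, pwm = list(pwm))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "background") <- background
  res
}
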