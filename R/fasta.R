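#' Read a (multi-)FASTA genome
#'
#' Reads plain or gzip-compressed FASTA (compression is detected from the
#' gzip magic bytes, so the file extension does not matter). Sequence names
#' are the first whitespace-delimited token of each header; descriptions are
#' discarded. Lowercase bases are uppercased and any character outside
#' `{A,C,G,T,N}` is mapped to `N`. Multi-line sequences are concatenated, so
#' the result is insensitive to line wrapping.
#'
#' @param source Path to a FASTA file, or a readable connection.
#' @return A tibble with one row per record and columns `name` (character),
#'   `seq` (character, uppercase over `{A,C,G,T,N}`) and `length` (integer).
#' @details Malformed input — an empty file, text before the first `>`
#'   header, or a record with an empty sequence — raises an error naming the
#'   offending line number.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a description", "acgt", "ACGT", ">s2", "NNN"), f)
#' read_fasta(f)
read_fasta <- function(source) {
  if (is.character(source)) {
    # gzfile() reads both gzip-compressed and plain text transparently
    con <- gzfile(source, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
  } else {
    lines <- readLines(source, warn = FALSE)
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    abort("malformed FASTA: empty input (line 1)", class = "seedchain_malformed_input")
  }
  is_header <- startsWith(lines, ">")
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!is_header[first_content]) {
    abort(sprintf("malformed FASTA: text before first '>' header (line %d)", first_content),
          class = "seedchain_malformed_input")
  }
  hdr_idx <- which(is_header)
  names <- sub("\\s.*$", "", substring(lines[hdr_idx], 2))
  if (any(!nzchar(names))) {
    bad <- hdr_idx[!nzchar(names)][1]
    abort(sprintf("malformed FASTA: empty sequence name (line %d)", bad),
          class = "seedchain_malformed_input")
  }
  # group sequence lines by the preceding header
  grp <- cumsum(is_header)
  seq_lines <- !is_header & nzchar(lines)
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[seq_lines & grp == i], collapse = "")
  }, character(1))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(sprintf("malformed FASTA: record '%s' has an empty sequence (line %d)",
                  names[which(empty)[1]], hdr_idx[which(empty)[1]]),
          class = "seedchain_malformed_input")
  }
  seqs <- toupper(seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  tibble(name = names, seq = seqs, length = nchar(seqs))
}

#' Write a genome tibble as FASTA
#'
#' @param genome A tibble with columns `name` and `seq` (as returned by
#'   [read_fasta()] or [random_genome()]).
#' @param path Output file path or writable connection.
#' @param width Sequence line width (default 60).
#' @return Invisibly, `genome`.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  lines <- unlist(lapply(seq_len(nrow(genome)), function(i) {
    s <- genome$seq[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    c(paste0(">", genome$name[i]),
      substring(s, starts, pmin(starts + width - 1L, n)))
  }))
  writeLines(lines, path)
  invisible(genome)
}
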