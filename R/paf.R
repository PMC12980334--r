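#' PAF record tibbles
#'
#' Alignment records use the 12 mandatory PAF columns plus a `tags`
#' list-column. All coordinates are 0-based, half-open — the single
#' convention used throughout the package. Tags are stored verbatim as
#' `TAG:TYPE:VALUE` strings and keep their insertion order on output.
#'
#' @param qname,tname Query/target sequence names.
#' @param qlen,tlen Query/target sequence lengths (bases).
#' @param qstart,qend,tstart,tend 0-based half-open alignment intervals.
#' @param strand `"+"` or `"-"`.
#' @param nmatch Number of matching residues.
#' @param alnlen Alignment block length (total CIGAR columns).
#' @param mapq Mapping quality in `[0, 255]`.
#' @param tags List of character vectors of `TAG:TYPE:VALUE` strings.
#' @return A tibble with one row per record.
#' @export
paf_tibble <- function(qname = character(), qlen = integer(),
                       qstart = integer(), qend = integer(),
                       strand = character(), tname = character(),
                       tlen = integer(), tstart = integer(), tend = integer(),
                       nmatch = integer(), alnlen = integer(),
                       mapq = integer(), tags = list()) {
  tibble(qname = as.character(qname), qlen = as.integer(qlen),
         qstart = as.integer(qstart), qend = as.integer(qend),
         strand = as.character(strand), tname = as.character(tname),
         tlen = as.integer(tlen), tstart = as.integer(tstart),
         tend = as.integer(tend), nmatch = as.integer(nmatch),
         alnlen = as.integer(alnlen), mapq = as.integer(mapq),
         tags = tags)
}

validate_paf <- function(records) {
  ok <- records$qstart >= 0 & records$qstart < records$qend &
    records$qend <= records$qlen &
    records$tstart >= 0 & records$tstart < records$tend &
    records$tend <= records$tlen &
    records$nmatch <= records$alnlen &
    records$mapq >= 0 & records$mapq <= 255 &
    records$strand %in% c("+", "-")
  if (any(!ok)) {
    i <- which(!ok)[1]
    abort(sprintf("PAF record %d ('%s' vs '%s') violates an invariant",
                  i, records$qname[i], records$tname[i]),
          class = "seedchain_internal_error")
  }
  invisible(records)
}

paf_lines <- function(records) {
  if (nrow(records) == 0) return(character())
  tagstr <- vapply(records$tags, function(t) {
    if (length(t) == 0) "" else paste0("\t", paste(t, collapse = "\t"))
  }, character(1))
  paste0(records$qname, "\t", records$qlen, "\t", records$qstart, "\t",
         records$qend, "\t", records$strand, "\t", records$tname, "\t",
         records$tlen, "\t", records$tstart, "\t", records$tend, "\t",
         records$nmatch, "\t", records$alnlen, "\t", records$mapq, tagstr)
}

#' Write alignment records in PAF format
#'
#' One tab-separated line per record: the 12 mandatory PAF columns followed
#' by the record's tags in insertion order. Output order equals input order.
#'
#' @param records A PAF tibble (see [paf_tibble()]).
#' @param sink Output path or writable connection.
#' @return Invisibly, `records`.
#' @export
write_paf <- function(records, sink) {
  validate_paf(records)
  writeLines(paf_lines(records), sink)
  invisible(records)
}

#' Parse PAF text into a record tibble
#'
#' Inverse of [write_paf()] on its image. Unknown tags are preserved
#' verbatim. Lines with fewer than 12 columns, or with non-integer values in
#' a numeric column, raise a malformed-input error.
#'
#' @param source Path, connection, or character vector of PAF lines.
#' @return A PAF tibble.
#' @export
parse_paf <- function(source) {
  lines <- if (is.character(source) && length(source) > 1) source
  else if (is.character(source) && !file.exists(source)) source
  else readLines(source, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(paf_tibble())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(sprintf("malformed PAF: line %d has %d < 12 columns",
                  which(nf < 12)[1], nf[which(nf < 12)[1]]),
          class = "seedchain_malformed_input")
  }
  int_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  ints <- lapply(int_cols, function(i) {
    v <- suppressWarnings(as.integer(get(i)))
    if (anyNA(v)) {
      abort(sprintf("malformed PAF: non-integer value in column %d (line %d)",
                    i, which(is.na(v))[1]),
            class = "seedchain_malformed_input")
    }
    v
  })
  paf_tibble(qname = get(1), qlen = ints[[1]], qstart = ints[[2]],
             qend = ints[[3]], strand = get(5), tname = get(6),
             tlen = ints[[4]], tstart = ints[[5]], tend = ints[[6]],
             nmatch = ints[[7]], alnlen = ints[[8]], mapq = ints[[9]],
             tags = lapply(fields, function(f) if (length(f) > 12) f[13:length(f)] else character()))
}
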