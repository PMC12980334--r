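#' @importFrom generics glance tidy
#' @export
generics::glance

#' @export
generics::tidy

#' One-row summary of a genome alignment
#'
#' @param x A `genome_alignment` tibble from [align_genomes()].
#' @param ... Unused.
#' @return A one-row tibble: record counts, primary/secondary split, total
#'   aligned query bases (primary records) and mean per-record identity
#'   (`nmatch / alnlen`).
#' @method glance genome_alignment
#' @export
glance.genome_alignment <- function(x, ...) {
  prim <- vapply(x$tags, function(t) any(t == "tp:A:P"), logical(1))
  tibble(n_records = nrow(x),
         n_primary = sum(prim),
         n_secondary = sum(!prim),
         query_bases_aligned = sum(x$qend[prim] - x$qstart[prim]),
         mean_identity = if (nrow(x) == 0) NA_real_ else
           mean(x$nmatch / x$alnlen))
}

#' Flatten a genome alignment to a plain tibble
#'
#' Drops the `tags` list-column and adds a `tp` column (`"P"`/`"S"`)
#' extracted from the `tp:A:` tag.
#'
#' @param x A `genome_alignment` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy genome_alignment
#' @export
tidy.genome_alignment <- function(x, ...) {
  out <- x[setdiff(names(x), "tags")]
  out$tp <- vapply(x$tags, function(t) {
    hit <- grep("^tp:A:", t, value = TRUE)
    if (length(hit)) sub("^tp:A:", "", hit[1]) else NA_character_
  }, character(1))
  as_tibble(out)
}

#' Alignment dot plot
#'
#' Draws each PAF record as a diagonal segment in query x target space,
#' faceted by sequence pair, with strand mapped to colour and secondary
#' records drawn thinner.
#'
#' @param object A `genome_alignment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genome_alignment
#' @export
autoplot.genome_alignment <- function(object, ...) {
  d <- tidy(object)
  d$y_start <- ifelse(d$strand == "+", d$tstart, d$tend)
  d$y_end <- ifelse(d$strand == "+", d$tend, d$tstart)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$qstart, xend = .data$qend,
      y = .data$y_start, yend = .data$y_end,
      colour = .data$strand, linewidth = .data$tp == "P")) +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                    labels = c(`TRUE` = "primary", `FALSE` = "secondary"),
                                    name = NULL) +
    ggplot2::facet_grid(.data$tname ~ .data$qname) +
    ggplot2::labs(x = "query position (bp)", y = "target position (bp)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
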