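#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_segment geom_point
#'   geom_hline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot strand-specific 5'-end counts of a pileup
#'
#' Forward 5'-end counts point up, reverse 5'-end counts down; vertical
#' pileups of read ends mark in vitro cleavage positions.
#'
#' @param object An `end_pileup`.
#' @param region Optional `c(start, end)` zoom.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot end_pileup
#' @export
autoplot.end_pileup <- function(object, region = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(region))
    d <- dplyr::filter(d, .data$pos >= region[1], .data$pos < region[2])
  d <- dplyr::filter(d, .data$F > 0 | .data$R > 0)
  ggplot(d, aes(x = .data$pos)) +
    geom_segment(aes(xend = .data$pos, y = 0, yend = .data$F),
                 colour = "#2166AC") +
    geom_segment(aes(xend = .data$pos, y = 0, yend = -.data$R),
                 colour = "#B2182B") +
    labs(x = "position (bp)", y = "5'-end count (+F / -R)",
         title = attr(object, "contig")) +
    theme_minimal()
}

#' Plot called cleavage sites along the genome
#'
#' @param object A `cleavage_calls` tibble.
#' @param ... Unused.
#' @return A ggplot (lollipop of scores by position, faceted by contig).
#' @method autoplot cleavage_calls
#' @export
autoplot.cleavage_calls <- function(object, ...) {
  params <- attr(object, "params")
  d <- as_tibble(unclass_keep_tbl(object))
  p <- ggplot(d, aes(x = .data$cut_position, y = .data$score)) +
    geom_segment(aes(xend = .data$cut_position, y = 0, yend = .data$score),
                 colour = "grey50") +
    geom_point(aes(colour = factor(.data$best_overhang)), size = 2) +
    labs(x = "position (bp)", y = "cleavage score",
         colour = "overhang (nt)") +
    theme_minimal()
  if (!is.null(params))
    p <- p + geom_hline(yintercept = params$cutoff, linetype = "dashed")
  if (length(unique(d$contig)) > 1) p <- p + facet_wrap(~contig)
  p
}

#' Plot ranked mutant patterns of an amplicon
#'
#' @param object An `indel_summary`.
#' @param top Number of top patterns to show.
#' @param ... Unused.
#' @return A ggplot (bar chart, filled by frame class).
#' @method autoplot indel_summary
#' @export
autoplot.indel_summary <- function(object, top = 10, ...) {
  d <- utils::head(object$patterns, top)
  d$signature <- factor(d$signature, levels = rev(d$signature))
  ggplot(d, aes(x = .data$count, y = .data$signature, fill = .data$frame)) +
    geom_col() +
    labs(x = "reads", y = NULL, fill = NULL) +
    theme_minimal()
}
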