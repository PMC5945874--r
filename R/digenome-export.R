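#' Export cleavage calls as BED
#'
#' One line per call, 0-based half-open (`cut_position`, `cut_position+1`).
#' Column 5 carries the score capped at 1000 per BED convention; the raw
#' score is column 7 and the best overhang column 8.
#'
#' @param calls A `cleavage_calls` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_sites <- function(calls, path) {
  lines <- "track name=cleavage_sites description=\"called in vitro cleavage sites\""
  if (nrow(calls)) {
    name <- sprintf("site_%s_%d", calls$contig, calls$cut_position)
    lines <- c(lines, sprintf(
      "%s\t%d\t%d\t%s\t%d\t.\t%.6g\t%d",
      calls$contig, calls$cut_position, calls$cut_position + 1L, name,
      as.integer(round(pmin(calls$score, 1000))), calls$score,
      calls$best_overhang))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a BED file written by [export_sites()]
#' @param path BED path.
#' @return Tibble with contig, cut_position, score, best_overhang.
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines))
    return(tibble(contig = character(0), cut_position = integer(0),
                  score = numeric(0), best_overhang = integer(0)))
  d <- readr::read_tsv(I(lines), col_names = c(
    "contig", "start", "end", "name", "score5", "strand", "score",
    "best_overhang"), show_col_types = FALSE)
  tibble(contig = d$contig, cut_position = as.integer(d$start),
         score = d$score, best_overhang = as.integer(d$best_overhang))
}

#' Export a per-position score track as bedGraph
#'
#' @param scores Tibble with contig, cut_position, score (e.g. all scored
#'   positions or calls).
#' @param path Output path.
#' @param floor Only positions with score >= floor are written.
#' @return The path, invisibly.
#' @export
export_track <- function(scores, path, floor = 0.1) {
  keep <- scores$score >= floor
  lines <- "track type=bedGraph name=cleavage_score"
  if (any(keep)) {
    d <- scores[keep, , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.6g", d$contig, d$cut_position,
                              d$cut_position + 1L, d$score))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a bedGraph written by [export_track()]
#' @param path bedGraph path.
#' @return Tibble with contig, cut_position, score.
#' @export
read_track_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines))
    return(tibble(contig = character(0), cut_position = integer(0),
                  score = numeric(0)))
  d <- readr::read_tsv(I(lines), col_names = c("contig", "start", "end",
                                               "score"),
                       show_col_types = FALSE)
  tibble(contig = d$contig, cut_position = as.integer(d$start),
         score = d$score)
}
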