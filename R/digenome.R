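#' Cleavage-scoring parameters
#'
#' Defaults model a Cpf1-style staggered cut leaving 5' overhangs of 1-5 nt
#' and use the conventional score cutoff of 2.5.
#'
#' @param overhang_min,overhang_max Overhang sweep bounds in nt.
#' @param cutoff Score at or above which a position is called.
#' @param min_support Minimum supporting 5'-end reads per strand.
#' @param merge_distance Calls within this many bp collapse to the
#'   highest-scoring representative.
#' @param score_fun Scoring function, see [cleavage_score_default()];
#'   pluggable so alternative published score variants can be swapped in.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(overhang_min = 1, overhang_max = 5, cutoff = 2.5,
                           min_support = 3, merge_distance = 10,
                           score_fun = cleavage_score_default) {
  if (overhang_min < 1 || overhang_min > overhang_max)
    abort("need 1 <= overhang_min <= overhang_max")
  if (cutoff <= 0) abort("cutoff must be positive")
  if (min_support < 1) abort("min_support must be at least 1")
  structure(list(overhang_min = as.integer(overhang_min),
                 overhang_max = as.integer(overhang_max),
                 cutoff = cutoff, min_support = as.integer(min_support),
                 merge_distance = as.integer(merge_distance),
                 score_fun = score_fun),
            class = "scoring_params")
}

#' Per-overhang cleavage score
#'
#' The score at top-strand cut position `f` under overhang `o` pairs the
#' forward 5'-end pileup at `f` with the reverse 5'-end pileup at
#' `r = f + o - 1`:
#'
#' \deqn{S_o = \frac{F(f)}{D_f(f)} \times \frac{R(r)}{D_r(r)} \times
#'       \frac{F(f) + R(r)}{2}}
#'
#' i.e. the product of the strand-wise fractions of reads that terminate
#' exactly at the putative cut, scaled by the mean end support.  A fully
#' cleaved site at depth d scores ~d; random shearing scores far below 1.
#' The score is 0 when either depth is 0 or either end count is below
#' `min_support`.  All arguments are vectorized.
#'
#' @param F,Df Forward 5'-end count and forward depth at `f`.
#' @param R,Dr Reverse 5'-end count and reverse depth at `r = f + o - 1`.
#' @param min_support Per-strand support floor.
#' @return Numeric score vector.
#' @export
cleavage_score_default <- function(F, R, Df, Dr, min_support = 3) {
  s <- ifelse(Df == 0 | Dr == 0 | F < min_support | R < min_support,
              0, (F / Df) * (R / Dr) * (F + R) / 2)
  s[is.na(s)] <- 0
  s
}

# Score every position of a pileup (vectorized overhang sweep).  Returns a
# tibble with one row per scoreable position in [from, to): score,
# best_overhang (smallest overhang on ties), and the supporting counts at
# the best overhang.
score_pileup_positions <- function(pileup, params, from = NULL, to = NULL) {
  start <- attr(pileup, "start")
  end <- attr(pileup, "end")
  omax <- params$overhang_max
  from <- max(from %||% start, start)
  to <- min(to %||% end, end - omax + 1L)
  if (to <= from)
    return(tibble(contig = character(0), cut_position = integer(0),
                  score = numeric(0), best_overhang = integer(0),
                  F = integer(0), R = integer(0), Df = integer(0),
                  Dr = integer(0)))
  idx <- (from - start + 1L):(to - start)       # row indices of f positions
  n <- length(idx)
  Fv <- pileup$F; Rv <- pileup$R; Dfv <- pileup$Df; Drv <- pileup$Dr

  best_score <- rep(0, n)
  best_o <- rep(params$overhang_min, n)
  for (o in params$overhang_min:omax) {
    ridx <- idx + o - 1L
    s <- params$score_fun(Fv[idx], Rv[ridx], Dfv[idx], Drv[ridx],
                          min_support = params$min_support)
    better <- s > best_score
    best_o[better] <- o
    best_score[better] <- s[better]
  }
  ro <- idx + best_o - 1L
  tibble(contig = attr(pileup, "contig"),
         cut_position = as.integer(from) + seq_len(n) - 1L,
         score = best_score, best_overhang = best_o,
         F = Fv[idx], R = Rv[ro], Df = Dfv[idx], Dr = Drv[ro])
}

#' Cleavage score at given positions
#'
#' @param pileup An `end_pileup` from [build_end_pileup()].
#' @param f Integer vector of 0-based top-strand cut positions; `f` and
#'   `f + overhang_max - 1` must lie inside the pileup span.
#' @param params A [scoring_params()].
#' @return Tibble with one row per position: contig, cut_position, score,
#'   best_overhang and the supporting counts at the best overhang.
#' @export
cleavage_score <- function(pileup, f, params = scoring_params()) {
  start <- attr(pileup, "start"); end <- attr(pileup, "end")
  if (any(f < start | f + params$overhang_max - 1 >= end))
    abort("position (plus overhang context) outside the pileup span")
  scored <- purrr::map_dfr(f, function(p)
    score_pileup_positions(pileup, params, from = p, to = p + 1L))
  scored
}

#' Scan a genome for cleavage sites
#'
#' Scores every position of a pileup (or of a list of overlapping tiles
#' from [stream_pileups()]), keeps positions with score >= cutoff, and
#' collapses runs of nearby calls with [merge_calls()].
#'
#' @param pileup An `end_pileup` or a list of tiles.
#' @param params A [scoring_params()].
#' @param merge Collapse nearby calls (default TRUE).
#' @return A tibble of class `cleavage_calls`, ordered by
#'   (contig, cut_position).
#' @export
scan_genome <- function(pileup, params = scoring_params(), merge = TRUE) {
  tiles <- if (inherits(pileup, "end_pileup")) list(pileup) else pileup
  calls <- purrr::map_dfr(tiles, function(tile) {
    core <- attr(tile, "core") %||%
      c(attr(tile, "start"), attr(tile, "end"))
    scored <- score_pileup_positions(tile, params,
                                     from = core[1], to = core[2])
    dplyr::filter(scored, .data$score >= params$cutoff)
  })
  calls <- dplyr::arrange(calls, .data$contig, .data$cut_position)
  calls <- dplyr::distinct(calls, .data$contig, .data$cut_position,
                           .keep_all = TRUE)
  if (merge) calls <- merge_calls(calls, params$merge_distance)
  new_cleavage_calls(calls, params)
}

new_cleavage_calls <- function(tbl, params = NULL) {
  structure(as_tibble(tbl), class = c("cleavage_calls", class(as_tibble(tbl))),
            params = params)
}

#' Collapse nearby cleavage calls
#'
#' Calls on the same contig within `merge_distance` bp of each other (by
#' chaining) collapse to the highest-scoring representative; ties go to the
#' smaller coordinate.  The number of calls never increases.
#'
#' @param calls Tibble of calls sorted by (contig, cut_position).
#' @param merge_distance Maximum gap in bp.
#' @return Tibble of merged calls.
#' @export
merge_calls <- function(calls, merge_distance = 10) {
  if (!nrow(calls)) return(calls)
  calls <- dplyr::arrange(calls, .data$contig, .data$cut_position)
  calls |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(cluster = cumsum(
      c(1L, as.integer(diff(.data$cut_position) > merge_distance)))) |>
    dplyr::group_by(.data$contig, .data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$cut_position,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$contig, .data$cut_position)
}
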