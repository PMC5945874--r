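#' Alignment filters for end-pileup construction
#'
#' Defaults mirror common Digenome-seq practice: base-quality cutoff 15 and
#' duplicate reads kept (duplicates are genuine signal when many molecules
#' are cut at the same bond).
#'
#' @param min_base_quality Phred cutoff.  Applied to the terminal (5'-end)
#'   base for end counting and per-base for depth.
#' @param keep_duplicates Keep reads flagged as PCR/optical duplicates.
#' @param min_mapping_quality Minimum MAPQ.
#' @param primary_only Drop secondary and supplementary alignments.
#' @return A list of class `alignment_filter`.
#' @export
alignment_filter <- function(min_base_quality = 15, keep_duplicates = TRUE,
                             min_mapping_quality = 0, primary_only = TRUE) {
  if (min_base_quality < 0 || min_mapping_quality < 0)
    abort("quality thresholds must be non-negative")
  structure(list(min_base_quality = as.integer(min_base_quality),
                 keep_duplicates = keep_duplicates,
                 min_mapping_quality = as.integer(min_mapping_quality),
                 primary_only = primary_only),
            class = "alignment_filter")
}

#' Build a strand-specific read-end pileup
#'
#' For every position of the region this tallies `F`, the number of
#' forward-strand reads whose leftmost reference-aligned base is that
#' position; `R`, the number of reverse-strand reads whose rightmost
#' reference-aligned base (their 5' terminus) is that position; and the
#' strand depths `Df`/`Dr`.  Soft-clipped bases never contribute to ends or
#' depth; CIGAR deletions consume reference and count toward depth,
#' insertions do not.  Bases below `min_base_quality` are excluded from
#' depth, and a read whose 5'-terminal base fails the cutoff is excluded
#' from `F`/`R`.
#'
#' @param x A SAM/BAM file path, or a tibble of alignments as returned by
#'   [simulate_digest()] (columns qname, flag, contig, pos (0-based),
#'   strand, mapq, cigar, qual).
#' @param contig Contig to pile up (defaults to the only contig present).
#' @param region Optional numeric `c(start, end)`, 0-based half-open;
#'   defaults to the whole contig.
#' @param filter An [alignment_filter()].
#' @return A tibble of class `end_pileup` with columns contig, pos, F, R,
#'   Df, Dr (one row per position), and a `log` attribute summarizing
#'   skipped records.
#' @export
build_end_pileup <- function(x, contig = NULL, region = NULL,
                             filter = alignment_filter()) {
  UseMethod("build_end_pileup")
}

#' @export
build_end_pileup.character <- function(x, contig = NULL, region = NULL,
                                       filter = alignment_filter()) {
  bam <- x
  if (grepl("\\.sam$", x, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(x, dest, overwrite = TRUE))
  }
  header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(contig)) {
    if (length(header) != 1 && is.null(region))
      abort("multiple contigs in header; supply `contig`")
    contig <- names(header)[1]
  }
  if (!contig %in% names(header)) abort(paste0("unknown contig: ", contig))
  if (is.null(region)) region <- c(0, header[[contig]])

  param <- Rsamtools::ScanBamParam(
    what = c("flag", "mapq"),
    which = GenomicRanges::GRanges(contig,
      IRanges::IRanges(region[1] + 1, region[2]))
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param,
                                           use.names = FALSE)
  qual <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = "qual",
    which = GenomicRanges::GRanges(contig,
      IRanges::IRanges(region[1] + 1, region[2]))))[[1]]$qual
  rec <- tibble(
    flag = S4Vectors::mcols(ga)$flag,
    mapq = S4Vectors::mcols(ga)$mapq,
    pos = GenomicAlignments::start(ga) - 1L,
    strand = as.character(GenomicAlignments::strand(ga)),
    cigar = GenomicAlignments::cigar(ga),
    qual = as.character(qual)
  )
  count_end_pileup(rec, contig, region[1], region[2], filter)
}

#' @export
build_end_pileup.data.frame <- function(x, contig = NULL, region = NULL,
                                        filter = alignment_filter()) {
  x <- as_tibble(x)
  if (is.null(contig)) {
    cc <- unique(x$contig)
    if (length(cc) > 1) abort("multiple contigs; supply `contig`")
    contig <- if (length(cc)) cc else "chrS"
  }
  x <- dplyr::filter(x, .data$contig == !!contig)
  if (is.null(region)) {
    hi <- if (nrow(x)) max(x$pos + cigar_ref_width(x$cigar)) else 0L
    region <- c(0, hi)
  }
  count_end_pileup(x, contig, region[1], region[2], filter)
}

cigar_ref_width <- function(cigar) {
  simple <- grepl("^\\d+M$", cigar)
  if (all(simple)) return(as.integer(sub("M", "", cigar)))
  w <- integer(length(cigar))
  w[simple] <- as.integer(sub("M", "", cigar[simple]))
  w[!simple] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[!simple])
  w
}

# leading/trailing soft-clip lengths (hard clips carry no SEQ/QUAL bases)
cigar_clips <- function(cigar) {
  lead <- rep(0L, length(cigar))
  has <- grepl("^(\\d+H)?\\d+S", cigar)
  lead[has] <- as.integer(sub("^(?:\\d+H)?(\\d+)S.*$", "\\1", cigar[has]))
  trail <- rep(0L, length(cigar))
  has <- grepl("\\d+S(\\d+H)?$", cigar)
  trail[has] <- as.integer(sub("^.*?(\\d+)S(?:\\d+H)?$", "\\1", cigar[has]))
  list(lead = lead, trail = trail)
}

# 0-based reference position of each query base (NA for S/I), one read.
map_query_to_ref <- function(cigar, pos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  out <- integer(0)
  r <- pos
  for (i in seq_along(ops)) {
    op <- ops[i]; n <- lens[i]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, r + seq_len(n) - 1L); r <- r + n
    } else if (op %in% c("S", "I")) {
      out <- c(out, rep(NA_integer_, n))
    } else if (op %in% c("D", "N")) {
      r <- r + n
    }
  }
  out
}

count_end_pileup <- function(rec, contig, start, end, filter) {
  start <- as.integer(start); end <- as.integer(end)
  span <- end - start
  if (span < 0) abort("region end must be >= start")

  flag <- rec$flag %||% rep(0L, nrow(rec))
  skip_unmapped <- bitwAnd(flag, 4L) != 0L
  skip_nonprimary <- filter$primary_only &
    (bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L)
  skip_dup <- !filter$keep_duplicates & bitwAnd(flag, 1024L) != 0L
  mapq <- rec$mapq %||% rep(60L, nrow(rec))
  mapq[is.na(mapq)] <- 0L
  skip_mapq <- mapq < filter$min_mapping_quality
  log <- c(total = nrow(rec), unmapped = sum(skip_unmapped),
           nonprimary = sum(skip_nonprimary & !skip_unmapped),
           duplicate = sum(skip_dup), low_mapq = sum(skip_mapq))
  rec <- rec[!(skip_unmapped | skip_nonprimary | skip_dup | skip_mapq), ,
             drop = FALSE]

  zero <- tibble(contig = contig,
                 pos = if (span > 0) start + 0:(span - 1L) else integer(0),
                 F = 0L, R = 0L, Df = 0L, Dr = 0L)
  if (!nrow(rec) || span == 0)
    return(new_end_pileup(zero, contig, start, end, log))

  refw <- cigar_ref_width(rec$cigar)
  clips <- cigar_clips(rec$cigar)
  pos <- as.integer(rec$pos)
  rend <- pos + refw                             # half-open alignment end
  keep <- rend > start & pos < end
  rec <- rec[keep, , drop = FALSE]
  refw <- refw[keep]; pos <- pos[keep]; rend <- rend[keep]
  lead <- clips$lead[keep]; trail <- clips$trail[keep]

  # per-base qualities (concatenated for vectorized decoding)
  qlen <- nchar(rec$qual)
  offs <- c(0L, cumsum(qlen))
  allq <- as.integer(charToRaw(paste(rec$qual, collapse = ""))) -
    phred_offset
  term_idx <- ifelse(rec$strand == "+",
                     offs[seq_len(nrow(rec))] + lead + 1L,
                     offs[seq_len(nrow(rec))] + qlen - trail)
  term_ok <- allq[term_idx] >= filter$min_base_quality
  # '*' quality (absent) decodes to 9 ('*' - 33 = 9); treat as passing
  term_ok[rec$qual == "*"] <- TRUE

  is_f <- rec$strand == "+"
  f_at <- pos[is_f & term_ok] - start
  r_at <- (rend - 1L)[!is_f & term_ok] - start
  F <- tabulate(f_at[f_at >= 0 & f_at < span] + 1L, nbins = span)
  R <- tabulate(r_at[r_at >= 0 & r_at < span] + 1L, nbins = span)

  depth_of <- function(sel) {
    if (!any(sel)) return(integer(span))
    w <- max(c(rend[sel], end))
    s1 <- pmax(pos[sel] + 1L, 1L)
    e1 <- pmin(rend[sel], w)
    cov <- IRanges::coverage(IRanges::IRanges(s1, e1), width = w)
    d <- as.integer(cov)[(start + 1L):end]
    d[is.na(d)] <- 0L
    d
  }
  Df <- depth_of(is_f)
  Dr <- depth_of(!is_f)

  # subtract low-quality bases from depth
  if (filter$min_base_quality > 0) {
    low <- which(allq < filter$min_base_quality)
    low <- low[rec$qual[findInterval(low, offs + 1L)] != "*"]
    if (length(low)) {
      ridx <- findInterval(low, offs + 1L)       # read index of each low base
      qpos <- low - offs[ridx]                   # 1-based query position
      simple <- !grepl("[IDN]", rec$cigar[ridx])
      rp <- rep(NA_integer_, length(low))
      rp[simple] <- pos[ridx[simple]] + (qpos[simple] - lead[ridx[simple]] - 1L)
      in_aln <- simple & qpos > lead[ridx] & qpos <= qlen[ridx] - trail[ridx]
      rp[!in_aln] <- NA_integer_
      for (j in which(!simple)) {
        m <- map_query_to_ref(rec$cigar[ridx[j]], pos[ridx[j]])
        rp[j] <- m[qpos[j]]
      }
      ok <- !is.na(rp) & rp >= start & rp < end
      if (any(ok)) {
        sub_f <- tabulate(rp[ok & is_f[ridx]] - start + 1L, nbins = span)
        sub_r <- tabulate(rp[ok & !is_f[ridx]] - start + 1L, nbins = span)
        Df <- Df - sub_f
        Dr <- Dr - sub_r
      }
    }
  }

  out <- tibble(contig = contig, pos = start + 0:(span - 1L),
                F = F, R = R, Df = Df, Dr = Dr)
  new_end_pileup(out, contig, start, end, log)
}

new_end_pileup <- function(tbl, contig, start, end, log) {
  structure(tbl, class = c("end_pileup", class(tbl)),
            contig = contig, start = start, end = end, log = log)
}

#' Tile a contig into overlapping end-pileup windows
#'
#' Tiles jointly cover the region; adjacent tiles share `overlap` positions
#' so that a cut site bisected by a tile boundary is still scoreable with
#' full overhang context.  Each tile carries a `core` attribute marking the
#' half-open interval it owns (cores partition the region).
#'
#' @inheritParams build_end_pileup
#' @param window_size Tile core width in bp; must exceed `2 * overlap`.
#' @param overlap Overlap between adjacent tiles, at least the maximum
#'   overhang under consideration (default 5).
#' @return List of `end_pileup` tiles.
#' @export
stream_pileups <- function(x, window_size, overlap = 5, contig = NULL,
                           region = NULL, filter = alignment_filter()) {
  if (window_size <= 2 * overlap) abort("window_size must exceed 2 * overlap")
  if (is.null(region)) {
    probe <- build_end_pileup(x, contig = contig, filter = filter)
    region <- c(attr(probe, "start"), attr(probe, "end"))
    contig <- attr(probe, "contig")
    if (region[2] - region[1] <= window_size + overlap) {
      attr(probe, "core") <- region
      return(list(probe))
    }
  }
  starts <- seq(region[1], region[2] - 1, by = window_size)
  purrr::map(starts, function(s) {
    core_end <- min(region[2], s + window_size)
    tile_end <- min(region[2], core_end + overlap)
    tile <- build_end_pileup(x, contig = contig, region = c(s, tile_end),
                             filter = filter)
    attr(tile, "core") <- c(s, core_end)
    tile
  })
}

#' Export an end pileup as TSV
#' @param pileup An `end_pileup`.
#' @param path Output path.
#' @param drop_empty Omit positions with all-zero counts (default TRUE).
#' @return The path, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path, drop_empty = TRUE) {
  d <- as_tibble(pileup)
  if (drop_empty)
    d <- dplyr::filter(d, .data$F + .data$R + .data$Df + .data$Dr > 0)
  readr::write_tsv(d, path)
  invisible(path)
}
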