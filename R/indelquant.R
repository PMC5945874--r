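#' Amplicon analysis configuration
#'
#' @param reference Amplicon reference sequence.
#' @param guide_window 0-based half-open interval `c(start, end)` covering
#'   protospacer + PAM within the amplicon; indels are only counted when
#'   they overlap this window padded by `window_pad`.
#' @param window_pad Padding in bp (default 5).  A span (rather than a
#'   point cut estimate) is robust to the cut-position uncertainty of a
#'   staggered cutter.
#' @param min_read_length Reads shorter than this are excluded (counted).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; a gap of
#'   length k costs `gap_open + k * gap_extend` (negative values).
#' @return A list of class `amplicon_config`.
#' @export
amplicon_config <- function(reference, guide_window, window_pad = 5,
                            min_read_length = 30, match = 2, mismatch = -4,
                            gap_open = -10, gap_extend = -1) {
  reference <- toupper(reference)
  if (guide_window[1] < 0 || guide_window[2] > nchar(reference) ||
      guide_window[1] >= guide_window[2])
    abort("guide_window must be a non-empty interval inside the amplicon")
  if (window_pad < 0) abort("window_pad must be non-negative")
  structure(list(reference = reference,
                 guide_window = as.integer(guide_window),
                 window_pad = as.integer(window_pad),
                 min_read_length = as.integer(min_read_length),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "amplicon_config")
}

#' Align amplicon reads to the reference
#'
#' Affine-gap alignment in which the whole read aligns but the amplicon's
#' ends are gap-free (a read may cover only part of the amplicon without
#' end-gap penalty).  Indel operations are extracted in reference
#' coordinates and left-aligned (VCF-style normalization: a gap inside a
#' repeat run is shifted to its leftmost equivalent placement), so pattern
#' tables are stable.
#'
#' @param reads Character vector of read sequences, or a tibble with
#'   columns `read_id` and `seq`.
#' @param config An [amplicon_config()].
#' @return List with `ops` (tibble: read_id, kind ("ins"/"del"), position
#'   (0-based reference coordinate), length, seq) and `reads` (tibble:
#'   read_id, score, too_short, n_ops).
#' @export
align_reads <- function(reads, config) {
  if (is.character(reads))
    reads <- tibble(read_id = sprintf("read_%06d", seq_along(reads)),
                    seq = reads)
  too_short <- nchar(reads$seq) < config$min_read_length
  usable <- reads[!too_short, , drop = FALSE]

  ops <- tibble(read_id = character(0), kind = character(0),
                position = integer(0), length = integer(0),
                seq = character(0))
  score <- numeric(0)
  if (nrow(usable)) {
    L <- nchar(config$reference)
    ref_raw <- charToRaw(config$reference)
    # Substitution-only fast path: for a full-length read with Hamming
    # distance <= 2, any alignment using a gap is bounded strictly below
    # the gap-free score under these penalties (a single gap costs at
    # least |gap_open + gap_extend| = 11 > 2 * (match - mismatch)), so the
    # gap-free alignment is provably optimal and carries no indel ops.
    hm <- rep(NA_integer_, nrow(usable))
    eq <- which(nchar(usable$seq) == L)
    hm[eq] <- vapply(usable$seq[eq],
                     function(s) sum(charToRaw(s) != ref_raw), integer(1),
                     USE.NAMES = FALSE)
    fast <- !is.na(hm) & hm <= 2L
    score <- rep(NA_real_, nrow(usable))
    score[fast] <- config$match * (L - hm[fast]) + config$mismatch * hm[fast]

    slow_seqs <- unique(usable$seq[!fast])
    if (length(slow_seqs)) {
      mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = config$match, mismatch = config$mismatch)
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(slow_seqs),
        subject = Biostrings::DNAString(config$reference),
        type = "global-local", substitutionMatrix = mat,
        gapOpening = -config$gap_open, gapExtension = -config$gap_extend)
      sc <- Biostrings::score(aln)
      pat <- as.character(Biostrings::alignedPattern(aln))
      sub <- as.character(Biostrings::alignedSubject(aln))
      ref_off <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based
      per_seq <- purrr::map(seq_along(slow_seqs), function(i) {
        o <- gapped_to_ops(pat[i], sub[i], ref_off[i])
        if (nrow(o)) o <- left_align_ops(o, config$reference)
        o
      })
      idx <- match(usable$seq[!fast], slow_seqs)
      score[!fast] <- sc[idx]
      slow_ids <- usable$read_id[!fast]
      ops <- purrr::map_dfr(seq_along(idx), function(k) {
        o <- per_seq[[idx[k]]]
        if (nrow(o)) o$read_id <- slow_ids[k]
        o
      })
      if (nrow(ops)) ops <- ops[, c("read_id", "kind", "position", "length",
                                    "seq")]
    }
  }
  n_ops <- rep(0L, nrow(reads))
  if (nrow(ops)) {
    cnt <- dplyr::count(ops, .data$read_id)
    n_ops[match(cnt$read_id, reads$read_id)] <- cnt$n
  }
  sc <- rep(NA_real_, nrow(reads))
  sc[!too_short] <- score
  list(ops = ops,
       reads = tibble(read_id = reads$read_id, score = sc,
                      too_short = too_short, n_ops = n_ops))
}

# Walk equal-length gapped pattern/subject strings; emit indel ops in
# 0-based reference coordinates.  ref_off is the 0-based reference
# coordinate of the first aligned subject base.
gapped_to_ops <- function(pat, sub, ref_off) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  gap_p <- p == "-"
  gap_s <- s == "-"
  state <- ifelse(gap_s, "ins", ifelse(gap_p, "del", "m"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # reference position before each alignment column (0-based)
  ref_consumed <- cumsum(!gap_s)
  out <- purrr::map_dfr(which(r$values != "m"), function(k) {
    a <- starts[k]; b <- ends[k]
    if (r$values[k] == "del") {
      tibble(kind = "del",
             position = ref_off + ref_consumed[a] - 1L,
             length = b - a + 1L,
             seq = paste(s[a:b], collapse = ""))
    } else {
      tibble(kind = "ins",
             position = ref_off + ref_consumed[a],   # insertion before this ref base
             length = b - a + 1L,
             seq = paste(p[a:b], collapse = ""))
    }
  })
  out
}

# Left-align (normalize) indels within repeat context against the full
# reference.  `position` is 0-based.
left_align_ops <- function(ops, reference) {
  rc <- strsplit(reference, "")[[1]]
  for (i in seq_len(nrow(ops))) {
    pos <- ops$position[i]
    sq <- strsplit(ops$seq[i], "")[[1]]
    len <- ops$length[i]
    if (ops$kind[i] == "del") {
      while (pos > 0 && rc[pos] == rc[pos + len]) pos <- pos - 1L
      sq <- rc[(pos + 1):(pos + len)]
    } else {
      while (pos > 0 && rc[pos] == sq[length(sq)]) {
        sq <- c(rc[pos], sq[-length(sq)])
        pos <- pos - 1L
      }
    }
    ops$position[i] <- pos
    ops$seq[i] <- paste(sq, collapse = "")
  }
  ops
}

#' Call windowed indel events per read
#'
#' Substitutions never count as indels.  An op is in-window when it
#' overlaps the guide window padded by `window_pad`; a read is an indel
#' read when it has at least one in-window op.
#'
#' @param alignment Result of [align_reads()].
#' @param config An [amplicon_config()].
#' @return Tibble of per-read events: read_id, analyzed, n_ops,
#'   net_length_change, in_window, signature (left-aligned op signature of
#'   in-window ops; `NA` for non-indel reads).
#' @export
call_indels <- function(alignment, config) {
  win <- c(config$guide_window[1] - config$window_pad,
           config$guide_window[2] + config$window_pad)
  ops <- alignment$ops
  if (nrow(ops)) {
    op_end <- ops$position + ifelse(ops$kind == "del", ops$length, 0L)
    op_start <- ops$position
    # an insertion occupies a point between bases; a deletion a span
    ops$in_window <- ifelse(
      ops$kind == "del",
      op_start < win[2] & op_end > win[1],
      op_start <= win[2] & op_start >= win[1])
    per_read <- ops |>
      dplyr::group_by(.data$read_id) |>
      dplyr::summarise(
        n_ops = dplyr::n(),
        net_length_change = sum(ifelse(.data$kind == "ins", .data$length,
                                       -.data$length)),
        in_window = any(.data$in_window),
        signature = paste(sprintf("%s@%d:%s", .data$kind, .data$position,
                                  .data$seq), collapse = ","),
        .groups = "drop")
  } else {
    per_read <- tibble(read_id = character(0), n_ops = integer(0),
                       net_length_change = integer(0), in_window = logical(0),
                       signature = character(0))
  }
  out <- alignment$reads |>
    dplyr::select("read_id", "too_short") |>
    dplyr::left_join(per_read, by = "read_id") |>
    dplyr::mutate(
      analyzed = !.data$too_short,
      n_ops = dplyr::coalesce(.data$n_ops, 0L),
      net_length_change = dplyr::coalesce(.data$net_length_change, 0L),
      in_window = dplyr::coalesce(.data$in_window, FALSE),
      signature = ifelse(.data$in_window, .data$signature, NA_character_)
    ) |>
    dplyr::select("read_id", "analyzed", "n_ops", "net_length_change",
                  "in_window", "signature")
  out
}

#' Summarize editing outcomes for one amplicon
#'
#' Indel frequency is `100 * indel_reads / analyzed_reads`.  Among indel
#' reads, each read is classed in-frame or out-of-frame by its net length
#' change mod 3 (frameshift rule); the two fractions total 100 exactly.
#' Mutant patterns are keyed by the left-aligned op signature, ranked by
#' count (ties broken lexicographically).
#'
#' @param events Tibble from [call_indels()].
#' @param total_reads Total input reads (defaults to `nrow(events)`).
#' @return A list of class `indel_summary` with elements `summary` (one-row
#'   tibble), `patterns` (ranked tibble) and `events`.
#' @export
summarize_indels <- function(events, total_reads = NULL) {
  total_reads <- total_reads %||% nrow(events)
  analyzed <- sum(events$analyzed)
  indel <- dplyr::filter(events, .data$analyzed, .data$in_window)
  n_indel <- nrow(indel)
  freq <- if (analyzed > 0) 100 * n_indel / analyzed else NA_real_
  oof <- if (n_indel > 0)
    100 * sum(indel$net_length_change %% 3 != 0) / n_indel else NA_real_
  patterns <- if (n_indel > 0) {
    indel |>
      dplyr::mutate(frame = ifelse(.data$net_length_change %% 3 == 0,
                                   "in-frame", "out-of-frame")) |>
      dplyr::count(.data$signature, .data$net_length_change, .data$frame,
                   name = "count") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$signature)
  } else {
    tibble(signature = character(0), net_length_change = integer(0),
           frame = character(0), count = integer(0))
  }
  structure(list(
    summary = tibble(total_reads = total_reads, analyzed_reads = analyzed,
                     indel_reads = n_indel, indel_frequency = freq,
                     out_of_frame_fraction = oof,
                     in_frame_fraction = if (n_indel > 0) 100 - oof
                                         else NA_real_),
    patterns = patterns, events = events), class = "indel_summary")
}

#' Quantify one amplicon FASTQ end to end
#'
#' @param fastq FASTQ path (or character vector of read sequences).
#' @param config An [amplicon_config()].
#' @return An `indel_summary`.
#' @export
quantify_amplicon <- function(fastq, config) {
  reads <- if (is.character(fastq) && length(fastq) == 1 &&
               file.exists(fastq)) {
    x <- Biostrings::readDNAStringSet(fastq, format = "fastq")
    tibble(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x))
  } else {
    tibble(read_id = sprintf("read_%06d", seq_along(fastq)), seq = fastq)
  }
  if (!nrow(reads))
    return(summarize_indels(tibble(read_id = character(0), analyzed = logical(0),
                                   n_ops = integer(0),
                                   net_length_change = integer(0),
                                   in_window = logical(0),
                                   signature = character(0)),
                            total_reads = 0))
  aln <- align_reads(reads, config)
  summarize_indels(call_indels(aln, config), total_reads = nrow(reads))
}

#' Quantify a batch of amplicons
#'
#' @param samples Tibble with columns `amplicon_id` and `fastq`.
#' @param configs Named list of [amplicon_config()]s, one per amplicon_id.
#' @return Tibble with one summary row per amplicon.
#' @export
batch_quantify <- function(samples, configs) {
  if (anyDuplicated(samples$amplicon_id))
    abort("duplicate amplicon IDs in sample sheet")
  missing <- setdiff(samples$amplicon_id, names(configs))
  if (length(missing))
    abort(paste0("no amplicon config for: ", paste(missing, collapse = ", ")))
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    id <- samples$amplicon_id[i]
    res <- quantify_amplicon(samples$fastq[i], configs[[id]])
    dplyr::bind_cols(tibble(amplicon_id = id), res$summary)
  })
}
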