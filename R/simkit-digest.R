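#' Simulate sequencing of an in-vitro-digested genome
#'
#' Each simulated molecule is a full-length copy of the genome.  Background
#' shearing breaks it at Poisson-distributed blunt breakpoints (exponential
#' spacing, mean `fragment_mean`).  Each planted site additionally cuts the
#' molecule with probability `efficiency`, with staggered geometry: the top
#' strand is cut at the bond before `c_top` and the bottom strand `overhang`
#' bp downstream, so forward-read 5' ends pile up at `c_top` and
#' reverse-read 5' ends at `c_top + overhang - 1` (0-based).  Both ends of
#' every fragment are sequenced (paired-end); substitution errors are added
#' at `sequencing_error_rate` and flagged by a low base quality.
#'
#' Alignments are emitted directly (the simulator knows the true
#' coordinates, so SAM records carry exact POS/CIGAR/FLAG and no external
#' aligner is needed); FASTQ is also written when `out_prefix` is given, for
#' end-to-end runs through a real aligner.
#'
#' @param genome Named character vector (one contig), e.g. from
#'   [sim_genome()].
#' @param spec A [sim_spec()].
#' @param out_prefix Optional path prefix; writes `<prefix>.sam`,
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq`, `<prefix>_truth.tsv`.
#' @param min_fragment Fragments whose strands are both shorter than this
#'   are dropped (unsequenceable); default 20 bp.
#' @return List with `alignments` (tibble: qname, flag, contig, pos, strand,
#'   mapq, cigar, seq, qual; `pos` 0-based leftmost reference base),
#'   `fragments` (the truth ledger: per-fragment strand spans and cut
#'   labels), `cuts` (per-molecule planted-cut events, the oracle for
#'   efficiency estimates), and `files` (paths written, if any).
#' @export
simulate_digest <- function(genome, spec, out_prefix = NULL, min_fragment = 20) {
  contig <- names(genome)[1]
  seq <- unname(genome[1])
  L <- nchar(seq)
  if (L != spec$genome_length)
    warn("genome length differs from spec$genome_length; using the sequence")

  sites <- spec$planted_sites
  keep <- vapply(sites, function(s) {
    ok <- s$position >= spec$read_length &&
      s$position + s$overhang <= L - spec$read_length
    if (!ok) warn(paste0("planted site at ", s$position,
                         " is within read_length of a contig edge; skipped"))
    ok
  }, logical(1))
  sites <- sites[keep]

  # Number of whole-genome molecules that yields the target fold coverage:
  # each fragment of mean size fragment_mean contributes two reads.
  n_mol <- max(1L, as.integer(round(
    spec$coverage * spec$fragment_mean / (2 * spec$read_length))))

  per_mol <- withr::with_seed(derive_seed(spec$seed, "digest"), {
    purrr::map(seq_len(n_mol), function(m) {
      # background blunt breakpoints (bonds in (0, L))
      gaps <- stats::rexp(ceiling(3 * L / spec$fragment_mean) + 10,
                          rate = 1 / spec$fragment_mean)
      bg <- floor(cumsum(gaps))
      bg <- unique(bg[bg > 0 & bg < L])
      cut_top <- bg; cut_bot <- bg
      lab <- rep("background", length(bg))
      cuts <- tibble(molecule = integer(0), guide_id = character(0),
                     position = integer(0), overhang = integer(0))
      for (s in sites) {
        if (stats::runif(1) <= s$efficiency) {
          cut_top <- c(cut_top, s$position)
          cut_bot <- c(cut_bot, s$position + s$overhang)
          id <- ifelse(is.na(s$guide_id), "planted", s$guide_id)
          lab <- c(lab, id)
          cuts <- dplyr::bind_rows(cuts, tibble(
            molecule = m, guide_id = id, position = s$position,
            overhang = s$overhang))
        }
      }
      o <- order(cut_top)
      cut_top <- c(0L, cut_top[o], L)
      cut_bot <- cummax(c(0L, cut_bot[o], L))  # enforce non-crossing strands
      lab <- c("edge", lab[o], "edge")
      n <- length(cut_top) - 1L
      frags <- tibble(
        molecule = m, fragment = seq_len(n),
        top_start = cut_top[-length(cut_top)], top_end = cut_top[-1],
        bottom_start = cut_bot[-length(cut_bot)], bottom_end = cut_bot[-1],
        left_cut = lab[-length(lab)], right_cut = lab[-1]
      )
      list(frags = frags, cuts = cuts)
    })
  })
  frags <- purrr::map_dfr(per_mol, "frags")
  cuts <- purrr::map_dfr(per_mol, "cuts")
  frags <- dplyr::filter(frags,
                         .data$top_end > .data$top_start,
                         .data$bottom_end > .data$bottom_start,
                         pmax(.data$top_end - .data$top_start,
                              .data$bottom_end - .data$bottom_start) >= min_fragment)

  rl <- spec$read_length
  f_len <- pmin(rl, frags$top_end - frags$top_start)
  r_len <- pmin(rl, frags$bottom_end - frags$bottom_start)
  f_start <- frags$top_start                 # forward 5' end
  r_end <- frags$bottom_end                  # reverse 5' end at r_end - 1
  r_start <- r_end - r_len

  f_seq <- substring(seq, f_start + 1, f_start + f_len)
  r_seq <- substring(seq, r_start + 1, r_end)  # reference orientation

  err <- withr::with_seed(derive_seed(spec$seed, "seqerr"), {
    list(f = apply_seq_errors(f_seq, spec$sequencing_error_rate),
         r = apply_seq_errors(r_seq, spec$sequencing_error_rate))
  })

  qname <- sprintf("frag_%d_%d", frags$molecule, frags$fragment)
  alignments <- tibble(
    qname = rep(qname, 2),
    flag = c(rep(99L, nrow(frags)), rep(147L, nrow(frags))),
    contig = contig,
    pos = c(f_start, r_start),
    strand = rep(c("+", "-"), each = nrow(frags)),
    mapq = 60L,
    cigar = paste0(c(f_len, r_len), "M"),
    seq = c(err$f$seq, err$r$seq),
    qual = c(err$f$qual, err$r$qual)
  ) |>
    dplyr::arrange(.data$pos, .data$qname, .data$flag)

  files <- character(0)
  if (!is.null(out_prefix)) {
    sam <- paste0(out_prefix, ".sam")
    write_sam(alignments, stats::setNames(L, contig), sam)
    fq <- write_fastq_pair(alignments, out_prefix)
    truth <- paste0(out_prefix, "_truth.tsv")
    readr::write_tsv(frags, truth)
    cuts_path <- paste0(out_prefix, "_cuts.tsv")
    readr::write_tsv(cuts, cuts_path)
    files <- c(sam = sam, fq, truth = truth, cuts = cuts_path)
  }
  list(alignments = alignments, fragments = frags, cuts = cuts, files = files)
}

# Minimal SAM v1.6 writer for simulator output (header + one line per read;
# paired flags already set; RNEXT/PNEXT left "*"/0 -- mates are implicit in
# the truth ledger and unused by the pileup).
write_sam <- function(alignments, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 alignments$qname, alignments$flag, alignments$contig,
                 alignments$pos + 1L, alignments$mapq, alignments$cigar,
                 alignments$seq, alignments$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# FASTQ as sequenced: reverse-strand reads are written reverse-complemented
# with reversed quality strings.
write_fastq_pair <- function(alignments, out_prefix) {
  write_one <- function(d, path, rc) {
    s <- d$seq; q <- d$qual
    if (rc && nrow(d)) {
      s <- revcomp(s)
      q <- vapply(strsplit(q, ""), function(x) paste(rev(x), collapse = ""),
                  character(1))
    }
    writeLines(as.vector(rbind(paste0("@", d$qname), s, "+", q)), path)
    path
  }
  r1 <- paste0(out_prefix, "_R1.fastq")
  r2 <- paste0(out_prefix, "_R2.fastq")
  d <- dplyr::arrange(alignments, .data$qname)
  write_one(dplyr::filter(d, .data$strand == "+"), r1, rc = FALSE)
  write_one(dplyr::filter(d, .data$strand == "-"), r2, rc = TRUE)
  c(r1 = r1, r2 = r2)
}
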