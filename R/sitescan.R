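#' Describe a crRNA guide target
#'
#' @param guide_id Identifier.
#' @param protospacer Protospacer sequence over A/C/G/T, PAM-proximal end
#'   first (default length 23 for LbCpf1).
#' @param pam_pattern IUPAC PAM pattern 5' of the protospacer (default
#'   TTTV, the T-rich Cpf1 PAM; V = A/C/G).
#' @param contig,start,end,strand Genomic placement of the intended
#'   on-target locus (0-based half-open protospacer span); optional.
#' @param expected_cut Expected 0-based top-strand cut coordinate.
#' @return A one-row tibble of class `guide_target`.
#' @export
guide_target <- function(guide_id, protospacer, pam_pattern = "TTTV",
                         contig = NA_character_, start = NA_integer_,
                         end = NA_integer_, strand = NA_character_,
                         expected_cut = NA_integer_) {
  protospacer <- toupper(protospacer)
  if (!grepl("^[ACGT]+$", protospacer))
    abort("protospacer must be over A/C/G/T")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pam_pattern))
    abort("pam_pattern must be IUPAC")
  out <- tibble(guide_id = guide_id, protospacer = protospacer,
                pam_pattern = pam_pattern, contig = contig,
                start = as.integer(start), end = as.integer(end),
                strand = strand, expected_cut = as.integer(expected_cut))
  structure(out, class = c("guide_target", class(out)))
}

# mismatch counts of `pattern` (concrete bases) against every substring of
# the genome; genome Ns never match.
scan_mismatches <- function(gchars, pattern_chars) {
  N <- length(gchars)
  L <- length(pattern_chars)
  n_pos <- N - L + 1L
  if (n_pos < 1) return(integer(0))
  mm <- integer(n_pos)
  for (j in seq_len(L)) {
    g <- gchars[j:(j + n_pos - 1L)]
    mm <- mm + as.integer(g != pattern_chars[j] | g == "N")
  }
  mm
}

# TRUE where the IUPAC pam pattern matches exactly (genome Ns never match).
scan_pam <- function(gchars, pam_chars) {
  N <- length(gchars)
  L <- length(pam_chars)
  n_pos <- N - L + 1L
  if (n_pos < 1) return(logical(0))
  ok <- rep(TRUE, n_pos)
  for (j in seq_len(L)) {
    allowed <- iupac_bases(pam_chars[j])       # never contains N
    ok <- ok & gchars[j:(j + n_pos - 1L)] %in% allowed
  }
  ok
}

#' Enumerate candidate (off-)target sites by exhaustive PAM-anchored scan
#'
#' Scans both strands of a genome for loci where the IUPAC PAM matches
#' exactly immediately 5' of the protospacer (on the hit's strand) and the
#' protospacer Hamming distance is at most `max_mismatches`.  Ambiguous
#' genome bases (N) never match.  This is an exhaustive Cas-OFFinder-style
#' search; no bulges are considered.
#'
#' @param genome Named character vector of contig sequences, a
#'   DNAStringSet, or a FASTA path.
#' @param guide A [guide_target()].
#' @param max_mismatches Maximum protospacer mismatches (default 4).
#' @return Tibble of hits: contig, start, end (0-based half-open
#'   protospacer span on the + strand), strand, mismatches, pam_observed,
#'   site_sequence (protospacer as read on the hit strand), sorted by
#'   (contig, start, strand).
#' @export
find_candidate_sites <- function(genome, guide, max_mismatches = 4) {
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  ps <- strsplit(guide$protospacer, "")[[1]]
  np <- length(ps)
  if (max_mismatches < 0 || max_mismatches > np)
    abort("max_mismatches must lie in [0, protospacer length]")
  pam <- strsplit(guide$pam_pattern, "")[[1]]
  npam <- length(pam)
  L <- npam + np

  one_strand <- function(gchars, contig, strand, N) {
    if (length(gchars) < L)
      return(tibble(contig = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    mismatches = integer(0), pam_observed = character(0),
                    site_sequence = character(0)))
    pam_ok <- scan_pam(gchars, pam)
    # protospacer occupies offsets npam+1 .. npam+np after each PAM start
    mm <- scan_mismatches(gchars[-seq_len(npam)], ps)
    n <- min(length(pam_ok), length(mm))
    hit <- which(pam_ok[seq_len(n)] & mm[seq_len(n)] <= max_mismatches)
    if (!length(hit))
      return(tibble(contig = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    mismatches = integer(0), pam_observed = character(0),
                    site_sequence = character(0)))
    i0 <- hit - 1L                               # 0-based PAM start, this strand
    ps_start <- i0 + npam
    seqs <- vapply(hit, function(h)
      paste(gchars[(h + npam):(h + npam + np - 1L)], collapse = ""),
      character(1))
    pams <- vapply(hit, function(h)
      paste(gchars[h:(h + npam - 1L)], collapse = ""), character(1))
    if (strand == "+") {
      start <- ps_start
    } else {
      # strand-local coordinate -> plus-strand coordinate
      start <- N - (ps_start + np)
    }
    tibble(contig = contig, start = as.integer(start),
           end = as.integer(start + np), strand = strand,
           mismatches = mm[hit], pam_observed = pams, site_sequence = seqs)
  }

  hits <- purrr::map_dfr(names(genome), function(ctg) {
    seq <- toupper(genome[[ctg]])
    N <- nchar(seq)
    gchars <- strsplit(seq, "")[[1]]
    rc <- strsplit(revcomp(seq), "")[[1]]
    dplyr::bind_rows(one_strand(gchars, ctg, "+", N),
                     one_strand(rc, ctg, "-", N))
  })
  dplyr::arrange(hits, .data$contig, .data$start, .data$strand)
}

#' Annotate cleavage calls against candidate target sites
#'
#' Labels each call `ON` when it lies within `window` bp of the guide's
#' on-target locus, `OT-n` when within `window` bp of a candidate hit with
#' n protospacer mismatches (nearest hit wins), and `UNEXPLAINED`
#' otherwise.
#'
#' @param calls A `cleavage_calls` tibble.
#' @param hits Hits from [find_candidate_sites()].
#' @param guide The [guide_target()] (for the on-target locus); optional.
#' @param window Distance tolerance in bp (default 25).
#' @return `calls` with added columns `label`, `site_mismatches`,
#'   `site_distance`.
#' @export
annotate_calls <- function(calls, hits, guide = NULL, window = 25) {
  dist_to <- function(p, ctg, start, end, contigs) {
    ifelse(contigs != ctg, Inf,
           ifelse(p >= start & p < end, 0, pmin(abs(p - start),
                                                abs(p - (end - 1)))))
  }
  n <- nrow(calls)
  label <- rep("UNEXPLAINED", n)
  mm <- rep(NA_integer_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- calls$cut_position[i]; ctg <- calls$contig[i]
    if (nrow(hits)) {
      d <- dist_to(p, ctg, hits$start, hits$end, hits$contig)
      j <- which.min(d)
      if (length(j) && d[j] <= window) {
        label[i] <- paste0("OT-", hits$mismatches[j])
        mm[i] <- hits$mismatches[j]
        dist[i] <- d[j]
      }
    }
    if (!is.null(guide) && !is.na(guide$contig)) {
      d_on <- dist_to(p, ctg, guide$start, guide$end, guide$contig)
      if (is.finite(d_on) && d_on <= window) {
        label[i] <- "ON"
        mm[i] <- 0L
        dist[i] <- d_on
      }
    }
  }
  dplyr::mutate(as_tibble(calls), label = label, site_mismatches = mm,
                site_distance = dist)
}
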