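#' Define a planted indel spectrum for amplicon simulation
#'
#' @param entries Tibble or data frame with columns `net` (signed nt length
#'   change, nonzero), `offset` (signed nt, placement of the indel relative
#'   to the cut position) and `fraction` (proportion of reads).
#' @param wild_type_fraction Proportion of unedited reads.
#' @return A list of class `indel_spectrum`.
#' @export
indel_spectrum <- function(entries, wild_type_fraction) {
  entries <- as_tibble(entries)
  stopifnot(all(c("net", "offset", "fraction") %in% names(entries)))
  if (any(entries$net == 0)) abort("net length change must be nonzero")
  tot <- sum(entries$fraction) + wild_type_fraction
  if (abs(tot - 1) > 1e-9) abort("fractions must sum to 1")
  structure(list(entries = entries, wild_type_fraction = wild_type_fraction),
            class = "indel_spectrum")
}

#' Simulate amplicon deep-sequencing reads with a planted indel spectrum
#'
#' Each read is a copy of the amplicon reference; with probability given by
#' the spectrum it carries one indel of the stated net length at
#' `cut_position + offset` (deletions remove reference bases starting
#' there; insertions add random bases before that position).  Substitution
#' sequencing errors are then applied at `error_rate`.  A truth ledger
#' records each read's class.
#'
#' @param amplicon_reference Amplicon sequence (character scalar).
#' @param spectrum An [indel_spectrum()].
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution error probability.
#' @param cut_position 0-based expected cut coordinate within the amplicon.
#' @param seed Integer seed.
#' @param out_prefix Optional path prefix; writes `<prefix>.fastq` and
#'   `<prefix>_truth.tsv`.
#' @return List with `reads` (tibble: read_id, seq, qual), `truth` (tibble:
#'   read_id, class, net, offset) and `files`.  `class` is "WT" or the
#'   signed net length (e.g. "-4", "+1").
#' @export
simulate_amplicon <- function(amplicon_reference, spectrum, n_reads,
                              error_rate = 0, cut_position, seed,
                              out_prefix = NULL) {
  ref <- toupper(amplicon_reference)
  L <- nchar(ref)
  if (cut_position < 0 || cut_position >= L)
    abort("cut_position must lie inside the amplicon")
  ent <- spectrum$entries
  if (any(-ent$net >= L)) abort("indel longer than the amplicon")

  classes <- c(sprintf("%+d", ent$net), "WT")
  probs <- c(ent$fraction, spectrum$wild_type_fraction)

  out <- withr::with_seed(derive_seed(seed, "amplicon"), {
    idx <- sample.int(length(classes), n_reads, replace = TRUE, prob = probs)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      k <- idx[i]
      if (classes[k] == "WT") { seqs[i] <- ref; next }
      net <- ent$net[k]
      at <- cut_position + ent$offset[k]          # 0-based
      at <- max(1L, min(L - 1L, at))
      if (net < 0) {
        del_end <- min(L, at + (-net))
        seqs[i] <- paste0(substr(ref, 1, at), substr(ref, del_end + 1, L))
      } else {
        ins <- paste(sample(DNA_BASES, net, replace = TRUE), collapse = "")
        seqs[i] <- paste0(substr(ref, 1, at), ins, substr(ref, at + 1, L))
      }
    }
    err <- apply_seq_errors(seqs, error_rate)
    list(idx = idx, seq = err$seq, qual = err$qual)
  })

  read_id <- sprintf("amp_%06d", seq_len(n_reads))
  reads <- tibble(read_id = read_id, seq = out$seq, qual = out$qual)
  truth <- tibble(
    read_id = read_id,
    class = classes[out$idx],
    net = c(ent$net, 0L)[out$idx],
    offset = c(ent$offset, NA_integer_)[out$idx]
  )

  files <- character(0)
  if (!is.null(out_prefix)) {
    fq <- paste0(out_prefix, ".fastq")
    writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+",
                               reads$qual)), fq)
    truth_path <- paste0(out_prefix, "_truth.tsv")
    readr::write_tsv(truth, truth_path)
    files <- c(fastq = fq, truth = truth_path)
  }
  list(reads = reads, truth = truth, files = files)
}
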