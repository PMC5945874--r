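#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
NULL

# Derive a stage-local seed from a root seed and a text label, so that each
# generator stage draws from its own reproducible stream.  Polynomial string
# hash mod (2^31 - 1), kept in exact double arithmetic.
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  as.integer(h)
}

phred_offset <- 33L

# Complement/reverse-complement for plain character vectors of DNA.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> allowed concrete bases.  "N" in the genome never matches any
# pattern code, so N is absent from every allowed set on the genome side.
iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) abort(paste0("unknown IUPAC code: ", code))
  strsplit(map[[code]], "")[[1]]
}

read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

write_genome_fasta <- function(genome, path) {
  stopifnot(!is.null(names(genome)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

# Substitution sequencing errors: mutate random bases to a different base
# and mark those positions in the quality string.  `seqs` are
# reference-orientation strings; returns list(seq, qual).
apply_seq_errors <- function(seqs, error_rate, base_qual = "I", err_qual = "#") {
  lens <- nchar(seqs)
  quals <- strrep(base_qual, lens)
  if (error_rate <= 0) return(list(seq = seqs, qual = quals))
  n_err <- stats::rbinom(length(seqs), lens, error_rate)
  hit <- which(n_err > 0)
  if (!length(hit)) return(list(seq = seqs, qual = quals))
  ridx <- rep(hit, n_err[hit])
  pos <- unlist(lapply(hit, function(i) sample.int(lens[i], n_err[i])))
  old <- match(substring(seqs[ridx], pos, pos), DNA_BASES)
  new <- DNA_BASES[((old - 1L + sample.int(3, length(old), replace = TRUE))
                    %% 4L) + 1L]
  for (k in seq_along(ridx)) {
    substr(seqs[ridx[k]], pos[k], pos[k]) <- new[k]
    substr(quals[ridx[k]], pos[k], pos[k]) <- err_qual
  }
  list(seq = seqs, qual = quals)
}

json_manifest <- function(files, path) {
  files <- files[file.exists(files)]
  manifest <- list(
    files = purrr::map(
      stats::setNames(as.list(files), basename(files)),
      function(f) list(path = basename(f), md5 = unname(tools::md5sum(f)),
                       bytes = file.size(f))
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
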