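#' Parameterize a synthetic digestion experiment
#'
#' A `sim_spec` fully determines a synthetic in-vitro-digestion sequencing
#' run: the genome, the background fragmentation, the planted cleavage
#' sites, and the read layer.  Identical specs (same seed) reproduce
#' byte-identical FASTA/FASTQ/SAM/TSV outputs.
#'
#' @param seed Integer root seed; every stage derives its own stream from it.
#' @param genome_length Genome length in bp.
#' @param gc_content Target GC fraction in `[0, 1]`.
#' @param planted_sites List of [planted_site()] records.
#' @param fragment_mean Mean background fragment size in bp (random shearing
#'   is modelled as a Poisson break process, i.e. exponential inter-break
#'   distances with this mean).
#' @param read_length Read length in bp (paired-end, both fragment ends).
#' @param coverage Target fold coverage (linear x).
#' @param sequencing_error_rate Per-base substitution error probability.
#' @param contig Contig name used in all outputs.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(seed, genome_length = 1e6, gc_content = 0.42,
                     planted_sites = list(), fragment_mean = 400,
                     read_length = 150, coverage = 30,
                     sequencing_error_rate = 0.001, contig = "chrS") {
  if (genome_length <= 0) abort("genome_length must be positive")
  if (coverage <= 0) abort("coverage must be positive")
  if (gc_content < 0 || gc_content > 1) abort("gc_content must lie in [0, 1]")
  if (sequencing_error_rate < 0 || sequencing_error_rate > 1)
    abort("sequencing_error_rate must lie in [0, 1]")
  if (genome_length < 10 * fragment_mean)
    abort("genome_length must be at least 10 * fragment_mean")
  for (s in planted_sites) {
    if (s$position < 0 || s$position + s$overhang > genome_length)
      abort("planted site coordinates outside genome bounds")
  }
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_content = gc_content, planted_sites = planted_sites,
         fragment_mean = fragment_mean, read_length = as.integer(read_length),
         coverage = coverage, sequencing_error_rate = sequencing_error_rate,
         contig = contig),
    class = "sim_spec"
  )
}

#' Describe a planted cleavage site
#'
#' @param position 0-based top-strand cut coordinate `c_top`: the bond
#'   between `position - 1` and `position` is broken on the top strand.
#' @param overhang 5' overhang length in nt, one of 1:5.
#' @param efficiency Fraction of molecules cleaved, in `[0, 1]`.
#' @param guide_id Optional guide identifier.
#' @return A list of class `planted_site`.
#' @export
planted_site <- function(position, overhang = 4, efficiency = 1,
                         guide_id = NA_character_) {
  if (!overhang %in% 1:5) abort("overhang must be one of 1, 2, 3, 4, 5")
  if (efficiency < 0 || efficiency > 1) abort("efficiency must lie in [0, 1]")
  structure(list(position = as.integer(position), overhang = as.integer(overhang),
                 efficiency = efficiency, guide_id = guide_id),
            class = "planted_site")
}

#' Read or write a sim_spec as YAML
#' @param spec A [sim_spec()].
#' @param path File path.
#' @return `read_sim_spec` returns a `sim_spec`; `write_sim_spec` its path,
#'   invisibly.
#' @export
write_sim_spec <- function(spec, path) {
  x <- unclass(spec)
  x$planted_sites <- purrr::map(x$planted_sites, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$planted_sites <- purrr::map(x$planted_sites, ~ do.call(planted_site, .x))
  do.call(sim_spec, x)
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc_content / 2`.  For genomes
#' of 100 kb or more the realized GC fraction is within ~2% of the target
#' (binomial concentration).
#'
#' @param spec A [sim_spec()], or an integer length (with `gc_content` and
#'   `seed` supplied).
#' @param gc_content,seed,contig Used when `spec` is a bare length.
#' @param fasta Optional path; when given the genome is also written as FASTA.
#' @return Named character vector of length 1 (contig name -> sequence).
#' @export
sim_genome <- function(spec, gc_content = 0.42, seed = NULL, contig = "chrS",
                       fasta = NULL) {
  if (inherits(spec, "sim_spec")) {
    len <- spec$genome_length; gc <- spec$gc_content
    seed <- spec$seed; contig <- spec$contig
  } else {
    len <- as.integer(spec); gc <- gc_content
    if (is.null(seed)) abort("seed must be supplied")
    if (len <= 0) abort("genome length must be positive")
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- withr::with_seed(derive_seed(seed, "genome"), {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  })
  names(genome) <- contig
  if (!is.null(fasta)) write_genome_fasta(genome, fasta)
  genome
}

#' Plant a PAM + protospacer locus into a genome
#'
#' Writes a TTTV-style PAM followed by the protospacer at `pam_position`,
#' substituting exactly `mismatches` seeded random protospacer positions, so
#' that off-target loci at a known Hamming distance can be planted.  The
#' PAM's degenerate positions are drawn from their allowed bases (V is one
#' of A/C/G, never T).
#'
#' @param genome Named character vector (one contig) as from [sim_genome()].
#' @param guide_id Identifier for the resulting [guide_target()].
#' @param protospacer Protospacer sequence, PAM-proximal end first
#'   (default length 23).
#' @param pam_position 0-based position where the 4-nt PAM starts.
#' @param mismatches Number of protospacer substitutions to plant.
#' @param pam_pattern IUPAC PAM pattern written at the locus.
#' @param seed Seed for the mismatch/PAM draws.
#' @param cut_offset Expected top-strand cut, bp downstream of protospacer
#'   start (Cpf1 cuts distal to the PAM; default 18).
#' @return List with `genome` (modified sequence) and `guide`
#'   (a [guide_target()] row describing the planted locus).
#' @export
plant_guide_site <- function(genome, guide_id, protospacer, pam_position,
                             mismatches = 0, pam_pattern = "TTTV", seed = 1,
                             cut_offset = 18) {
  contig <- names(genome)[1]
  seq <- unname(genome[1])
  ps <- toupper(protospacer)
  np <- nchar(ps)
  npam <- nchar(pam_pattern)
  if (mismatches < 0 || mismatches > np)
    abort("mismatches must lie in [0, protospacer length]")
  if (pam_position < 0 || pam_position + npam + np > nchar(seq))
    abort("locus does not fit inside the genome at pam_position")

  locus <- withr::with_seed(derive_seed(seed, paste0("plant:", guide_id)), {
    pam <- vapply(strsplit(pam_pattern, "")[[1]], function(code) {
      allowed <- iupac_bases(code)
      if (length(allowed) == 1) allowed else sample(allowed, 1)
    }, character(1))
    body <- strsplit(ps, "")[[1]]
    if (mismatches > 0) {
      at <- sample.int(np, mismatches)
      for (p in at) body[p] <- sample(setdiff(DNA_BASES, body[p]), 1)
    }
    paste(c(pam, body), collapse = "")
  })

  substr(seq, pam_position + 1, pam_position + npam + np) <- locus
  names(seq) <- contig
  start <- pam_position + npam
  guide <- guide_target(
    guide_id = guide_id, protospacer = ps, pam_pattern = pam_pattern,
    contig = contig, start = start, end = start + np, strand = "+",
    expected_cut = start + cut_offset
  )
  list(genome = seq, guide = guide)
}
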