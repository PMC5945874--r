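# Build a small synthetic study on disk: genome FASTA with an on-target and
# a 2-mismatch off-target locus, a digestion SAM cutting both, and amplicon
# FASTQs.  Returns the config list run_specificity()/run_efficiency() take.
make_study <- function(dir, seed = 101, eff_ot = 0.8) {
  spec <- sim_spec(seed = seed, genome_length = 60000, coverage = 30)
  g <- sim_genome(spec)
  ps <- random_dna(23, seed = seed + 1)
  on <- plant_guide_site(g, "on", ps, pam_position = 15000, mismatches = 0,
                         seed = seed + 2)
  ot <- plant_guide_site(on$genome, "ot", ps, pam_position = 45000,
                         mismatches = 2, seed = seed + 3)
  genome <- ot$genome
  cut_on <- on$guide$expected_cut
  cut_ot <- ot$guide$expected_cut
  spec$planted_sites <- list(
    planted_site(cut_on, overhang = 4, efficiency = 1, guide_id = "on"),
    planted_site(cut_ot, overhang = 4, efficiency = eff_ot, guide_id = "ot"))
  fasta <- file.path(dir, "genome.fa")
  digenomer:::write_genome_fasta(genome, fasta)
  dig <- simulate_digest(genome, spec, out_prefix = file.path(dir, "digest"))

  amp_ref <- substr(unname(genome), cut_on - 99, cut_on + 100)
  spectrum <- indel_spectrum(tibble::tibble(net = c(-4L, -3L),
                                            offset = c(0L, 1L),
                                            fraction = c(0.25, 0.05)),
                             wild_type_fraction = 0.7)
  amp <- simulate_amplicon(amp_ref, spectrum, n_reads = 400, error_rate = 0.003,
                           cut_position = 100, seed = seed + 4,
                           out_prefix = file.path(dir, "amp_on"))
  list(config = list(
         genome = fasta,
         alignments = unname(dig$files[["sam"]]),
         guides = list(list(guide_id = "on", protospacer = ps,
                            contig = "chrS", start = on$guide$start,
                            end = on$guide$end, strand = "+",
                            expected_cut = cut_on)),
         amplicons = list(list(amplicon_id = "on",
                               fastq = amp$files[["fastq"]],
                               reference = amp_ref,
                               guide_window = c(73, 100 + 5))),
         out_dir = file.path(dir, "out")),
       truth = list(cut_on = cut_on, cut_ot = cut_ot, amp = amp))
}

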