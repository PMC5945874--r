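test_that("genome generation is seed-deterministic and validates input", {
  g1 <- sim_genome(1000, gc_content = 0.5, seed = 7)
  g2 <- sim_genome(1000, gc_content = 0.5, seed = 7)
  expect_identical(g1, g2)
  expect_equal(nchar(unname(g1)), 1000)
  g3 <- sim_genome(1000, gc_content = 0.5, seed = 8)
  expect_false(identical(g1, g3))
  expect_error(sim_genome(0, seed = 1), "positive")
})

test_that("base composition tracks the GC target at 100 kb", {
  g <- sim_genome(1e5, gc_content = 0.5, seed = 3)
  gc <- sum(strsplit(unname(g), "")[[1]] %in% c("G", "C")) / 1e5
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
})

test_that("planted locus has the requested PAM and Hamming distance", {
  g <- sim_genome(5000, seed = 2)
  ps <- random_dna(23, seed = 9)
  pl0 <- plant_guide_site(g, "g0", ps, pam_position = 2000, mismatches = 0,
                          seed = 4)
  locus <- substr(unname(pl0$genome), 2001, 2027)
  pam <- substr(locus, 1, 4)
  expect_match(pam, "^TTT[ACG]$")               # V is never T
  expect_identical(substr(locus, 5, 27), ps)

  pl4 <- plant_guide_site(g, "g4", ps, pam_position = 2000, mismatches = 4,
                          seed = 4)
  body <- substr(unname(pl4$genome), 2005, 2027)
  hd <- sum(strsplit(body, "")[[1]] != strsplit(ps, "")[[1]])
  expect_equal(hd, 4)
  expect_match(substr(unname(pl4$genome), 2001, 2004), "^TTT[ACG]$")

  expect_error(plant_guide_site(g, "gx", ps, pam_position = 4990),
               "does not fit")
})

test_that("digestion output is deterministic and conserves reads", {
  spec <- sim_spec(seed = 5, genome_length = 20000, coverage = 10,
                   planted_sites = list(planted_site(10000, overhang = 3,
                                                     efficiency = 0.8,
                                                     guide_id = "g")))
  g <- sim_genome(spec)
  d1 <- simulate_digest(g, spec)
  d2 <- simulate_digest(g, spec)
  expect_identical(d1$alignments, d2$alignments)
  expect_identical(d1$fragments, d2$fragments)
  # paired ends: two reads per fragment
  expect_equal(nrow(d1$alignments), 2 * nrow(d1$fragments))

  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a"); p2 <- file.path(dir, "b")
  simulate_digest(g, spec, out_prefix = p1)
  simulate_digest(g, spec, out_prefix = p2)
  for (ext in c(".sam", "_R1.fastq", "_R2.fastq", "_truth.tsv")) {
    expect_identical(unname(tools::md5sum(paste0(p1, ext))),
                     unname(tools::md5sum(paste0(p2, ext))),
                     label = paste("byte-identical", ext))
  }
})

test_that("full cleavage leaves no forward read spanning the cut", {
  ct <- 10000L
  spec <- sim_spec(seed = 6, genome_length = 20000, coverage = 20,
                   sequencing_error_rate = 0,
                   planted_sites = list(planted_site(ct, overhang = 4,
                                                     efficiency = 1,
                                                     guide_id = "g")))
  g <- sim_genome(spec)
  d <- simulate_digest(g, spec)
  pu <- build_end_pileup(d$alignments)
  row <- dplyr::filter(tibble::as_tibble(pu), pos == ct)
  expect_gt(row$F, 0)
  expect_equal(row$F, row$Df)                    # every covering read starts here
  # cut ledger: every molecule carries a cut at the site
  expect_equal(nrow(d$cuts), length(unique(d$fragments$molecule)))
  frag_cuts <- dplyr::filter(d$fragments, right_cut == "g")
  expect_true(all(frag_cuts$top_end == ct))
  expect_true(all(frag_cuts$bottom_end == ct + 4))
})

test_that("zero efficiency looks like background at the planted position", {
  ct <- 10000L
  spec <- sim_spec(seed = 7, genome_length = 20000, coverage = 20,
                   planted_sites = list(planted_site(ct, overhang = 4,
                                                     efficiency = 0,
                                                     guide_id = "g")))
  g <- sim_genome(spec)
  d <- simulate_digest(g, spec)
  expect_false(any(d$fragments$right_cut == "g"))
  pu <- build_end_pileup(d$alignments)
  row <- dplyr::filter(tibble::as_tibble(pu), pos == ct)
  # background 5'-end rate per position is ~ depth / fragment_mean; at
  # depth ~10 per strand expect 0 or a handful, never a vertical pileup
  expect_lt(row$F, 5)
})

test_that("partial efficiency matches a binomial draw on the truth ledger", {
  ct <- 500000L
  spec <- sim_spec(seed = 11, genome_length = 1e6, coverage = 30,
                   sequencing_error_rate = 0,
                   planted_sites = list(planted_site(ct, overhang = 4,
                                                     efficiency = 0.6,
                                                     guide_id = "g")))
  g <- sim_genome(spec)
  d <- simulate_digest(g, spec)
  n_mol <- length(unique(d$fragments$molecule))
  n_cut <- nrow(d$cuts)
  ci <- stats::qbinom(c(0.005, 0.995), n_mol, 0.6)
  expect_gte(n_cut, ci[1])
  expect_lte(n_cut, ci[2])
  # every surviving cut fragment yields a forward read starting at c_top
  pu <- build_end_pileup(d$alignments)
  row <- dplyr::filter(tibble::as_tibble(pu), pos == ct)
  from_cuts <- nrow(dplyr::filter(d$fragments, left_cut == "g"))
  bg_starts <- nrow(dplyr::filter(d$fragments, left_cut != "g",
                                  top_start == ct))
  expect_equal(row$F, from_cuts + bg_starts)
})

test_that("sites too close to the contig edge are skipped with a warning", {
  spec <- sim_spec(seed = 8, genome_length = 20000, coverage = 5,
                   planted_sites = list(planted_site(50, overhang = 2,
                                                     efficiency = 1)))
  g <- sim_genome(spec)
  expect_warning(d <- simulate_digest(g, spec), "edge")
  expect_false(any(d$fragments$right_cut == "planted"))
})

test_that("sim_spec validates geometry and round-trips through YAML", {
  expect_error(sim_spec(1, genome_length = 100, fragment_mean = 400), "10 *")
  expect_error(planted_site(10, overhang = 6), "overhang")
  expect_error(planted_site(10, efficiency = 1.2), "efficiency")
  expect_error(sim_spec(1, genome_length = 1e5,
                        planted_sites = list(planted_site(2e5))),
               "bounds")
  spec <- sim_spec(seed = 9, genome_length = 5e4, coverage = 3,
                   planted_sites = list(planted_site(2e4, overhang = 5,
                                                     efficiency = .5,
                                                     guide_id = "q")))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_spec(spec, path)
  expect_equal(read_sim_spec(path), spec, ignore_attr = TRUE)
})

test_that("amplicon simulation honors the spectrum and the truth ledger", {
  ref <- random_dna(200, seed = 12)
  # all-WT, no error: reads identical to reference
  wt <- indel_spectrum(tibble::tibble(net = -4L, offset = 0L, fraction = 0),
                       wild_type_fraction = 1)
  s0 <- simulate_amplicon(ref, wt, n_reads = 50, error_rate = 0,
                          cut_position = 100, seed = 1)
  expect_true(all(s0$reads$seq == ref))
  expect_true(all(s0$truth$class == "WT"))

  mix <- indel_spectrum(tibble::tibble(net = -4L, offset = 0L, fraction = 0.3),
                        wild_type_fraction = 0.7)
  s1 <- simulate_amplicon(ref, mix, n_reads = 1000, error_rate = 0,
                          cut_position = 100, seed = 3)
  n_del <- sum(s1$truth$class == "-4")
  expect_equal(n_del + sum(s1$truth$class == "WT"), 1000)
  ci <- stats::qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(n_del, ci[1]); expect_lte(n_del, ci[2])
  # the planted deletion shortens exactly the -4 reads
  expect_true(all(nchar(s1$reads$seq[s1$truth$class == "-4"]) == 196))
  expect_true(all(nchar(s1$reads$seq[s1$truth$class == "WT"]) == 200))

  half <- indel_spectrum(tibble::tibble(net = c(-3L, 1L), offset = c(0L, 0L),
                                        fraction = c(0.5, 0.5)),
                         wild_type_fraction = 0)
  s2 <- simulate_amplicon(ref, half, n_reads = 400, error_rate = 0,
                          cut_position = 100, seed = 4)
  expect_true(all(s2$truth$class != "WT"))
  in_frame <- s2$truth$net %% 3 == 0
  expect_equal(sort(unique(s2$truth$net)), c(-3L, 1L))
  expect_equal(sum(in_frame) + sum(!in_frame), 400)

  expect_error(indel_spectrum(tibble::tibble(net = 0L, offset = 0L,
                                             fraction = 0.5),
                              wild_type_fraction = 0.5), "nonzero")
  expect_error(indel_spectrum(tibble::tibble(net = -4L, offset = 0L,
                                             fraction = 0.5),
                              wild_type_fraction = 0.4), "sum to 1")
  long <- indel_spectrum(tibble::tibble(net = -300L, offset = 0L,
                                        fraction = 1),
                         wild_type_fraction = 0)
  expect_error(simulate_amplicon(ref, long, 10, 0, 100, 1), "longer")
})
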