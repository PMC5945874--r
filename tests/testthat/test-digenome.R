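toy_pileup <- function(F, R, Df, Dr, start = 0, contig = "chrT") {
  n <- length(F)
  tbl <- tibble::tibble(contig = contig, pos = start + seq_len(n) - 1L,
                        F = F, R = R, Df = Df, Dr = Dr)
  digenomer:::new_end_pileup(tbl, contig, start, start + n,
                             c(total = 0L))
}

test_that("score formula matches hand evaluation", {
  # F=10/Df=10 at f; R=8/Dr=10 at f+3 (overhang 4): 1.0 * 0.8 * 9 = 7.2
  pu <- toy_pileup(F = c(10, 0, 0, 0, 0, 0),
                   R = c(0, 0, 0, 8, 0, 0),
                   Df = c(10, 10, 10, 10, 10, 10),
                   Dr = c(10, 10, 10, 10, 10, 10))
  got <- cleavage_score(pu, f = 0)
  expect_equal(got$score, 7.2)
  expect_equal(got$best_overhang, 4L)
  expect_equal(got$F, 10L)
  expect_equal(got$R, 8L)
})

test_that("score is zero without forward support and support floors apply", {
  pu <- toy_pileup(F = rep(0, 6), R = rep(10, 6),
                   Df = rep(10, 6), Dr = rep(10, 6))
  expect_equal(cleavage_score(pu, f = 0)$score, 0)
  # counts below min_support are zeroed
  pu2 <- toy_pileup(F = c(2, 0, 0, 0, 0, 0), R = c(2, 2, 2, 2, 2, 2),
                    Df = rep(10, 6), Dr = rep(10, 6))
  expect_equal(cleavage_score(pu2, f = 0)$score, 0)
  expect_gt(cleavage_score(pu2, f = 0,
                           scoring_params(min_support = 1))$score, 0)
  # zero depth on either strand zeroes the score rather than dividing by 0
  pu3 <- toy_pileup(F = c(5, 0, 0, 0, 0, 0), R = rep(5, 6),
                    Df = rep(0, 6), Dr = rep(10, 6))
  expect_equal(cleavage_score(pu3, f = 0)$score, 0)
})

test_that("full cleavage at depth d scores d and ties pick the smallest overhang", {
  d <- 30
  pu <- toy_pileup(F = c(d, 0, 0, 0, 0, 0), R = c(d, 0, 0, 0, 0, 0),
                   Df = rep(d, 6), Dr = rep(d, 6))
  got <- cleavage_score(pu, f = 0)                # overhang 1: r = f
  expect_equal(got$score, d)
  expect_equal(got$best_overhang, 1L)
  # equal scores at overhang 2 and 4 -> smallest wins
  pu2 <- toy_pileup(F = c(10, 0, 0, 0, 0, 0), R = c(0, 6, 0, 6, 0, 0),
                    Df = rep(10, 6), Dr = rep(10, 6))
  expect_equal(cleavage_score(pu2, f = 0)$best_overhang, 2L)
  expect_error(cleavage_score(pu, f = 3), "span")
})

test_that("score is monotone in F and R at fixed depths", {
  base <- function(F1, R4) {
    pu <- toy_pileup(F = c(F1, 0, 0, 0, 0, 0), R = c(0, 0, 0, R4, 0, 0),
                     Df = rep(20, 6), Dr = rep(20, 6))
    cleavage_score(pu, f = 0)$score
  }
  s <- vapply(3:20, function(f) base(f, 10), numeric(1))
  expect_true(all(diff(s) >= 0))
  s2 <- vapply(3:20, function(r) base(10, r), numeric(1))
  expect_true(all(diff(s2) >= 0))
})

test_that("scan equals exhaustive per-position recomputation on a toy pileup", {
  withr::with_seed(31, {
    n <- 400
    F <- rpois(n, 0.5); R <- rpois(n, 0.5)
    Df <- F + rpois(n, 8); Dr <- R + rpois(n, 8)
    F[200] <- 25; Df[200] <- 28
    R[203] <- 24; Dr[203] <- 27
    pu <- toy_pileup(F, R, Df, Dr)
    want <- oracle_score_scan(pu)
    got <- scan_genome(pu, scoring_params(), merge = FALSE)
    want_calls <- dplyr::filter(want, score >= 2.5)
    expect_equal(got$cut_position, as.integer(want_calls$pos))
    expect_equal(got$score, want_calls$score)
    expect_equal(got$best_overhang, as.integer(want_calls$best_overhang))
    # every scored position agrees, not just the calls
    all_pos <- cleavage_score(pu, f = 0:(n - 5))
    expect_equal(all_pos$score, want$score)
    expect_equal(all_pos$best_overhang, as.integer(want$best_overhang))
  })
})

test_that("planted sites are called with their overhang on simulated data", {
  for (case in list(list(seed = 41, oh = 1L, eff = 1.0),
                    list(seed = 42, oh = 4L, eff = 0.7),
                    list(seed = 43, oh = 5L, eff = 0.5))) {
    ct <- 30000L
    spec <- sim_spec(seed = case$seed, genome_length = 60000, coverage = 30,
                     planted_sites = list(planted_site(ct, overhang = case$oh,
                                                       efficiency = case$eff,
                                                       guide_id = "g")))
    d <- simulate_digest(sim_genome(spec), spec)
    calls <- scan_genome(build_end_pileup(d$alignments))
    hit <- dplyr::filter(calls, abs(cut_position - ct) <= 5)
    expect_equal(nrow(hit), 1, label = paste("seed", case$seed))
    expect_equal(hit$best_overhang, case$oh, label = paste("seed", case$seed))
    expect_gte(hit$score, 2.5)
  }
})

test_that("expected site score increases with planted efficiency", {
  score_at <- function(eff, seed) {
    ct <- 30000L
    spec <- sim_spec(seed = seed, genome_length = 60000, coverage = 30,
                     planted_sites = list(planted_site(ct, overhang = 3,
                                                       efficiency = eff,
                                                       guide_id = "g")))
    d <- simulate_digest(sim_genome(spec), spec)
    pu <- build_end_pileup(d$alignments)
    cleavage_score(pu, f = ct)$score
  }
  seeds <- 51:55
  s02 <- vapply(seeds, function(s) score_at(0.2, s), numeric(1))
  s05 <- vapply(seeds, function(s) score_at(0.5, s), numeric(1))
  s10 <- vapply(seeds, function(s) score_at(1.0, s), numeric(1))
  expect_lt(mean(s02), mean(s05))
  expect_lt(mean(s05), mean(s10))
})

test_that("raising the cutoff above the maximum score silences all calls", {
  spec <- sim_spec(seed = 44, genome_length = 30000, coverage = 20,
                   planted_sites = list(planted_site(15000, overhang = 2,
                                                     efficiency = 1,
                                                     guide_id = "g")))
  d <- simulate_digest(sim_genome(spec), spec)
  pu <- build_end_pileup(d$alignments)
  calls <- scan_genome(pu)
  expect_gte(nrow(calls), 1)
  high <- scan_genome(pu, scoring_params(cutoff = max(calls$score) + 1))
  expect_equal(nrow(high), 0)
})

test_that("merge_calls keeps the best representative and is idempotent", {
  calls <- tibble::tibble(contig = "chrT",
                          cut_position = c(100L, 104L),
                          score = c(5, 9), best_overhang = c(1L, 2L),
                          F = c(5L, 9L), R = c(5L, 9L),
                          Df = c(10L, 10L), Dr = c(10L, 10L))
  m <- merge_calls(calls, 10)
  expect_equal(nrow(m), 1)
  expect_equal(m$cut_position, 104L)
  expect_equal(merge_calls(m, 10), m)
  # ties go to the smaller coordinate
  tie <- dplyr::mutate(calls, score = 5)
  expect_equal(merge_calls(tie, 10)$cut_position, 100L)
  # beyond the distance both survive
  far <- dplyr::mutate(calls, cut_position = c(100L, 200L))
  expect_equal(nrow(merge_calls(far, 10)), 2)
  # chains collapse transitively and count never increases
  chain <- tibble::tibble(contig = "chrT",
                          cut_position = c(100L, 108L, 116L),
                          score = c(3, 4, 8), best_overhang = 1L,
                          F = 3L, R = 3L, Df = 9L, Dr = 9L)
  expect_equal(merge_calls(chain, 10)$cut_position, 116L)
  expect_equal(nrow(merge_calls(calls[0, ], 10)), 0)
})

test_that("BED and bedGraph exports round-trip coordinates exactly", {
  calls <- tibble::tibble(contig = c("chrT", "chrT"),
                          cut_position = c(1000L, 2500L),
                          score = c(38.25, 3.75), best_overhang = c(4L, 1L),
                          F = c(30L, 4L), R = c(30L, 4L),
                          Df = c(30L, 10L), Dr = c(30L, 10L))
  bed <- withr::local_tempfile(fileext = ".bed")
  export_sites(calls, bed)
  lines <- readLines(bed)
  expect_match(lines[2], "^chrT\t1000\t1001\t")
  back <- read_sites_bed(bed)
  expect_equal(back$cut_position, calls$cut_position)
  expect_equal(back$score, calls$score)
  expect_equal(back$best_overhang, calls$best_overhang)

  bg <- withr::local_tempfile(fileext = ".bedgraph")
  export_track(calls, bg, floor = 0.1)
  track <- read_track_bedgraph(bg)
  expect_equal(track$cut_position, calls$cut_position)
  expect_equal(track$score, calls$score)
  # floor drops sub-threshold rows
  export_track(calls, bg, floor = 10)
  expect_equal(nrow(read_track_bedgraph(bg)), 1)

  # empty call set -> header-only files that parse to empty tables
  export_sites(calls[0, ], bed)
  expect_equal(nrow(read_sites_bed(bed)), 0)
  export_track(calls[0, ], bg)
  expect_equal(nrow(read_track_bedgraph(bg)), 0)
})

test_that("tidy and glance summarize scans", {
  pu <- toy_pileup(F = c(20, 0, 0, 0, 0, 0), R = c(20, 0, 0, 0, 0, 0),
                   Df = rep(20, 6), Dr = rep(20, 6))
  calls <- scan_genome(pu)
  expect_s3_class(calls, "cleavage_calls")
  td <- generics::tidy(calls)
  expect_false(inherits(td, "cleavage_calls"))
  g <- generics::glance(calls)
  expect_equal(g$n_sites, nrow(calls))
  expect_equal(g$cutoff, 2.5)
})
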