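---
title: "Calling Cpf1 cleavage sites and quantifying editing outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling Cpf1 cleavage sites and quantifying editing outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenomer)
library(dplyr)
```

# The problem

Cpf1 (Cas12a) nucleases such as LbCpf1 are attractive for in vivo therapeutic
editing: the coding sequence fits an AAV together with its crRNA, the enzyme
needs no tracrRNA, and it recognizes a T-rich PAM (5'-TTTV-3') 5' of the
protospacer. Two computational questions dominate the assessment of such a
nuclease:

1. **Specificity** — where does the enzyme actually cut genomic DNA?
   Digested-genome sequencing answers this empirically: cell-free genomic DNA
   is digested in vitro with the ribonucleoprotein, sequenced to moderate
   whole-genome depth, and cleavage positions are recovered from the
   alignment, because reads from cut molecules all *start* at the cut bond
   rather than at random shear points. A complementary in-silico scan
   enumerates every candidate site with partial guide homology.
2. **Efficiency** — how often does repair of the break leave an indel at a
   target locus, and what fraction of those indels shifts the reading frame?
   Amplicon deep sequencing answers this per locus.

`digenomer` implements both workflows end to end, plus a seeded simulation
kit that generates genomes, digestion read sets and amplicon read sets with
known ground truth, so every estimator in the package can be validated
without any external data.

# Cut geometry and coordinates

All coordinates are 0-based, half-open. A "cut at `c_top`" means the top
strand's phosphodiester bond between positions `c_top - 1` and `c_top` is
broken. Cpf1 produces a staggered double-strand break distal to the PAM with
a 5'-protruding overhang of 1–5 nt: the bottom-strand cut lies `o` bp
downstream of the top-strand cut. The consequence visible in sequencing data
is the pairing rule used throughout the package:

* forward-strand read 5' ends pile up at `f = c_top`;
* reverse-strand read 5' ends pile up at `r = c_top + o - 1`.

The simulator and the scorer share this single convention, which is what the
planted-site recovery tests exercise.

# The cleavage score

`build_end_pileup()` reduces an alignment file to four per-position vectors:
`F` and `R`, the strand-specific counts of read 5' termini, and the strand
depths `Df`, `Dr`. For a candidate top-strand cut `f` and overhang `o`
(reverse position `r = f + o - 1`) the score is

$$ S_o(f) \;=\; \frac{F(f)}{D_f(f)} \times \frac{R(r)}{D_r(r)} \times
   \frac{F(f) + R(r)}{2} $$

and a position's score is the maximum of `S_o` over the overhang sweep
(ties resolved to the smallest overhang, for determinism). The two ratio
factors measure how *vertical* the end pileup is — at a fully cleaved site
every covering read terminates at the cut, so both ratios are 1 — and the
mean end support scales the score by the evidence, so a site cut in every
molecule at depth `d` scores approximately `d`, while random Covaris-style
shearing, which spreads 5' ends uniformly, scores far below 1. Positions
with score at or above the cutoff (default 2.5) become calls; calls within
`merge_distance` (10 bp) collapse to the best-scoring representative.

The score is zeroed when either strand has zero depth or fewer than
`min_support` (default 3) supporting ends; the floor suppresses
division-noise calls at ragged low-depth positions and is the one guard not
inherited from the published workflow, which states no support floor. The
scoring function itself is a pluggable parameter of `scoring_params()`, so
published variants of the statistic can be swapped in without touching the
scanning machinery.

Defaults worth knowing, all surfaced in `scoring_params()`:

| parameter        | default | meaning                                     |
|------------------|--------:|---------------------------------------------|
| `overhang_min/max` | 1 / 5 | 5' overhang sweep, nt                        |
| `cutoff`         |     2.5 | score at or above which a position is called |
| `min_support`    |       3 | minimum 5'-end reads per strand              |
| `merge_distance` |      10 | bp; nearby calls collapse                    |

Alignment filtering follows common digested-genome practice: base-quality
cutoff 15 and duplicates kept (`alignment_filter()`); when many molecules
are cleaved at one bond, identical read starts are signal, not PCR
artifacts. The quality cutoff is applied to the terminal (5'-end) base for
end counting — that is the base that defines the cut evidence — and
per-base for depth. Both behaviors are flags.

# Candidate-site enumeration

`find_candidate_sites()` is an exhaustive, Cas-OFFinder-style scanner: a hit
requires an exact IUPAC match of the PAM (default `TTTV`; V = A/C/G)
immediately 5' of the protospacer on the hit's strand, and protospacer
Hamming distance at most `k` (default 4, the conventional search radius for
this enzyme class). Ambiguous genome bases (N) never match. No DNA/RNA
bulges are considered, and both strands are scanned; overlapping hits on
opposite strands are distinct cleavage opportunities and are both reported.
At desk scale (genomes up to a few Mb) the exhaustive scan is fast enough
that indexing would be complexity without benefit.

`annotate_calls()` joins the empirical calls to the candidate list: a call
within 25 bp (`window`) of the guide's intended locus is labelled `ON`,
within 25 bp of a k-mismatch candidate `OT-k`, otherwise `UNEXPLAINED`.

# Amplicon indel quantification

Each read is aligned to its amplicon reference with an affine-gap aligner
(match 2, mismatch −4, gap open −10, gap extend −1; a gap of length k costs
`open + k·extend`). The read aligns end to end while the amplicon's ends are
gap-free, so partial-span reads are not penalized for not covering the whole
amplicon. Indel operations are extracted in reference coordinates and
left-aligned (VCF-style normalization), which makes the mutant pattern table
stable under equivalent gap placements. Full-length reads within Hamming
distance 2 of the reference take a gap-free fast path; under these scores a
single gap costs at least 11 while two substitutions cost at most 12, and
any gapped alternative for such a read is bounded strictly below the
gap-free score, so the shortcut is exact, not approximate.

A read is an *indel read* when at least one insertion or deletion overlaps
the guide window (protospacer + PAM span) padded by 5 bp. A window rather
than a point estimate is used because Cpf1 cuts distal to the PAM and can
re-cut after small indels, so the empirical indel position wobbles around
the nominal cut. Substitutions never count as indels — which is also why
moderate sequencing error (≤0.5%) does not bias the frequency estimate.

Summaries report `indel_frequency = 100 × indel_reads / analyzed_reads`,
and split indel reads into in-frame and out-of-frame by the *net* length
change modulo 3 per read (per-op framing is ill-defined for multi-op
reads); the two fractions total 100 exactly. When no reads are analyzable
the frequency is reported as missing, never as 0. Patterns are keyed by the
left-aligned op signature and ranked by count with lexicographic
tie-breaks.

# What the simulator emulates — and what it does not

`simulate_digest()` models each sequenced molecule as a full-length genome
copy broken at two kinds of bonds: background shearing (a Poisson process,
i.e. exponential inter-break spacing with mean `fragment_mean`, default
400 bp — the published protocols state Covaris shearing but no size target)
and planted staggered cuts applied per molecule with probability
`efficiency`. Both ends of every fragment are sequenced (paired 150 bp
reads, fixed high base quality, substitution errors at
`sequencing_error_rate` flagged by a low quality character). Because the
simulator knows every true coordinate it emits already-aligned SAM next to
the FASTQ, which removes the external aligner from the unit-test loop; the
FASTQ output still supports end-to-end runs through a real aligner. It also
returns the alignments in memory, so large multi-seed validation runs can
skip file I/O; the file path and the in-memory path are asserted equal on a
seeded dataset.

The read layer for digestion data deliberately omits PCR amplification
bias, duplicate-read simulation, quality-score error models, indel
sequencing errors and adapters. Passing recovery tests therefore
demonstrates correctness of the coordinate logic and the estimator under
idealized noise, not robustness to every artifact of real libraries — on
real data, mapping ambiguity and chimeric fragments are additional failure
modes the score's support floor only partially addresses.

Simulation scales used by the test-suite and the reproduction script were
chosen as the smallest sizes at which the claims are meaningful: a 1 Mb
genome at 30× for site recovery (a planted site at efficiency 0.5 then has
~15 supporting molecules per strand, comfortably above `min_support` yet
far from saturated), 20 replicate seeds, and 1000-read amplicons (binomial
99% intervals of ±2–4 percentage points around the planted fractions).

`simulate_amplicon()` draws each read's class from the planted spectrum
(wild type, or one signed net-length change at a stated offset from the
cut), applies the indel, then substitution errors, and writes a truth
ledger naming every read's class — the oracle for the frequency and frame
estimators.

# Numerical and design choices

* **Determinism.** Every stage derives its own RNG stream from one root
  seed by a fixed label, so stages are individually reproducible and
  whole-pipeline reruns are byte-identical (the workflow writes a JSON
  manifest with md5 checksums of each output).
* **Overhang ties** go to the smallest overhang; **merge ties** to the
  smaller coordinate; **pattern ties** to lexicographic order. All
  tie-breaks are documented determinism guarantees, not biology.
* **Reverse-read 5' end** is the rightmost reference-aligned base
  (alignment end − 1): that is the biological 5' terminus created by
  bottom-strand cleavage.
* **Deletions** consume reference and count toward depth; **insertions**
  and **soft clips** never contribute to ends or depth (standard pileup
  semantics).
* **Degenerate inputs**: empty alignment sets yield all-zero pileups and
  empty call lists, not errors; zero analyzable amplicon reads yield
  missing frequencies; planted sites within a read length of a contig edge
  are skipped with a warning.
* **Tiling**: `stream_pileups()` tiles a contig with overlap ≥ the maximum
  overhang and each tile owns a core interval; cores partition the genome,
  so tiled and untiled scans are exactly equal — including for a site
  bisected by a tile boundary.

# Known limitations

* The cleavage-score statistic is this package's explicit reconstruction of
  the per-position scoring idea used in nuclease-digestion sequencing
  studies; published formulations vary and the original equation for this
  assay is not printed in the source literature, so the cutoff (2.5) should
  be treated as a tunable operating point, not a universal constant. The
  score interface is pluggable for exactly this reason.
* Blunt cuts (overhang 0) are outside the default sweep; set
  `overhang_min = 0` at your own calibration risk.
* Paired-end overlap merging, UMIs, chimeric reads and base-editing
  (substitution) outcomes are out of scope for the amplicon module.
* CRAM input is not supported; SAM/BAM only.

# A compact worked example

```{r example, eval = FALSE}
library(digenomer)

# a 60 kb genome with a planted on-target locus
spec <- sim_spec(seed = 7, genome_length = 60000, coverage = 30)
genome <- sim_genome(spec)
protospacer <- "ATGACAGGCCGGAAACCCCGAGA"
planted <- plant_guide_site(genome, "TS3", protospacer,
                            pam_position = 30000)
spec$planted_sites <- list(planted_site(planted$guide$expected_cut,
                                        overhang = 4, efficiency = 0.8,
                                        guide_id = "TS3"))

dig <- simulate_digest(planted$genome, spec)
pileup <- build_end_pileup(dig$alignments)
calls <- scan_genome(pileup)
glance(calls)

hits <- find_candidate_sites(planted$genome, planted$guide)
annotate_calls(calls, hits, planted$guide)
```
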