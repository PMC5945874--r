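# Independent reference implementations used as oracles.  These are kept
# deliberately naive (per-read / per-position loops) and share no code with
# the package internals they check.

# --- naive end-pileup recount ------------------------------------------------

parse_cigar_naive <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(ops = ops, lens = lens)
}

oracle_end_pileup <- function(rec, start, end, min_bq = 15,
                              keep_dup = TRUE, min_mapq = 0,
                              primary_only = TRUE) {
  span <- end - start
  F <- integer(span); R <- integer(span)
  Df <- integer(span); Dr <- integer(span)
  bump <- function(v, p) {                       # p: 0-based ref position
    if (p >= start && p < end) v[p - start + 1] <- v[p - start + 1] + 1L
    v
  }
  for (i in seq_len(nrow(rec))) {
    flag <- rec$flag[i]
    if (bitwAnd(flag, 4L)) next
    if (primary_only && (bitwAnd(flag, 256L) || bitwAnd(flag, 2048L))) next
    if (!keep_dup && bitwAnd(flag, 1024L)) next
    if (!is.na(rec$mapq[i]) && rec$mapq[i] < min_mapq) next
    cg <- parse_cigar_naive(rec$cigar[i])
    q <- utf8ToInt(rec$qual[i]) - 33L
    no_qual <- rec$qual[i] == "*"
    refp <- rec$pos[i]                           # 0-based
    qp <- 0L
    base_ref <- integer(0); base_q <- integer(0)
    for (k in seq_along(cg$ops)) {
      op <- cg$ops[k]; n <- cg$lens[k]
      if (op %in% c("M", "=", "X")) {
        base_ref <- c(base_ref, refp + seq_len(n) - 1L)
        base_q <- c(base_q, if (no_qual) rep(99L, n) else q[qp + seq_len(n)])
        refp <- refp + n; qp <- qp + n
      } else if (op == "D" || op == "N") {
        if (op == "D") {                          # deletions count toward depth
          base_ref <- c(base_ref, refp + seq_len(n) - 1L)
          base_q <- c(base_q, rep(99L, n))
        }
        refp <- refp + n
      } else if (op == "S" || op == "I") {
        qp <- qp + n
      }
    }
    fwd <- rec$strand[i] == "+"
    for (k in seq_along(base_ref)) {
      if (base_q[k] >= min_bq) {
        if (fwd) Df <- bump(Df, base_ref[k]) else Dr <- bump(Dr, base_ref[k])
      }
    }
    # terminal 5'-end base: leftmost aligned base (forward) / rightmost
    # (reverse); counted when its base quality passes
    aligned_q <- base_q[base_q != 99L | no_qual]
    end5 <- if (fwd) base_ref[1] else base_ref[length(base_ref)]
    q5 <- if (fwd) base_q[1] else base_q[length(base_q)]
    if (length(end5) && q5 >= min_bq) {
      if (fwd) F <- bump(F, end5) else R <- bump(R, end5)
    }
  }
  tibble::tibble(pos = start + seq_len(span) - 1L, F = F, R = R,
                 Df = Df, Dr = Dr)
}

# --- brute-force candidate-site scan ----------------------------------------

oracle_find_sites <- function(genome, protospacer, pam_pattern = "TTTV",
                              max_mismatches = 4) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  pam_allowed <- lapply(strsplit(pam_pattern, "")[[1]],
                        function(cd) strsplit(iupac[[cd]], "")[[1]])
  ps <- strsplit(protospacer, "")[[1]]
  npam <- length(pam_allowed); np <- length(ps); L <- npam + np
  scan1 <- function(chars, strand, N, contig) {
    out <- list()
    if (length(chars) < L) return(out)
    for (i in 0:(length(chars) - L)) {
      ok <- TRUE
      for (j in seq_len(npam)) {
        if (!(chars[i + j] %in% pam_allowed[[j]])) { ok <- FALSE; break }
      }
      if (!ok) next
      w <- chars[(i + npam + 1):(i + L)]
      mm <- sum(w != ps | w == "N")
      if (mm <= max_mismatches) {
        ps0 <- i + npam
        start <- if (strand == "+") ps0 else N - (ps0 + np)
        out[[length(out) + 1]] <- tibble::tibble(
          contig = contig, start = start, end = start + np, strand = strand,
          mismatches = mm, site_sequence = paste(w, collapse = ""))
      }
    }
    out
  }
  res <- list()
  for (ctg in names(genome)) {
    seq <- toupper(genome[[ctg]]); N <- nchar(seq)
    fwd <- strsplit(seq, "")[[1]]
    rev <- strsplit(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))), "")[[1]]
    res <- c(res, scan1(fwd, "+", N, ctg), scan1(rev, "-", N, ctg))
  }
  if (!length(res))
    return(tibble::tibble(contig = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          mismatches = integer(0),
                          site_sequence = character(0)))
  dplyr::arrange(dplyr::bind_rows(res), contig, start, strand)
}

# --- quadratic DP alignment score (read global, reference ends free) --------

oracle_align_score <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = -10, gap_extend = -1) {
  r <- strsplit(read, "")[[1]]; s <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(s)
  NEG <- -1e9
  open1 <- -(gap_open + gap_extend)              # cost of a length-1 gap
  ext1 <- -gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)                 # gap in reference (insertion)
  Y <- matrix(NEG, n + 1, m + 1)                 # gap in read (deletion)
  M[1, ] <- 0                                    # free leading reference
  for (i in 2:(n + 1)) {
    for (j in 1:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open1, X[i - 1, j] - ext1,
                     Y[i - 1, j] - open1)
      if (j >= 2) {
        sc <- if (r[i - 1] == s[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
        Y[i, j] <- max(M[i, j - 1] - open1, Y[i, j - 1] - ext1,
                       X[i, j - 1] - open1)
      }
    }
  }
  max(M[n + 1, ], X[n + 1, ])                    # free trailing reference
}

# --- exhaustive cleavage-score recomputation --------------------------------

oracle_score_scan <- function(pileup, overhang_min = 1, overhang_max = 5,
                              min_support = 3) {
  d <- tibble::as_tibble(pileup)
  n <- nrow(d)
  res <- list()
  for (i in seq_len(n - overhang_max + 1)) {
    best <- 0; best_o <- overhang_min
    for (o in overhang_min:overhang_max) {
      j <- i + o - 1
      Fv <- d$F[i]; Rv <- d$R[j]; Dfv <- d$Df[i]; Drv <- d$Dr[j]
      s <- if (Dfv == 0 || Drv == 0 || Fv < min_support || Rv < min_support)
        0 else (Fv / Dfv) * (Rv / Drv) * (Fv + Rv) / 2
      if (s > best) { best <- s; best_o <- o }
    }
    res[[i]] <- c(pos = d$pos[i], score = best, best_overhang = best_o)
  }
  out <- as.data.frame(do.call(rbind, res))
  tibble::as_tibble(out)
}

# --- small SAM fixture writer ------------------------------------------------

write_sam_fixture <- function(rec, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  rec <- rec[order(rec$pos), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   rec$qname, rec$flag, rec$contig, rec$pos + 1L, rec$mapq,
                   rec$cigar, rec$seq, rec$qual)
  writeLines(c(hdr, lines), path)
  path
}

# random alignment records (occasionally clipped/indel-bearing, duplicate or
# secondary flagged) for recount oracles
random_rec <- function(n, contig = "chrT", contig_len = 300, seed = 1) {
  withr::with_seed(seed, {
    pos <- sample(0:(contig_len - 60), n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    kind <- sample(c("plain", "clip", "ins", "del"), n, replace = TRUE,
                   prob = c(.6, .2, .1, .1))
    cigar <- character(n); qlen <- integer(n)
    for (i in seq_len(n)) {
      cigar[i] <- switch(kind[i],
        plain = "40M", clip = "5S35M3S", ins = "20M2I18M", del = "20M3D20M")
      qlen[i] <- switch(kind[i], plain = 40L, clip = 43L, ins = 40L, del = 40L)
    }
    qual <- vapply(qlen, function(l)
      intToUtf8(33L + sample(c(2L, 20L, 40L), l, replace = TRUE,
                             prob = c(.1, .2, .7))), character(1))
    flag <- ifelse(strand == "-", 16L, 0L)
    dup <- sample(c(0L, 1024L), n, replace = TRUE, prob = c(.8, .2))
    sec <- sample(c(0L, 256L), n, replace = TRUE, prob = c(.9, .1))
    tibble::tibble(
      qname = sprintf("r%03d", seq_len(n)), flag = flag + dup + sec,
      contig = contig, pos = pos, strand = strand, mapq = 60L,
      cigar = cigar,
      seq = vapply(qlen, function(l) paste(sample(c("A", "C", "G", "T"), l,
                                                  replace = TRUE),
                                           collapse = ""), character(1)),
      qual = qual)
  })
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
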