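#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML/JSON config (or takes a list), fills defaults (score
#' cutoff 2.5, overhang sweep 1-5 nt, up to 4 protospacer mismatches,
#' annotation window 25 bp), and validates.  All problems are collected
#' and reported together, each naming the offending key path.
#' Normalization is idempotent.
#'
#' @param x Path to a YAML/JSON file, or a list.
#' @return A normalized list of class `pipeline_config`.
#' @export
validate_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(paste0("config file not found: ", x))
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else yaml::read_yaml(x)
  }
  if (!is.list(x)) abort("config must be a list or a YAML/JSON path")
  errors <- character(0)
  need <- function(key, ok, msg) {
    if (!ok) errors <<- c(errors, paste0(key, ": ", msg))
  }

  sp <- x$scoring %||% list()
  x$scoring <- list(
    overhang_min = sp$overhang_min %||% 1,
    overhang_max = sp$overhang_max %||% 5,
    cutoff = sp$cutoff %||% 2.5,
    min_support = sp$min_support %||% 3,
    merge_distance = sp$merge_distance %||% 10
  )
  x$max_mismatches <- x$max_mismatches %||% 4
  x$annotation_window <- x$annotation_window %||% 25
  x$seed <- x$seed %||% 1

  need("scoring.cutoff", x$scoring$cutoff > 0, "must be positive")
  need("scoring.overhang_min",
       x$scoring$overhang_min >= 1 &&
         x$scoring$overhang_min <= x$scoring$overhang_max,
       "need 1 <= overhang_min <= overhang_max")
  need("max_mismatches", x$max_mismatches >= 0, "must be non-negative")

  need("genome", !is.null(x$genome), "missing genome FASTA path")
  if (!is.null(x$genome))
    need("genome", file.exists(x$genome), "file does not exist")
  if (!is.null(x$alignments))
    need("alignments", file.exists(x$alignments), "file does not exist")

  gs <- x$guides %||% list()
  need("guides", length(gs) >= 1, "at least one guide is required")
  x$guides <- purrr::map(gs, function(g) {
    list(guide_id = g$guide_id %||% g$id %||% NA_character_,
         protospacer = g$protospacer %||% NA_character_,
         pam_pattern = g$pam_pattern %||% "TTTV",
         contig = g$contig %||% NA_character_,
         start = g$start %||% NA_integer_,
         end = g$end %||% NA_integer_,
         strand = g$strand %||% NA_character_,
         expected_cut = g$expected_cut %||% NA_integer_)
  })
  for (i in seq_along(x$guides)) {
    g <- x$guides[[i]]
    need(paste0("guides[", i, "].guide_id"), !is.na(g$guide_id), "missing")
    need(paste0("guides[", i, "].protospacer"),
         !is.na(g$protospacer) && grepl("^[ACGTacgt]+$", g$protospacer),
         "missing or not A/C/G/T")
  }

  amps <- x$amplicons %||% list()
  x$amplicons <- purrr::map(amps, function(a) {
    list(amplicon_id = a$amplicon_id %||% a$id %||% NA_character_,
         fastq = a$fastq %||% NA_character_,
         reference = a$reference %||% NA_character_,
         guide_window = a$guide_window %||% NULL,
         window_pad = a$window_pad %||% 5)
  })
  for (i in seq_along(x$amplicons)) {
    a <- x$amplicons[[i]]
    need(paste0("amplicons[", i, "].amplicon_id"), !is.na(a$amplicon_id),
         "missing")
    need(paste0("amplicons[", i, "].reference"), !is.na(a$reference),
         "missing amplicon reference sequence")
    need(paste0("amplicons[", i, "].guide_window"),
         length(a$guide_window) == 2, "need c(start, end)")
    if (!is.na(a$fastq))
      need(paste0("amplicons[", i, "].fastq"), file.exists(a$fastq),
           "file does not exist")
  }
  ids <- purrr::map_chr(x$amplicons, "amplicon_id")
  need("amplicons", !anyDuplicated(ids), "duplicate amplicon IDs")

  x$out_dir <- x$out_dir %||% "digenomer_out"
  if (length(errors)) abort(paste0("invalid config:\n  ",
                                   paste(errors, collapse = "\n  ")))
  keep <- c("genome", "alignments", "guides", "amplicons", "scoring",
            "max_mismatches", "annotation_window", "seed", "out_dir")
  x <- stats::setNames(lapply(keep, function(k) x[[k]]), keep)
  structure(x, class = "pipeline_config")
}

config_guides <- function(config) {
  purrr::map(config$guides, ~ do.call(guide_target, .x))
}

config_amplicon_configs <- function(config) {
  out <- purrr::map(config$amplicons, function(a)
    amplicon_config(a$reference, unlist(a$guide_window),
                    window_pad = a$window_pad))
  names(out) <- purrr::map_chr(config$amplicons, "amplicon_id")
  out
}

#' Run the specificity workflow
#'
#' Executes end pileup -> cleavage scoring and calling -> candidate-site
#' annotation, and, when amplicon FASTQs are configured, per-site indel
#' quantification.  All intermediates are written under `out_dir` together
#' with a JSON manifest carrying md5 checksums; reruns on identical inputs
#' are byte-identical.
#'
#' @param config A [validate_config()] result (or something it accepts).
#' @param out_dir Output directory (overrides the config's).
#' @return Invisible list with `calls` (annotated tibble), `hits`,
#'   `summaries` (per-amplicon tibble or NULL) and `files`.
#' @export
run_specificity <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$alignments))
    abort("stage endpileup: config$alignments (SAM/BAM) is required")

  genome <- read_genome_fasta(config$genome)
  params <- scoring_params(
    overhang_min = config$scoring$overhang_min,
    overhang_max = config$scoring$overhang_max,
    cutoff = config$scoring$cutoff,
    min_support = config$scoring$min_support,
    merge_distance = config$scoring$merge_distance)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("stage ", stage, ": ", conditionMessage(e))))
  }

  calls <- run_stage("digenome", {
    purrr::map_dfr(names(genome), function(ctg) {
      pu <- build_end_pileup(config$alignments, contig = ctg)
      scan_genome(pu, params)
    })
  })
  calls <- new_cleavage_calls(calls, params)

  guides <- config_guides(config)
  annotated <- run_stage("sitescan", {
    purrr::map_dfr(guides, function(g) {
      hits <- find_candidate_sites(genome, g,
                                   max_mismatches = config$max_mismatches)
      ann <- annotate_calls(calls, hits, guide = g,
                            window = config$annotation_window)
      dplyr::bind_cols(tibble(guide_id = g$guide_id[1]), ann)
    })
  })
  hits_all <- run_stage("sitescan", {
    purrr::map_dfr(guides, function(g)
      dplyr::bind_cols(tibble(guide_id = g$guide_id[1]),
                       find_candidate_sites(genome, g,
                                            max_mismatches = config$max_mismatches)))
  })

  summaries <- NULL
  if (length(config$amplicons) &&
      all(!is.na(purrr::map_chr(config$amplicons, "fastq")))) {
    summaries <- run_stage("indelquant", {
      samples <- tibble(
        amplicon_id = purrr::map_chr(config$amplicons, "amplicon_id"),
        fastq = purrr::map_chr(config$amplicons, "fastq"))
      batch_quantify(samples, config_amplicon_configs(config))
    })
  }

  files <- c(
    sites_bed = file.path(out_dir, "cleavage_sites.bed"),
    track = file.path(out_dir, "cleavage_score.bedgraph"),
    calls_tsv = file.path(out_dir, "annotated_calls.tsv"),
    hits_tsv = file.path(out_dir, "candidate_sites.tsv"))
  export_sites(calls, files[["sites_bed"]])
  export_track(calls, files[["track"]], floor = 0)
  readr::write_tsv(annotated, files[["calls_tsv"]])
  readr::write_tsv(hits_all, files[["hits_tsv"]])
  if (!is.null(summaries)) {
    files <- c(files, summaries_tsv = file.path(out_dir, "site_indel_summaries.tsv"))
    readr::write_tsv(summaries, files[["summaries_tsv"]])
  }
  manifest <- file.path(out_dir, "manifest.json")
  json_manifest(files, manifest)
  invisible(list(calls = annotated, hits = hits_all, summaries = summaries,
                 files = c(files, manifest = manifest)))
}

#' Run the efficiency workflow
#'
#' Per-amplicon indel quantification (frequency, frame split, patterns)
#' over the configured FASTQs, with a manifest of outputs.
#'
#' @inheritParams run_specificity
#' @return Invisible list with `summaries` and `files`.
#' @export
run_efficiency <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!length(config$amplicons))
    abort("stage indelquant: no amplicons configured")
  samples <- tibble(
    amplicon_id = purrr::map_chr(config$amplicons, "amplicon_id"),
    fastq = purrr::map_chr(config$amplicons, "fastq"))
  if (anyNA(samples$fastq)) abort("stage indelquant: amplicon without fastq")
  summaries <- batch_quantify(samples, config_amplicon_configs(config))
  out <- file.path(out_dir, "amplicon_summaries.tsv")
  readr::write_tsv(summaries, out)
  manifest <- file.path(out_dir, "manifest.json")
  json_manifest(out, manifest)
  invisible(list(summaries = summaries,
                 files = c(summaries_tsv = out, manifest = manifest)))
}
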