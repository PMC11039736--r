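# End-to-end orchestration: footprint calling -> size filter -> optional
# known-motif masking -> iterative discovery -> database comparison and
# reports, with a differential two-condition entry point and a small CLI.

#' Run configuration
#'
#' A flat key-value list mirroring the CLI flags. Recognized keys: `track`
#' (bedGraph/BigWig path) or `track_a`/`track_b` for differential runs,
#' `genome` (FASTA), `out_dir`, optional `motif_db` (JASPAR), `mask_mode`
#' (`motif_location`/`whole_fp`), `dialect`, `seed`, plus any [fp_params]
#' or [discovery_params] field.
#'
#' @param path TOML-style `key = value` text file; `#` comments allowed.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1L], collapse = "="))
    v <- gsub('^"|"$', "", v)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[[1L]]), ""))
}

config_params <- function(config, ctor) {
  fml <- names(formals(ctor))
  do.call(ctor, config[intersect(names(config), fml)])
}

#' End-to-end de novo discovery run
#'
#' Executes footprint calling, merging and size filtering on the input score
#' track, optionally masks footprint portions explained by a known motif
#' database, runs [iterative_discovery], compares the consensus motifs to the
#' database, and writes footprints (BED), per-iteration and consensus motifs
#' (JASPAR + MEME minimal), reports (TSV) and a manifest (JSON) into
#' `out_dir`. Deterministic given `seed`: reruns produce byte-identical
#' motif files.
#'
#' @param config list (or config file path) — see [read_config]. Required:
#'   `track`, `genome`, `out_dir`.
#' @param track optional pre-loaded [score_track] overriding `config$track`.
#' @return list of class `"fp_run"` with footprints, discovery result,
#'   database comparison and output paths. `status` is 0 on success and 3
#'   when no footprint or motif survived (empty-result warning path).
#' @export
run_discovery <- function(config, track = NULL) {
  if (is.character(config)) config <- read_config(config)
  for (key in c("genome", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  if (is.null(track) && is.null(config$track))
    stop("config is missing required key: track")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- if (is.character(config$genome) && length(config$genome) == 1L &&
                file.exists(config$genome)) read_fasta(config$genome)
            else config$genome
  if (is.null(track)) {
    dialect <- config$dialect %||%
      (if (grepl("\\.(bw|bigwig)$", config$track, ignore.case = TRUE))
        "bigwig" else "bedgraph")
    track <- read_score_track(config$track, dialect,
                              chrom_lengths = nchar(genome))
  }
  fpp <- config_params(config, fp_params)
  dpp <- config_params(config, discovery_params)
  if (!is.null(config$seed)) dpp$rng_seed <- as.integer(config$seed)

  fps <- call_footprints(track, fpp)
  fps <- merge_footprints(fps, track, fpp$merge_gap_max, fpp$merge_depth_frac)
  fps <- filter_by_size(fps, fpp$min_fp_size)

  db <- NULL
  mask_report <- NULL
  if (!is.null(config$motif_db)) {
    db <- if (is.character(config$motif_db)) read_motifs(config$motif_db,
                                                         "jaspar")
          else config$motif_db
    if (nrow(fps) > 0L) {
      seqs <- extract_sequences(genome, fps)
      hits <- scan_sequences(seqs, db, intervals = fps)
      before <- nrow(fps)
      fps <- mask_known(fps, hits, config$mask_mode %||% "motif_location",
                        fpp$min_fp_size, track)
      mask_report <- data.frame(fps_before = before, hits = nrow(hits),
                                fps_after = nrow(fps))
    }
  }

  write_footprints_bed(fps, file.path(out_dir, "footprints.bed"))
  if (nrow(fps) == 0L) {
    warning("no footprint survived filtering; empty result")
    manifest(config, dpp, fpp, out_dir, status = 3L)
    return(structure(list(footprints = fps, discovery = NULL,
                          comparison = NULL, out_dir = out_dir, status = 3L),
                     class = "fp_run"))
  }

  disc <- iterative_discovery(fps, genome, dpp)
  write_motifs(disc$significant,
               file.path(out_dir, "iteration_motifs.jaspar"), "jaspar")
  write_motifs(disc$consensus, file.path(out_dir, "consensus_motifs.jaspar"),
               "jaspar")
  write_motifs(disc$consensus, file.path(out_dir, "consensus_motifs.meme"),
               "meme_minimal")
  write.table(data.frame(iteration = seq_along(disc$pool_sizes),
                         pool_size = disc$pool_sizes),
              file.path(out_dir, "pool_trajectory.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  comparison <- NULL
  if (!is.null(db) && length(disc$consensus)) {
    comparison <- compare_to_database(disc$consensus, db,
                                      dpp$merge_threshold)
    write.table(comparison$summary,
                file.path(out_dir, "database_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(mask_report))
    write.table(mask_report, file.path(out_dir, "masking_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  status <- if (length(disc$consensus)) 0L else 3L
  manifest(config, dpp, fpp, out_dir, status)
  structure(list(footprints = fps, discovery = disc, comparison = comparison,
                 out_dir = out_dir, status = status), class = "fp_run")
}

#' Differential two-condition discovery run
#'
#' Computes the differential track `max(0, A - B)` and hands it to
#' [run_discovery]; resulting motifs stem from binding events unique to
#' condition A (run again with swapped tracks for the other direction).
#'
#' @param config list or config file path with `track_a`, `track_b`,
#'   `genome`, `out_dir` (see [read_config]).
#' @return An `"fp_run"` object; condition labels are recorded in the
#'   manifest.
#' @export
run_differential <- function(config) {
  if (is.character(config)) config <- read_config(config)
  for (key in c("track_a", "track_b"))
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  genome <- if (is.character(config$genome) && length(config$genome) == 1L &&
                file.exists(config$genome)) read_fasta(config$genome)
            else config$genome
  config$genome <- genome
  load <- function(x) {
    if (inherits(x, "score_track")) return(x)
    dialect <- if (grepl("\\.(bw|bigwig)$", x, ignore.case = TRUE))
      "bigwig" else "bedgraph"
    read_score_track(x, dialect, chrom_lengths = nchar(genome))
  }
  diff <- differential_track(load(config$track_a), load(config$track_b))
  config$mode <- "differential"
  run_discovery(config, track = diff)
}

manifest <- function(config, dpp, fpp, out_dir, status) {
  # keep only scalar settings: pre-loaded tracks/genomes are not serializable
  cfg <- config[vapply(config, function(x) {
    is.atomic(x) && length(x) == 1L
  }, logical(1))]
  checksums <- lapply(cfg[vapply(cfg, function(x) {
    is.character(x) && file.exists(x) && !dir.exists(x)
  }, logical(1))], function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(
    list(package = "denovofp",
         version = as.character(utils::packageVersion("denovofp")),
         status = status, config = cfg, fp_params = unclass(fpp),
         discovery_params = unclass(dpp), input_checksums = checksums),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `footprints`, `discover`, `diff`, `run`
#' (`discover` and `run` are synonyms; `characterize` reports on an existing
#' run). Flags are `--key value` pairs overriding the optional
#' `--config FILE`. Exit codes: 0 success, 2 validation error, 3
#' empty-result warning.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
fp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: denovofp <simulate|footprints|discover|diff|run> [--key value ...]\n")
    return(invisible(2L))
  }
  cmd <- args[[1L]]
  flags <- args[-1L]
  config <- list()
  i <- 1L
  while (i <= length(flags)) {
    key <- sub("^--", "", flags[[i]])
    val <- if (i + 1L <= length(flags)) flags[[i + 1L]] else ""
    num <- suppressWarnings(as.numeric(val))
    config[[key]] <- if (!is.na(num)) num else val
    i <- i + 2L
  }
  if (!is.null(config$config)) {
    file_cfg <- read_config(config$config)
    config <- utils::modifyList(file_cfg, config[names(config) != "config"])
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        keys <- setdiff(intersect(names(config),
                                  names(formals(simulate_dataset))),
                        "out_dir")
        do.call(simulate_dataset, c(list(out_dir = config$out_dir %||% "."),
                                    config[keys]))
        0L
      },
      footprints = {
        genome <- read_fasta(config$genome)
        track <- read_score_track(config$track,
                                  config$dialect %||% "bedgraph",
                                  chrom_lengths = nchar(genome))
        fpp <- config_params(config, fp_params)
        fps <- filter_by_size(
          merge_footprints(call_footprints(track, fpp), track,
                           fpp$merge_gap_max, fpp$merge_depth_frac),
          fpp$min_fp_size)
        dir.create(config$out_dir %||% ".", showWarnings = FALSE,
                   recursive = TRUE)
        write_footprints_bed(fps, file.path(config$out_dir %||% ".",
                                            "footprints.bed"))
        0L
      },
      discover = ,
      run = run_discovery(config)$status,
      diff = run_differential(config)$status,
      characterize = {
        mot <- read_motifs(config$motifs, "jaspar")
        db <- read_motifs(config$motif_db, "jaspar")
        cmp <- compare_to_database(mot, db)
        dir.create(config$out_dir %||% ".", showWarnings = FALSE,
                   recursive = TRUE)
        write.table(cmp$summary,
                    file.path(config$out_dir %||% ".",
                              "database_comparison.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      { message("unknown subcommand: ", cmd); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
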