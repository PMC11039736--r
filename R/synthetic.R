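# Synthetic fixtures: random genomes with implanted motif instances and
# flat-topped footprint score tracks, optionally in two conditions.
# All generators are bit-reproducible given rng_seed.

#' Built-in truth motifs for simulations
#'
#' Four mutually dissimilar position frequency matrices with a dominant-base
#' probability of 0.85 per column, wide enough (8-10 bp) to be recovered by
#' the default discovery width range. The consensi were selected so that
#' every pairwise [motif_distance] (which considers all ungapped overlaps of
#' at least 4 columns, both orientations) exceeds 0.5 — comfortably above the
#' 0.4 merge/rediscovery threshold, keeping the implant truth unambiguous.
#'
#' @param n number of motifs (1 to 4).
#' @return list of `motif` objects.
#' @export
truth_motifs <- function(n = 4L) {
  consensi <- c(truthA = "TGGAGTCT", truthB = "AAGGCACA",
                truthC = "GACGGATGC", truthD = "TCATCATATC")
  stopifnot(n >= 1, n <= length(consensi))
  lapply(seq_len(n), function(i) {
    cons <- consensi[[i]]
    w <- nchar(cons)
    counts <- matrix(0.05, 4, w)
    counts[cbind(encode_dna(cons) + 1L, seq_len(w))] <- 0.85
    new_motif(counts * 100, nsites = 100, name = names(consensi)[i],
              source = "synthetic truth")
  })
}

#' Random genome sequence
#'
#' i.i.d. bases with `P(G) = P(C) = gc_fraction / 2`. The default GC content
#' of 0.41 approximates a mammalian genome.
#'
#' @param length genome length in bp (> 0).
#' @param gc_fraction GC fraction in (0, 1).
#' @param rng_seed integer seed.
#' @param chrom chromosome name.
#' @return named character vector of length 1.
#' @export
make_genome <- function(length, gc_fraction = 0.41, rng_seed = 1L,
                        chrom = "chrS") {
  stopifnot(length > 0, gc_fraction > 0, gc_fraction < 1)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  seq <- with_seed(rng_seed, paste(sample(DNA_BASES, length, replace = TRUE,
                                          prob = p), collapse = ""))
  stats::setNames(seq, chrom)
}

#' Implant motif instances into a genome
#'
#' Site sequences are sampled per column from each PFM, placed uniformly at
#' non-overlapping positions (separated by at least `min_gap` bp so that the
#' implant truth stays unambiguous) on a random strand; minus-strand sites
#' are implanted as the reverse complement. `ratios` are converted to counts
#' of `total_sites`, e.g. the benchmark mixture 40/30/20/10% of 2,000 sites.
#'
#' @param genome named character vector (single chromosome or more).
#' @param pfms list of `motif` objects to implant.
#' @param counts integer vector of site counts per motif; alternatively give
#'   `ratios` and `total_sites`.
#' @param ratios numeric vector of proportions (summing to 1) per motif.
#' @param total_sites total implant count used with `ratios`.
#' @param min_gap minimum spacing between implants (bp).
#' @param rng_seed integer seed.
#' @param avoid optional data.frame with start/end intervals (e.g. a previous
#'   truth table) that implants must keep clear of, so that successive
#'   implant rounds on the same genome stay non-overlapping.
#' @return list with `genome` (sequence with implants) and `truth`
#'   (data.frame chrom, start, end, strand, motif).
#' @export
implant_motifs <- function(genome, pfms, counts = NULL, ratios = NULL,
                           total_sites = NULL, min_gap = 30L, rng_seed = 1L,
                           avoid = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(ratios), !is.null(total_sites),
              abs(sum(ratios) - 1) < 1e-6)
    counts <- round(ratios * total_sites)
  }
  stopifnot(length(counts) == length(pfms))
  with_seed(rng_seed, {
    chrom <- names(genome)[1L]
    gl <- nchar(genome[[1L]])
    widths <- vapply(pfms, motif_width, integer(1))
    n_total <- sum(counts)
    wmax <- max(widths)
    # sample non-overlapping positions by rejection with bounded retries
    placed_start <- if (is.null(avoid)) integer(0) else as.integer(avoid$start)
    placed_end <- if (is.null(avoid)) integer(0) else as.integer(avoid$end)
    rows <- list()
    for (m in seq_along(pfms)) {
      p <- motif_probs(pfms[[m]])
      w <- widths[m]
      for (k in seq_len(counts[m])) {
        ok <- FALSE
        for (try in 1:1000) {
          s <- sample.int(gl - w + 1L, 1L) - 1L
          if (!any(placed_start < s + w + min_gap &
                     placed_end + min_gap > s)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("could not place ", n_total, " non-overlapping sites in ",
               gl, " bp")
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, s + w)
        site <- paste(vapply(seq_len(w), function(j) {
          sample(DNA_BASES, 1L, prob = p[, j])
        }, character(1)), collapse = "")
        strand <- sample(c("+", "-"), 1L)
        implant <- if (strand == "-") revcomp(site) else site
        substr(genome[[1L]], s + 1L, s + w) <- implant
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = chrom, start = s, end = s + w, strand = strand,
                     motif = pfms[[m]]$name)
      }
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = genome, truth = truth)
  })
}

#' Footprint-shaped score track over implanted sites
#'
#' Each site produces a flat-topped bump of height `peak_height` spanning the
#' site extended by `plateau_pad` bp on both sides; elsewhere the track is
#' truncated-at-zero Gaussian noise (scores are non-negative by definition).
#'
#' @param genome_length chromosome length in bp.
#' @param truth_sites data.frame with start/end (e.g. from [implant_motifs]).
#' @param peak_height bump height (score units).
#' @param plateau_pad bump extension beyond the site (bp).
#' @param noise_sd standard deviation of the background noise.
#' @param rng_seed integer seed.
#' @param chrom chromosome name.
#' @return A [score_track].
#' @export
make_fp_track <- function(genome_length, truth_sites, peak_height = 10,
                          plateau_pad = 5L, noise_sd = 0.1, rng_seed = 1L,
                          chrom = "chrS") {
  with_seed(rng_seed, {
    x <- if (noise_sd > 0) pmax(0, rnorm(genome_length, 0, noise_sd))
         else numeric(genome_length)
    for (i in seq_len(nrow(truth_sites))) {
      lo <- max(0L, truth_sites$start[i] - plateau_pad)
      hi <- min(genome_length, truth_sites$end[i] + plateau_pad)
      x[(lo + 1L):hi] <- peak_height
    }
    score_track(stats::setNames(list(x), chrom))
  })
}

#' Two-condition score tracks with shared and exclusive sites
#'
#' Condition A carries bumps at both the shared and the exclusive sites;
#' condition B carries the shared bumps only, so [differential_track]`(A, B)`
#' retains signal exclusively at the A-specific sites (exactly so in the
#' noise-free case).
#'
#' @param genome_length chromosome length in bp.
#' @param shared_sites,exclusive_sites truth data.frames (start/end).
#' @param peak_height,plateau_pad,noise_sd,chrom see [make_fp_track].
#' @param rng_seed integer seed (conditions use derived sub-seeds).
#' @return list with `track_a`, `track_b`, `truth` (list shared/exclusive).
#' @export
make_two_condition_tracks <- function(genome_length, shared_sites,
                                      exclusive_sites, peak_height = 10,
                                      plateau_pad = 5L, noise_sd = 0.1,
                                      rng_seed = 1L, chrom = "chrS") {
  a_sites <- rbind(shared_sites[, c("start", "end")],
                   exclusive_sites[, c("start", "end")])
  track_a <- make_fp_track(genome_length, a_sites, peak_height, plateau_pad,
                           noise_sd, rng_seed = rng_seed * 2L + 1L,
                           chrom = chrom)
  track_b <- make_fp_track(genome_length, shared_sites, peak_height,
                           plateau_pad, noise_sd,
                           rng_seed = rng_seed * 2L + 2L, chrom = chrom)
  list(track_a = track_a, track_b = track_b,
       truth = list(shared = shared_sites, exclusive = exclusive_sites))
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits FASTA genome, bedGraph score track, BED truth sites and JASPAR truth
#' motifs — only standard text formats, so every downstream step can be
#' exercised from files alone.
#'
#' @param out_dir output directory (created if needed).
#' @param genome_length,gc_fraction,ratios,total_sites,peak_height,plateau_pad,noise_sd,rng_seed
#'   generator settings; defaults follow the benchmark mixture design
#'   (40/30/20/10% of `total_sites`).
#' @param n_motifs number of truth motifs implanted.
#' @return invisibly, a list with `paths` (output files), `truth` (site
#'   table), `motifs`, `track` and `genome` (in-memory objects).
#' @export
simulate_dataset <- function(out_dir, genome_length = 200000L,
                             gc_fraction = 0.41,
                             ratios = c(0.4, 0.3, 0.2, 0.1),
                             total_sites = 2000L, n_motifs = length(ratios),
                             peak_height = 10, plateau_pad = 5L,
                             noise_sd = 0, rng_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  motifs <- truth_motifs(n_motifs)
  genome <- make_genome(genome_length, gc_fraction, rng_seed)
  imp <- implant_motifs(genome, motifs, ratios = ratios[seq_len(n_motifs)] /
                          sum(ratios[seq_len(n_motifs)]),
                        total_sites = total_sites, rng_seed = rng_seed + 1L)
  track <- make_fp_track(genome_length, imp$truth, peak_height, plateau_pad,
                         noise_sd, rng_seed + 2L,
                         chrom = names(genome)[1L])
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                track = file.path(out_dir, "track.bedgraph"),
                truth_bed = file.path(out_dir, "truth_sites.bed"),
                truth_motifs = file.path(out_dir, "truth_motifs.jaspar"))
  write_fasta(imp$genome, paths$genome)
  write_score_track(track, paths$track)
  write_bed(data.frame(chrom = imp$truth$chrom, start = imp$truth$start,
                       end = imp$truth$end, name = imp$truth$motif,
                       score = 0, strand = imp$truth$strand),
            paths$truth_bed)
  write_motifs(motifs, paths$truth_motifs, "jaspar")
  invisible(list(paths = paths, truth = imp$truth, motifs = motifs,
                 track = track, genome = imp$genome))
}
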