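# Characterization of discovered motifs: genome scanning, region enrichment,
# feature annotation, gene-set enrichment, database comparison and TF-class
# assignment via binding-site overlap, plus aggregate footprint profiles.

#' Genome-wide motif scan
#'
#' [scan_sequences] applied chromosome-wide; hit coordinates are genomic.
#'
#' @param motif a `motif` object (or list of motifs).
#' @param genome named character vector of chromosome sequences.
#' @param threshold_quantile tail probability of the match threshold.
#' @param background optional 4-vector; defaults to the genome composition.
#' @return data.frame of hits (motif, chrom, start, end, strand, score).
#' @export
genome_scan <- function(motif, genome, threshold_quantile = 1e-4,
                        background = NULL) {
  scan_sequences(genome, motif, threshold_quantile, background)
}

#' Binding-site enrichment in a region set
#'
#' `fold = (hits_in_regions / region_bp) / (hits_total / genome_bp)`; the
#' p-value is the one-sided binomial tail `P(X >= hits_in_regions)` with
#' `n = hits_total` and `p0 = region_bp / genome_bp` (the genome side is a
#' fixed length, hence binomial rather than Fisher). Overlapping regions are
#' merged first. With no hits at all, fold 0 / p 1 are returned with
#' `undefined = TRUE`.
#'
#' @param hits data.frame of motif hits.
#' @param regions data.frame of regions (chrom/start/end).
#' @param genome_bp total genome size in bp.
#' @return one-row data.frame: hits_in_regions, hits_total, region_bp,
#'   genome_bp, fold, p_value, undefined.
#' @export
region_enrichment <- function(hits, regions, genome_bp) {
  regions <- merge_intervals(regions)
  region_bp <- sum(regions$end - regions$start)
  if (genome_bp < region_bp) stop("genome_bp smaller than total region bp")
  n <- nrow(hits)
  if (n == 0L)
    return(data.frame(hits_in_regions = 0L, hits_total = 0L,
                      region_bp = region_bp, genome_bp = genome_bp,
                      fold = 0, p_value = 1, undefined = TRUE))
  k <- sum(vapply(seq_len(n), function(i) {
    any(regions$chrom == hits$chrom[i] & regions$start < hits$end[i] &
          regions$end > hits$start[i])
  }, logical(1)))
  p0 <- region_bp / genome_bp
  data.frame(hits_in_regions = k, hits_total = n, region_bp = region_bp,
             genome_bp = genome_bp,
             fold = (k / region_bp) / (n / genome_bp),
             p_value = pbinom(k - 1, n, p0, lower.tail = FALSE),
             undefined = FALSE)
}

# merge overlapping/adjacent intervals per chromosome
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end")])
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  out <- list()
  cur <- x[1L, c("chrom", "start", "end")]
  for (i in seq_len(nrow(x))[-1L]) {
    if (x$chrom[i] == cur$chrom && x$start[i] <= cur$end) {
      cur$end <- max(cur$end, x$end[i])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- x[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate hits with the nearest genomic feature
#'
#' Each hit is assigned the nearest feature anchor within `max_distance` bp
#' of its midpoint; the anchor is the feature start for + strand features and
#' the feature end for - strand features (0-based). The signed distance is
#' `anchor - midpoint`, 0 when the hit overlaps the feature body. Ties go to
#' the smaller absolute distance, then the lexicographically smaller feature
#' name. Hits without a feature in range get `NA`.
#'
#' @param hits data.frame of motif hits.
#' @param features data.frame with chrom/start/end/strand/name.
#' @param max_distance search radius in bp (default 10 kb).
#' @return `hits` with extra columns `feature` and `distance`.
#' @export
annotate_hits <- function(hits, features, max_distance = 10000L) {
  anchor <- ifelse(features$strand == "-", features$end, features$start)
  res <- lapply(seq_len(nrow(hits)), function(i) {
    mid <- (hits$start[i] + hits$end[i]) %/% 2L
    f <- which(features$chrom == hits$chrom[i])
    if (!length(f)) return(c(NA_character_, NA_real_))
    overlap <- features$start[f] < hits$end[i] & features$end[f] > hits$start[i]
    dist <- ifelse(overlap, 0, anchor[f] - mid)
    inr <- abs(dist) <= max_distance
    if (!any(inr)) return(c(NA_character_, NA_real_))
    f <- f[inr]; dist <- dist[inr]
    j <- order(abs(dist), features$name[f])[1L]
    c(features$name[f[j]], dist[j])
  })
  hits$feature <- vapply(res, `[[`, "", 1L)
  hits$distance <- as.numeric(vapply(res, `[[`, "", 2L))
  hits
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, the overlap k of the query genes with the set (both
#' restricted to the universe) is tested with the hypergeometric tail
#' `P(X >= k)`; Benjamini-Hochberg correction is applied across sets.
#'
#' @param genes character vector of query genes (subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. [read_gene_sets]).
#' @param universe character vector of all annotatable genes.
#' @return data.frame with set, set_size, overlap, fold, p_value, q_value.
#' @export
gsea <- function(genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  genes <- unique(intersect(genes, universe))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(genes, set))
    K <- length(set)
    N <- length(universe)
    n <- length(genes)
    expected <- n * K / N
    data.frame(set = nm, set_size = K, overlap = k,
               fold = if (expected > 0) k / expected else 0,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Compare consensus motifs to a reference database
#'
#' Per motif, the minimum [motif_distance] over the database decides the
#' label: below `threshold` the motif is a rediscovered database motif,
#' otherwise it is novel (a distance exactly at the threshold counts as
#' novel). The full distance matrix is returned for heatmaps.
#'
#' @param motifs list of consensus motifs.
#' @param db_motifs non-empty list of database motifs.
#' @param threshold similarity-distance threshold (default 0.4).
#' @return list with `summary` (data.frame motif, best_match, distance,
#'   label) and `distance_matrix` (motifs x database).
#' @export
compare_to_database <- function(motifs, db_motifs, threshold = 0.4) {
  if (!length(db_motifs)) stop("database is empty")
  dm <- matrix(NA_real_, length(motifs), length(db_motifs),
               dimnames = list(vapply(motifs, `[[`, "", "name"),
                               vapply(db_motifs, `[[`, "", "name")))
  for (i in seq_along(motifs))
    for (j in seq_along(db_motifs))
      dm[i, j] <- motif_distance(motifs[[i]], db_motifs[[j]])
  best <- apply(dm, 1L, which.min)
  summary <- data.frame(
    motif = rownames(dm),
    best_match = colnames(dm)[best],
    distance = dm[cbind(seq_along(motifs), best)],
    label = ifelse(dm[cbind(seq_along(motifs), best)] < threshold,
                   "rediscovered", "novel"))
  if (!length(motifs))
    summary <- data.frame(motif = character(), best_match = character(),
                          distance = numeric(), label = character())
  rownames(summary) <- NULL
  list(summary = summary, distance_matrix = dm)
}

#' Binding-site overlap coefficient between two hit sets
#'
#' The fraction of hits in the smaller set that share at least 1 bp with any
#' hit of the larger set (each hit counted once); 0 when either set is empty.
#'
#' @param hits_a,hits_b data.frames of motif hits on the same genome.
#' @return overlap coefficient in [0, 1].
#' @export
binding_site_overlap <- function(hits_a, hits_b) {
  if (nrow(hits_a) == 0L || nrow(hits_b) == 0L) return(0)
  if (nrow(hits_b) < nrow(hits_a)) { tmp <- hits_a; hits_a <- hits_b; hits_b <- tmp }
  big <- merge_intervals(hits_b)
  hit <- vapply(seq_len(nrow(hits_a)), function(i) {
    any(big$chrom == hits_a$chrom[i] & big$start < hits_a$end[i] &
          big$end > hits_a$start[i])
  }, logical(1))
  mean(hit)
}

#' TF-class enrichment via binding-site overlap
#'
#' The binding-site overlap of the target motif against every database motif
#' is computed; the database motifs above the `percentile` of that overlap
#' distribution form the top set N. For each TF-class, n = members of N in
#' the class is compared with dn = database motifs in the class out of
#' DN = database size: `fold = (n/N) / (dn/DN)`, p-value from the
#' hypergeometric tail `P(X >= n)` (drawing N from DN with dn successes),
#' BH-corrected across classes. Database motifs without a class annotation
#' are excluded from all counts. The percentile is computed per target motif.
#'
#' @param target_hits data.frame of the target motif's genome-scan hits.
#' @param db_motifs list of database motifs carrying `tf_class` annotations.
#' @param db_hits list of hit data.frames, parallel to `db_motifs`.
#' @param percentile overlap percentile defining the top set (default 95).
#' @return data.frame with tf_class, n, N, dn, DN, fold, p_value, q_value;
#'   zero rows with attribute `empty_top_set = TRUE` when N is empty.
#' @export
tf_class_enrichment <- function(target_hits, db_motifs, db_hits,
                                percentile = 95) {
  stopifnot(length(db_motifs) == length(db_hits))
  classes <- vapply(db_motifs, function(m) m$tf_class %||% NA_character_,
                    character(1))
  keep <- !is.na(classes)
  if (!any(keep)) stop("no database motif carries a TF-class annotation")
  classes <- classes[keep]
  db_hits <- db_hits[keep]
  ov <- vapply(db_hits, function(h) binding_site_overlap(target_hits, h),
               numeric(1))
  thr <- quantile(ov, percentile / 100)
  top <- which(ov > thr)
  DN <- length(classes)
  N <- length(top)
  empty <- data.frame(tf_class = character(), n = integer(), N = integer(),
                      dn = integer(), DN = integer(), fold = numeric(),
                      p_value = numeric(), q_value = numeric())
  if (N == 0L) {
    attr(empty, "empty_top_set") <- TRUE
    return(empty)
  }
  rows <- lapply(sort(unique(classes)), function(cl) {
    n <- sum(classes[top] == cl)
    dn <- sum(classes == cl)
    data.frame(tf_class = cl, n = n, N = N, dn = dn, DN = DN,
               fold = (n / N) / (dn / DN),
               p_value = phyper(n - 1, dn, DN - dn, N, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Aggregate signal profile around motif hits
#'
#' Mean per-base track signal in windows of width `2 * flank_bp` centered on
#' hit midpoints (default 120 bp view); minus-strand windows are reversed.
#' Only hits whose full window lies within the chromosome contribute.
#'
#' @param track a [score_track] (footprint-score or cut-site signal).
#' @param hits data.frame of motif hits.
#' @param flank_bp half window width (default 60).
#' @return list with `profile` (numeric vector, length `2 * flank_bp`) and
#'   `n` (number of hits used).
#' @export
aggregate_profile <- function(track, hits, flank_bp = 60L) {
  flank_bp <- as.integer(flank_bp)
  lens <- track_chrom_lengths(track)
  acc <- numeric(2L * flank_bp)
  n <- 0L
  for (i in seq_len(nrow(hits))) {
    ch <- hits$chrom[i]
    if (!ch %in% names(lens)) next
    mid <- (hits$start[i] + hits$end[i]) %/% 2L
    lo <- mid - flank_bp
    hi <- mid + flank_bp
    if (lo < 0L || hi > lens[[ch]]) next
    wnd <- track[[ch]][(lo + 1L):hi]
    if (!is.null(hits$strand) && hits$strand[i] == "-") wnd <- rev(wnd)
    acc <- acc + wnd
    n <- n + 1L
  }
  if (n == 0L) stop("no hit with a fully in-bounds window")
  list(profile = acc / n, n = n)
}
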