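# Motif similarity distance and clustering/merging into consensus motifs.
#
# The distance is 1 minus the best overlap-weighted mean per-column Pearson
# correlation over all ungapped alignments (both orientations, minimum 4
# overlapping columns). The 0.4 default threshold used for every merging
# operation below matches the similarity-distance threshold used throughout
# the workflow.

# all ungapped alignments of m2 (given orientation) against m1:
# offset k means m2 column j aligns with m1 column j + k; the mean column
# correlation is weighted by overlap / min(w1, w2) so that a chance match
# over a 4-column ledge cannot outrank a full-width alignment
align_scores <- function(p1, p2, min_overlap = 4L) {
  w1 <- ncol(p1); w2 <- ncol(p2)
  offsets <- (-(w2 - min_overlap)):(w1 - min_overlap)
  sc <- vapply(offsets, function(k) {
    j1 <- max(1L, 1L + k):min(w1, w2 + k)
    j2 <- j1 - k
    cors <- vapply(seq_along(j1), function(t) {
      a <- p1[, j1[t]]; b <- p2[, j2[t]]
      if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
    }, numeric(1))
    mean(cors) * length(j1) / min(w1, w2)
  }, numeric(1))
  list(offsets = offsets, scores = sc)
}

#' Similarity distance between two motifs
#'
#' `1 - max` over all ungapped offsets with at least `min_overlap` overlapping
#' columns, over the second motif and its reverse complement, of the mean
#' per-column Pearson correlation between probability columns (a constant
#' column correlates 0 with anything), weighted by the overlap fraction
#' `overlap / min(W1, W2)`. The weight is 1 whenever the narrower motif is
#' fully covered — identical motifs still have distance 0 — but keeps chance
#' agreement over a minimal 4-column ledge from pulling unrelated motifs
#' under the 0.4 merge threshold. Symmetric; clamped to [0, 1].
#'
#' @param m1,m2 `motif` objects of width >= 4.
#' @param min_overlap minimum number of overlapping columns.
#' @return distance in [0, 1]; 0 for identical motifs (up to orientation).
#' @export
motif_distance <- function(m1, m2, min_overlap = 4L) {
  best <- best_alignment(m1, m2, min_overlap)$score
  min(1, max(0, 1 - best))
}

# best ungapped alignment of m2 onto m1 over both orientations
best_alignment <- function(m1, m2, min_overlap = 4L) {
  if (motif_width(m1) < min_overlap || motif_width(m2) < min_overlap)
    stop("motif widths must be >= ", min_overlap)
  p1 <- motif_probs(m1)
  best <- list(score = -Inf, offset = 0L, orientation = "+")
  for (orient in c("+", "-")) {
    m2o <- if (orient == "-") reverse_complement_motif(m2) else m2
    al <- align_scores(p1, motif_probs(m2o), min_overlap)
    k <- which.max(al$scores)
    if (al$scores[k] > best$score)
      best <- list(score = al$scores[k], offset = al$offsets[k],
                   orientation = orient)
  }
  best
}

#' Cluster motifs and merge similar ones into consensus motifs
#'
#' Single-linkage clustering on [motif_distance] cut at `threshold` (edges
#' where distance < threshold). Within a cluster, each member is aligned at
#' its best offset/orientation to the member with the highest `nsites` (ties
#' broken by name) and counts are summed column-wise over the overlapping
#' span; columns outside the reference span are trimmed, and `nsites` are
#' summed. Singleton clusters pass through unchanged.
#'
#' @param motifs list of `motif` objects.
#' @param threshold distance below which motifs join a cluster (default 0.4).
#' @return list of consensus motifs ordered by decreasing total `nsites`
#'   (ties by name).
#' @export
cluster_and_merge <- function(motifs, threshold = 0.4) {
  if (length(motifs) == 0L) return(list())
  stopifnot(threshold > 0, threshold < 1)
  n <- length(motifs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (motif_distance(motifs[[i]], motifs[[j]]) < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(unique(comp), function(cid) {
    members <- motifs[comp == cid]
    if (length(members) == 1L) return(members[[1L]])
    ns <- vapply(members, `[[`, numeric(1), "nsites")
    nm <- vapply(members, `[[`, character(1), "name")
    ref <- members[[order(-ns, nm)[1L]]]
    counts <- ref$counts
    for (m in members[order(-ns, nm)[-1L]]) {
      al <- best_alignment(ref, m)
      mo <- if (al$orientation == "-") reverse_complement_motif(m) else m
      j2 <- seq_len(motif_width(mo))
      j1 <- j2 + al$offset
      keep <- j1 >= 1L & j1 <= ncol(counts)
      counts[, j1[keep]] <- counts[, j1[keep]] + mo$counts[, j2[keep]]
    }
    ev <- vapply(members, `[[`, numeric(1), "evalue")
    new_motif(counts, nsites = sum(ns),
              name = paste(sort(nm), collapse = "+"),
              evalue = if (all(is.na(ev))) NA_real_ else min(ev, na.rm = TRUE),
              source = ref$source)
  })
  ns <- vapply(merged, `[[`, numeric(1), "nsites")
  nm <- vapply(merged, `[[`, character(1), "name")
  merged[order(-ns, nm)]
}
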