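# Footprint calling from a continuous binding-score track.
#
# A candidate footprint is a maximal run of positions whose score exceeds both
# zero and a local height limit. Retained candidates must fall within a width
# window and pass a flat-top test; nearby footprints are merged when the gap
# between them is narrow and shallow.

#' Footprint-calling parameters
#'
#' @param min_width,max_width allowed footprint width range in bp; typical TF
#'   footprints are 6-60 bp.
#' @param local_window width (bp) of the centered window used for the local
#'   height limit (truncated at chromosome ends; forced odd).
#' @param height_factor a position is part of a candidate when its score
#'   exceeds `height_factor` times the windowed mean.
#' @param flat_top_tolerance fraction of the region maximum defining the
#'   summit plateau; the plateau must be contiguous and at least 2 bp wide
#'   (regions narrower than 4 bp are exempt).
#' @param merge_gap_max footprints closer than this many bp may merge.
#' @param merge_depth_frac minimum score in the gap, relative to the smaller
#'   of the two footprint maxima, required for a merge.
#' @param min_fp_size minimum footprint width kept by [filter_by_size].
#' @return list of class `"fp_params"`.
#' @export
fp_params <- function(min_width = 6L, max_width = 60L, local_window = 200L,
                      height_factor = 1.5, flat_top_tolerance = 0.15,
                      merge_gap_max = 6L, merge_depth_frac = 0.5,
                      min_fp_size = 8L) {
  stopifnot(min_width > 0, min_width <= max_width,
            flat_top_tolerance > 0, flat_top_tolerance < 1,
            merge_depth_frac >= 0, merge_depth_frac <= 1,
            local_window >= 1, height_factor > 0)
  structure(list(min_width = as.integer(min_width),
                 max_width = as.integer(max_width),
                 local_window = as.integer(local_window),
                 height_factor = height_factor,
                 flat_top_tolerance = flat_top_tolerance,
                 merge_gap_max = as.integer(merge_gap_max),
                 merge_depth_frac = merge_depth_frac,
                 min_fp_size = as.integer(min_fp_size)),
            class = "fp_params")
}

#' Local height limit of a score vector
#'
#' `threshold[i] = height_factor * mean(scores in the centered window)`, the
#' window being truncated at the chromosome ends. An even `local_window` is
#' widened by 1 bp to stay centered.
#'
#' @param scores numeric vector of per-base scores.
#' @param local_window window width in bp.
#' @param height_factor multiplier applied to the windowed mean.
#' @return numeric vector of thresholds, same length as `scores`.
#' @export
local_threshold <- function(scores, local_window = 200L, height_factor = 1.5) {
  n <- length(scores)
  if (n == 0L) return(numeric(0))
  w <- as.integer(local_window)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(scores))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  height_factor * (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call footprints on a score track
#'
#' Candidate regions are maximal runs with `score > local_threshold` and
#' `score > 0`; a candidate is kept when its width lies within
#' `[min_width, max_width]` and its summit plateau (positions with score >=
#' `(1 - flat_top_tolerance) * max`) is contiguous and at least 2 bp wide
#' (regions narrower than 4 bp are exempt from the plateau test). The summit
#' is the leftmost maximum. Because the height limit is relative, calls are
#' invariant under positive rescaling of the track.
#'
#' @param track a [score_track].
#' @param params an [fp_params] object.
#' @return data.frame of class `"footprints"` with columns chrom, start, end
#'   (0-based half-open), max_score, mean_score, summit (0-based offset of the
#'   leftmost maximum within the footprint), sorted by (chrom, start).
#' @export
call_footprints <- function(track, params = fp_params()) {
  stopifnot(inherits(track, "score_track"), inherits(params, "fp_params"))
  out <- lapply(sort(names(track_chrom_lengths(track))), function(ch) {
    x <- track[[ch]]
    thr <- local_threshold(x, params$local_window, params$height_factor)
    above <- x > thr & x > 0
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    rows <- lapply(runs, function(k) {
      s <- starts[k]; e <- ends[k]
      wdt <- e - s + 1L
      if (wdt < params$min_width || wdt > params$max_width) return(NULL)
      seg <- x[s:e]
      if (!flat_top_ok(seg, params$flat_top_tolerance)) return(NULL)
      data.frame(chrom = ch, start = s - 1L, end = e,
                 max_score = max(seg), mean_score = mean(seg),
                 summit = which.max(seg) - 1L)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      max_score = numeric(), mean_score = numeric(),
                      summit = integer())
  class(out) <- c("footprints", "data.frame")
  out
}

flat_top_ok <- function(seg, tolerance) {
  if (length(seg) < 4L) return(TRUE)
  plateau <- which(seg >= (1 - tolerance) * max(seg))
  length(plateau) >= 2L && all(diff(plateau) == 1L)
}

#' Merge nearby footprints
#'
#' Walking left to right per chromosome, footprint B is merged into its left
#' neighbour A when the gap `B.start - A.end` is shorter than `merge_gap_max`
#' bp and the minimum track score inside the gap is at least
#' `merge_depth_frac * min(A.max_score, B.max_score)` (an empty gap always
#' satisfies the depth test). Merging is re-evaluated transitively: a merged
#' footprint may absorb further neighbours. Scores and summit are recomputed
#' from the track.
#'
#' @param fps a footprints data.frame sorted by (chrom, start).
#' @param track the [score_track] the footprints were called on.
#' @param merge_gap_max,merge_depth_frac see [fp_params].
#' @return Merged footprints data.frame.
#' @export
merge_footprints <- function(fps, track, merge_gap_max = 6L,
                             merge_depth_frac = 0.5) {
  if (nrow(fps) == 0L) return(fps)
  if (any(order(fps$chrom, fps$start) != seq_len(nrow(fps))))
    stop("footprints must be sorted by (chrom, start)")
  res <- lapply(split(fps, fps$chrom), function(d) {
    x <- track[[d$chrom[1L]]]
    acc <- d[1L, ]
    rows <- list()
    for (i in seq_len(nrow(d))[-1L]) {
      b <- d[i, ]
      gap <- b$start - acc$end
      depth_ok <- gap <= 0L ||
        min(x[(acc$end + 1L):b$start]) >=
          merge_depth_frac * min(acc$max_score, b$max_score)
      if (gap < merge_gap_max && depth_ok) {
        seg <- x[(acc$start + 1L):b$end]
        acc$end <- b$end
        acc$max_score <- max(seg)
        acc$mean_score <- mean(seg)
        acc$summit <- which.max(seg) - 1L
      } else {
        rows[[length(rows) + 1L]] <- acc
        acc <- b
      }
    }
    rows[[length(rows) + 1L]] <- acc
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("footprints", "data.frame")
  out
}

#' Drop footprints below a minimum size
#'
#' @param fps footprints data.frame.
#' @param min_fp_size minimum width (bp) to keep.
#' @return Filtered footprints, original order preserved.
#' @export
filter_by_size <- function(fps, min_fp_size = 8L) {
  fps[fps$end - fps$start >= min_fp_size, , drop = FALSE]
}

#' Export footprints as BED6
#'
#' Name is the footprint index; the BED score is `max_score * 1000` clipped
#' to [0, 1000].
#'
#' @param fps footprints data.frame.
#' @param path output BED path.
#' @export
write_footprints_bed <- function(fps, path) {
  nm <- if (nrow(fps)) paste0("FP", seq_len(nrow(fps))) else character(0)
  bed <- data.frame(chrom = fps$chrom, start = fps$start, end = fps$end,
                    name = nm,
                    score = round(pmin(pmax(fps$max_score * 1000, 0), 1000)),
                    strand = rep(".", nrow(fps)))
  write_bed(bed, path)
}
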