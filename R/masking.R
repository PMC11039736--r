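# Scanning sequences with PWMs and removing footprint portions explained by
# known database motifs.

#' Exact PWM score threshold from the background score distribution
#'
#' The log-odds score distribution of a random W-mer under the background is
#' computed exactly by dynamic programming over per-column score
#' distributions, discretized to 0.01 bins. The threshold is the smallest
#' score t with `P(S >= t) <= threshold_quantile`. When even the best
#' possible W-mer is more frequent under the background than the requested
#' quantile (unavoidable for short motifs: a 6-mer's best word already has
#' probability about 2.4e-4 under a uniform background), the threshold falls
#' back to the top score bin, i.e. only best-possible matches count.
#'
#' @param pwm 4 x W log2-odds matrix (see [pfm_to_pwm]).
#' @param background positive 4-vector summing to 1.
#' @param threshold_quantile tail probability, e.g. 1e-4.
#' @return threshold score; attribute `"achieved_p"` carries the exact tail
#'   probability at the returned threshold.
#' @export
pwm_score_threshold <- function(pwm, background = rep(0.25, 4),
                                threshold_quantile = 1e-4) {
  check_background(background)
  stopifnot(threshold_quantile > 0, threshold_quantile < 1)
  q <- round(pwm * 100)
  lo <- 0L; hi <- 0L
  dp <- 1
  for (j in seq_len(ncol(q))) {
    newlo <- lo + min(q[, j]); newhi <- hi + max(q[, j])
    nd <- numeric(newhi - newlo + 1L)
    for (b in 1:4) {
      idx <- (lo:hi) + q[b, j] - newlo + 1L
      nd[idx] <- nd[idx] + background[b] * dp
    }
    dp <- nd; lo <- newlo; hi <- newhi
  }
  scores <- (lo:hi) / 100
  tail_p <- rev(cumsum(rev(dp)))
  k <- which(tail_p <= threshold_quantile)
  thr_idx <- if (length(k)) min(k) else max(which(dp > 0))
  structure(scores[thr_idx], achieved_p = tail_p[thr_idx])
}

#' Scan sequences for motif occurrences
#'
#' Both strands are scanned with the motif's log2-odds PWM; a hit requires a
#' score at or above the per-motif threshold defined by the exact background
#' score distribution at `threshold_quantile` (see [pwm_score_threshold]).
#' Minus-strand hits are reported on forward coordinates. Sequences shorter
#' than the motif yield no hits.
#'
#' @param sequences named character vector of DNA sequences.
#' @param motifs list of `motif` objects (a single motif is accepted).
#' @param threshold_quantile tail probability defining "sufficiently good"
#'   matches (default 1e-4, the conventional motif-match level).
#' @param background 4-vector; defaults to the strand-symmetrized empirical
#'   composition of `sequences`.
#' @param intervals optional data.frame (chrom/start/end, one row per
#'   sequence) locating each sequence on a genome; hit coordinates are then
#'   genomic. Otherwise `chrom` is the sequence name and coordinates are
#'   sequence-relative.
#' @return data.frame with motif, chrom, start, end, strand, score.
#' @export
scan_sequences <- function(sequences, motifs, threshold_quantile = 1e-4,
                           background = NULL, intervals = NULL) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  if (is.null(background)) background <- background_from_sequences(sequences)
  check_background(background)
  if (!is.null(intervals)) {
    check_intervals(intervals)
    if (nrow(intervals) != length(sequences))
      stop("intervals must have one row per sequence")
  }
  enc <- lapply(sequences, encode_dna)
  out <- lapply(motifs, function(m) {
    # scanning uses the same 0.01-binned PWM as the threshold DP, so the
    # achieved tail probability is exact for the scanner as well
    pwm <- round(pfm_to_pwm(m, background) * 100) / 100
    pwm_rc <- round(pfm_to_pwm(reverse_complement_motif(m),
                               background) * 100) / 100
    thr <- as.numeric(pwm_score_threshold(pwm, background, threshold_quantile))
    rows <- lapply(seq_along(enc), function(i) {
      # epsilon guards against float drift between the summed per-column
      # bins and the integer-derived threshold
      h <- scan_pwm_cpp(enc[[i]], pwm, pwm_rc, thr - 1e-9)
      if (!length(h$pos)) return(NULL)
      if (is.null(intervals)) {
        ch <- names(sequences)[i] %||% as.character(i)
        off <- 0L
      } else {
        ch <- intervals$chrom[i]
        off <- intervals$start[i]
      }
      data.frame(motif = m$name, chrom = ch, start = off + h$pos,
                 end = off + h$pos + motif_width(m),
                 strand = c("+", "-")[h$strand + 1L], score = h$score)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(motif = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric())
  rownames(out) <- NULL
  out
}

#' Remove footprint portions explained by known motif hits
#'
#' In `whole_fp` mode any footprint overlapping a hit by at least 1 bp is
#' dropped. In `motif_location` mode only the union of overlapping hit
#' intervals is subtracted from each footprint, and every remaining fragment
#' of at least `min_fp_size` bp is kept — retaining the flanks for further
#' discovery. With no hits the input is returned unchanged (database-free
#' mode).
#'
#' @param fps footprints data.frame.
#' @param hits data.frame of motif hits (chrom/start/end).
#' @param mode `"motif_location"` or `"whole_fp"`.
#' @param min_fp_size minimum fragment width kept in `motif_location` mode.
#' @param track optional [score_track]; fragment max/mean/summit are
#'   recomputed from it, otherwise inherited from the parent footprint.
#' @return Filtered footprints data.frame.
#' @export
mask_known <- function(fps, hits, mode = c("motif_location", "whole_fp"),
                       min_fp_size = 8L, track = NULL) {
  mode <- match.arg(mode)
  if (nrow(fps) == 0L || nrow(hits) == 0L) return(fps)
  rows <- lapply(seq_len(nrow(fps)), function(i) {
    fp <- fps[i, ]
    h <- hits[hits$chrom == fp$chrom & hits$start < fp$end &
                hits$end > fp$start, , drop = FALSE]
    if (nrow(h) == 0L) return(fp)
    if (mode == "whole_fp") return(NULL)
    frags <- subtract_interval(fp$start, fp$end, h$start, h$end)
    frags <- frags[frags$end - frags$start >= min_fp_size, , drop = FALSE]
    if (nrow(frags) == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(frags)), function(k) {
      out <- fp
      out$start <- frags$start[k]
      out$end <- frags$end[k]
      if (!is.null(track)) {
        seg <- track[[fp$chrom]][(out$start + 1L):out$end]
        out$max_score <- max(seg)
        out$mean_score <- mean(seg)
        out$summit <- which.max(seg) - 1L
      } else {
        out$summit <- 0L
      }
      out
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- fps[0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# subtract the union of [bs, be) intervals from [s, e); returns fragments
subtract_interval <- function(s, e, bs, be) {
  bs <- pmax(bs, s); be <- pmin(be, e)
  o <- order(bs)
  bs <- bs[o]; be <- be[o]
  frags <- list()
  cur <- s
  for (k in seq_along(bs)) {
    if (bs[k] > cur) frags[[length(frags) + 1L]] <- c(cur, bs[k])
    cur <- max(cur, be[k])
  }
  if (cur < e) frags[[length(frags) + 1L]] <- c(cur, e)
  if (!length(frags)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, frags)
  data.frame(start = m[, 1], end = m[, 2])
}
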