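#' Per-base binding-score track
#'
#' Dense per-chromosome vectors of non-negative scores, as emitted by an
#' upstream footprint scorer. Missing data are represented as 0.
#'
#' @param scores named list of numeric vectors, one per chromosome; vector
#'   length equals the chromosome length in bp.
#' @return An object of class `"score_track"`.
#' @export
score_track <- function(scores) {
  if (!is.list(scores) || is.null(names(scores)) || any(names(scores) == ""))
    stop("scores must be a named list of per-chromosome numeric vectors")
  if (anyDuplicated(names(scores)))
    stop("duplicate chromosome names in score track")
  scores <- lapply(scores, function(v) {
    v <- as.numeric(v)
    if (any(!is.finite(v))) stop("score track contains non-finite values")
    if (any(v < 0)) stop("score track contains negative values")
    v
  })
  structure(scores, class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %d chromosome(s), %d bp total\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Chromosome lengths of a track
#' @param track a `score_track`.
#' @export
track_chrom_lengths <- function(track) lengths(unclass(track))

#' Differential score track
#'
#' Pointwise `max(0, a - b)`: scores of the second condition are subtracted
#' from the first and negative values are clamped to zero, leaving signal
#' unique to the first condition.
#'
#' @param a,b `score_track` objects over identical chromosome sets/lengths.
#' @return A `score_track`.
#' @export
differential_track <- function(a, b) {
  la <- track_chrom_lengths(a)
  lb <- track_chrom_lengths(b)
  if (!identical(sort(names(la)), sort(names(lb))))
    stop("tracks have different chromosome sets")
  if (any(la[names(lb)] != lb))
    stop("tracks have different chromosome lengths")
  score_track(lapply(stats::setNames(nm = names(la)), function(chrom) {
    pmax(0, a[[chrom]] - b[[chrom]])
  }))
}
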