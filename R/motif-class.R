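#' Position frequency matrix motif
#'
#' A motif is represented by a 4 x W count matrix (rows A, C, G, T) together
#' with an effective site count `nsites`. On construction every column is
#' rescaled to sum to `nsites`, so the count matrix and the probability matrix
#' differ only by the factor `nsites`. Optional metadata carry the motif's
#' significance (`evalue`), provenance (`source`, e.g. discovery iteration or
#' condition label) and a transcription-factor class annotation (`tf_class`).
#'
#' @param counts numeric 4 x W matrix of non-negative base counts
#'   (rows in A, C, G, T order; W >= 4).
#' @param nsites effective number of contributing sites; defaults to the mean
#'   column sum of `counts`.
#' @param name motif identifier.
#' @param evalue significance E-value (optional).
#' @param source provenance tag such as an iteration index or condition label.
#' @param tf_class transcription-factor class annotation (optional).
#' @return An object of class `"motif"`.
#' @export
new_motif <- function(counts, nsites = NULL, name = "motif", evalue = NA_real_,
                      source = NA_character_, tf_class = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("motif counts must have 4 rows (A, C, G, T), got ", nrow(counts))
  if (ncol(counts) < 4L)
    stop("motif width must be >= 4, got ", ncol(counts))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("motif counts must be finite and non-negative")
  csum <- colSums(counts)
  if (any(csum <= 0))
    stop("motif column ", which(csum <= 0)[1L], " has zero total count")
  if (is.null(nsites)) nsites <- mean(csum)
  if (!is.finite(nsites) || nsites <= 0) stop("nsites must be positive")
  counts <- sweep(counts, 2L, csum, "/") * nsites
  rownames(counts) <- DNA_BASES
  structure(
    list(counts = counts, nsites = nsites, name = as.character(name),
         evalue = as.numeric(evalue), source = source, tf_class = tf_class),
    class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s  width=%d  nsites=%.1f  evalue=%s\n",
              x$name, motif_width(x), x$nsites,
              if (is.na(x$evalue)) "NA" else format(x$evalue, digits = 3)))
  cat("  consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Motif width (number of columns)
#' @param motif a `motif` object.
#' @export
motif_width <- function(motif) ncol(motif$counts)

#' Column probability matrix of a motif
#' @param motif a `motif` object.
#' @return 4 x W matrix with columns summing to 1.
#' @export
motif_probs <- function(motif) sweep(motif$counts, 2L, colSums(motif$counts), "/")

#' Consensus string (most frequent base per column)
#' @param motif a `motif` object.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$counts, 2L, which.max)], collapse = "")
}

#' Convert counts to a log2-odds position weight matrix
#'
#' `pwm[b, j] = log2( (counts[b, j] + pseudocount * background[b]) /
#' (nsites + pseudocount) / background[b] )`.
#'
#' @param motif a `motif` object.
#' @param background base composition, a positive 4-vector summing to 1
#'   (A, C, G, T order).
#' @param pseudocount total pseudocount distributed according to `background`.
#' @return 4 x W numeric matrix of log2 odds.
#' @export
pfm_to_pwm <- function(motif, background = rep(0.25, 4), pseudocount = 1) {
  check_background(background)
  if (!is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  log2((motif$counts + pseudocount * background) /
         (motif$nsites + pseudocount) / background)
}

check_background <- function(background) {
  if (length(background) != 4L || any(!is.finite(background)) ||
      any(background <= 0))
    stop("background must be a positive 4-vector")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background must sum to 1")
  invisible(background)
}

#' Information content of a motif in bits
#'
#' Per-column relative entropy versus the background,
#' `IC_j = sum_b p_bj * log2(p_bj / background_b)` with `0 * log(0) := 0`,
#' computed from raw column probabilities (no pseudocount).
#'
#' @param motif a `motif` object.
#' @param background positive 4-vector summing to 1.
#' @return list with elements `total` (bits) and `per_column` (numeric vector).
#' @export
information_content <- function(motif, background = rep(0.25, 4)) {
  check_background(background)
  p <- motif_probs(motif)
  term <- p * log2(sweep(p, 1L, background, "/"))
  term[p == 0] <- 0
  per_col <- colSums(term)
  list(total = sum(per_col), per_column = per_col)
}

#' Reverse complement of a motif
#'
#' Columns reversed and rows swapped A<->T, C<->G; an involution.
#'
#' @param motif a `motif` object.
#' @export
reverse_complement_motif <- function(motif) {
  counts <- motif$counts[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(motif$counts))),
                         drop = FALSE]
  rownames(counts) <- DNA_BASES
  out <- motif
  out$counts <- counts
  out
}

#' Empirical mononucleotide background of a sequence pool
#'
#' Frequencies are symmetrized over strands (averaged with the complement) so
#' that plus- and minus-strand scans share one background model. Returns the
#' uniform distribution when no sequence (or no A/C/G/T base) is supplied.
#'
#' @param sequences character vector of DNA sequences (may be empty).
#' @return 4-vector of base probabilities in A, C, G, T order.
#' @export
background_from_sequences <- function(sequences) {
  if (length(sequences) == 0L) return(rep(0.25, 4))
  tab <- table(factor(strsplit(paste(toupper(sequences), collapse = ""),
                               "", fixed = TRUE)[[1L]], levels = DNA_BASES))
  n <- sum(tab)
  if (n == 0L) return(rep(0.25, 4))
  # one pseudo-observation per base keeps every entry positive even for
  # degenerate pools (e.g. a single AT-only sequence)
  p <- (as.numeric(tab) + 1) / (n + 4)
  (p + rev(p)) / 2  # complement of (A,C,G,T) is (T,G,C,A) = rev
}
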