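# Iterative de novo motif generation from footprint sequences.
#
# Each iteration seeds a ZOOPS-EM motif finder with over-represented k-mers,
# evaluates candidate motifs by a binomial E-value, keeps the candidates in
# front of the knee of the sorted E-value curve, and removes the exact motif
# locations from the sequence pool while retaining the flanks (so motifs of
# closely bound factors remain discoverable). The loop stops when the pool is
# exhausted or no significant motif appears for several iterations; all
# significant motifs are finally clustered and merged into consensus motifs.

#' Discovery parameters
#'
#' @param w_min,w_max motif width range scanned per iteration (bp).
#' @param seeds_per_iteration top over-represented k-mer seeds per width.
#' @param motifs_per_iteration at most this many significant motifs are
#'   retained (and their sites subtracted) per iteration.
#' @param max_iterations hard iteration cap.
#' @param stagnation_limit consecutive iterations without a significant motif
#'   before termination ("several" fixed at 3).
#' @param evalue_cap absolute E-value ceiling for significance.
#' @param merge_threshold similarity-distance threshold for the final
#'   clustering/merging (0.4 for all merging operations).
#' @param min_fragment_size minimum flank fragment (bp) re-entering the pool.
#' @param rng_seed seed forwarded to the motif finder.
#' @return list of class `"discovery_params"`.
#' @export
discovery_params <- function(w_min = 6L, w_max = 15L, seeds_per_iteration = 2L,
                             motifs_per_iteration = 3L, max_iterations = 30L,
                             stagnation_limit = 3L, evalue_cap = 0.05,
                             merge_threshold = 0.4, min_fragment_size = 8L,
                             rng_seed = 1L) {
  stopifnot(w_min >= 4, w_min <= w_max, stagnation_limit >= 1)
  structure(list(w_min = as.integer(w_min), w_max = as.integer(w_max),
                 seeds_per_iteration = as.integer(seeds_per_iteration),
                 motifs_per_iteration = as.integer(motifs_per_iteration),
                 max_iterations = as.integer(max_iterations),
                 stagnation_limit = as.integer(stagnation_limit),
                 evalue_cap = evalue_cap, merge_threshold = merge_threshold,
                 min_fragment_size = as.integer(min_fragment_size),
                 rng_seed = as.integer(rng_seed)),
            class = "discovery_params")
}

#' Over-represented k-mer seeds
#'
#' k-mers are counted on both strands (a k-mer and its reverse complement are
#' collapsed into one class, represented by its more frequent orientation) and
#' ranked by the z-score of the observed count against the expectation under
#' the pool's mononucleotide background. k-mers containing N are skipped.
#' Classes observed fewer than `min_count` times are discarded before
#' ranking: for long k-mers the background expectation is so small that any
#' singleton would otherwise dominate the z-ranking, seeding spurious or
#' chimeric motifs.
#'
#' @param sequences character vector.
#' @param w k-mer width.
#' @param top_k number of seeds returned.
#' @param background optional 4-vector; defaults to the pool composition.
#' @param min_count minimum both-strand occurrence count of a seed class.
#' @return character vector of up to `top_k` seed k-mers (empty when no
#'   sequence is at least `w` long or no class reaches `min_count`), with
#'   attribute `n_classes`: the number of k-mer classes that passed
#'   `min_count`, i.e. the size of the motif search space at this width.
#' @export
seed_kmers <- function(sequences, w, top_k = 3L, background = NULL,
                       min_count = 5L) {
  seqs <- toupper(sequences[nchar(sequences) >= w])
  if (!length(seqs)) return(character(0))
  if (is.null(background)) background <- background_from_sequences(seqs)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - w + 1L), w:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (!length(kmers)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  obs <- table(canon)
  obs <- obs[as.numeric(obs) >= min_count]
  if (!length(obs)) return(character(0))
  classes <- names(obs)
  crc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(classes)))
  logp_of <- function(ks) {
    codes <- matrix(match(unlist(strsplit(ks, "", fixed = TRUE)), DNA_BASES),
                    nrow = w)
    colSums(matrix(log(background)[codes], nrow = w))
  }
  p <- exp(logp_of(classes))
  p <- ifelse(classes == crc, p, p + exp(logp_of(crc)))
  e <- length(kmers) * p
  z <- (as.numeric(obs) - e) / sqrt(e)
  top <- order(-z, classes)[seq_len(min(top_k, length(classes)))]
  fwd <- table(kmers)
  cf <- ifelse(classes %in% names(fwd), as.numeric(fwd[classes]), 0)
  cr <- ifelse(crc %in% names(fwd), as.numeric(fwd[crc]), 0)
  structure(ifelse(cr[top] > cf[top], crc[top], classes[top]),
            n_classes = length(classes))
}

#' ZOOPS-EM motif finder
#'
#' Expectation-maximization under the zero-or-one-occurrence-per-sequence
#' model: each sequence carries at most one motif site (prior gamma), at a
#' uniform offset and strand. The PFM is initialized from the seed (0.7 on
#' the seed base, 0.1 elsewhere) and re-estimated with pseudocount 0.1 until
#' the log-likelihood gain drops below `tol` or `max_iter` is reached. The
#' final motif is built from the hard maximum-posterior site assignments: a
#' sequence is assigned only when its best site posterior beats the no-site
#' posterior AND the site's log2-odds score passes the fitted PWM's exact
#' background score distribution at a per-sequence false-assignment rate of
#' `alpha` (Bonferroni over the `2 * (L - w + 1)` windows). The second
#' condition keeps a large fitted gamma from absorbing pure-background
#' sequences, which would otherwise be subtracted from the discovery pool.
#' The fit is deterministic given its inputs; `rng_seed` is accepted for
#' interface compatibility with stochastic finders.
#'
#' @param sequences character vector over {A,C,G,T,N}; sequences shorter than
#'   the seed are ignored (an error if none remains).
#' @param seed seed k-mer; its width sets the motif width.
#' @param max_iter,tol EM stopping rule.
#' @param rng_seed unused by the deterministic EM; part of the finder
#'   contract.
#' @param background 4-vector; defaults to the pool composition.
#' @param pseudocount PFM pseudocount used in the M-step.
#' @param gamma_init initial site prior.
#' @param alpha per-sequence false-assignment rate of the site significance
#'   gate.
#' @param trim_col_ic edge columns with information content below this many
#'   bits are trimmed from the final motif (flank columns fitted on random
#'   context otherwise blur motif comparisons); sites are narrowed
#'   accordingly. Trimming never reduces the width below 4 columns.
#' @param name motif name.
#' @return list with `motif` (a [new_motif], or `NULL` when no sequence is
#'   assigned), `sites` (data.frame seq/offset/strand/posterior, 0-based
#'   offsets), `gamma`, and `loglik` (trace).
#' @export
em_zoops <- function(sequences, seed, max_iter = 100L, tol = 1e-3,
                     rng_seed = 1L, background = NULL, pseudocount = 0.1,
                     gamma_init = 0.5, alpha = 0.05, trim_col_ic = 0.25,
                     name = "em_motif") {
  w <- nchar(seed)
  if (w < 4L) stop("seed width must be >= 4")
  if (is.null(background)) background <- background_from_sequences(sequences)
  check_background(background)
  seed_codes <- encode_dna(seed)
  if (any(seed_codes > 3L)) stop("seed must be over {A,C,G,T}")
  theta0 <- matrix(0.1, 4, w)
  theta0[cbind(seed_codes + 1L, seq_len(w))] <- 0.7
  enc <- lapply(sequences, encode_dna)
  fit <- em_zoops_cpp(enc, theta0, background, gamma_init,
                      as.integer(max_iter), tol, pseudocount)
  sites <- data.frame(seq = fit$assign_seq, offset = fit$assign_offset,
                      strand = c("+", "-")[fit$assign_strand + 1L],
                      posterior = fit$assign_posterior)
  if (nrow(sites) > 0L) {
    # per-site significance gate against the fitted PWM's exact background
    # score distribution
    pwm <- log2(sweep(fit$theta, 1L, background, "/"))
    lbar <- mean(nchar(sequences)[nchar(sequences) >= w])
    q <- min(0.5, alpha / (2 * max(1, lbar - w + 1)))
    thr_obj <- pwm_score_threshold(pwm, background, q)
    thr <- as.numeric(thr_obj)
    site_rate <- 1 - (1 - attr(thr_obj, "achieved_p"))^(2 * max(1, lbar - w + 1))
    keep <- vapply(seq_len(nrow(sites)), function(r) {
      s <- substr(sequences[[sites$seq[r]]], sites$offset[r] + 1L,
                  sites$offset[r] + w)
      if (sites$strand[r] == "-") s <- revcomp(s)
      codes <- encode_dna(s)
      if (any(codes > 3L)) return(FALSE)
      sum(pwm[cbind(codes + 1L, seq_len(w))]) >= thr
    }, logical(1))
    sites <- sites[keep, , drop = FALSE]
  }
  motif <- NULL
  if (nrow(sites) > 0L) {
    counts <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
    for (r in seq_len(nrow(sites))) {
      s <- substr(sequences[[sites$seq[r]]], sites$offset[r] + 1L,
                  sites$offset[r] + w)
      if (sites$strand[r] == "-") s <- revcomp(s)
      codes <- encode_dna(s)
      counts[cbind(codes + 1L, seq_len(w))] <-
        counts[cbind(codes + 1L, seq_len(w))] + 1
    }
    # columns can contain N-coded gaps in pathological pools; guard zero sums
    if (all(colSums(counts) > 0)) {
      motif <- new_motif(counts, nsites = nrow(sites), name = name)
      ic <- information_content(motif, background)$per_column
      a <- 1L; b <- w
      while (b - a + 1L > 4L && ic[a] < trim_col_ic) a <- a + 1L
      while (b - a + 1L > 4L && ic[b] < trim_col_ic) b <- b - 1L
      if (a > 1L || b < w) {
        motif <- new_motif(counts[, a:b, drop = FALSE],
                           nsites = nrow(sites), name = name)
        plus <- sites$strand == "+"
        sites$offset <- ifelse(plus, sites$offset + (a - 1L),
                               sites$offset + (w - b))
      }
    }
  }
  list(motif = motif, sites = sites, gamma = fit$gamma, loglik = fit$loglik,
       site_rate = if (nrow(sites) > 0L) site_rate else 0)
}

#' Binomial E-value of a discovered motif
#'
#' The per-sequence chance that a background sequence of mean length `L`
#' contains a site as informative as the motif is approximated as
#' `p0 = min(1, 2 * (L - W + 1) * 2^(-IC_total))`; the p-value is the binomial
#' tail `P(X >= site_count)` over `pool_size` sequences and the E-value is
#' `p * tests_performed`, clamped to `[0, tests_performed]`. When the finder
#' gated site assignment at a known per-sequence false rate, pass it as
#' `p0_floor`: the null assignment probability cannot be smaller than the
#' gate's own false-assignment rate, and the floor keeps EM-optimized noise
#' motifs from looking significant.
#'
#' @param motif a `motif` object.
#' @param site_count number of sequences supporting the motif.
#' @param pool_size number of sequences in the discovery pool.
#' @param mean_seq_len mean pool sequence length (bp).
#' @param background 4-vector for the information content.
#' @param tests_performed number of candidate motifs evaluated alongside.
#' @param p0_floor lower bound on the per-sequence null probability (e.g. the
#'   finder's site-gate false-assignment rate).
#' @return E-value.
#' @export
motif_evalue <- function(motif, site_count, pool_size, mean_seq_len,
                         background = rep(0.25, 4), tests_performed = 1,
                         p0_floor = 0) {
  stopifnot(site_count <= pool_size)
  w <- motif_width(motif)
  ic <- information_content(motif, background)$total
  p0 <- min(1, max(max(0, 2 * (mean_seq_len - w + 1)) * 2^(-ic), p0_floor))
  p <- if (site_count <= 0) 1
       else pbinom(site_count - 1, pool_size, p0, lower.tail = FALSE)
  min(max(p * tests_performed, 0), tests_performed)
}

#' Dynamic significance filter by knee location
#'
#' E-values are mapped to `-log10` scale, sorted decreasingly, min-max
#' normalized, and the knee is located as the point of maximum perpendicular
#' distance to the chord joining the first and last point (Kneedle-style on a
#' piecewise-linear curve). Motifs strictly before the knee that also satisfy
#' `E <= evalue_cap` are significant. With fewer than 3 values — or a flat
#' curve, which has no knee — the cap alone decides.
#'
#' @param evalues numeric vector of E-values.
#' @param evalue_cap absolute ceiling (default 0.05).
#' @return sorted integer indices (into `evalues`) of significant motifs.
#' @export
knee_filter <- function(evalues, evalue_cap = 0.05) {
  stopifnot(length(evalues) >= 1L)
  pass_cap <- which(evalues <= evalue_cap)
  if (length(evalues) < 3L) return(pass_cap)
  s <- -log10(pmax(evalues, 1e-300))
  ord <- order(s, decreasing = TRUE)
  y <- s[ord]
  yr <- diff(range(y))
  if (yr == 0) return(pass_cap)
  yn <- (y - min(y)) / yr
  x <- seq(0, 1, length.out = length(y))
  x1 <- x[1L]; y1 <- yn[1L]; x2 <- x[length(x)]; y2 <- yn[length(yn)]
  d <- abs((y2 - y1) * x - (x2 - x1) * yn + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  knee <- which.max(d)
  sort(intersect(ord[seq_len(knee - 1L)], pass_cap))
}

#' Remove motif sites from a sequence pool, retaining the flanks
#'
#' Each used sequence is split at its site boundaries; fragments of at least
#' `min_fragment_size` bp re-enter the pool with updated genomic coordinates,
#' shorter fragments are dropped and untouched sequences pass through.
#'
#' @param pool data.frame with columns id, chrom, start, end, seq (start/end
#'   are genomic, 0-based half-open; seq is the plus-strand sequence).
#' @param sites data.frame with columns `pool_row` (index into `pool`),
#'   `start`, `end` (0-based offsets within the sequence).
#' @param min_fragment_size minimum fragment width (bp).
#' @return Reduced pool data.frame.
#' @export
subtract_sites <- function(pool, sites, min_fragment_size = 8L) {
  if (nrow(sites) == 0L) return(pool)
  if (any(sites$pool_row < 1L | sites$pool_row > nrow(pool)))
    stop("site references unknown pool row")
  lens <- nchar(pool$seq)[sites$pool_row]
  if (any(sites$start < 0L | sites$end > lens | sites$start >= sites$end))
    stop("site out of sequence bounds")
  touched <- unique(sites$pool_row)
  keep <- pool[-touched, , drop = FALSE]
  frag_rows <- lapply(touched, function(i) {
    sel <- sites$pool_row == i
    frags <- subtract_interval(0L, nchar(pool$seq[i]),
                               sites$start[sel], sites$end[sel])
    frags <- frags[frags$end - frags$start >= min_fragment_size, ,
                   drop = FALSE]
    if (nrow(frags) == 0L) return(NULL)
    data.frame(id = paste0(pool$id[i], ".", seq_len(nrow(frags))),
               chrom = pool$chrom[i],
               start = pool$start[i] + frags$start,
               end = pool$start[i] + frags$end,
               seq = substring(pool$seq[i], frags$start + 1L, frags$end))
  })
  out <- rbind(keep, do.call(rbind, frag_rows))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative de novo motif discovery
#'
#' Extracts the footprint sequence pool (sequences containing N are dropped),
#' then iterates: seed k-mers per width, fit the finder, rank candidates by
#' E-value, apply the knee filter, keep at most `motifs_per_iteration`
#' distinct significant motifs and subtract their site locations from the
#' pool (flanks retained). Terminates on an empty pool, `max_iterations`, or
#' `stagnation_limit` consecutive iterations without a significant motif.
#' All significant motifs are finally clustered and merged at
#' `merge_threshold`.
#'
#' @param fps footprints data.frame (non-empty).
#' @param genome named character vector of chromosome sequences.
#' @param params a [discovery_params] object.
#' @param finder motif finder honoring the [em_zoops] contract.
#' @param verbose print per-iteration progress.
#' @return list of class `"discovery_result"` with elements `iterations`
#'   (per-iteration candidate motifs, E-values and significance flags),
#'   `consensus` (merged motifs), `significant` (flat list of significant
#'   per-iteration motifs), `sites` (genomic site list per significant
#'   motif), `pool_sizes` (pool-size trajectory, entry i = size entering
#'   iteration i) and `params`.
#' @export
iterative_discovery <- function(fps, genome, params = discovery_params(),
                                finder = em_zoops, verbose = FALSE) {
  if (is.null(fps) || nrow(fps) == 0L) stop("footprint list is empty")
  seqs <- extract_sequences(genome, fps)
  ok <- !grepl("N", seqs, fixed = TRUE)
  pool <- data.frame(id = paste0("FP", seq_len(nrow(fps))),
                     chrom = fps$chrom, start = fps$start, end = fps$end,
                     seq = seqs)[ok, , drop = FALSE]
  background <- background_from_sequences(pool$seq)
  iterations <- list()
  significant <- list()
  all_sites <- list()
  pool_sizes <- integer(0)
  pool_bp <- integer(0)
  stagnant <- 0L
  for (it in seq_len(params$max_iterations)) {
    pool_sizes <- c(pool_sizes, nrow(pool))
    pool_bp <- c(pool_bp, sum(nchar(pool$seq)))
    if (nrow(pool) == 0L) break
    cands <- list()
    n_classes_total <- 0L
    for (w in params$w_min:params$w_max) {
      seeds <- seed_kmers(pool$seq, w, params$seeds_per_iteration, background)
      n_classes_total <- n_classes_total + (attr(seeds, "n_classes") %||% 0L)
      for (sd in seeds) {
        fit <- finder(pool$seq, sd, rng_seed = params$rng_seed,
                      background = background,
                      name = sprintf("iter%02d_w%d_%s", it, w, sd))
        if (!is.null(fit$motif)) cands[[length(cands) + 1L]] <- fit
      }
    }
    if (!length(cands)) {
      iterations[[it]] <- list(motifs = list(), evalues = numeric(0),
                               significant = integer(0),
                               pool_size = nrow(pool))
      stagnant <- stagnant + 1L
      if (stagnant >= params$stagnation_limit) break
      next
    }
    lbar <- mean(nchar(pool$seq))
    # multiplicity: the seed ranking implicitly tested every k-mer class
    # that reached min_count, not just the fitted candidates
    evals <- vapply(cands, function(f) {
      motif_evalue(f$motif, f$motif$nsites, nrow(pool), lbar, background,
                   tests_performed = max(n_classes_total, length(cands)),
                   p0_floor = f$site_rate %||% 0)
    }, numeric(1))
    for (k in seq_along(cands)) cands[[k]]$motif$evalue <- evals[k]
    sig_idx <- knee_filter(evals, params$evalue_cap)
    # keep at most motifs_per_iteration distinct significant motifs
    chosen <- integer(0)
    for (k in sig_idx[order(evals[sig_idx])]) {
      dup <- any(vapply(chosen, function(j) {
        motif_distance(cands[[k]]$motif, cands[[j]]$motif) <
          params$merge_threshold
      }, logical(1)))
      if (!dup) chosen <- c(chosen, k)
      if (length(chosen) >= params$motifs_per_iteration) break
    }
    iterations[[it]] <- list(
      motifs = lapply(cands, `[[`, "motif"), evalues = evals,
      significant = chosen, pool_size = nrow(pool))
    if (verbose)
      message(sprintf("iteration %d: pool %d, %d candidates, %d significant",
                      it, nrow(pool), length(cands), length(chosen)))
    if (!length(chosen)) {
      stagnant <- stagnant + 1L
      if (stagnant >= params$stagnation_limit) break
      next
    }
    stagnant <- 0L
    site_frames <- list()
    for (k in chosen) {
      m <- cands[[k]]$motif
      m$source <- sprintf("iteration %d", it)
      significant[[length(significant) + 1L]] <- m
      st <- cands[[k]]$sites
      w <- motif_width(m)
      all_sites[[m$name]] <- data.frame(
        motif = m$name, chrom = pool$chrom[st$seq],
        start = pool$start[st$seq] + st$offset,
        end = pool$start[st$seq] + st$offset + w, strand = st$strand)
      site_frames[[length(site_frames) + 1L]] <-
        data.frame(pool_row = st$seq, start = st$offset,
                   end = st$offset + w)
    }
    pool <- subtract_sites(pool, do.call(rbind, site_frames),
                           params$min_fragment_size)
  }
  consensus <- cluster_and_merge(significant, params$merge_threshold)
  structure(list(iterations = iterations, consensus = consensus,
                 significant = significant, sites = all_sites,
                 pool_sizes = pool_sizes, pool_bp = pool_bp, params = params),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(paste0("<discovery_result> %d iteration(s), %d significant ",
                     "motif(s), %d consensus motif(s)\n"),
              length(x$iterations), length(x$significant),
              length(x$consensus)))
  invisible(x)
}
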