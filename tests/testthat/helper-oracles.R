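# Independent oracles and fixture builders. Oracles are deliberately written
# as plain loops over the rule definitions, independent of the package's
# vectorized/Rcpp implementations they check.

# brute-force footprint caller: position-by-position threshold, run scan,
# width filter, plateau test
bf_call_footprints <- function(x, params) {
  L <- length(x)
  w <- params$local_window
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  above <- logical(L)
  for (i in seq_len(L)) {
    thr <- params$height_factor * mean(x[max(1, i - h):min(L, i + h)])
    above[i] <- x[i] > thr && x[i] > 0
  }
  rows <- list()
  i <- 1
  while (i <= L) {
    if (!above[i]) { i <- i + 1; next }
    j <- i
    while (j < L && above[j + 1]) j <- j + 1
    seg <- x[i:j]
    wd <- j - i + 1
    keep <- wd >= params$min_width && wd <= params$max_width
    if (keep && wd >= 4) {
      plateau <- which(seg >= (1 - params$flat_top_tolerance) * max(seg))
      keep <- length(plateau) >= 2 && all(diff(plateau) == 1)
    }
    if (keep)
      rows[[length(rows) + 1]] <- data.frame(
        start = i - 1, end = j, max_score = max(seg),
        mean_score = mean(seg), summit = which.max(seg) - 1)
    i <- j + 1
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      max_score = numeric(), mean_score = numeric(),
                      summit = integer()))
  do.call(rbind, rows)
}

# brute-force motif distance: same definition, independent loops
bf_motif_distance <- function(m1, m2, min_overlap = 4) {
  p1 <- motif_probs(m1)
  best <- -Inf
  for (orient in 1:2) {
    m2o <- if (orient == 2) reverse_complement_motif(m2) else m2
    p2 <- motif_probs(m2o)
    w1 <- ncol(p1); w2 <- ncol(p2)
    for (k in (-(w2 - min_overlap)):(w1 - min_overlap)) {
      tot <- 0; cnt <- 0
      for (j1 in 1:w1) {
        j2 <- j1 - k
        if (j2 >= 1 && j2 <= w2) {
          a <- p1[, j1]; b <- p2[, j2]
          r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else
            stats::cor(a, b)
          tot <- tot + r
          cnt <- cnt + 1
        }
      }
      if (cnt >= min_overlap) {
        sc <- tot / cnt * cnt / min(w1, w2)
        if (sc > best) best <- sc
      }
    }
  }
  min(1, max(0, 1 - best))
}

# exact hypergeometric upper tail P[X >= k], drawing n from N with K successes
bf_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  tot <- 0
  for (i in k:min(K, n))
    tot <- tot + choose(K, i) * choose(N - K, n - i) / choose(N, n)
  tot
}

# random score track: sparse flat bumps over truncated-normal noise
random_bumpy_track <- function(len, seed, n_bumps = 5) {
  set.seed(seed)
  x <- pmax(0, rnorm(len, 0.2, 0.3))
  for (b in seq_len(n_bumps)) {
    w <- sample(3:30, 1)
    s <- sample(len - w, 1)
    x[s:(s + w - 1)] <- runif(1, 2, 8)
  }
  x
}

random_pfm_motif <- function(w, seed, name = paste0("rand", seed)) {
  set.seed(seed)
  counts <- matrix(stats::rgamma(4 * w, shape = 0.6) + 1e-3, 4, w)
  new_motif(counts * 10, nsites = 10 * mean(colSums(counts)), name = name)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""),
    character(1))
}

one_hot_motif <- function(cons, name = cons, nsites = 10) {
  w <- nchar(cons)
  counts <- matrix(0, 4, w)
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  counts[cbind(idx, 1:w)] <- nsites
  new_motif(counts, nsites = nsites, name = name)
}

expect_same_footprints <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
    expect_equal(a$max_score, b$max_score)
    expect_equal(a$mean_score, b$mean_score)
    expect_equal(a$summit, b$summit)
  }
}
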