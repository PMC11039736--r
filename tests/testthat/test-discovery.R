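make_implant_pool <- function(n, len, word, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    pos <- sample(len - nchar(word) + 1, 1)
    s[pos:(pos + nchar(word) - 1)] <- strsplit(word, "")[[1]]
    paste(s, collapse = "")
  }, character(1))
}

test_that("seed_kmers ranks an implanted word first", {
  pool <- make_implant_pool(100, 30, "TATAAT", 1)
  seeds <- seed_kmers(pool, 6, 3)
  expect_true(seeds[1] %in% c("TATAAT", "ATTATA"))
  expect_gte(attr(seeds, "n_classes"), 1)
  # sequences shorter than w -> empty
  expect_length(seed_kmers(c("ACG", "TTA"), 6), 0)
})

test_that("random pools produce only modest seed z-scores", {
  # no 8-mer class reaches min_count in 50 random 40-mers
  set.seed(5)
  pool <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
    character(1))
  expect_length(seed_kmers(pool, 8, 3), 0)
})

test_that("em_zoops recovers an exact implant with >= 95% exact offsets", {
  word <- "TATAAT"
  pool <- make_implant_pool(200, 50, word, 2)
  truth_pos <- vapply(pool, function(s)
    as.integer(regexpr(word, s, fixed = TRUE)) - 1L, integer(1),
    USE.NAMES = FALSE)
  fit <- em_zoops(pool, word)
  expect_equal(motif_consensus(fit$motif), word)
  plus <- fit$sites[fit$sites$strand == "+", ]
  exact <- sum(plus$offset == truth_pos[plus$seq])
  expect_gte(exact / 200, 0.95)
})

test_that("em_zoops on a signal-free pool assigns few sequences", {
  set.seed(3)
  pool <- vapply(1:150, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
    character(1))
  fit <- em_zoops(pool, "ACGTAC")
  n <- if (is.null(fit$motif)) 0 else nrow(fit$sites)
  expect_lte(n / length(pool), 0.2)
})

test_that("em_zoops degenerate single-sequence fit is the one-hot seed", {
  fit <- em_zoops("TATAAT", "TATAAT")
  expect_equal(nrow(fit$sites), 1)
  expect_equal(fit$motif$nsites, 1)
  expect_equal(motif_probs(fit$motif),
               motif_probs(one_hot_motif("TATAAT")), ignore_attr = TRUE)
  expect_error(em_zoops(c("ACG", "TT"), "TATAAT"), "no sequence")
})

test_that("motif_evalue follows the binomial-tail definition", {
  m <- one_hot_motif("ACGTACGTAC", nsites = 100)  # width 10, IC 20 bits
  # site_count 0 -> p = 1, E = tests
  expect_equal(motif_evalue(m, 0, 100, 50, tests_performed = 7), 7)
  # deterministic motif carried by the entire pool: E computed in log space
  # is far below any significance cap
  e <- motif_evalue(m, 100, 100, 50)
  expect_lt(e, 1e-50)
  # site_count at the null expectation is not significant (p near 1/2)
  m6 <- one_hot_motif("ACGTAC", nsites = 10)  # IC 12 bits
  lbar <- 209.8  # p0 = 2 * (lbar - 5) * 2^-12 = 0.1
  p0 <- 2 * (lbar - 6 + 1) * 2^-12
  expect_equal(p0, 0.1, tolerance = 1e-12)
  e2 <- motif_evalue(m6, 100, 1000, lbar)
  expect_gt(e2, 0.4)
  expect_lt(e2, 0.6)
  # the p0 floor dominates when larger than the IC-based rate
  e3 <- motif_evalue(m, 5, 100, 50, p0_floor = 0.05)
  expect_equal(e3, pbinom(4, 100, 0.05, lower.tail = FALSE))
})

test_that("knee_filter finds the low-E cluster and applies the cap", {
  e <- c(1e-50, 1e-48, 1e-45, 1e-3, 0.5, 2, 10)
  expect_equal(knee_filter(e, 0.05), 1:3)
  expect_equal(knee_filter(rep(10, 5), 0.05), integer(0))
  # fewer than 3 motifs: cap-only fallback
  expect_equal(knee_filter(1e-10, 0.05), 1L)
  expect_equal(knee_filter(c(0.5, 1e-10), 0.05), 2L)
  # flat curve has no knee: cap decides
  expect_equal(knee_filter(rep(1e-10, 4), 0.05), 1:4)
  # order independence of the selected set
  ee <- rev(e)
  expect_equal(sort(ee[knee_filter(ee, 0.05)]), sort(e[1:3]))
})

test_that("subtract_sites splits sequences and keeps long flanks", {
  pool <- data.frame(id = "FP1", chrom = "c", start = 100L, end = 130L,
                     seq = strrep("A", 30))
  out <- subtract_sites(pool, data.frame(pool_row = 1, start = 10, end = 16),
                        min_fragment_size = 8)
  expect_equal(out$start, c(100L, 116L))
  expect_equal(out$end, c(110L, 130L))
  expect_equal(nchar(out$seq), c(10L, 14L))

  out2 <- subtract_sites(pool, data.frame(pool_row = 1, start = 10, end = 16),
                         min_fragment_size = 12)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$start, 116L)

  gone <- subtract_sites(pool, data.frame(pool_row = 1, start = 0, end = 30),
                         min_fragment_size = 8)
  expect_equal(nrow(gone), 0)
  expect_error(subtract_sites(pool, data.frame(pool_row = 1, start = 10,
                                               end = 31), 8), "bounds")
  expect_error(subtract_sites(pool, data.frame(pool_row = 2, start = 0,
                                               end = 5), 8), "unknown")
})

test_that("iterative discovery makes strict pool progress and keeps books", {
  tm <- truth_motifs(2)
  g <- make_genome(25000, rng_seed = 51)
  imp <- implant_motifs(g, tm, counts = c(120L, 80L), rng_seed = 52)
  tr <- make_fp_track(25000, imp$truth, noise_sd = 0, rng_seed = 53)
  fps <- filter_by_size(merge_footprints(call_footprints(tr), tr, 6, 0.5), 8)
  res <- iterative_discovery(fps, imp$genome, discovery_params())

  # pool bp shrinks after each iteration that produced a significant motif
  sig_per_iter <- vapply(res$iterations, function(it)
    length(it$significant), integer(1))
  for (i in seq_along(sig_per_iter))
    if (sig_per_iter[i] > 0 && i < length(res$pool_bp))
      expect_lt(res$pool_bp[i + 1], res$pool_bp[i])
  expect_true(all(diff(res$pool_bp) <= 0))

  # subtracted sites never reappear in later pools: a site found at a later
  # iteration can never overlap a site subtracted at an earlier one
  all_sites <- do.call(rbind, res$sites)
  if (!is.null(all_sites) && nrow(all_sites) > 1) {
    all_sites$iter <- as.integer(sub("^iter(\\d+).*", "\\1",
                                     all_sites$motif))
    for (i in seq_len(nrow(all_sites))) for (j in seq_len(nrow(all_sites))) {
      if (all_sites$iter[j] > all_sites$iter[i])
        expect_false(all_sites$start[j] < all_sites$end[i] &&
                       all_sites$end[j] > all_sites$start[i])
    }
  }

  # every consensus motif traces back to >= 1 significant motif
  expect_gte(length(res$significant), length(res$consensus))

  # bit-reproducible rerun
  res2 <- iterative_discovery(fps, imp$genome, discovery_params())
  expect_identical(lapply(res$consensus, `[[`, "counts"),
                   lapply(res2$consensus, `[[`, "counts"))

  expect_error(iterative_discovery(fps[0, ], imp$genome), "empty")
})

test_that("sequences containing N are dropped from the discovery pool", {
  g <- c(c1 = paste0(strrep("N", 30), strrep("ACGT", 10)))
  fps <- data.frame(chrom = "c1", start = c(0L, 40L), end = c(20L, 60L),
                    max_score = 1, mean_score = 1, summit = 0L)
  res <- iterative_discovery(fps, g, discovery_params(max_iterations = 1))
  expect_equal(res$pool_sizes[1], 1L)
})
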