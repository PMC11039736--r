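test_that("local_threshold is the truncated windowed mean times the factor", {
  expect_equal(local_threshold(rep(3, 10), 5, 1.5), rep(4.5, 10))
  expect_equal(local_threshold(numeric(7), 5, 2), numeric(7))
  expect_equal(local_threshold(c(0, 0, 10, 0, 0), 5, 1)[3], 2.0)
  # truncation at the ends
  expect_equal(local_threshold(c(4, 0, 0, 0, 0), 5, 1)[1], 4 / 3)
})

test_that("call_footprints applies the run, width and flat-top rules", {
  x <- numeric(30)
  x[6:13] <- 1.0  # 0-based [5, 13)
  tr <- score_track(list(c1 = x))
  p <- fp_params(min_width = 4, max_width = 15, local_window = 21,
                 height_factor = 1, flat_top_tolerance = 0.1)
  fps <- call_footprints(tr, p)
  expect_equal(nrow(fps), 1)
  expect_equal(fps$start, 5L)
  expect_equal(fps$end, 13L)
  expect_equal(fps$max_score, 1.0)
  expect_same_footprints(fps, bf_call_footprints(x, p))

  # min_width filter
  p2 <- fp_params(min_width = 10, max_width = 15, local_window = 21,
                  height_factor = 1, flat_top_tolerance = 0.1)
  expect_equal(nrow(call_footprints(tr, p2)), 0)

  # 1 bp spike: width filter at min_width 2; width < 4 exempt at min_width 1
  y <- numeric(30)
  y[15] <- 5
  tr2 <- score_track(list(c1 = y))
  expect_equal(nrow(call_footprints(tr2, fp_params(
    min_width = 2, max_width = 15, local_window = 21, height_factor = 1,
    flat_top_tolerance = 0.1))), 0)
  one <- call_footprints(tr2, fp_params(
    min_width = 1, max_width = 15, local_window = 21, height_factor = 1,
    flat_top_tolerance = 0.1))
  expect_equal(nrow(one), 1)
  expect_equal(one$end - one$start, 1L)

  # non flat top: sharp triangle of width >= 4 fails the plateau rule
  z <- numeric(40)
  z[11:17] <- c(1, 2, 4, 9, 4, 2, 1)
  fps3 <- call_footprints(score_track(list(c1 = z)), fp_params(
    min_width = 4, max_width = 20, local_window = 21, height_factor = 1,
    flat_top_tolerance = 0.1))
  expect_equal(nrow(fps3), 0)
})

test_that("call_footprints matches the brute-force oracle on random tracks", {
  p <- fp_params()
  for (seed in 1:25) {
    len <- sample(c(300, 700, 1500), 1)
    x <- random_bumpy_track(len, seed)
    got <- call_footprints(score_track(list(c1 = x)), p)
    expect_same_footprints(got, bf_call_footprints(x, p))
  }
})

test_that("calls are invariant under positive rescaling of the track", {
  x <- random_bumpy_track(1000, 99)
  p <- fp_params()
  a <- call_footprints(score_track(list(c1 = x)), p)
  b <- call_footprints(score_track(list(c1 = 7.3 * x)), p)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
})

test_that("merge_footprints follows the gap and depth rules", {
  x <- numeric(40)
  x[6:10] <- 1.0    # [5, 10)
  x[11:12] <- 0.45  # gap [10, 12)
  x[13:16] <- 0.9   # [12, 16)
  tr <- score_track(list(c1 = x))
  fps <- data.frame(chrom = "c1", start = c(5L, 12L), end = c(10L, 16L),
                    max_score = c(1.0, 0.9), mean_score = c(1.0, 0.9),
                    summit = c(0L, 0L))
  m1 <- merge_footprints(fps, tr, merge_gap_max = 5, merge_depth_frac = 0.4)
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$start, m1$end), c(5L, 16L))
  expect_equal(m1$max_score, 1.0)

  m2 <- merge_footprints(fps, tr, merge_gap_max = 5, merge_depth_frac = 0.6)
  expect_equal(nrow(m2), 2)

  # gap 7 >= gap_max 5: never merged
  fps3 <- data.frame(chrom = "c1", start = c(5L, 17L), end = c(10L, 20L),
                     max_score = c(1, 1), mean_score = c(1, 1),
                     summit = c(0L, 0L))
  expect_equal(nrow(merge_footprints(fps3, tr, 5, 0)), 2)

  expect_error(merge_footprints(fps[2:1, ], tr, 5, 0.4), "sorted")
})

test_that("merging never loses coverage and keeps the max of parts", {
  for (seed in 1:10) {
    x <- random_bumpy_track(800, seed + 500, n_bumps = 12)
    tr <- score_track(list(c1 = x))
    fps <- call_footprints(tr, fp_params())
    if (nrow(fps) < 2) next
    merged <- merge_footprints(fps, tr, 10, 0.2)
    expect_gte(sum(merged$end - merged$start), sum(fps$end - fps$start))
    expect_equal(max(merged$max_score), max(fps$max_score))
  }
})

test_that("differential_track is clamped subtraction with validation", {
  a <- score_track(list(c1 = c(5, 2, 0)))
  b <- score_track(list(c1 = c(1, 3, 0)))
  expect_equal(differential_track(a, b)[["c1"]], c(4, 0, 0))
  expect_equal(differential_track(a, a)[["c1"]], c(0, 0, 0))
  zero <- score_track(list(c1 = numeric(3)))
  expect_equal(differential_track(a, zero)[["c1"]], a[["c1"]])
  expect_error(differential_track(a, score_track(list(c2 = 1:3 / 1))),
               "chromosome sets")
  expect_error(differential_track(a, score_track(list(c1 = c(1, 2)))),
               "lengths")
  # property: never negative, zero wherever a <= b
  set.seed(7)
  ra <- score_track(list(c = runif(500)))
  rb <- score_track(list(c = runif(500)))
  d <- differential_track(ra, rb)[["c"]]
  expect_true(all(d >= 0))
  expect_true(all(d[ra[["c"]] <= rb[["c"]]] == 0))
})

test_that("filter_by_size keeps order and applies the width cutoff", {
  fps <- data.frame(chrom = "c", start = c(0L, 20L, 40L),
                    end = c(5L, 28L, 52L), max_score = 1, mean_score = 1,
                    summit = 0L)
  expect_equal(filter_by_size(fps, 8)$end - filter_by_size(fps, 8)$start,
               c(8L, 12L))
  expect_equal(nrow(filter_by_size(fps, 1)), 3)
  expect_equal(nrow(filter_by_size(fps, 100)), 0)
})

test_that("footprints export as BED6 with clipped scores", {
  fps <- data.frame(chrom = "c", start = 0L, end = 10L, max_score = 2.5,
                    mean_score = 1, summit = 3L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_footprints_bed(fps, f)
  b <- read_bed(f)
  expect_equal(b$score, 1000)
  expect_equal(b$name, "FP1")
})
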