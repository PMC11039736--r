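test_that("genome_scan finds planted sites and only those", {
  # exact-consensus implants so a strict threshold matches all of them
  tm <- one_hot_motif("TTGACATT", "hot")
  g <- make_genome(20000, rng_seed = 61)
  imp <- implant_motifs(g, list(tm), counts = 10L, rng_seed = 62)
  hits <- genome_scan(tm, imp$genome, threshold_quantile = 1e-5)
  # every truth site is matched by a hit at the same location
  found <- vapply(seq_len(nrow(imp$truth)), function(i)
    any(hits$start == imp$truth$start[i] & hits$end == imp$truth$end[i]),
    logical(1))
  expect_true(all(found))
  expect_lte(nrow(hits), 10 + 3)  # rare chance occurrences tolerated

  # empty genome -> no hits
  expect_equal(nrow(genome_scan(tm, c(e = strrep("A", 50)),
                                background = rep(0.25, 4))), 0)

  # scanning the reverse complement genome mirrors the hits
  rcg <- c(chrS = denovofp:::revcomp(unname(imp$genome)))
  hits_rc <- genome_scan(tm, rcg, threshold_quantile = 1e-5)
  L <- nchar(imp$genome[[1]])
  expect_setequal(L - hits_rc$end, hits$start)
})

test_that("region_enrichment computes fold and binomial p-value", {
  regions <- data.frame(chrom = "c", start = 0L, end = 100L)  # 1% of 10 kb
  mk_hits <- function(starts) data.frame(
    motif = rep("m", length(starts)), chrom = rep("c", length(starts)),
    start = starts, end = starts + 6L, strand = rep("+", length(starts)),
    score = rep(1, length(starts)))
  # 8 of 10 hits inside 1% of the genome -> fold 80
  hits <- mk_hits(c(seq(10, 80, by = 10), 200, 300))
  re <- region_enrichment(hits, regions, 10000)
  expect_equal(re$fold, 80)
  expect_equal(re$hits_in_regions, 8)

  # 1 of 100 uniform hits in 1% regions -> fold 1, p ~ 0.63
  hits2 <- mk_hits(c(10, seq(110, 9910, by = 99)))
  re2 <- region_enrichment(hits2, regions, 10000)
  expect_equal(re2$fold, 1.0)
  expect_equal(re2$p_value, 1 - 0.99^100, tolerance = 1e-12)

  # no hits at all: flagged undefined
  re3 <- region_enrichment(mk_hits(numeric(0)), regions, 10000)
  expect_true(re3$undefined)
  expect_equal(re3$fold, 0)
  expect_equal(re3$p_value, 1)

  # 0 hits in regions
  re4 <- region_enrichment(mk_hits(c(200, 300)), regions, 10000)
  expect_equal(re4$fold, 0)
  expect_equal(re4$p_value, 1)
})

test_that("uniform hits give fold near 1 over seeds", {
  regions <- data.frame(chrom = "c", start = c(0L, 5000L),
                        end = c(1000L, 6000L))
  folds <- vapply(1:10, function(seed) {
    set.seed(seed)
    starts <- sample(0:9990, 400)
    hits <- data.frame(motif = "m", chrom = "c", start = starts,
                       end = starts + 6L, strand = "+", score = 1)
    region_enrichment(hits, regions, 10000)$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.15)
})

test_that("annotate_hits picks the nearest anchor with tie rules", {
  feats <- data.frame(chrom = "c", start = c(1500L, 5000L),
                      end = c(2000L, 5200L), strand = c("+", "+"),
                      name = c("gA", "gB"))
  hit <- data.frame(motif = "m", chrom = "c", start = 997L, end = 1003L,
                    strand = "+", score = 1)
  ann <- annotate_hits(hit, feats, 2000)
  expect_equal(ann$feature, "gA")
  expect_equal(ann$distance, 500)

  # out of range -> unannotated
  ann2 <- annotate_hits(hit, feats, 100)
  expect_true(is.na(ann2$feature))

  # equidistant anchors -> lexicographically smaller name
  feats3 <- data.frame(chrom = "c", start = c(1500L, 500L),
                       end = c(1600L, 600L), strand = c("+", "-"),
                       name = c("zz", "aa"))
  ann3 <- annotate_hits(hit, feats3, 2000)
  expect_equal(ann3$feature, "aa")
  expect_equal(ann3$distance, -400)

  # overlap -> distance 0
  feats4 <- data.frame(chrom = "c", start = 990L, end = 1010L, strand = "+",
                       name = "ov")
  expect_equal(annotate_hits(hit, feats4, 2000)$distance, 0)

  # minus-strand feature anchored at its end
  feats5 <- data.frame(chrom = "c", start = 1500L, end = 1700L,
                       strand = "-", name = "m1")
  expect_equal(annotate_hits(hit, feats5, 2000)$distance, 700)
})

test_that("gsea matches the exact hypergeometric oracle", {
  universe <- paste0("g", 1:100)
  sets <- list(S = paste0("g", 1:10))
  genes <- c(paste0("g", 1:3), "g50", "g60")  # overlap 3
  res <- gsea(genes, sets, universe)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_value, bf_hyper_tail(3, 10, 100, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 0.00664, tolerance = 1e-3)

  # overlap 0 -> p = 1
  res0 <- gsea(c("g99", "g98"), list(S = paste0("g", 1:10)), universe)
  expect_equal(res0$p_value, 1)

  # query = set is minimal p among same-size queries
  resq <- gsea(paste0("g", 1:10), sets, universe)
  expect_lt(resq$p_value, res$p_value)
  expect_error(gsea("g1", sets, character(0)), "empty")

  # BH correction across sets
  sets2 <- list(A = paste0("g", 1:10), B = paste0("g", 40:60))
  r2 <- gsea(paste0("g", 1:5), sets2, universe)
  expect_equal(r2$q_value, p.adjust(r2$p_value, "BH"))
})

test_that("compare_to_database labels rediscovered vs novel", {
  db <- list(one_hot_motif("TATAAT", "db1"), one_hot_motif("CCCGGG", "db2"))
  q <- list(one_hot_motif("TATAAT", "q1"), one_hot_motif("AGAGAG", "q2"))
  cmp <- compare_to_database(q, db, 0.4)
  expect_equal(cmp$summary$label, c("rediscovered", "novel"))
  expect_equal(cmp$summary$best_match[1], "db1")
  expect_equal(cmp$summary$distance[1], 0)
  expect_equal(dim(cmp$distance_matrix), c(2, 2))
  # invariance under database reordering
  cmp2 <- compare_to_database(q, rev(db), 0.4)
  expect_equal(cmp2$summary$label, cmp$summary$label)
  expect_equal(cmp2$summary$best_match, cmp$summary$best_match)
  # boundary: distance exactly at the threshold is novel (strict <)
  d <- cmp$summary$distance[2]
  cmp3 <- compare_to_database(q[2], db, threshold = d)
  expect_equal(cmp3$summary$label, "novel")
  expect_error(compare_to_database(q, list()), "empty")
})

test_that("binding_site_overlap is the smaller-set overlap coefficient", {
  mk <- function(starts) data.frame(motif = "m", chrom = "c", start = starts,
                                    end = starts + 10L, strand = "+",
                                    score = 1)
  a <- mk(seq(0, 900, by = 100))          # 10 hits
  expect_equal(binding_site_overlap(a, a), 1.0)
  b <- mk(seq(5000, 6900, by = 100))      # disjoint, 20 hits
  expect_equal(binding_site_overlap(a, b), 0.0)
  # 5 of A's 10 hits overlapped by the larger set B
  b2 <- mk(c(seq(5, 405, by = 100), seq(5000, 6400, by = 100)))
  expect_equal(binding_site_overlap(a, b2), 0.5)
  expect_equal(binding_site_overlap(a, b2), binding_site_overlap(b2, a))
  expect_equal(binding_site_overlap(a[0, ], b), 0)
})

test_that("tf_class_enrichment counts n/N vs dn/DN with hypergeometric p", {
  # 40 database motifs: 10 of class X, 30 of class Y; target overlaps the
  # X motifs strongly and two Y motifs weakly
  mk <- function(starts) data.frame(motif = "m", chrom = "c", start = starts,
                                    end = starts + 10L, strand = "+",
                                    score = 1)
  target <- mk(seq(0, 990, by = 100))
  db_motifs <- lapply(1:40, function(i) {
    m <- one_hot_motif("ACGTAC", paste0("db", i))
    m$tf_class <- if (i <= 10) "X" else "Y"
    m
  })
  # two class-X motifs overlap every target hit, the rest of class X about
  # half, class Y almost none -> the >95th-percentile top set is {db1, db2}
  db_hits <- c(
    lapply(1:2, function(i) mk(seq(0, 990, by = 100))),            # overlap 1
    # larger sets covering half the target -> overlap coefficient 0.5
    lapply(3:10, function(i) mk(c(seq(5, 405, by = 100),
                                  seq(20000, 20900, by = 100)))),
    lapply(11:12, function(i) mk(c(5, seq(5000, 6000, 100)))),     # 0.1
    lapply(13:40, function(i) mk(seq(10000, 11000, by = 100))))    # 0
  res <- tf_class_enrichment(target, db_motifs, db_hits, percentile = 95)
  x <- res[res$tf_class == "X", ]
  expect_equal(x$DN, 40)
  expect_equal(x$dn, 10)
  expect_equal(x$N, 2)
  expect_equal(x$n, 2)
  expect_equal(x$fold, (2 / 2) / (10 / 40))
  expect_equal(x$p_value, bf_hyper_tail(2, 10, 40, 2), tolerance = 1e-12)
  y <- res[res$tf_class == "Y", ]
  expect_equal(y$n, 0)
  expect_equal(y$fold, 0)
  expect_equal(y$p_value, 1)

  # worked arithmetic: N=20, n=10, DN=200, dn=20 -> fold 5, exact tail
  expect_equal((10 / 20) / (20 / 200), 5)
  expect_equal(phyper(9, 20, 180, 20, lower.tail = FALSE),
               bf_hyper_tail(10, 20, 200, 20), tolerance = 1e-12)

  # all-identical overlaps: nothing exceeds the percentile -> flagged empty
  res2 <- tf_class_enrichment(target, db_motifs,
                              lapply(1:40, function(i) mk(0)), 95)
  expect_equal(nrow(res2), 0)
  expect_true(isTRUE(attr(res2, "empty_top_set")))
})

test_that("aggregate_profile averages motif-centered windows", {
  x <- rep(1, 1000)
  hits <- data.frame(motif = "m", chrom = "c",
                     start = c(100L, 300L, 500L), end = c(110L, 310L, 510L),
                     strand = c("+", "-", "+"), score = 1)
  tr <- score_track(list(c = x))
  prof <- aggregate_profile(tr, hits, 60)
  expect_equal(prof$n, 3)
  expect_equal(prof$profile, rep(1, 120))

  # depletion at every site: center/flank ratio recovered
  y <- rep(1, 1000)
  for (s in c(100, 300, 500)) y[(s + 1):(s + 10)] <- 0.2
  prof2 <- aggregate_profile(score_track(list(c = y)), hits, 60)
  expect_equal(min(prof2$profile), 0.2)
  expect_equal(which.min(abs(seq_len(120) - 60.5)) %in%
                 which(prof2$profile == min(prof2$profile)), TRUE)
  expect_equal(prof2$profile[1], 1)

  # single hit -> profile equals that window
  one <- hits[1, ]
  prof3 <- aggregate_profile(score_track(list(c = y)), one, 20)
  mid <- (one$start + one$end) %/% 2
  expect_equal(prof3$profile, y[(mid - 20 + 1):(mid + 20)])

  # out-of-bounds windows are skipped; all out -> error
  edge <- data.frame(motif = "m", chrom = "c", start = 1L, end = 9L,
                     strand = "+", score = 1)
  expect_error(aggregate_profile(tr, edge, 60), "in-bounds")
})
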