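test_that("edge gap is zero on overlap/abutment, symmetric, Inf across chromosomes", {
  a <- list(chrom = "c", start = 100, end = 200)
  expect_equal(edge_gap(a, list(chrom = "c", start = 150, end = 300)), 0)
  expect_equal(edge_gap(a, list(chrom = "c", start = 200, end = 300)), 0)
  expect_equal(edge_gap(a, list(chrom = "c", start = 650, end = 700)), 450)
  expect_equal(edge_gap(list(chrom = "c", start = 650, end = 700), a), 450)
  expect_equal(edge_gap(a, list(chrom = "d", start = 100, end = 200)), Inf)

  set.seed(11)
  for (k in 1:50) {
    s1 <- sample(1000, 1); e1 <- s1 + sample(200, 1)
    s2 <- sample(1000, 1); e2 <- s2 + sample(200, 1)
    # brute force: min over the four edge differences, clamped at 0
    brute <- if (s1 < e2 && s2 < e1) 0 else min(abs(c(s1 - e2, s2 - e1)))
    expect_equal(edge_gap(list(chrom = "c", start = s1, end = e1),
                          list(chrom = "c", start = s2, end = e2)), brute)
  }
})

test_that("sweep nearest_distance equals the all-pairs oracle on random sets", {
  g <- genome_model(c("c1", "c2"), c(1e6, 1e6))
  A <- rand_peaks(g, 200, seed = 21, label = "A")
  B <- rand_peaks(g, 200, seed = 22, label = "B")
  expect_equal(nearest_distance(A, B), brute_nearest(A, B))
  expect_true(all(nearest_distance(A, A) == 0))
  expect_true(all(nearest_distance(A, peak_set(data.frame(), g, "E")) == Inf))
  # a chromosome without B peaks yields Inf for its A peaks
  B1 <- peak_set(B$intervals[B$intervals$chrom == "c1", ], g, "B1")
  nd <- nearest_distance(A, B1)
  expect_true(all(is.infinite(nd[A$intervals$chrom == "c2"])))
})

test_that("nearest_distance agrees with IRanges on a random fixture", {
  g <- genome_model("c1", 1e6)
  A <- rand_peaks(g, 150, seed = 31, label = "A")
  B <- rand_peaks(g, 150, seed = 32, label = "B")
  ia <- IRanges::IRanges(A$intervals$start + 1, A$intervals$end)
  ib <- IRanges::IRanges(B$intervals$start + 1, B$intervals$end)
  hits <- IRanges::distanceToNearest(ia, ib)
  expect_equal(nearest_distance(A, B),
               as.numeric(S4Vectors::mcols(hits)$distance))
})

test_that("select_within partitions and names nested classes", {
  g <- genome_model("chr1", 1e6)
  A <- peak_set(data.frame(chrom = "chr1", start = c(100, 1000),
                           end = c(200, 1100)), g, "CDC6")
  B <- peak_set(data.frame(chrom = "chr1", start = 750, end = 800), g, "MCM7")
  sel <- select_within(A, B, d = 500)
  expect_equal(sel$selected$intervals$start, 1000)   # gap 200
  expect_equal(sel$complement$intervals$start, 100)  # gap 550
  expect_identical(sel$selected$label, "CDC6_w0.5_MCM7")
  expect_identical(sel$complement$label, "CDC6_wo0.5_MCM7")

  # partition: selected + complement recompose A exactly
  A2 <- rand_peaks(g, 300, seed = 41, label = "A")
  B2 <- rand_peaks(g, 100, seed = 42, label = "B")
  s2 <- select_within(A2, B2, 500)
  expect_equal(n_peaks(s2$selected) + n_peaks(s2$complement), 300)
  both <- rbind(s2$selected$intervals, s2$complement$intervals)
  both <- both[order(both$start), ]
  rownames(both) <- NULL
  expect_equal(both$start, A2$intervals$start)

  # monotone in d
  sizes <- vapply(c(0, 100, 500, 2000, 10000),
                  function(d) n_peaks(select_within(A2, B2, d)$selected), 0L)
  expect_true(all(diff(sizes) >= 0))

  # chained selection composes labels
  C <- rand_peaks(g, 100, seed = 43, label = "sGRWD1")
  chain <- select_within(select_within(A2, B2, 500)$selected, C, 500)
  expect_identical(chain$selected$label, "A_w0.5_B_w0.5_sGRWD1")
})

test_that("shuffles preserve the length multiset and are seed-deterministic", {
  g <- genome_model(c("c1", "c2", "c3"), c(1e6, 2e6, 3e6))
  A <- rand_peaks(g, 250, seed = 51, label = "A")
  s1 <- shuffle_peaks(A, g, seed = 7)
  s2 <- shuffle_peaks(A, g, seed = 7)
  s3 <- shuffle_peaks(A, g, seed = 8)
  expect_equal(s1$intervals, s2$intervals)
  expect_false(isTRUE(all.equal(s1$intervals$start, s3$intervals$start)))
  # same_chrom: per-chromosome length multiset preserved
  for (ch in g$chrom) {
    la <- sort(with(A$intervals[A$intervals$chrom == ch, ], end - start))
    ls <- sort(with(s1$intervals[s1$intervals$chrom == ch, ], end - start))
    expect_equal(ls, la)
  }
  # genome_wide: global multiset preserved, chromosomes drawn by length
  sw <- shuffle_peaks(A, g, seed = 9, mode = "genome_wide")
  expect_equal(sort(sw$intervals$end - sw$intervals$start),
               sort(A$intervals$end - A$intervals$start))
  cnt <- table(factor(sw$intervals$chrom, levels = g$chrom))
  p <- stats::chisq.test(cnt, p = g$length / sum(g$length))$p.value
  expect_gt(p, 0.001)
})

test_that("shuffled starts are uniform over the valid range", {
  g <- genome_model("c1", 1e6)
  A <- peak_set(data.frame(chrom = "c1", start = 0, end = 1000), g, "one")
  starts <- vapply(1:1000, function(s) shuffle_peaks(A, g, seed = s)$intervals$start, 0)
  ks <- suppressWarnings(stats::ks.test(starts / (1e6 - 1000), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("venn counts are direction-aware", {
  g <- genome_model("c1", 1e6)
  far_a <- peak_set(data.frame(chrom = "c1", start = c(1000, 5000),
                               end = c(1100, 5100)), g, "A")
  far_b <- peak_set(data.frame(chrom = "c1", start = 900000, end = 900100), g, "B")
  v <- venn_counts(far_a, far_b, 500)
  expect_equal(v$n_A_with_B, 0)
  expect_equal(v$n_B_with_A, 0)
  expect_equal(venn_counts(far_a, far_a, 0)$n_A_with_B, 2)

  # three A peaks clustered around one B peak: 3 vs 1
  A3 <- peak_set(data.frame(chrom = "c1", start = c(1000, 1400, 1800),
                            end = c(1100, 1500, 1900)), g, "A3")
  B1 <- peak_set(data.frame(chrom = "c1", start = 1450, end = 1460), g, "B1")
  v3 <- venn_counts(A3, B1, 500)
  expect_equal(v3$n_A_with_B, 3)
  expect_equal(v3$n_B_with_A, 1)
})

test_that("coloc_test saturates when the window spans the chromosome", {
  g <- genome_model("c1", 1e6)
  A <- rand_peaks(g, 50, seed = 61, label = "A")
  B <- rand_peaks(g, 50, seed = 62, label = "B")
  r <- coloc_test(A, B, d = 2e6, n_shuffles = 3, seed = 1)
  expect_equal(r$fraction_observed, 1)
  expect_equal(r$fraction_null, 1)
  expect_equal(r$chi2, 0)
  expect_error(coloc_test(peak_set(data.frame(), g, "E"), B), "no peaks")
})

test_that("genuine co-localization is detected as highly significant", {
  g <- make_genome(1, 1e7)
  B <- simulate_peaks(g, 500, seed = 71, label = "B")
  A <- simulate_peaks(g, 1000, fraction = 0.5, window = 500, anchor = B,
                      seed = 72, label = "A")
  r <- coloc_test(A, B, d = 500, n_shuffles = 10, seed = 73)
  expect_lt(r$p_value, 0.001)
  expect_equal(r$fraction_observed, 0.5)
  expect_lt(r$fraction_null, 0.25)
})

test_that("center-to-center metric measures midpoint distances", {
  g <- genome_model("c1", 1e6)
  A <- peak_set(data.frame(chrom = "c1", start = 1000, end = 2000), g, "A")
  B <- peak_set(data.frame(chrom = "c1", start = 2000, end = 2200), g, "B")
  expect_equal(nearest_distance(A, B), 0)                      # abutting
  expect_equal(nearest_distance(A, B, metric = "center"), 600) # 2100 - 1500
})

test_that("TSS proximity testing finds planted enrichment and not null noise", {
  g <- make_genome(1, 1e7)
  ann <- simulate_annotation(g, 200, length_range = c(1e4, 3e4), seed = 81)
  # peaks planted at every TSS -> observed fraction 1
  tdf <- ann$records
  at_tss <- peak_set(data.frame(chrom = tdf$chrom, start = pmax(tdf$tss - 50, 0),
                                end = tdf$tss + 50), g, "atTSS")
  r <- tss_proximity_test(at_tss, ann, n_shuffles = 2, seed = 82)
  expect_equal(r$fraction_observed, 1)
  expect_lt(r$p_value, 0.001)
  # peaks biased to TSS at f = 0.6
  biased <- simulate_peaks(g, 500, fraction = 0.6, window = 500,
                           anchor = tss_sites(ann), seed = 83, label = "bias")
  expect_lt(tss_proximity_test(biased, ann, n_shuffles = 5, seed = 84)$p_value,
            0.001)
  expect_error(tss_proximity_test(at_tss, gene_annotation(data.frame(), g)),
               "empty")
})
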