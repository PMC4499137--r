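test_that("self-aggregation is symmetric with its maximum at the center", {
  g <- make_genome(1, 2e7)
  A <- simulate_peaks(g, 1000, seed = 31, label = "A")
  pr <- aggregate_peak_density(A, A, flank = 5000, step = 100)
  i0 <- which(pr$offsets == 0)
  expect_equal(which.max(pr$mean_value), i0)
  v <- pr$mean_value
  asym <- max(abs(v[i0 + 1:49] - v[i0 - 1:49])) / v[i0]
  expect_lt(asym, 0.05)
})

test_that("independent uniform peaks give a flat fold-enrichment profile", {
  g <- make_genome(1, 2e6)
  anchors <- rand_peaks(g, 1000, seed = 32, label = "anc")
  query <- rand_peaks(g, 32000, seed = 33, max_len = 200, label = "q")
  pr <- aggregate_peak_density(query, anchors, flank = 5000, step = 100)
  expect_true(all(abs(pr$mean_value - 1) < 0.1))
  # shuffled-anchor baseline agrees with the analytic genome density
  pr2 <- aggregate_peak_density(query, anchors, flank = 5000, step = 100,
                                baseline = "shuffled_anchors", seed = 3)
  expect_lt(abs(pr2$baseline / pr$baseline - 1), 0.05)
})

test_that("planted co-localization concentrates enrichment near the anchor", {
  g <- make_genome(1, 2e7)
  anchors <- simulate_peaks(g, 1000, seed = 34, label = "anc")
  q <- simulate_peaks(g, 2000, fraction = 0.27, window = 500, anchor = anchors,
                      seed = 35, label = "q")
  pr <- aggregate_peak_density(q, anchors, flank = 5000, step = 100)
  near <- abs(pr$offsets) <= 2000   # peak-length + window geometry
  far <- abs(pr$offsets) >= 3000
  expect_gt(max(pr$mean_value[near]), 2)
  # far flanks average to the genome baseline (per-bin counts are Poisson
  # with mean ~10 here, so the band is judged on its mean, not per bin)
  expect_lt(abs(mean(pr$mean_value[far]) - 1), 0.15)
})

test_that("signal aggregation matches a brute-force recount and handles edges", {
  g <- genome_model(c("a", "b"), c(1e5, 8e4))
  for (fix in 1:20) {
    reads <- rand_reads(g, 400, seed = 400 + fix)
    tr <- bin_reads(reads, g, step = 100, window = 1000)
    anchors <- rand_peaks(g, 30, seed = 500 + fix, label = "anc")
    pr <- aggregate_signal(tr, anchors, flank = 2000)
    expect_equal(pr$mean_value, brute_signal_profile(tr, anchors, 2000))
  }
  # constant track -> flat profile at the constant
  ct <- prercoloc:::new_track(list(a = rep(2.5, 1000), b = rep(2.5, 800)),
                              g, 100, 1000, "rpm", 1e6)
  anchors <- rand_peaks(g, 25, seed = 600, label = "anc")
  prc <- aggregate_signal(ct, anchors, flank = 2000)
  expect_true(all(prc$mean_value == 2.5))
  expect_equal(prc$baseline, 2.5)
  # anchors on a read-free chromosome: zero profile, anchors still counted
  rb <- read_set(list(a = c(5e4, 5e4 + 10)), g)
  tr0 <- bin_reads(rb, g)
  anc_b <- peak_set(data.frame(chrom = "b", start = c(2e4, 4e4),
                               end = c(2e4 + 100, 4e4 + 100)), g, "ancb")
  pr0 <- aggregate_signal(tr0, anc_b, flank = 1000)
  expect_true(all(pr0$mean_value == 0))
  expect_equal(pr0$anchors_used, 2L)
})

test_that("synthetic open sites produce a centered signal bump", {
  g <- make_genome(1, 1e7)
  sites <- simulate_peaks(g, 300, length_range = c(400, 600), seed = 36,
                          label = "open")
  rs <- simulate_reads(g, sites, n_reads = 5e4, enrichment = 80,
                       paired_input = TRUE, seed = 37)
  tr <- subtract_input(normalize_rpm(bin_reads(rs$sample, g)),
                       normalize_rpm(bin_reads(rs$input, g)))
  pr <- aggregate_signal(tr, sites, flank = 2000)
  peak_off <- pr$offsets[which.max(pr$mean_value)]
  expect_lte(abs(peak_off), 100)
})

test_that("metagene profiles conserve mass and respect strand orientation", {
  g <- make_genome(1, 1e7)
  ann <- simulate_annotation(g, 100, length_range = c(10000, 30000), seed = 38)
  peaks <- rand_peaks(g, 2000, seed = 39, max_len = 400, label = "p")
  mg <- metagene_frequency(peaks, ann, flank = 5000)
  # oracle: per-gene midpoint count in [tss-flank, tes+flank) spans
  mids <- (peaks$intervals$start + peaks$intervals$end) / 2
  expected <- 0
  for (i in seq_len(100)) {
    lo <- ann$records$tx_start[i] - 5000
    hi <- ann$records$tx_end[i] + 5000
    expected <- expected + sum(mids >= lo & mids < hi)
  }
  expect_equal(mg$total_assigned, expected)
  expect_equal(sum(mg$counts), mg$total_assigned)

  # plus-strand gene with a peak midpoint just after the TSS -> first body bin
  ann1 <- gene_annotation(data.frame(gene_id = "gp", chrom = "chrS1",
                                     strand = "+", tx_start = 100000,
                                     tx_end = 120000), g)
  pk <- peak_set(data.frame(chrom = "chrS1", start = 100000, end = 100001),
                 g, "pk")
  m1 <- metagene_frequency(pk, ann1)
  expect_equal(which(m1$counts == 1), 51)  # first bin after the 50 flank bins
  # minus-strand gene: a peak at the genomic start maps to the TES end
  ann2 <- gene_annotation(data.frame(gene_id = "gm", chrom = "chrS1",
                                     strand = "-", tx_start = 100000,
                                     tx_end = 120000), g)
  m2 <- metagene_frequency(pk, ann2)
  expect_equal(which(m2$counts == 1), 150)  # last body bin
})

test_that("uniform peaks give flat metagene density across flanks and body", {
  g <- make_genome(1, 5e6)
  ann <- simulate_annotation(g, 60, length_range = c(20000, 40000), seed = 40)
  peaks <- rand_peaks(g, 30000, seed = 41, max_len = 100, label = "p")
  mg <- metagene_frequency(peaks, ann, flank = 5000)
  up <- mean(mg$value[mg$section == "upstream"])
  body <- mean(mg$value[mg$section == "body"])
  down <- mean(mg$value[mg$section == "downstream"])
  expect_lt(abs(up / body - 1), 0.1)
  expect_lt(abs(down / body - 1), 0.1)
})

test_that("short genes are skipped rather than rescaled up", {
  g <- make_genome(1, 1e6)
  ann <- gene_annotation(data.frame(
    gene_id = c("ok", "tiny"), chrom = "chrS1", strand = "+",
    tx_start = c(10000, 50000), tx_end = c(30000, 50050)), g)
  peaks <- rand_peaks(g, 100, seed = 42, label = "p")
  mg <- metagene_frequency(peaks, ann, flank = 5000, body_bins = 100)
  expect_equal(mg$n_genes, 1L)
  expect_equal(mg$n_skipped, 1L)
})

test_that("identical FAIRE conditions compare as a null", {
  g <- make_genome(1, 1e6)
  tr <- normalize_rpm(bin_reads(rand_reads(g, 5000, seed = 43), g))
  anchors <- rand_peaks(g, 50, seed = 44, label = "anc")
  cmp <- faire_compare(tr, tr, anchors)
  expect_equal(cmp$percent_change, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(faire_compare(tr, tr, peak_set(data.frame(), g, "E")), "anchors")
})

test_that("knockdown factors are recovered as percent change", {
  g <- make_genome(3, 2e7)
  sites <- simulate_peaks(g, 1000, seed = 45, label = "sites")
  mk <- function(eff, seed) {
    rs <- simulate_reads(g, sites, n_reads = 1.2e5, enrichment = 100,
                         effect = eff, paired_input = TRUE, seed = seed)
    subtract_input(normalize_rpm(bin_reads(rs$sample, g)),
                   normalize_rpm(bin_reads(rs$input, g)))
  }
  ctrl <- mk(1, 46)
  for (gfac in c(0.5, 0.7, 0.9)) {
    kd <- mk(gfac, 47 + round(100 * gfac))
    cmp <- faire_compare(ctrl, kd, sites)
    expect_lt(abs(cmp$percent_change - 100 * (gfac - 1)), 5)
    expect_lt(cmp$p_value, 0.001)
    cmp_t <- faire_compare(ctrl, kd, sites, test = "paired_t")
    expect_lt(cmp_t$p_value, 0.001)
  }
})

test_that("equal conditions with independent noise keep the false-positive rate low", {
  g <- make_genome(1, 5e6)
  sites <- simulate_peaks(g, 200, seed = 48, label = "s")
  rej <- 0
  n_runs <- 100
  for (i in seq_len(n_runs)) {
    mk <- function(seed) {
      rs <- simulate_reads(g, sites, n_reads = 2e4, enrichment = 50,
                           paired_input = TRUE, seed = seed)
      subtract_input(normalize_rpm(bin_reads(rs$sample, g)),
                     normalize_rpm(bin_reads(rs$input, g)))
    }
    cmp <- faire_compare(mk(1000 + 2 * i), mk(1001 + 2 * i), sites)
    if (cmp$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_runs, 0.10)
})
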