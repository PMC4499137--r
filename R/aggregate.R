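#' Aggregate peak density around anchor sites
#'
#' Classic aggregation ("average") plot for two peak sets: for every anchor
#' interval midpoint, query-peak midpoints are counted in offset bins of
#' width `step` from `-flank` to `+flank`, averaged over anchors, and
#' divided by the expected density to give fold enrichment. Anchors whose
#' window runs off a chromosome end contribute only their valid offsets.
#'
#' The reference point of an interval is its midpoint throughout — summit
#' information is not assumed.
#'
#' @param query,anchors [peak_set()]s on a shared genome; `anchors`
#'   non-empty.
#' @param flank Half-width of the profile in bp (default 5000).
#' @param step Offset bin width in bp (default 100).
#' @param baseline `"genome_density"` (expected query midpoints per bin from
#'   the global density; default) or `"shuffled_anchors"` (mean bin count
#'   around one length-preserving shuffle of the anchors).
#' @param seed Seed for the shuffled-anchor baseline.
#' @return An `aggregate_profile` object: `offsets` (bp, bin centers
#'   symmetric about 0), `mean_value` (fold enrichment), `mean_count`,
#'   `baseline` (expected count per bin), `anchors_used`, `n_valid` per
#'   offset.
#' @export
aggregate_peak_density <- function(query, anchors, flank = 5000, step = 100,
                                   baseline = c("genome_density",
                                                "shuffled_anchors"),
                                   seed = 1) {
  stopifnot(inherits(query, "peak_set"), inherits(anchors, "peak_set"))
  baseline <- match.arg(baseline)
  if (n_peaks(anchors) == 0L) stop("anchor set is empty")
  if (!identical(query$genome$chrom, anchors$genome$chrom)) {
    stop("peak sets are on different genome models")
  }
  raw <- density_profile_raw(query, anchors, flank, step)
  base_count <- if (baseline == "genome_density") {
    n_peaks(query) / genome_length(query$genome) * step
  } else {
    sh <- shuffle_peaks(anchors, anchors$genome, seed = seed)
    mean(density_profile_raw(query, sh, flank, step)$mean_count)
  }
  structure(list(offsets = raw$offsets,
                 mean_value = raw$mean_count / base_count,
                 mean_count = raw$mean_count,
                 baseline = base_count,
                 baseline_mode = baseline,
                 anchors_used = n_peaks(anchors),
                 n_valid = raw$n_valid,
                 kind = "peak_density"),
            class = "aggregate_profile")
}

density_profile_raw <- function(query, anchors, flank, step) {
  offsets <- seq(-flank, flank, by = step)
  nb <- length(offsets)
  sums <- numeric(nb)
  nval <- numeric(nb)
  qdf <- query$intervals
  adf <- anchors$intervals
  for (ch in unique(adf$chrom)) {
    q <- sort((qdf$start[qdf$chrom == ch] + qdf$end[qdf$chrom == ch]) / 2)
    L <- chrom_length(query$genome, ch)
    amid <- (adf$start[adf$chrom == ch] + adf$end[adf$chrom == ch]) / 2
    for (m in amid) {
      edges <- m + c(offsets - step / 2, flank + step / 2)
      cnt <- diff(findInterval(edges, q, left.open = TRUE))
      valid <- edges[-length(edges)] >= 0 & edges[-1L] <= L
      sums[valid] <- sums[valid] + cnt[valid]
      nval <- nval + valid
    }
  }
  if (any(nval == 0)) nval[nval == 0] <- NA_real_
  list(offsets = offsets, mean_count = sums / nval, n_valid = nval)
}

#' Aggregate track signal around anchor sites
#'
#' Mean track value per offset across anchor midpoints, with offsets aligned
#' to the track's bin grid; the cumulative-signal profile used to compare
#' chromatin openness at site classes. Baseline is the genome-wide track
#' mean. Offsets that fall off a chromosome contribute nothing for that
#' anchor.
#'
#' @param track A [binned_track()].
#' @param anchors A non-empty [peak_set()] on the track's genome.
#' @param flank Half-width in bp (default 2000), rounded to the track step.
#' @return An `aggregate_profile` with `mean_value` in track units.
#' @export
aggregate_signal <- function(track, anchors, flank = 2000) {
  stopifnot(inherits(track, "binned_track"), inherits(anchors, "peak_set"))
  if (n_peaks(anchors) == 0L) stop("anchor set is empty")
  if (!identical(track$genome$chrom, anchors$genome$chrom)) {
    stop("track and anchors are on different genome models")
  }
  step <- track$step
  k <- floor(flank / step)
  koff <- (-k):k
  sums <- numeric(length(koff))
  nval <- numeric(length(koff))
  adf <- anchors$intervals
  for (ch in unique(adf$chrom)) {
    v <- track$values[[ch]]
    nb <- length(v)
    amid <- (adf$start[adf$chrom == ch] + adf$end[adf$chrom == ch]) / 2
    b0 <- amid %/% step # 0-based bin of each anchor midpoint
    for (b in b0) {
      idx <- b + koff
      valid <- idx >= 0 & idx < nb
      sums[valid] <- sums[valid] + v[idx[valid] + 1]
      nval <- nval + valid
    }
  }
  if (any(nval == 0)) nval[nval == 0] <- NA_real_
  structure(list(offsets = koff * step,
                 mean_value = sums / nval,
                 mean_count = sums / nval,
                 baseline = track_mean(track),
                 baseline_mode = "track_mean",
                 anchors_used = n_peaks(anchors),
                 n_valid = nval,
                 kind = "signal"),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf("aggregate profile (%s): %d offsets in [%d, %d] bp, %d anchor(s)\n",
              x$kind, length(x$offsets), min(x$offsets), max(x$offsets),
              x$anchors_used))
  i0 <- which(x$offsets == 0)
  cat(sprintf("  value at offset 0: %.3f; baseline: %.4g\n",
              x$mean_value[i0], x$baseline))
  invisible(x)
}

#' @export
plot.aggregate_profile <- function(x, ...) {
  ylab <- if (x$kind == "peak_density") "fold enrichment" else "mean signal"
  graphics::plot(x$offsets, x$mean_value, type = "l",
                 xlab = "offset from anchor midpoint (bp)", ylab = ylab, ...)
  if (x$kind == "peak_density") graphics::abline(h = 1, lty = 2)
  else graphics::abline(h = x$baseline, lty = 2)
  invisible(x)
}

#' Write an aggregate profile as TSV
#' @param profile An `aggregate_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("offset\tmean\tbaseline", con)
  writeLines(sprintf("%d\t%.6g\t%.6g", as.integer(profile$offsets),
                     profile$mean_value, profile$baseline), con)
  invisible(path)
}

#' Metagene frequency profile of a peak set
#'
#' Peak midpoints are mapped onto a strand-oriented gene coordinate system:
#' a fixed-width upstream flank (5' of the TSS), a gene body linearly
#' rescaled to `body_bins` bins, and a fixed-width downstream flank (3' of
#' the TES). Flank bins have width `flank / flank_bins` bp (100 bp at the
#' defaults). The reported value per bin is the mean peak density across
#' genes (peaks per bp per gene), so a uniform peak set gives a flat profile
#' across flanks and body alike. Region boundaries are half-open, so no
#' midpoint is counted twice within a gene. Genes shorter than `body_bins`
#' bp are skipped (rescaling them up would alias bins) and counted in
#' `n_skipped`.
#'
#' @param peaks A [peak_set()].
#' @param annotation A non-empty [gene_annotation()] on the same genome.
#' @param flank Flank width in bp (default 5000).
#' @param flank_bins Number of bins per flank (default 50).
#' @param body_bins Number of gene-body bins (default 100).
#' @return A `metagene_profile`: `value` (mean density per bin), `counts`
#'   (total midpoints per bin), `section` (upstream/body/downstream),
#'   `n_genes`, `n_skipped`, `total_assigned`.
#' @export
metagene_frequency <- function(peaks, annotation, flank = 5000,
                               flank_bins = 50, body_bins = 100) {
  stopifnot(inherits(peaks, "peak_set"), inherits(annotation, "gene_annotation"))
  if (n_genes(annotation) == 0L) stop("empty annotation")
  fw <- flank / flank_bins
  ntot <- flank_bins + body_bins + flank_bins
  counts <- numeric(ntot)
  dens_sum <- numeric(ntot)
  pdf <- peaks$intervals
  mids <- split((pdf$start + pdf$end) / 2, pdf$chrom)
  mids <- lapply(mids, sort)
  gdf <- annotation$records
  used <- 0L; skipped <- 0L
  for (g in seq_len(nrow(gdf))) {
    ts <- gdf$tx_start[g]; te <- gdf$tx_end[g]
    len <- te - ts
    if (len < body_bins) { skipped <- skipped + 1L; next }
    used <- used + 1L
    q <- mids[[gdf$chrom[g]]]
    if (is.null(q) || !length(q)) next
    lo <- ts - flank; hi <- te + flank
    q <- q[q >= lo & q < hi]
    if (!length(q)) next
    # genomic bin triplet: upstream-of-start flank, body, downstream-of-end flank
    up_g <- q[q < ts]
    body_g <- q[q >= ts & q < te]
    down_g <- q[q >= te]
    bin_left <- floor((up_g - lo) / fw)                      # 0..flank_bins-1
    bin_body <- pmin(floor((body_g - ts) / len * body_bins), body_bins - 1)
    bin_right <- floor((down_g - te) / fw)                   # 0..flank_bins-1
    if (gdf$strand[g] == "+") {
      idx <- c(bin_left + 1,
               flank_bins + bin_body + 1,
               flank_bins + body_bins + bin_right + 1)
    } else {
      idx <- c(flank_bins + body_bins + (flank_bins - 1 - bin_left) + 1,
               flank_bins + (body_bins - 1 - bin_body) + 1,
               (flank_bins - 1 - bin_right) + 1)
    }
    gene_counts <- tabulate(idx, nbins = ntot)
    counts <- counts + gene_counts
    widths <- c(rep(fw, flank_bins), rep(len / body_bins, body_bins),
                rep(fw, flank_bins))
    dens_sum <- dens_sum + gene_counts / widths
  }
  if (used == 0L) stop("all genes shorter than body_bins bp; nothing to profile")
  structure(list(value = dens_sum / used,
                 counts = counts,
                 section = rep(c("upstream", "body", "downstream"),
                               c(flank_bins, body_bins, flank_bins)),
                 flank = flank, flank_bins = flank_bins, body_bins = body_bins,
                 n_genes = used, n_skipped = skipped,
                 total_assigned = sum(counts)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene profile: %d genes (%d skipped), %d peak midpoints assigned\n",
              x$n_genes, x$n_skipped, x$total_assigned))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  n <- length(x$value)
  graphics::plot(seq_len(n), x$value, type = "l", xaxt = "n",
                 xlab = "", ylab = "mean peak density (per bp per gene)", ...)
  b1 <- x$flank_bins + 0.5
  b2 <- x$flank_bins + x$body_bins + 0.5
  graphics::abline(v = c(b1, b2), lty = 2)
  graphics::axis(1, at = c(0.5, b1, b2, n + 0.5),
                 labels = c(sprintf("-%g kb", x$flank / 1000), "TSS", "TES",
                            sprintf("+%g kb", x$flank / 1000)))
  invisible(x)
}

#' Two-condition signal comparison in fixed windows
#'
#' Per-anchor mean signal over a `± halfwidth` bp window around each anchor
#' midpoint in two tracks on the same grid (e.g. FAIRE openness in control
#' and knockdown conditions), summarized as overall means, percent change,
#' and a paired test across anchors. The default paired Wilcoxon signed-rank
#' test is robust to the skew of coverage data; a paired t-test is
#' available.
#'
#' @param track_ctrl,track_kd [binned_track()]s on the same grid.
#' @param anchors A [peak_set()] with at least 2 peaks.
#' @param halfwidth Window half-width in bp (default 2000).
#' @param test `"paired_wilcoxon"` (default) or `"paired_t"`.
#' @return A `window_comparison`: per-anchor means `signal_1`/`signal_2`,
#'   `mean_1`, `mean_2`, `percent_change` (100 * (mean_2 - mean_1) /
#'   mean_1), `p_value`, `test_name`.
#' @export
faire_compare <- function(track_ctrl, track_kd, anchors, halfwidth = 2000,
                          test = c("paired_wilcoxon", "paired_t")) {
  stopifnot(inherits(track_ctrl, "binned_track"),
            inherits(track_kd, "binned_track"),
            inherits(anchors, "peak_set"))
  test <- match.arg(test)
  check_same_grid(track_ctrl, track_kd)
  if (n_peaks(anchors) < 2L) stop("need at least 2 anchors for a paired test")
  s1 <- window_means(track_ctrl, anchors, halfwidth)
  s2 <- window_means(track_kd, anchors, halfwidth)
  m1 <- mean(s1); m2 <- mean(s2)
  pc <- if (m1 > 0) 100 * (m2 - m1) / m1 else NA_real_
  diffs <- s2 - s1
  if (all(diffs == 0)) {
    p <- 1
  } else if (test == "paired_wilcoxon") {
    p <- stats::wilcox.test(s2, s1, paired = TRUE, exact = FALSE)$p.value
  } else {
    p <- stats::t.test(s2, s1, paired = TRUE)$p.value
  }
  structure(list(halfwidth = halfwidth, signal_1 = s1, signal_2 = s2,
                 mean_1 = m1, mean_2 = m2, percent_change = pc,
                 p_value = p, test_name = test,
                 anchors_used = n_peaks(anchors)),
            class = "window_comparison")
}

window_means <- function(track, anchors, halfwidth) {
  adf <- anchors$intervals
  out <- numeric(nrow(adf))
  step <- track$step
  j <- 0L
  for (ch in unique(adf$chrom)) {
    v <- track$values[[ch]]
    nb <- length(v)
    rows <- which(adf$chrom == ch)
    amid <- (adf$start[rows] + adf$end[rows]) / 2
    for (r in seq_along(rows)) {
      jlo <- max(0, floor((amid[r] - halfwidth) / step))
      jhi <- min(nb - 1, ceiling((amid[r] + halfwidth) / step) - 1)
      out[rows[r]] <- if (jhi >= jlo) mean(v[(jlo:jhi) + 1]) else 0
    }
  }
  out
}

#' @export
print.window_comparison <- function(x, ...) {
  cat(sprintf("window comparison (+/- %d bp, %d anchors, %s)\n",
              x$halfwidth, x$anchors_used, x$test_name))
  cat(sprintf("  mean condition 1: %.4g; condition 2: %.4g\n", x$mean_1, x$mean_2))
  cat(sprintf("  percent change: %.1f%%; p = %.3g\n", x$percent_change, x$p_value))
  invisible(x)
}
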