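#' Edge gap between two intervals
#'
#' Distance between nearest edges of two intervals on the same chromosome:
#' 0 when they overlap or abut, otherwise the size of the gap. Symmetric.
#' Intervals on different chromosomes are at infinite distance (never
#' co-localized), returned as `Inf` rather than raised as an error.
#'
#' @param a,b Lists or one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Gap in bp (0 for overlap/abutment; `Inf` across chromosomes).
#' @examples
#' edge_gap(list(chrom = "c", start = 100, end = 200),
#'          list(chrom = "c", start = 650, end = 700))  # 450
#' @export
edge_gap <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  max(0, a$start - b$end, b$start - a$end)
}

# Per-chromosome sweep: for query intervals [s, e) and a subject set sorted by
# start, the nearest edge gap is min over (i) subjects starting at or before s,
# whose best candidate is the one with the largest end (prefix cummax), and
# (ii) the first subject starting after s, since gap grows with start beyond
# that. Exactly equivalent to the all-pairs minimum; O((n+m) log m).
nearest_gap_sorted <- function(qs, qe, bs, be) {
  m <- length(bs)
  if (m == 0L) return(rep(Inf, length(qs)))
  cm <- cummax(be)
  k <- findInterval(qs, bs)
  left <- ifelse(k > 0L, pmax(0, qs - cm[pmax(k, 1L)]), Inf)
  right <- ifelse(k < m, pmax(0, bs[pmin(k + 1L, m)] - qe), Inf)
  pmin(left, right)
}

# center-to-center metric: |midpoint difference| to nearest subject midpoint
nearest_center_sorted <- function(qc, bc) {
  m <- length(bc)
  if (m == 0L) return(rep(Inf, length(qc)))
  k <- findInterval(qc, bc)
  left <- ifelse(k > 0L, qc - bc[pmax(k, 1L)], Inf)
  right <- ifelse(k < m, bc[pmin(k + 1L, m)] - qc, Inf)
  pmin(left, right)
}

#' Distance from each peak in A to its nearest peak in B
#'
#' For every interval of `A`, the minimum [edge_gap()] to any interval of `B`
#' (`metric = "edge"`, default) or the minimum absolute midpoint distance
#' (`metric = "center"`). Peaks on chromosomes with no `B` peak get `Inf`.
#' Implemented as a sorted sweep that matches the brute-force all-pairs
#' minimum exactly.
#'
#' @param A,B [peak_set()]s on the same genome.
#' @param metric `"edge"` or `"center"`.
#' @return Numeric vector of distances, one per `A` interval in `A`'s sorted
#'   order.
#' @export
nearest_distance <- function(A, B, metric = c("edge", "center")) {
  stopifnot(inherits(A, "peak_set"), inherits(B, "peak_set"))
  metric <- match.arg(metric)
  if (!identical(A$genome$chrom, B$genome$chrom)) {
    stop("peak sets are on different genome models")
  }
  da <- A$intervals
  db <- B$intervals
  out <- rep(Inf, nrow(da))
  for (ch in unique(da$chrom)) {
    qi <- which(da$chrom == ch)
    bi <- which(db$chrom == ch)
    if (metric == "edge") {
      out[qi] <- nearest_gap_sorted(da$start[qi], da$end[qi],
                                    db$start[bi], db$end[bi])
    } else {
      bc <- sort((db$start[bi] + db$end[bi]) / 2)
      out[qi] <- nearest_center_sorted((da$start[qi] + da$end[qi]) / 2, bc)
    }
  }
  out
}

coloc_label <- function(a, b, d, within = TRUE) {
  sprintf("%s_%s%s_%s", a, if (within) "w" else "wo", format(d / 1000), b)
}

#' Partition a peak set by proximity to another
#'
#' Splits `A` into the peaks that have a `B` peak within `d` bp
#' (`A_w{d/1000}_B`) and the remaining peaks (`A_wo{d/1000}_B`), the
#' nested-set selection used to build classes like `CDC6_w0.5_MCM7` and, by
#' chaining, `CDC6_w0.5_MCM7_w0.5_sGRWD1_w0.5_SNS`. "Within d" means edge
#' gap `<= d` by default, so overlapping peaks count at distance 0.
#'
#' @param A,B [peak_set()]s on the same genome.
#' @param d Distance window in bp (default 500).
#' @param metric `"edge"` (default) or `"center"`.
#' @return A list with [peak_set()]s `selected` and `complement`;
#'   `n_peaks(selected) + n_peaks(complement) == n_peaks(A)`.
#' @examples
#' g <- genome_model("chr1", 1e6)
#' A <- peak_set(data.frame(chrom = "chr1", start = c(100, 1000),
#'                          end = c(200, 1100)), g, "A")
#' B <- peak_set(data.frame(chrom = "chr1", start = 750, end = 800), g, "B")
#' sel <- select_within(A, B, d = 500)
#' n_peaks(sel$selected)  # 1: the peak at 1000 (gap 200)
#' @export
select_within <- function(A, B, d = 500, metric = c("edge", "center")) {
  stopifnot(d >= 0)
  metric <- match.arg(metric)
  nd <- nearest_distance(A, B, metric = metric)
  keep <- nd <= d
  list(
    selected = peak_set(A$intervals[keep, , drop = FALSE], A$genome,
                        coloc_label(A$label, B$label, d, TRUE)),
    complement = peak_set(A$intervals[!keep, , drop = FALSE], A$genome,
                          coloc_label(A$label, B$label, d, FALSE))
  )
}

#' Shuffle a peak set (null model)
#'
#' Random relocation preserving the number of peaks and the multiset of peak
#' lengths — the chance-co-localization null. With `mode = "same_chrom"`
#' each peak is replaced on its own chromosome at a uniform start; with
#' `mode = "genome_wide"` a destination chromosome is first drawn with
#' probability proportional to its length (among chromosomes long enough to
#' hold the peak).
#'
#' @param A A [peak_set()].
#' @param genome Genome model (defaults to `A$genome`).
#' @param seed Integer seed; same seed, same shuffle.
#' @param mode `"same_chrom"` (default) or `"genome_wide"`.
#' @return A [peak_set()] labelled `"shuffled_<label>"`.
#' @export
shuffle_peaks <- function(A, genome = A$genome, seed = 1,
                          mode = c("same_chrom", "genome_wide")) {
  stopifnot(inherits(A, "peak_set"), inherits(genome, "genome_model"))
  mode <- match.arg(mode)
  df <- A$intervals
  n <- nrow(df)
  len <- df$end - df$start
  with_seed(seed, {
    if (mode == "same_chrom") {
      L <- chrom_length(genome, df$chrom)
      if (any(len > L)) stop("peak longer than its chromosome; cannot shuffle")
      ns <- floor(stats::runif(n) * (L - len + 1))
      chrom <- df$chrom
    } else {
      chrom <- character(n)
      ns <- numeric(n)
      for (i in seq_len(n)) {
        ok <- genome$length >= len[i]
        if (!any(ok)) stop("peak longer than every chromosome; cannot shuffle")
        ci <- sample(which(ok), 1L, prob = genome$length[ok])
        chrom[i] <- genome$chrom[ci]
        ns[i] <- floor(stats::runif(1) * (genome$length[ci] - len[i] + 1))
      }
    }
    peak_set(data.frame(chrom = chrom, start = ns, end = ns + len,
                        name = df$name, score = df$score, strand = df$strand,
                        stringsAsFactors = FALSE),
             genome, paste0("shuffled_", A$label))
  })
}

#' Windowed co-localization test against a shuffled null
#'
#' Counts how many `A` peaks have a `B` peak within `d` bp, builds the same
#' count for `n_shuffles` length-preserving shuffles of `A`, and tests the
#' observed versus mean-null proportions with a Pearson chi-square on the
#' 2x2 table (df = 1, no continuity correction). Pooling several shuffles
#' stabilizes the null fraction without changing its expectation; the null
#' column of the table is scaled back to per-shuffle (i.e. `n_A`) totals.
#'
#' @param A,B [peak_set()]s on a shared genome.
#' @param d Distance window in bp.
#' @param n_shuffles Number of shuffles pooled into the null (default 10).
#' @param seed Integer seed for the shuffles.
#' @param metric `"edge"` or `"center"`.
#' @param mode Shuffle mode, see [shuffle_peaks()].
#' @return An `overlap_report` object with observed and null counts and
#'   fractions, the chi-square statistic and its p-value.
#' @export
coloc_test <- function(A, B, d = 500, n_shuffles = 10, seed = 1,
                       metric = c("edge", "center"),
                       mode = c("same_chrom", "genome_wide")) {
  stopifnot(inherits(A, "peak_set"), inherits(B, "peak_set"))
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  nA <- n_peaks(A)
  if (nA == 0L) stop("coloc_test: A has no peaks")
  obs <- sum(nearest_distance(A, B, metric = metric) <= d)
  null_sum <- 0
  for (s in seq_len(n_shuffles)) {
    sh <- shuffle_peaks(A, A$genome, seed = seed + s - 1L, mode = mode)
    null_sum <- null_sum + sum(nearest_distance(sh, B, metric = metric) <= d)
  }
  null_per <- null_sum / n_shuffles
  tab <- rbind(observed = c(with = obs, without = nA - obs),
               null = c(with = null_per, without = nA - null_per))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    chi2 <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic)
    p <- unname(ct$p.value)
    if (is.nan(chi2)) { chi2 <- 0; p <- 1 }
  }
  structure(list(label_A = A$label, label_B = B$label, d = d,
                 n_A = nA, n_B = n_peaks(B),
                 n_A_with_B = obs, n_shuffle_with_B = null_sum,
                 n_shuffles = n_shuffles,
                 fraction_observed = obs / nA,
                 fraction_null = null_per / nA,
                 chi2 = chi2, p_value = p,
                 metric = metric, mode = mode),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("co-localization of '%s' with '%s' within %s kb\n",
              x$label_A, x$label_B, format(x$d / 1000)))
  cat(sprintf("  observed: %d / %d (%.1f%%)\n", x$n_A_with_B, x$n_A,
              100 * x$fraction_observed))
  cat(sprintf("  shuffled null: %.1f / %d (%.1f%%) over %d shuffle(s)\n",
              x$n_shuffle_with_B / x$n_shuffles, x$n_A,
              100 * x$fraction_null, x$n_shuffles))
  cat(sprintf("  chi-square = %.2f (df = 1), p = %.3g\n", x$chi2, x$p_value))
  invisible(x)
}

#' Venn counts for two peak sets at a distance window
#'
#' The four numbers behind a windowed Venn diagram: set sizes and, in each
#' direction, how many peaks have a partner within `d` bp. The two overlap
#' counts can differ because the windowed relation is many-to-one (three `A`
#' peaks can share one `B` peak).
#'
#' @param A,B [peak_set()]s on a shared genome.
#' @param d Distance window in bp.
#' @param metric `"edge"` or `"center"`.
#' @return Named list: `n_A`, `n_B`, `n_A_with_B`, `n_B_with_A`.
#' @export
venn_counts <- function(A, B, d = 500, metric = c("edge", "center")) {
  metric <- match.arg(metric)
  list(n_A = n_peaks(A), n_B = n_peaks(B),
       n_A_with_B = sum(nearest_distance(A, B, metric = metric) <= d),
       n_B_with_A = sum(nearest_distance(B, A, metric = metric) <= d))
}

#' TSS-proximity test for a peak set
#'
#' Tests whether peaks sit near transcription start sites more often than
#' shuffled peaks do: TSSs become 1 bp intervals and the comparison delegates
#' to [coloc_test()].
#'
#' @param peaks A [peak_set()].
#' @param annotation A non-empty [gene_annotation()].
#' @param d Distance window in bp (default 500).
#' @param n_shuffles,seed,metric,mode Passed to [coloc_test()].
#' @return An `overlap_report`.
#' @export
tss_proximity_test <- function(peaks, annotation, d = 500, n_shuffles = 10,
                               seed = 1, metric = c("edge", "center"),
                               mode = c("same_chrom", "genome_wide")) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (n_genes(annotation) == 0L) stop("tss_proximity_test: empty annotation")
  coloc_test(peaks, tss_sites(annotation), d = d, n_shuffles = n_shuffles,
             seed = seed, metric = match.arg(metric), mode = match.arg(mode))
}
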