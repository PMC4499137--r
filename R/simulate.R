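#' Synthetic genome model
#'
#' Deterministic genome of `n_chroms` equal-length chromosomes named
#' `chrS1, chrS2, ...` — the sampling space for all synthetic generators.
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in bp (>= 10 kb).
#' @param seed Unused placeholder kept for interface symmetry with the other
#'   generators (the model is fully deterministic).
#' @return A [genome_model()].
#' @export
make_genome <- function(n_chroms = 3, chrom_length = 2e7, seed = 1) {
  if (n_chroms < 1) stop("need at least one chromosome")
  if (chrom_length < 1e4) stop("chromosomes shorter than 10 kb are degenerate")
  genome_model(paste0("chrS", seq_len(n_chroms)),
               rep(floor(chrom_length), n_chroms))
}

# edge gap from one query interval to the nearest interval of a sorted
# peak-set data.frame, per chromosome
gap_to_set <- function(chrom, s, e, df) {
  i <- which(df$chrom == chrom)
  if (!length(i)) return(Inf)
  nearest_gap_sorted(s, e, df$start[i], df$end[i])
}

#' Simulate a peak set with a controlled co-localization fraction
#'
#' Generates `n_peaks` intervals with uniform lengths in `length_range`.
#' When `fraction` and an `anchor` set are given, a fraction `fraction` of
#' the peaks (rounded to the nearest integer) is placed with edge gap at
#' most `window` bp from a uniformly chosen anchor peak, and the rest are
#' placed uniformly, rejecting any position within `window` bp of an anchor.
#' [select_within()] against the anchors therefore recovers the requested
#' fraction by construction. Co-localized peaks get a signed edge gap
#' uniform on `[-overlap, window]` (overlap capped by the shorter of the two
#' intervals), which yields a sharp central aggregation peak without
#' modelling summit offsets.
#'
#' Placement is rejection-sampled; after `max_attempts` failures for one
#' peak a capacity error is raised rather than silently biasing the
#' fraction.
#'
#' @param genome A [genome_model()].
#' @param n_peaks Number of peaks.
#' @param length_range Two-element bp range for uniform peak lengths
#'   (default 300-1500 bp, a plausible broad-peak scale; exposed, not fitted
#'   to any particular dataset).
#' @param fraction Co-localized fraction in `[0, 1]`, or `NULL` for fully
#'   independent placement.
#' @param window Co-localization window `d` in bp (default 500).
#' @param anchor Anchor [peak_set()]; required when `fraction` is given.
#' @param min_gap Minimum edge gap between same-set peaks (default 0 = no
#'   constraint).
#' @param distinct_anchors Attach each co-localized peak to a different
#'   anchor (sampling without replacement; requires
#'   `round(fraction * n_peaks) <= n_peaks(anchor)`). With this option the
#'   number of *anchor* peaks that gain a neighbour is controlled too, which
#'   is what nested-class emulation needs.
#' @param seed Integer seed; same seed, same peaks.
#' @param label Set label.
#' @param max_attempts Rejection-sampling cap per peak.
#' @return A [peak_set()].
#' @export
simulate_peaks <- function(genome, n_peaks, length_range = c(300, 1500),
                           fraction = NULL, window = 500, anchor = NULL,
                           min_gap = 0, distinct_anchors = FALSE, seed = 1,
                           label = "synthetic", max_attempts = 1000) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.null(fraction)) {
    if (is.null(anchor)) stop("fraction given but no anchor peak set")
    if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
    if (n_peaks(anchor) == 0L) stop("anchor set is empty")
  }
  lmin <- length_range[1L]; lmax <- length_range[2L]
  if (lmin < 1 || lmax < lmin) stop("bad length range")
  n_coloc <- if (is.null(fraction)) 0L else as.integer(round(fraction * n_peaks))
  adf <- if (is.null(anchor)) NULL else anchor$intervals
  if (distinct_anchors && n_coloc > 0L && n_coloc > nrow(adf)) {
    stop("distinct_anchors: need at least ", n_coloc, " anchor peaks")
  }
  with_seed(seed, {
    anchor_pick <- if (distinct_anchors && n_coloc > 0L) {
      sample.int(nrow(adf), n_coloc)
    } else NULL
    chrom <- character(n_peaks); st <- numeric(n_peaks); en <- numeric(n_peaks)
    placed <- list(chrom = character(0), start = numeric(0), end = numeric(0))
    for (i in seq_len(n_peaks)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        len <- lmin + floor(stats::runif(1) * (lmax - lmin + 1))
        if (i <= n_coloc) {
          j <- if (is.null(anchor_pick)) sample.int(nrow(adf), 1L)
               else anchor_pick[i]
          ach <- adf$chrom[j]
          ov <- min(len, adf$end[j] - adf$start[j])
          g <- -ov + floor(stats::runif(1) * (window + ov + 1))
          if (stats::runif(1) < 0.5) s <- adf$end[j] + g
          else s <- adf$start[j] - g - len
          L <- chrom_length(genome, ach)
          if (s < 0 || s + len > L) next
          ch <- ach
        } else {
          ci <- sample.int(length(genome$chrom), 1L, prob = genome$length)
          ch <- genome$chrom[ci]
          L <- genome$length[ci]
          if (len > L) next
          s <- floor(stats::runif(1) * (L - len + 1))
          if (!is.null(adf) && gap_to_set(ch, s, s + len, adf) <= window) next
        }
        if (min_gap > 0 && length(placed$start)) {
          pi <- placed$chrom == ch
          if (any(pi) &&
              min(pmax(0, pmax(placed$start[pi] - (s + len),
                               s - placed$end[pi]))) < min_gap) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("capacity error: could not place peak ", i, " after ",
             max_attempts, " attempts (genome too crowded?)")
      }
      chrom[i] <- ch; st[i] <- s; en[i] <- s + len
      if (min_gap > 0) {
        placed$chrom <- c(placed$chrom, ch)
        placed$start <- c(placed$start, s)
        placed$end <- c(placed$end, s + len)
      }
    }
    peak_set(data.frame(chrom = chrom, start = st, end = en,
                        name = sprintf("%s_%d", label, seq_len(n_peaks)),
                        score = 0, strand = ".", stringsAsFactors = FALSE),
             genome, label)
  })
}

#' Simulate nested peak layers
#'
#' Chained [simulate_peaks()]: each layer after the first is anchored to the
#' previous layer with its own co-localization fraction, emulating nested
#' site classes such as pre-RC peaks that carry further factors. A single
#' layer is identical to a plain [simulate_peaks()] call.
#'
#' @param genome A [genome_model()].
#' @param layers List of per-layer argument lists (fields of
#'   [simulate_peaks()]: `label`, `n_peaks`, `length_range`, `fraction`,
#'   `window`, `min_gap`, `seed`). The first layer must not request a
#'   fraction.
#' @return Named list of [peak_set()]s in layer order.
#' @export
simulate_nested_peaks <- function(genome, layers) {
  if (!length(layers)) stop("no layers given")
  out <- list()
  prev <- NULL
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    if (is.null(ly$label)) ly$label <- paste0("layer", k)
    ps <- simulate_peaks(
      genome, n_peaks = ly$n_peaks,
      length_range = if (is.null(ly$length_range)) c(300, 1500) else ly$length_range,
      fraction = ly$fraction,
      window = if (is.null(ly$window)) 500 else ly$window,
      anchor = if (is.null(ly$fraction)) NULL else prev,
      min_gap = if (is.null(ly$min_gap)) 0 else ly$min_gap,
      seed = if (is.null(ly$seed)) k else ly$seed,
      label = ly$label)
    out[[ly$label]] <- ps
    prev <- ps
  }
  out
}

#' Simulate an enriched read set with optional matched input
#'
#' Emits exactly `n_reads` read points: each enriched peak receives a
#' Poisson-distributed count with mean `enrichment * effect`, placed
#' uniformly within the peak, and the remaining budget is uniform genomic
#' background. The matched input (if requested) is purely uniform with its
#' own budget. `effect` is the per-site multiplicative factor used to build
#' knockdown conditions (e.g. 0.7 for a 30% loss of openness at affected
#' sites).
#'
#' @param genome A [genome_model()].
#' @param enriched A [peak_set()] of enriched sites, or `NULL` for a purely
#'   uniform sample.
#' @param n_reads Total reads emitted for the sample (exact).
#' @param enrichment Mean enriched reads per peak.
#' @param effect Per-peak multiplicative factor(s), recycled to the number
#'   of peaks (default 1).
#' @param paired_input Also emit a uniform input read set?
#' @param input_n_reads Input budget (defaults to `n_reads`).
#' @param seed Integer seed.
#' @return List with `sample` (a [read_set()]) and `input` (a [read_set()]
#'   or `NULL`).
#' @export
simulate_reads <- function(genome, enriched = NULL, n_reads, enrichment = 0,
                           effect = 1, paired_input = FALSE,
                           input_n_reads = n_reads, seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_reads <= 0) stop("n_reads must be positive")
  with_seed(seed, {
    pos_ch <- character(0); pos_p <- numeric(0)
    if (!is.null(enriched) && n_peaks(enriched) > 0 && enrichment > 0) {
      df <- enriched$intervals
      np <- nrow(df)
      eff <- rep_len(effect, np)
      if (any(eff < 0)) stop("effect factors must be >= 0")
      cnt <- stats::rpois(np, enrichment * eff)
      tot <- sum(cnt)
      if (tot > n_reads) {
        stop("enrichment exceeds the read budget: ", tot, " enriched reads > ",
             n_reads, " total")
      }
      idx <- rep.int(seq_len(np), cnt)
      if (length(idx)) {
        pos_ch <- df$chrom[idx]
        pos_p <- df$start[idx] +
          floor(stats::runif(length(idx)) * (df$end[idx] - df$start[idx]))
      }
    }
    n_bg <- n_reads - length(pos_p)
    if (n_bg > 0) {
      ci <- sample.int(length(genome$chrom), n_bg, replace = TRUE,
                       prob = genome$length)
      pos_ch <- c(pos_ch, genome$chrom[ci])
      pos_p <- c(pos_p, floor(stats::runif(n_bg) * genome$length[ci]))
    }
    sample_rs <- read_set(split(pos_p, factor(pos_ch, levels = genome$chrom)),
                          genome, total_mapped = n_reads)
    input_rs <- NULL
    if (paired_input) {
      ci <- sample.int(length(genome$chrom), input_n_reads, replace = TRUE,
                       prob = genome$length)
      ip <- floor(stats::runif(input_n_reads) * genome$length[ci])
      input_rs <- read_set(split(ip, factor(genome$chrom[ci],
                                            levels = genome$chrom)),
                           genome, total_mapped = input_n_reads)
    }
    list(sample = sample_rs, input = input_rs)
  })
}

#' Simulate a gene annotation
#'
#' Non-overlapping genes with uniform lengths and random strands (+/- with
#' probability 0.5 each), deterministic under the seed.
#'
#' @param genome A [genome_model()].
#' @param n_genes Number of genes.
#' @param length_range Two-element bp range for gene lengths.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap per gene.
#' @return A [gene_annotation()].
#' @export
simulate_annotation <- function(genome, n_genes, length_range = c(1e4, 1e5),
                                seed = 1, max_attempts = 1000) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_genes == 0L) return(gene_annotation(data.frame(), genome))
  lmin <- length_range[1L]; lmax <- length_range[2L]
  with_seed(seed, {
    chrom <- character(n_genes); st <- numeric(n_genes); en <- numeric(n_genes)
    strand <- character(n_genes)
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        len <- lmin + floor(stats::runif(1) * (lmax - lmin + 1))
        ci <- sample.int(length(genome$chrom), 1L, prob = genome$length)
        L <- genome$length[ci]
        if (len > L) next
        s <- floor(stats::runif(1) * (L - len + 1))
        prev <- which(chrom[seq_len(i - 1L)] == genome$chrom[ci])
        if (length(prev) && any(s < en[prev] & st[prev] < s + len)) next
        chrom[i] <- genome$chrom[ci]; st[i] <- s; en[i] <- s + len
        strand[i] <- if (stats::runif(1) < 0.5) "+" else "-"
        ok <- TRUE
        break
      }
      if (!ok) stop("capacity error: could not place gene ", i)
    }
    gene_annotation(data.frame(gene_id = sprintf("gene%d", seq_len(n_genes)),
                               chrom = chrom, strand = strand, tx_start = st,
                               tx_end = en, stringsAsFactors = FALSE),
                    genome)
  })
}
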