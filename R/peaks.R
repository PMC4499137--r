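#' Peak set
#'
#' A labelled set of genomic intervals tied to a genome model. Coordinates are
#' 0-based half-open throughout (BED native): an interval covers bases
#' `start, ..., end - 1`. Intervals are stored sorted by chromosome (genome
#' order) and start.
#'
#' @param intervals A data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param genome A [genome_model()] the intervals must fall inside.
#' @param label Non-empty set label (e.g. `"CDC6"`, `"CDC6_w0.5_MCM7"`).
#' @return An object of class `peak_set`: a list with elements `label`,
#'   `intervals` (sorted data.frame) and `genome`.
#' @export
peak_set <- function(intervals, genome, label) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("peak set label must be a non-empty string")
  }
  df <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     name = character(), score = numeric(), strand = character(),
                     stringsAsFactors = FALSE)
  } else {
    if (!all(c("chrom", "start", "end") %in% names(df))) {
      stop("intervals need chrom/start/end columns")
    }
    df$chrom <- as.character(df$chrom)
    df$start <- as.numeric(df$start)
    df$end <- as.numeric(df$end)
    if (is.null(df$name)) df$name <- label
    if (is.null(df$score)) df$score <- 0
    if (is.null(df$strand)) df$strand <- "."
    df <- df[c("chrom", "start", "end", "name", "score", "strand")]
    ci <- match(df$chrom, genome$chrom)
    if (anyNA(ci)) {
      stop("interval on chromosome absent from genome model: ",
           df$chrom[is.na(ci)][1L])
    }
    bad <- which(df$start < 0 | df$start >= df$end | df$end > genome$length[ci])
    if (length(bad)) {
      stop(sprintf("invalid interval %s:%.0f-%.0f (bounds or ordering)",
                   df$chrom[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]))
    }
    if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
    df <- df[order(ci, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(label = label, intervals = df, genome = genome),
            class = "peak_set")
}

#' Number of peaks in a set
#' @param peaks A [peak_set()].
#' @return Integer count.
#' @export
n_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  nrow(peaks$intervals)
}

# interval midpoints, possibly half-integral
peak_midpoints <- function(peaks) {
  (peaks$intervals$start + peaks$intervals$end) / 2
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak set '%s': %d interval(s) on %d chromosome(s)\n",
              x$label, nrow(x$intervals), length(unique(x$intervals$chrom))))
  if (nrow(x$intervals)) {
    cat(sprintf("  lengths %0.f-%0.f bp (median %.0f)\n",
                min(x$intervals$end - x$intervals$start),
                max(x$intervals$end - x$intervals$start),
                stats::median(x$intervals$end - x$intervals$start)))
  }
  invisible(x)
}

#' Read a BED file into a peak set
#'
#' Accepts BED3 or BED6 with 0-based half-open coordinates. `track` and
#' `browser` header lines are skipped (MACS2 emits them). Intervals on
#' chromosomes missing from the genome model, inverted or out-of-bounds
#' coordinates are errors naming the offending line, never silent drops:
#' a silently shrunken peak set would corrupt shuffle-based null models.
#'
#' @param path Path to a BED file.
#' @param genome A [genome_model()].
#' @param label Set label; defaults to the file name without extension.
#' @return A [peak_set()], sorted per chromosome.
#' @export
read_bed <- function(path, genome, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(peak_set(data.frame(), genome, label))
  fields <- strsplit(lines, "\t")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) {
    stop("BED line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("BED line ", lineno[bad[1L]], ": non-numeric coordinate")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""), label)
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", ""))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", ""), ".")
  ci <- match(chrom, genome$chrom)
  if (anyNA(ci)) {
    stop("BED line ", lineno[which(is.na(ci))[1L]],
         ": chromosome not in genome model: ", chrom[is.na(ci)][1L])
  }
  bad <- which(start < 0 | start >= end | end > genome$length[ci])
  if (length(bad)) {
    stop("BED line ", lineno[bad[1L]], ": interval out of bounds or start >= end")
  }
  peak_set(data.frame(chrom = chrom, start = start, end = end, name = name,
                      score = score, strand = strand, stringsAsFactors = FALSE),
           genome, label)
}

#' Write a peak set as BED6
#'
#' The round trip `read_bed(write_bed(p))` reproduces coordinates, names and
#' strands exactly.
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  df <- peaks$intervals
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df)) {
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%s\t%s",
                       df$chrom, df$start, df$end, df$name,
                       format(df$score, trim = TRUE, scientific = FALSE),
                       df$strand), con)
  }
  invisible(path)
}
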