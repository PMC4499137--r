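#' Read set
#'
#' Mapped reads reduced to single reference points (fragment midpoints), the
#' raw material of moving-average coverage tracks. Positions are stored per
#' chromosome, sorted. `total_mapped` is carried separately so RPM
#' normalization can reflect the full library even if only a subset of
#' positions is stored.
#'
#' @param positions Named list (by chromosome) of integer positions in bp.
#' @param genome A [genome_model()].
#' @param total_mapped Total mapped reads; defaults to the number of stored
#'   positions.
#' @return An object of class `read_set`.
#' @export
read_set <- function(positions, genome, total_mapped = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(names(positions)) && length(positions)) {
    stop("positions must be a named list (chromosome -> positions)")
  }
  unknown <- setdiff(names(positions), genome$chrom)
  if (length(unknown)) stop("reads on chromosome absent from genome: ", unknown[1L])
  pos <- stats::setNames(vector("list", length(genome$chrom)), genome$chrom)
  for (ch in genome$chrom) {
    p <- positions[[ch]]
    if (is.null(p)) p <- numeric()
    p <- as.numeric(p)
    L <- chrom_length(genome, ch)
    if (length(p) && (min(p) < 0 || max(p) >= L)) {
      stop("read position outside chromosome ", ch)
    }
    pos[[ch]] <- sort(p)
  }
  n <- sum(vapply(pos, length, 1L))
  if (is.null(total_mapped)) total_mapped <- n
  if (total_mapped < n) stop("total_mapped smaller than number of stored positions")
  structure(list(positions = pos, genome = genome, total_mapped = total_mapped),
            class = "read_set")
}

#' Number of stored read positions
#' @param reads A [read_set()].
#' @return Integer count.
#' @export
n_reads <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  sum(vapply(reads$positions, length, 1L))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d position(s) stored, total_mapped = %.0f\n",
              n_reads(x), x$total_mapped))
  invisible(x)
}

#' Read positions from a two-column TSV
#'
#' Simple text interchange for read reference points: one `chrom<TAB>pos` row
#' per read, 0-based positions.
#'
#' @param path Path to the TSV.
#' @param genome A [genome_model()].
#' @param total_mapped Optional library size override.
#' @return A [read_set()].
#' @export
read_positions_tsv <- function(path, genome, total_mapped = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos"),
                          colClasses = c("character", "numeric"))
  read_set(split(df$pos, factor(df$chrom, levels = unique(df$chrom))),
           genome, total_mapped)
}

#' Write read positions as a two-column TSV
#' @param reads A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions_tsv <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(reads$positions)) {
    p <- reads$positions[[ch]]
    if (length(p)) writeLines(sprintf("%s\t%.0f", ch, p), con)
  }
  invisible(path)
}
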