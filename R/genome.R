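#' Genome model
#'
#' A genome model is the ordered set of chromosome names and lengths. It is
#' the sampling space for every shuffle and every synthetic generator, and its
#' total length is the single source of truth for density and mean-interval
#' calculations.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return An object of class `genome_model`: a list with elements `chrom`
#'   and `length`, preserving the given order.
#' @examples
#' g <- genome_model(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_length(g)
#' @export
genome_model <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("genome model needs at least one chromosome")
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ", chrom[duplicated(chrom)][1L])
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(list(chrom = chrom, length = length), class = "genome_model")
}

#' Read a chrom.sizes file
#'
#' Parses the standard two-column whitespace-separated chromosome-sizes format
#' (name, length), preserving file order.
#'
#' @param path Path to a chrom.sizes file.
#' @return A [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) stop("chrom.sizes line ", bad[1L], ": need two columns")
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  nonint <- which(is.na(len) | len != floor(len) | len <= 0)
  if (length(nonint)) {
    stop("chrom.sizes line ", nonint[1L], ": length is not a positive integer")
  }
  if (anyDuplicated(nm)) {
    stop("chrom.sizes line ", which(duplicated(nm))[1L], ": duplicate chromosome name")
  }
  genome_model(nm, len)
}

#' Total genome length
#' @param genome A [genome_model()].
#' @return Total length in bp.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  sum(genome$length)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("chromosome not in genome model: ", chrom[is.na(i)][1L])
  genome$length[i]
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome model:", length(x$chrom), "chromosome(s),",
      format(genome_length(x), big.mark = ","), "bp total\n")
  n <- min(length(x$chrom), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-10s %s\n", x$chrom[i], format(x$length[i], big.mark = ",")))
  }
  if (length(x$chrom) > n) cat("  ...\n")
  invisible(x)
}

#' Write a chrom.sizes file
#' @param genome A [genome_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  writeLines(sprintf("%s\t%.0f", genome$chrom, genome$length), path)
  invisible(path)
}
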