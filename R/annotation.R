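#' Gene annotation
#'
#' Strand-aware gene records with derived transcription start (TSS) and end
#' (TES) sites. On the plus strand the TSS is `tx_start`; on the minus strand
#' it is `tx_end - 1`, the last covered 0-based coordinate, so a TSS is always
#' a valid position inside the transcript.
#'
#' @param records A data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tx_start`, `tx_end` (0-based half-open).
#' @param genome A [genome_model()].
#' @return An object of class `gene_annotation`; its `records` gain derived
#'   `tss` and `tes` columns.
#' @export
gene_annotation <- function(records, genome) {
  stopifnot(inherits(genome, "genome_model"))
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(gene_id = character(), chrom = character(),
                     strand = character(), tx_start = numeric(),
                     tx_end = numeric(), tss = numeric(), tes = numeric(),
                     stringsAsFactors = FALSE)
    return(structure(list(records = df, genome = genome),
                     class = "gene_annotation"))
  }
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(df))) stop("annotation needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$tx_start <- as.numeric(df$tx_start)
  df$tx_end <- as.numeric(df$tx_end)
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(df$tx_start >= df$tx_end)) stop("gene with tx_start >= tx_end")
  ci <- match(df$chrom, genome$chrom)
  if (anyNA(ci)) stop("gene on chromosome absent from genome: ", df$chrom[is.na(ci)][1L])
  if (any(df$tx_start < 0 | df$tx_end > genome$length[ci])) {
    stop("gene outside chromosome bounds")
  }
  plus <- df$strand == "+"
  df$tss <- ifelse(plus, df$tx_start, df$tx_end - 1)
  df$tes <- ifelse(plus, df$tx_end - 1, df$tx_start)
  df <- df[order(ci, df$tx_start), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(records = df, genome = genome), class = "gene_annotation")
}

#' Number of genes in an annotation
#' @param annotation A [gene_annotation()].
#' @return Integer count.
#' @export
n_genes <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  nrow(annotation$records)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene annotation: %d gene(s) (%d +, %d -)\n",
              nrow(x$records), sum(x$records$strand == "+"),
              sum(x$records$strand == "-")))
  invisible(x)
}

#' Read a gene annotation TSV
#'
#' Five columns: gene_id, chrom, strand, tx_start, tx_end; a header row is
#' detected and skipped if the fourth column is non-numeric.
#'
#' @param path Path to the TSV.
#' @param genome A [genome_model()].
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_annotation(data.frame(), genome))
  first <- strsplit(lines[1L], "\t")[[1L]]
  skip <- if (length(first) >= 4L && is.na(suppressWarnings(as.numeric(first[4L])))) 1L else 0L
  if (length(lines) <= skip) return(gene_annotation(data.frame(), genome))
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE, skip = skip,
                          col.names = c("gene_id", "chrom", "strand",
                                        "tx_start", "tx_end"),
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric"))
  gene_annotation(df, genome)
}

#' Write a gene annotation TSV
#' @param annotation A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  df <- annotation$records
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene_id\tchrom\tstrand\ttx_start\ttx_end", con)
  if (nrow(df)) {
    writeLines(sprintf("%s\t%s\t%s\t%.0f\t%.0f", df$gene_id, df$chrom,
                       df$strand, df$tx_start, df$tx_end), con)
  }
  invisible(path)
}

#' Transcription start sites as a 1 bp peak set
#'
#' Converts each gene's TSS into a 1 bp interval so TSS proximity can be
#' tested with the same windowed co-localization machinery as peak-peak
#' comparisons.
#'
#' @param annotation A [gene_annotation()].
#' @return A [peak_set()] labelled `"TSS"`.
#' @export
tss_sites <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  df <- annotation$records
  peak_set(data.frame(chrom = df$chrom, start = df$tss, end = df$tss + 1,
                      name = df$gene_id, score = 0, strand = df$strand,
                      stringsAsFactors = FALSE),
           annotation$genome, "TSS")
}
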